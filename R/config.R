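#' Load the run configuration
#'
#' Reads the plain-text `key = value` configuration dialect shared by all
#' pipeline stages.  List-valued keys use `;` as separator and `#` starts a
#' comment.  The shipped defaults (`inst/extdata/default_config.txt`) define
#' the complete key set; a user file may override any subset of keys but
#' unknown keys are rejected, so typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param path Optional path to a user configuration file layered on top of
#'   the shipped defaults.
#' @return A named list of character values with class `pul_config`.
#' @examples
#' cfg <- read_run_config()
#' cfg[["max_gap_genes"]]
#' @export
read_run_config <- function(path = NULL) {
  def_path <- system.file("extdata", "default_config.txt",
                          package = "pulcall", mustWork = TRUE)
  cfg <- parse_config_file(def_path)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_io(paste0("config file not found: ", path))
    }
    user <- parse_config_file(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      abort_config(paste0("unknown config key(s): ",
                          paste(unknown, collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  structure(cfg, class = "pul_config")
}

parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  lines <- lines[keep]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    abort_config(sprintf("config line %d is not 'key = value': %s",
                         idx[which(bad)[1]], lines[which(bad)[1]]))
  }
  key <- trimws(sub("=.*$", "", lines))
  val <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(key)) {
    abort_config(paste0("duplicated config key: ", key[duplicated(key)][1]))
  }
  as.list(stats::setNames(val, key))
}

cfg_chr <- function(cfg, key) {
  if (is.null(cfg[[key]])) abort_config(paste0("missing config key: ", key))
  cfg[[key]]
}

cfg_num <- function(cfg, key) {
  v <- suppressWarnings(as.numeric(cfg_chr(cfg, key)))
  if (is.na(v)) abort_config(paste0("config key ", key, " is not numeric"))
  v
}

cfg_list <- function(cfg, key) {
  toks <- trimws(strsplit(cfg_chr(cfg, key), ";", fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

#' Role-signature configuration
#'
#' Extracts the accession sets that map domain hits to gene roles.  Sets
#' feeding the same role priority (the three regulator subtypes) must be
#' disjoint; an overlap would make the role assignment ambiguous and is
#' rejected as a configuration error.
#'
#' @param config A `pul_config`, usually from [read_run_config()].
#' @return A list with elements `susc`, `susd`, `sulfatase`, `htcs`
#'   (sensor/response/output), `ecf` (r2/r4), `anti_sigma`,
#'   `cazyme_prefixes`.
#' @export
role_config <- function(config = read_run_config()) {
  rc <- list(
    susc      = cfg_list(config, "susc_domains"),
    susd      = cfg_list(config, "susd_domains"),
    sulfatase = cfg_list(config, "sulfatase_domains"),
    htcs = list(sensor   = cfg_list(config, "htcs_sensor_domains"),
                response = cfg_list(config, "htcs_response_domains"),
                output   = cfg_list(config, "htcs_output_domains")),
    ecf  = list(r2 = cfg_list(config, "ecf_sigma_r2_domains"),
                r4 = cfg_list(config, "ecf_sigma_r4_domains")),
    anti_sigma = cfg_list(config, "anti_sigma_domains"),
    cazyme_prefixes = cfg_list(config, "cazyme_class_prefixes")
  )
  if (!length(rc$susc)) abort_config("susc_domains must be non-empty")
  if (!length(rc$susd)) abort_config("susd_domains must be non-empty")
  reg_sets <- list(HTCS = unlist(rc$htcs, use.names = FALSE),
                   ECF_SIGMA = unlist(rc$ecf, use.names = FALSE),
                   ANTI_SIGMA = rc$anti_sigma)
  for (i in seq_along(reg_sets)) {
    for (j in seq_along(reg_sets)) {
      if (i < j && length(intersect(reg_sets[[i]], reg_sets[[j]]))) {
        abort_config(sprintf(
          "regulator signatures %s and %s share accession(s) %s: equal-priority roles must be disjoint",
          names(reg_sets)[i], names(reg_sets)[j],
          paste(intersect(reg_sets[[i]], reg_sets[[j]]), collapse = ", ")))
      }
    }
  }
  rc
}

#' Locus-extension (gap rule) configuration
#'
#' @param config A `pul_config`, usually from [read_run_config()].
#' @param max_gap_genes,max_gap_bp,pair_max_gap_genes,pair_orientation
#'   Optional overrides of the corresponding config keys.
#' @return A list with the four gap-rule settings.
#' @export
gap_config <- function(config = read_run_config(),
                       max_gap_genes = NULL, max_gap_bp = NULL,
                       pair_max_gap_genes = NULL, pair_orientation = NULL) {
  gc <- list(
    max_gap_genes      = max_gap_genes %||% cfg_num(config, "max_gap_genes"),
    max_gap_bp         = max_gap_bp %||% cfg_num(config, "max_gap_bp"),
    pair_max_gap_genes = pair_max_gap_genes %||%
      cfg_num(config, "pair_max_gap_genes"),
    pair_orientation   = pair_orientation %||%
      cfg_chr(config, "pair_orientation")
  )
  if (!gc$pair_orientation %in% c("transcription", "coordinate")) {
    abort_config("pair_orientation must be 'transcription' or 'coordinate'")
  }
  if (gc$max_gap_genes < 0 || gc$max_gap_bp < 0 || gc$pair_max_gap_genes < 0) {
    abort_config("gap rule settings must be non-negative")
  }
  gc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
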