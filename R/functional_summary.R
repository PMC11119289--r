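# Tabulation arithmetic behind functional-category (GO/COG/KEGG-style)
# summaries and the CAZyme class composition profile.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Build a category count table
#'
#' Aggregates gene-to-category assignments into per-category gene counts.  A
#' gene carrying the same category several times is counted once for that
#' category; a gene with several distinct categories contributes to each.
#'
#' @param assignments `data.frame` with columns `gene_id` and `category`
#'   (non-empty strings).
#' @param scheme Label for the classification scheme (e.g. `"GO-namespace"`,
#'   `"COG-letter"`).
#' @return A `category_table`: list with `scheme`, `rows` (a `data.frame`
#'   of `category`, `count` sorted by count descending then label) and
#'   `total`.
#' @examples
#' tab <- build_category_table(
#'   data.frame(gene_id = c("g1", "g2", "g3"),
#'              category = c("MF", "MF", "BP")), "GO-namespace")
#' category_share(tab, "MF")
#' @export
build_category_table <- function(assignments, scheme) {
  if (!all(c("gene_id", "category") %in% names(assignments))) {
    abort_parse("assignments need gene_id and category columns")
  }
  if (nrow(assignments) && any(!nzchar(assignments$category))) {
    abort_parse("categories must be non-empty strings")
  }
  uniq <- unique(assignments[, c("gene_id", "category")])
  if (!nrow(uniq)) {
    rows <- data.frame(category = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    tab <- table(uniq$category)
    rows <- data.frame(category = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$count, rows$category), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(scheme = scheme, rows = rows, total = sum(rows$count)),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("category_table (%s): %d categories, %d assignments\n",
              x$scheme, nrow(x$rows), x$total))
  print(x$rows, ...)
  invisible(x)
}

#' Percentage share of one category
#'
#' `100 * count / total`, rounded half-up to two decimals -- the printed
#' precision of genome-annotation reports.
#'
#' @param table A `category_table`.
#' @param category Category label; must be present in the table.
#' @return Percentage with two decimals.
#' @export
category_share <- function(table, category) {
  if (table$total == 0) abort_lookup("category table has total 0")
  i <- match(category, table$rows$category)
  if (is.na(i)) abort_lookup(paste0("category not in table: ", category))
  round_half_up(100 * table$rows$count[i] / table$total, 2)
}

#' Percentage share of a subcategory within a parent
#'
#' @param count Genes in the subcategory.
#' @param parent_total Genes in the parent category (`> 0`).
#' @return `100 * count / parent_total`, rounded half-up to two decimals.
#' @export
subcategory_share <- function(count, parent_total) {
  if (parent_total <= 0) abort_lookup("parent_total must be > 0")
  if (count < 0 || count > parent_total) {
    abort_lookup("count must lie in [0, parent_total]")
  }
  round_half_up(100 * count / parent_total, 2)
}

#' CAZyme class composition of a role assignment
#'
#' The class of a family label is its leading letter prefix (GH, GT, PL, CE,
#' AA, CBM).  A gene with families in several classes contributes one count
#' to each such class.  Labels with an unrecognised prefix are collected in
#' an "other" bucket (with a warning) and excluded from the proportions.
#'
#' @param roles Role assignments from [assign_roles()], or any `data.frame`
#'   with `role` and `families` columns.
#' @param prefixes Recognised class prefixes.
#' @return A `cazyme_profile`: list with integer `counts` per class,
#'   `proportions` (all `NA` with `proportions_defined = FALSE` when no
#'   class count is positive), `other` labels and `n_genes`.
#' @export
cazyme_class_profile <- function(roles,
                                 prefixes = c("GH", "GT", "PL", "CE", "AA",
                                              "CBM")) {
  caz <- roles[roles$role == "CAZYME", , drop = FALSE]
  counts <- stats::setNames(integer(length(prefixes)), prefixes)
  other <- character(0)
  for (f in caz$families) {
    toks <- trimws(unlist(strsplit(f, "[;|+]")))
    toks <- toks[nzchar(toks)]
    cls <- sub("^([A-Z]+).*$", "\\1", toks)
    known <- cls %in% prefixes
    if (any(!known)) other <- c(other, toks[!known])
    for (cl in unique(cls[known])) counts[cl] <- counts[cl] + 1L
  }
  if (length(other)) {
    warning(sprintf("%d family label(s) with unrecognised class prefix counted under 'other': %s",
                    length(other),
                    paste(utils::head(unique(other), 5), collapse = ", ")),
            call. = FALSE)
  }
  tot <- sum(counts)
  structure(list(
    counts = counts,
    proportions = if (tot > 0) counts / tot else
      stats::setNames(rep(NA_real_, length(prefixes)), prefixes),
    proportions_defined = tot > 0,
    other = unique(other),
    n_genes = nrow(caz)
  ), class = "cazyme_profile")
}

#' @export
print.cazyme_profile <- function(x, ...) {
  cat(sprintf("cazyme_profile over %d CAZyme gene(s)\n", x$n_genes))
  print(data.frame(class = names(x$counts), count = as.integer(x$counts),
                   proportion = round(x$proportions, 4)))
  invisible(x)
}

#' Write a category table (with shares) as TSV
#'
#' @param table A `category_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(table, path) {
  df <- table$rows
  df$share_percent <- vapply(df$category, function(cat) {
    category_share(table, cat)
  }, numeric(1))
  df <- cbind(scheme = table$scheme, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-category assignment table
#'
#' Dialect: tab-separated `gene_id`, `scheme`, `category` with a header.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the three columns.
#' @export
read_category_tsv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("assignment table not found: ", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) abort_parse(paste0("cannot parse ", path, ": ",
                                           conditionMessage(e))))
  if (!all(c("gene_id", "scheme", "category") %in% names(df))) {
    abort_parse("assignment table needs gene_id, scheme, category columns")
  }
  df
}
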