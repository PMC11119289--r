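# Substrate inference: score each locus against CAZyme-family signature
# sets for the four marine algal polysaccharides.

#' Default substrate signatures
#'
#' Builds the four shipped signatures from the configuration: alginate
#' (lyase families PL6/PL7/PL8), fucoidan (fucosidase families
#' GH29/GH95/GH141, sulfatase co-occurrence as accessory evidence since the
#' substrate is sulfated), laminarin (beta-1,3-glucanase families
#' GH3/GH16/GH51) and porphyran (GH16/GH86 porphyranase context, GH2 as
#' accessory).  A distinct matched core family contributes `core_weight`
#' (default 1.0) to the score and a distinct accessory family
#' `accessory_weight` (default 0.5).
#'
#' @param config A `pul_config`; substrates are discovered from
#'   `substrate.<name>.core` keys, so user configs can retune the sets.
#' @return A list of signatures, each a list with `substrate`, `core`,
#'   `accessory`, `core_weight`, `accessory_weight`.
#' @export
default_signatures <- function(config = read_run_config()) {
  keys <- grep("^substrate\\.[^.]+\\.core$", names(config), value = TRUE)
  substrates <- sort(sub("^substrate\\.([^.]+)\\.core$", "\\1", keys))
  cw <- cfg_num(config, "core_weight")
  aw <- cfg_num(config, "accessory_weight")
  lapply(substrates, function(s) {
    core <- cfg_list(config, paste0("substrate.", s, ".core"))
    acc_key <- paste0("substrate.", s, ".accessory")
    accessory <- if (is.null(config[[acc_key]])) character(0) else
      cfg_list(config, acc_key)
    if (!length(core)) {
      abort_config(paste0("substrate ", s, " has an empty core family set"))
    }
    if (length(intersect(core, accessory))) {
      abort_config(paste0("substrate ", s,
                          ": core and accessory families must be disjoint"))
    }
    structure(list(substrate = s, core = core, accessory = accessory,
                   core_weight = cw, accessory_weight = aw),
              class = "substrate_signature")
  })
}

#' Score one locus against substrate signatures
#'
#' Matching is on distinct features only: family multiplicity within the
#' locus does not raise the score.  The feature set is the locus's distinct
#' CAZyme families plus the pseudo-feature `SULFATASE` when the locus
#' contains a sulfatase gene.  One call is emitted per signature with at
#' least one matched family; calls are sorted by score (descending) and then
#' substrate name, so ties resolve alphabetically.
#'
#' @param pul A `pul` object (or anything with `cazyme_families` and
#'   `n_sulfatase` fields).
#' @param signatures Signature list from [default_signatures()].
#' @return A `data.frame` with columns `substrate`, `score`, `evidence`
#'   (`;`-joined `family(core)` / `family(accessory)` tokens); zero rows
#'   when nothing matches.
#' @examples
#' sig <- default_signatures()
#' pul <- list(cazyme_families = c("GH29", "GH95"), n_sulfatase = 1L)
#' map_substrates(pul, sig)
#' @export
map_substrates <- function(pul, signatures = default_signatures()) {
  feats <- unique(pul$cazyme_families)
  if (isTRUE(pul$n_sulfatase > 0)) feats <- c(feats, "SULFATASE")
  calls <- lapply(signatures, function(sig) {
    core_hit <- sort(intersect(sig$core, feats))
    acc_hit <- sort(intersect(sig$accessory, feats))
    score <- sig$core_weight * length(core_hit) +
      sig$accessory_weight * length(acc_hit)
    if (score <= 0) return(NULL)
    data.frame(
      substrate = sig$substrate, score = score,
      evidence = paste(c(sprintf("%s(core)", core_hit),
                         sprintf("%s(accessory)", acc_hit)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    return(data.frame(substrate = character(0), score = numeric(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  calls <- calls[order(-calls$score, calls$substrate), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Attach substrate calls to every locus of a set
#'
#' @param puls A `pul_set` from [predict_puls()].
#' @param signatures Signature list from [default_signatures()].
#' @return The `pul_set` with each locus's `substrate_calls` field filled as
#'   `substrate:score` strings (score at one decimal).
#' @export
annotate_substrates <- function(puls, signatures = default_signatures()) {
  for (i in seq_along(puls)) {
    calls <- map_substrates(puls[[i]], signatures)
    puls[[i]]$substrate_calls <- sprintf("%s:%.1f", calls$substrate,
                                         calls$score)
  }
  puls
}
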