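# PUL calling: role assignment from domain hits, tandem SusC/SusD pair
# detection, outward extension over CAZyme/sulfatase/regulator neighbours,
# and merging of overlapping loci.

ROLE_PRIORITY <- c("SUSC", "SUSD", "CAZYME", "SULFATASE", "REGULATOR")
ABSORBABLE_ROLES <- c("SUSC", "SUSD", "CAZYME", "SULFATASE", "REGULATOR")

# Extract CAZyme family labels (GH16, PL8, CBM4, ...) from accession
# strings.  Compound labels such as "GH16|CBM4" contribute each component.
cazyme_families_from_accessions <- function(accessions, prefixes) {
  toks <- trimws(unlist(strsplit(accessions, "[|+]")))
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")[0-9]+(_[0-9]+)?$")
  sort(unique(toks[grepl(pat, toks)]))
}

#' Assign a functional role to every gene
#'
#' Derives the PUL-relevant role of each gene from its domain hits: SusC-like
#' transporter (all SusC signature domains present), SusD-like binding
#' protein, CAZyme (any recognised family label), sulfatase, regulator
#' (HTCS, ECF-sigma or anti-sigma subtypes), or unknown.  When a gene
#' matches several signatures the role is resolved by the fixed priority
#' SusC > SusD > CAZyme > sulfatase > regulator, with a warning; the
#' transporter signatures anchor the loci, so they win conflicts.
#'
#' @param bundle An [annotation_bundle()].
#' @param rc Role-signature sets from [role_config()].
#' @param warn Emit a warning when a gene matches multiple signatures.
#' @return A `data.frame` with one row per gene: `gene_id`, `role`,
#'   `families` (`;`-joined, sorted, non-empty only for CAZymes) and
#'   `regulator_kind` (`HTCS`, `ECF_SIGMA`, `ANTI_SIGMA` or `NONE`).
#' @export
assign_roles <- function(bundle, rc = role_config(), warn = TRUE) {
  genes <- bundle$genes
  acc_by_gene <- split(bundle$hits$accession,
                       factor(bundle$hits$gene_id, levels = genes$gene_id))
  n <- nrow(genes)
  role <- character(n)
  families <- character(n)
  regulator_kind <- character(n)
  for (i in seq_len(n)) {
    acc <- unique(acc_by_gene[[i]])
    fams <- cazyme_families_from_accessions(acc, rc$cazyme_prefixes)
    cand <- character(0)
    if (all(rc$susc %in% acc)) cand <- c(cand, "SUSC")
    if (any(acc %in% rc$susd)) cand <- c(cand, "SUSD")
    if (length(fams)) cand <- c(cand, "CAZYME")
    if (any(acc %in% rc$sulfatase)) cand <- c(cand, "SULFATASE")
    kind <- "NONE"
    if (any(acc %in% rc$htcs$sensor) && any(acc %in% rc$htcs$response) &&
        any(acc %in% rc$htcs$output)) {
      kind <- "HTCS"
    } else if (any(acc %in% rc$ecf$r2) && any(acc %in% rc$ecf$r4)) {
      kind <- "ECF_SIGMA"
    } else if (any(acc %in% rc$anti_sigma)) {
      kind <- "ANTI_SIGMA"
    }
    if (kind != "NONE") cand <- c(cand, "REGULATOR")
    if (!length(cand)) {
      role[i] <- "UNKNOWN"
    } else {
      cand <- cand[order(match(cand, ROLE_PRIORITY))]
      role[i] <- cand[1]
      if (warn && length(cand) > 1) {
        warning(sprintf(
          "gene %s matches multiple role signatures (%s); assigned %s by priority",
          genes$gene_id[i], paste(cand, collapse = ", "), role[i]),
          call. = FALSE)
      }
    }
    families[i] <- if (role[i] == "CAZYME") paste(fams, collapse = ";") else ""
    regulator_kind[i] <- if (role[i] == "REGULATOR") kind else "NONE"
  }
  data.frame(gene_id = genes$gene_id, role = role, families = families,
             regulator_kind = regulator_kind, stringsAsFactors = FALSE)
}

role_vector <- function(genes, roles) {
  roles$role[match(genes$gene_id, roles$gene_id)]
}

#' Find tandem SusC/SusD pair blocks
#'
#' A block is a maximal run of one or more SusC-like genes followed
#' immediately -- in transcription order, with no intervening gene by
#' default -- by one or more SusD-like genes, all on one contig and one
#' strand.  On the minus strand "upstream" means higher coordinates, so the
#' plus-coordinate pattern there is SusD then SusC.  Runs with extra
#' consecutive SusC or SusD genes (tandem duplications) are absorbed into a
#' single block.
#'
#' @param genes Gene table sorted by (contig, start), as in an
#'   [annotation_bundle()].
#' @param roles Role assignments from [assign_roles()].
#' @param gap_cfg Gap-rule settings from [gap_config()]; uses
#'   `pair_max_gap_genes` and `pair_orientation`.
#' @return A list of pair blocks, each a list with `contig`, `strand`,
#'   `susc_gene_ids`, `susd_gene_ids` (both in transcription order),
#'   `gene_ids` (coordinate order), `start`, `end`.
#' @export
find_tandem_pairs <- function(genes, roles, gap_cfg = gap_config()) {
  r <- role_vector(genes, roles)
  blocks <- list()
  for (ct in unique(genes$contig)) {
    idx <- which(genes$contig == ct)
    m <- length(idx)
    i <- 1L
    while (i <= m) {
      k <- idx[i]
      s <- genes$strand[k]
      minus_like <- s == "-" && gap_cfg$pair_orientation == "transcription"
      first <- if (minus_like) "SUSD" else "SUSC"
      second <- if (minus_like) "SUSC" else "SUSD"
      if (r[k] != first) { i <- i + 1L; next }
      j <- i
      while (j < m && r[idx[j + 1L]] == first && genes$strand[idx[j + 1L]] == s) {
        j <- j + 1L
      }
      # allow up to pair_max_gap_genes intervening genes before the partner run
      p <- j + 1L
      skipped <- 0L
      while (p <= m && skipped < gap_cfg$pair_max_gap_genes &&
             !(r[idx[p]] == second && genes$strand[idx[p]] == s)) {
        p <- p + 1L
        skipped <- skipped + 1L
      }
      if (p <= m && r[idx[p]] == second && genes$strand[idx[p]] == s) {
        e <- p
        while (e < m && r[idx[e + 1L]] == second && genes$strand[idx[e + 1L]] == s) {
          e <- e + 1L
        }
        run1 <- genes$gene_id[idx[i:j]]
        run2 <- genes$gene_id[idx[p:e]]
        member_idx <- idx[i:e]
        if (minus_like) {
          # transcription order on '-' runs right-to-left
          susc <- rev(run2)
          susd <- rev(run1)
        } else {
          susc <- run1
          susd <- run2
        }
        blocks[[length(blocks) + 1L]] <- list(
          contig = ct, strand = s,
          susc_gene_ids = susc, susd_gene_ids = susd,
          gene_ids = genes$gene_id[member_idx],
          start = min(genes$start[member_idx]),
          end = max(genes$end[member_idx]))
        i <- e + 1L
      } else {
        i <- j + 1L
      }
    }
  }
  blocks
}

#' Extend a tandem pair block into a full locus
#'
#' Starting from the block, walks outward in both directions absorbing genes
#' whose role is CAZyme, sulfatase, regulator, SusC or SusD.  Extension in a
#' direction stops when more than `max_gap_genes` consecutive unknown genes
#' would have to be crossed, when two neighbouring genes are separated by
#' more than `max_gap_bp` intergenic bases, or at a contig end.  Unknown
#' genes interior to the final span stay in the member list.
#'
#' @param block One pair block from [find_tandem_pairs()].
#' @param genes Gene table sorted by (contig, start).
#' @param roles Role assignments from [assign_roles()].
#' @param gap_cfg Gap-rule settings from [gap_config()].
#' @return An object of class `pul`.
#' @export
extend_to_pul <- function(block, genes, roles, gap_cfg = gap_config()) {
  idx <- which(genes$contig == block$contig)
  g <- genes[idx, , drop = FALSE]
  r <- role_vector(g, roles)
  pos <- match(block$gene_ids, g$gene_id)
  lo <- min(pos)
  hi <- max(pos)
  n <- nrow(g)

  extend_dir <- function(edge, dir) {
    last <- edge
    pending <- 0L
    m <- edge + dir
    while (m >= 1L && m <= n) {
      a <- if (dir > 0L) m - 1L else m
      b <- if (dir > 0L) m else m + 1L
      gap_bp <- g$start[b] - g$end[a] - 1L
      if (gap_bp > gap_cfg$max_gap_bp) break
      if (r[m] == "UNKNOWN") {
        pending <- pending + 1L
        if (pending > gap_cfg$max_gap_genes) break
      } else if (r[m] %in% ABSORBABLE_ROLES) {
        last <- m
        pending <- 0L
      } else {
        break
      }
      m <- m + dir
    }
    last
  }

  lo <- extend_dir(lo, -1L)
  hi <- extend_dir(hi, +1L)
  new_pul(g, roles, lo:hi, list(block))
}

# Build a pul object from member row indices of a per-contig gene table.
new_pul <- function(ctg_genes, roles, member_idx, pair_blocks,
                    pul_id = NA_character_) {
  member_idx <- sort(unique(member_idx))
  g <- ctg_genes[member_idx, , drop = FALSE]
  rdf <- roles[match(g$gene_id, roles$gene_id), , drop = FALSE]
  fams <- unlist(lapply(rdf$families[rdf$role == "CAZYME"], function(f) {
    strsplit(f, ";", fixed = TRUE)[[1]]
  }), use.names = FALSE)
  fams <- fams[nzchar(fams %||% character(0))]
  strands <- unique(vapply(pair_blocks, `[[`, character(1), "strand"))
  structure(list(
    pul_id = pul_id,
    contig = g$contig[1],
    start = min(g$start),
    end = max(g$end),
    strand_consensus = if (length(strands) == 1) strands else ".",
    gene_ids = g$gene_id,
    pair_blocks = pair_blocks,
    cazyme_families = fams %||% character(0),
    regulators = rdf$regulator_kind[rdf$role == "REGULATOR"],
    n_sulfatase = sum(rdf$role == "SULFATASE"),
    cazyme_free = length(fams) == 0,
    substrate_calls = character(0)
  ), class = "pul")
}

#' @export
print.pul <- function(x, ...) {
  cat(sprintf("%s %s:%d-%d (%s) %d genes, %d pair block(s)%s\n",
              x$pul_id, x$contig, x$start, x$end, x$strand_consensus,
              length(x$gene_ids), length(x$pair_blocks),
              if (x$cazyme_free) ", cazyme-free" else
                paste0(", families: ",
                       paste(sort(unique(x$cazyme_families)), collapse = ","))))
  invisible(x)
}

#' @export
print.pul_set <- function(x, ...) {
  cat(sprintf("pul_set with %d predicted locus/loci\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' Predict polysaccharide utilization loci
#'
#' Full locus-calling procedure: assign gene roles from domain hits, detect
#' tandem SusC/SusD pair blocks, extend each block across its gene
#' neighbourhood, merge loci whose genomic spans overlap (union of members,
#' pair blocks concatenated), and number the result `PUL1`, `PUL2`, ... in
#' (contig, start) order.
#'
#' @param bundle An [annotation_bundle()] with genes and domain hits.
#' @param config A `pul_config`; used for both role and gap settings unless
#'   overridden.
#' @param rc Role-signature sets ([role_config()]).
#' @param gap_cfg Gap-rule settings ([gap_config()]).
#' @param warn Passed to [assign_roles()].
#' @return A `pul_set`: list of `pul` objects, with the role table attached
#'   as attribute `roles`.
#' @examples
#' sim <- generate_genome(genome_sim_spec(n_puls = 3, seed = 1))
#' predict_puls(sim$bundle)
#' @export
predict_puls <- function(bundle, config = read_run_config(),
                         rc = role_config(config),
                         gap_cfg = gap_config(config), warn = TRUE) {
  roles <- assign_roles(bundle, rc, warn = warn)
  blocks <- find_tandem_pairs(bundle$genes, roles, gap_cfg)
  puls <- lapply(blocks, extend_to_pul, genes = bundle$genes, roles = roles,
                 gap_cfg = gap_cfg)
  puls <- merge_overlapping_puls(puls, bundle$genes, roles)
  ord <- order(vapply(puls, `[[`, character(1), "contig"),
               vapply(puls, `[[`, numeric(1), "start"))
  puls <- puls[ord]
  for (i in seq_along(puls)) puls[[i]]$pul_id <- paste0("PUL", i)
  structure(puls, class = "pul_set", roles = roles)
}

merge_overlapping_puls <- function(puls, genes, roles) {
  if (length(puls) < 2) return(puls)
  out <- list()
  for (ct in unique(vapply(puls, `[[`, character(1), "contig"))) {
    ctg_genes <- genes[genes$contig == ct, , drop = FALSE]
    ps <- Filter(function(p) p$contig == ct, puls)
    ps <- ps[order(vapply(ps, `[[`, numeric(1), "start"))]
    cur_idx <- match(ps[[1]]$gene_ids, ctg_genes$gene_id)
    cur_blocks <- ps[[1]]$pair_blocks
    cur_end <- ps[[1]]$end
    flush <- function() {
      out[[length(out) + 1L]] <<- new_pul(ctg_genes, roles, cur_idx, cur_blocks)
    }
    for (p in ps[-1]) {
      if (p$start <= cur_end) {
        cur_idx <- union(cur_idx, match(p$gene_ids, ctg_genes$gene_id))
        cur_blocks <- c(cur_blocks, p$pair_blocks)
        cur_end <- max(cur_end, p$end)
      } else {
        flush()
        cur_idx <- match(p$gene_ids, ctg_genes$gene_id)
        cur_blocks <- p$pair_blocks
        cur_end <- p$end
      }
    }
    flush()
  }
  out
}
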