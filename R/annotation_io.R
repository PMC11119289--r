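#' Construct an annotation bundle
#'
#' An annotation bundle is the in-memory carrier for one annotated genome:
#' a gene table plus a table of per-gene domain/CAZyme hits.  Coordinates are
#' GFF3-style, 1-based and inclusive, throughout the package; the 0-based
#' half-open BED convention appears only in [write_pul_bed()].
#'
#' @param genes `data.frame` with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand` and optionally `product`.
#' @param hits `data.frame` with columns `gene_id`, `source`, `accession`,
#'   `evalue`, `coverage` (the last two may be `NA`).
#' @param provenance Free-text description of where the annotation came from.
#' @return An object of class `annotation_bundle`: a list with elements
#'   `genes` (sorted by contig then start), `hits` and `provenance`.
#' @export
annotation_bundle <- function(genes, hits = empty_domain_hits(),
                              provenance = "") {
  req <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    abort_parse(paste0("gene table lacks column(s): ",
                       paste(setdiff(req, names(genes)), collapse = ", ")))
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(is.na(genes$start)) || any(is.na(genes$end))) {
    abort_parse("gene coordinates must be integers")
  }
  if (any(genes$start < 1L) || any(genes$end < genes$start)) {
    bad <- which(genes$start < 1L | genes$end < genes$start)[1]
    abort_parse(sprintf("gene %s violates 1 <= start <= end (%d-%d)",
                        genes$gene_id[bad], genes$start[bad], genes$end[bad]))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_parse("gene strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort_parse(paste0("duplicated gene_id: ",
                       genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  ord <- order(genes$contig, genes$start, genes$end)
  genes <- genes[ord, c(req, "product"), drop = FALSE]
  rownames(genes) <- NULL
  hreq <- c("gene_id", "source", "accession", "evalue", "coverage")
  if (!all(hreq %in% names(hits))) {
    abort_parse("domain hit table lacks required columns")
  }
  orphan <- setdiff(hits$gene_id, genes$gene_id)
  if (length(orphan)) {
    abort_parse(paste0("domain hits refer to unknown gene(s): ",
                       paste(utils::head(orphan, 3), collapse = ", ")))
  }
  structure(list(genes = genes, hits = hits[, hreq, drop = FALSE],
                 provenance = provenance),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("annotation_bundle: %d genes on %d contig(s), %d domain hits\n",
              nrow(x$genes), length(unique(x$genes$contig)), nrow(x$hits)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

empty_domain_hits <- function() {
  data.frame(gene_id = character(), source = character(),
             accession = character(), evalue = numeric(),
             coverage = numeric(), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# GFF3

#' Read gene models from a GFF3 file
#'
#' Reads features of type `CDS` (falling back to `gene` when the file has no
#' CDS features; annotation pipelines differ on which level carries locus
#' tags).  The gene identifier is taken from the first of the `ID=`,
#' `locus_tag=` and `Name=` attributes.  Malformed lines are reported with
#' their line number.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type `"auto"` (default), `"CDS"` or `"gene"`.
#' @return An [annotation_bundle()] with genes only (no domain hits).
#' @export
parse_gff <- function(path, feature_type = c("auto", "CDS", "gene")) {
  feature_type <- match.arg(feature_type)
  if (!file.exists(path)) abort_io(paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "##FASTA")) break
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      abort_parse(sprintf(
        "GFF3 parse error at line %d: expected 9 tab-separated fields, found %d",
        ln, length(fields)))
    }
    type <- fields[3]
    if (!type %in% c("gene", "CDS")) next
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      abort_parse(sprintf("GFF3 parse error at line %d: non-integer coordinates", ln))
    }
    if (start < 1L || end < start) {
      abort_parse(sprintf(
        "GFF3 parse error at line %d: coordinates violate 1 <= start <= end (%d-%d)",
        ln, start, end))
    }
    if (!fields[7] %in% c("+", "-")) {
      abort_parse(sprintf("GFF3 parse error at line %d: strand must be '+' or '-'", ln))
    }
    attrs <- parse_gff_attributes(fields[9])
    id <- attrs[["ID"]] %||% attrs[["locus_tag"]] %||% attrs[["Name"]]
    if (is.null(id)) {
      abort_parse(sprintf(
        "feature at line %d (%s:%d-%d, type %s) has no ID=, locus_tag= or Name= attribute",
        ln, fields[1], start, end, type))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = id, contig = fields[1], start = start, end = end,
      strand = fields[7], product = attrs[["product"]] %||% NA_character_,
      type = type, stringsAsFactors = FALSE)
  }
  if (!length(recs)) abort_parse(paste0("no gene or CDS features in ", path))
  genes <- do.call(rbind, recs)
  use_type <- switch(feature_type,
    auto = if (any(genes$type == "CDS")) "CDS" else "gene",
    feature_type)
  genes <- genes[genes$type == use_type, , drop = FALSE]
  if (!nrow(genes)) {
    abort_parse(sprintf("no features of type %s in %s", use_type, path))
  }
  genes$type <- NULL
  annotation_bundle(genes,
                    provenance = paste0("parsed from ", basename(path),
                                        " (", use_type, " features)"))
}

parse_gff_attributes <- function(s) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    val <- utils::URLdecode(substr(kv, eq + 1, nchar(kv)))
    out[[key]] <- val
  }
  out
}

#' Write gene models as GFF3
#'
#' @param bundle An [annotation_bundle()].
#' @param path Output path.
#' @param feature_type Feature type to write (`"CDS"` by default).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(bundle, path, feature_type = "CDS") {
  g <- bundle$genes
  attrs <- sprintf("ID=%s", g$gene_id)
  has_prod <- !is.na(g$product) & nzchar(g$product)
  attrs[has_prod] <- paste0(attrs[has_prod], ";product=", g$product[has_prod])
  lines <- c("##gff-version 3",
             sprintf("%s\tpulcall\t%s\t%d\t%d\t.\t%s\t0\t%s",
                     g$contig, feature_type, g$start, g$end, g$strand, attrs))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(paste0("cannot write GFF3 to ", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Domain / CAZyme TSV dialect

#' Read a domain or CAZyme assignment table
#'
#' Expects the tab-separated dialect
#' `gene_id<TAB>accessions[<TAB>evalue[<TAB>coverage]]` with a header line;
#' the `accessions` field is a `;`-separated list and `#` lines are ignored.
#' One hit row is emitted per (gene, accession) combination.
#'
#' @param path Path to the TSV file.
#' @param source Catalog label stored with every hit (e.g. `"pfam"`,
#'   `"cazyme"`).
#' @return A `data.frame` of domain hits (`gene_id`, `source`, `accession`,
#'   `evalue`, `coverage`).
#' @export
parse_domain_tsv <- function(path, source = "cazyme") {
  if (!file.exists(path)) abort_io(paste0("domain table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) abort_parse(paste0("empty domain table: ", path))
  allowed <- c("gene_id\taccessions",
               "gene_id\taccessions\tevalue",
               "gene_id\taccessions\tevalue\tcoverage")
  header <- lines[1]
  if (!header %in% allowed) {
    abort_parse(paste0("unrecognised domain table header: ", header))
  }
  ncol <- length(strsplit(header, "\t", fixed = TRUE)[[1]])
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; restore them from the tab count
    n_tabs <- nchar(lines[i]) - nchar(gsub("\t", "", lines[i], fixed = TRUE))
    if (length(fields) < n_tabs + 1L) {
      fields <- c(fields, rep("", n_tabs + 1L - length(fields)))
    }
    if (length(fields) != ncol) {
      abort_parse(sprintf("domain table line %d: expected %d fields, found %d",
                          lnum[i], ncol, length(fields)))
    }
    accs <- trimws(strsplit(fields[2], ";", fixed = TRUE)[[1]])
    if (any(!nzchar(accs))) {
      warning(sprintf("domain table line %d: empty accession token skipped",
                      lnum[i]), call. = FALSE)
      accs <- accs[nzchar(accs)]
    }
    if (!length(accs)) next
    ev <- NA_real_
    cov <- NA_real_
    if (ncol >= 3 && nzchar(fields[3])) {
      ev <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(ev)) {
        abort_parse(sprintf("domain table line %d: non-numeric evalue", lnum[i]))
      }
      if (ev < 0) {
        abort_parse(sprintf("domain table line %d: negative evalue %g",
                            lnum[i], ev))
      }
    }
    if (ncol >= 4 && nzchar(fields[4])) {
      cov <- suppressWarnings(as.numeric(fields[4]))
      if (is.na(cov) || cov < 0 || cov > 1) {
        abort_parse(sprintf("domain table line %d: coverage outside [0,1]",
                            lnum[i]))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = fields[1], source = source, accession = accs,
      evalue = ev, coverage = cov, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_domain_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write domain hits in the package TSV dialect
#'
#' One row per hit, so that a parse/write/parse cycle is the identity.
#'
#' @param hits Domain hit `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(hits, path) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE,
                                                 trim = TRUE, digits = 15))
  lines <- c("gene_id\taccessions\tevalue\tcoverage",
             if (nrow(hits)) sprintf("%s\t%s\t%s\t%s", hits$gene_id,
                                     hits$accession, fmt(hits$evalue),
                                     fmt(hits$coverage)))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_io(paste0("cannot write domain table to ", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# PUL table / BED writers

pul_table_columns <- c("pul_id", "contig", "start", "end", "n_genes",
                       "n_pairs", "strand_consensus", "cazyme_families",
                       "regulators", "substrate_calls", "gene_ids")

#' Serialise a PUL set as a TSV table
#'
#' Columns: `pul_id`, `contig`, `start`, `end`, `n_genes`, `n_pairs`,
#' `strand_consensus`, `cazyme_families` (`;`-joined, sorted), `regulators`
#' (`;`-joined), `substrate_calls` (`;`-joined `substrate:score`, score at 1
#' decimal) and `gene_ids` (`;`-joined in coordinate order).
#'
#' @param puls A `pul_set` from [predict_puls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pul_table <- function(puls, path) {
  df <- as.data.frame(puls)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(paste0("cannot write PUL table to ", path))
  invisible(path)
}

#' @export
as.data.frame.pul_set <- function(x, ...) {
  if (!length(x)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(pul_table_columns)), pul_table_columns),
      stringsAsFactors = FALSE)
    return(df)
  }
  do.call(rbind, lapply(x, function(p) {
    data.frame(
      pul_id = p$pul_id, contig = p$contig, start = p$start, end = p$end,
      n_genes = length(p$gene_ids), n_pairs = length(p$pair_blocks),
      strand_consensus = p$strand_consensus,
      cazyme_families = paste(sort(p$cazyme_families), collapse = ";"),
      regulators = paste(p$regulators, collapse = ";"),
      substrate_calls = paste(p$substrate_calls %||% character(0),
                              collapse = ";"),
      gene_ids = paste(p$gene_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Read a PUL table written by [write_pul_table()]
#'
#' Reconstructs a lightweight `pul_set` (ids, spans, family multisets,
#' regulators, substrate calls, member gene ids).  Pair-block detail is not
#' serialised; `n_pairs` is carried as a count.
#'
#' @param path Path to the TSV file.
#' @return A `pul_set` list.
#' @export
read_pul_table <- function(path) {
  if (!file.exists(path)) abort_io(paste0("PUL table not found: ", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!identical(names(df), pul_table_columns)) {
    abort_parse(paste0("unrecognised PUL table columns in ", path))
  }
  split_semi <- function(s) {
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    toks[nzchar(toks)]
  }
  puls <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(
      pul_id = df$pul_id[i], contig = df$contig[i],
      start = as.integer(df$start[i]), end = as.integer(df$end[i]),
      strand_consensus = df$strand_consensus[i],
      gene_ids = split_semi(df$gene_ids[i]),
      pair_blocks = vector("list", as.integer(df$n_pairs[i])),
      cazyme_families = split_semi(df$cazyme_families[i]),
      regulators = split_semi(df$regulators[i]),
      substrate_calls = split_semi(df$substrate_calls[i]),
      n_sulfatase = NA_integer_,
      cazyme_free = !nzchar(df$cazyme_families[i])
    ), class = "pul")
  })
  structure(puls, class = "pul_set")
}

#' Serialise a PUL set as BED6
#'
#' BED uses 0-based half-open coordinates, so a locus spanning 1-based
#' inclusive `[start, end]` is written as `start - 1, end`.  The score column
#' holds the number of tandem SusC/SusD pair blocks.
#'
#' @param puls A `pul_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pul_bed <- function(puls, path) {
  lines <- vapply(puls, function(p) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", p$contig, p$start - 1L, p$end,
            p$pul_id, length(p$pair_blocks), p$strand_consensus)
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_io(paste0("cannot write BED to ", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# GC skew

#' Sliding-window GC skew
#'
#' Computes `(G - C) / (G + C)` over sliding windows of a nucleotide
#' sequence, the quantity used to orient replication strands on circular
#' genome maps.  Windows containing no G or C return a skew of 0 with the
#' `zero_denominator` flag set, so downstream summaries stay numeric.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @param window Window length in bases (`>= 1`, at most the sequence
#'   length).
#' @param step Step between window starts in bases (default: `window`, i.e.
#'   non-overlapping windows).
#' @return A `data.frame` with columns `start` (1-based window start),
#'   `skew` and `zero_denominator`.
#' @examples
#' gc_skew("GGGGCCAA", window = 4, step = 4)
#' @export
gc_skew <- function(sequence, window, step = window) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort_parse("sequence must be a non-empty nucleotide string")
  }
  if (!grepl("^[ACGTNacgtn]+$", sequence)) {
    abort_parse("sequence contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(sequence)
  if (window < 1 || step < 1) abort_parse("window and step must be >= 1")
  if (window > n) abort_parse("window exceeds sequence length")
  counts <- Biostrings::letterFrequencyInSlidingView(
    Biostrings::DNAString(toupper(sequence)), window, c("G", "C"))
  starts <- seq.int(1L, n - window + 1L, by = step)
  g <- counts[starts, "G"]
  cc <- counts[starts, "C"]
  den <- g + cc
  skew <- ifelse(den == 0, 0, (g - cc) / den)
  data.frame(start = starts, skew = as.numeric(skew),
             zero_denominator = den == 0)
}
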