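# Shared fixtures: hand-built annotation bundles from role strings, the
# brute-force locus oracle, and the reverse-complement transform.

# Accessions that the shipped default role map resolves to each role.  Kept
# literal (not read from the package config) so the fixtures pin down the
# documented defaults.
fixture_accessions <- function(role, family = "GH16") {
  switch(role,
    SUSC = c("PF00593", "PF07715"),
    SUSD = "PF07980",
    CAZYME = family,
    SULFATASE = "PF00884",
    REGULATOR = c("PF00512", "PF00072", "PF12833"),  # HTCS
    UNKNOWN = character(0))
}

# Build an annotation_bundle from parallel role/strand vectors.  Coordinates
# are laid out left to right with the given intergenic gaps (bp).
make_bundle <- function(roles, strands, gaps_bp = 100, contigs = "c1",
                        gene_len = 500, families = NULL) {
  n <- length(roles)
  strands <- rep_len(strands, n)
  gaps_bp <- rep_len(gaps_bp, n)
  contigs <- rep_len(contigs, n)
  if (is.null(families)) families <- rep("GH16", n)
  genes <- NULL
  hits <- NULL
  for (ct in unique(contigs)) {
    idx <- which(contigs == ct)
    pos <- 1L
    for (i in idx) {
      start <- pos
      end <- pos + gene_len - 1L
      pos <- end + 1L + gaps_bp[i]
      id <- sprintf("%s_g%03d", ct, i)
      genes <- rbind(genes, data.frame(
        gene_id = id, contig = ct, start = start, end = end,
        strand = strands[i], product = NA_character_,
        stringsAsFactors = FALSE))
      acc <- fixture_accessions(roles[i], families[i])
      if (length(acc)) {
        hits <- rbind(hits, data.frame(
          gene_id = id, source = "fixture", accession = acc,
          evalue = NA_real_, coverage = NA_real_, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), source = character(0),
                       accession = character(0), evalue = numeric(0),
                       coverage = numeric(0), stringsAsFactors = FALSE)
  }
  annotation_bundle(genes, hits, provenance = "test fixture")
}

# Canonical representation of a pul_set for set comparisons: sorted vector
# of ';'-joined member gene ids.
canon_puls <- function(puls) {
  sort(vapply(puls, function(p) paste(p$gene_ids, collapse = ";"),
              character(1)))
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle.  Formulated as window enumeration plus an
# extent predicate, deliberately different from the package's incremental
# scan-and-walk implementation.

ORACLE_ABSORB <- c("SUSC", "SUSD", "CAZYME", "SULFATASE", "REGULATOR")

# All maximal tandem-pair windows, by testing every contiguous window [a, b]
# against the pattern "run of first-role genes then run of second-role
# genes, one strand, one contig", with maximality at both edges.
oracle_blocks <- function(genes, role) {
  n <- nrow(genes)
  out <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a > b) next
      if (genes$contig[a] != genes$contig[b]) next
      idxs <- a:b
      if (length(unique(genes$contig[idxs])) != 1) next
      s <- unique(genes$strand[idxs])
      if (length(s) != 1) next
      first <- if (s == "-") "SUSD" else "SUSC"
      second <- if (s == "-") "SUSC" else "SUSD"
      rr <- role[idxs]
      ok <- FALSE
      for (k in seq_len(length(idxs) - 1)) {
        if (all(rr[1:k] == first) &&
            all(rr[(k + 1):length(rr)] == second)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      left_max <- a == 1 || genes$contig[a - 1] != genes$contig[a] ||
        !(role[a - 1] == first && genes$strand[a - 1] == s)
      right_max <- b == n || genes$contig[b + 1] != genes$contig[b] ||
        !(role[b + 1] == second && genes$strand[b + 1] == s)
      if (left_max && right_max) {
        out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  out
}

# Furthest valid extension of a block edge in one direction: enumerate every
# candidate endpoint and test the whole window predicate, then take the
# furthest endpoint that passes.
oracle_extent <- function(genes, role, edge, dir, max_gap_genes, max_gap_bp) {
  n <- nrow(genes)
  far <- edge
  e <- edge + dir
  while (e >= 1 && e <= n && genes$contig[e] == genes$contig[edge]) {
    idxs <- seq(edge, e, by = dir)
    path <- idxs[-1]
    ok <- role[e] %in% ORACLE_ABSORB
    if (ok) {
      for (q in path) {
        lo <- min(q, q - dir)
        hi <- max(q, q - dir)
        if (genes$start[hi] - genes$end[lo] - 1 > max_gap_bp) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      runs <- rle(role[path] == "UNKNOWN")
      if (any(runs$values & runs$lengths > max_gap_genes)) ok <- FALSE
    }
    if (ok) far <- e
    e <- e + dir
  }
  far
}

# Full oracle: blocks -> extents -> member index sets -> merge overlapping
# spans -> canonical member-id sets.
oracle_puls <- function(bundle, roles, max_gap_genes = 2, max_gap_bp = 5000) {
  genes <- bundle$genes
  role <- roles$role[match(genes$gene_id, roles$gene_id)]
  blocks <- oracle_blocks(genes, role)
  if (!length(blocks)) return(character(0))
  sets <- lapply(blocks, function(ab) {
    lo <- oracle_extent(genes, role, ab[1], -1, max_gap_genes, max_gap_bp)
    hi <- oracle_extent(genes, role, ab[2], +1, max_gap_genes, max_gap_bp)
    lo:hi
  })
  # merge sets whose genomic spans overlap (interval sweep per contig)
  merged <- TRUE
  while (merged && length(sets) > 1) {
    merged <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i >= j) next
        si <- sets[[i]]
        sj <- sets[[j]]
        if (genes$contig[si[1]] != genes$contig[sj[1]]) next
        if (max(genes$end[si]) >= min(genes$start[sj]) &&
            max(genes$end[sj]) >= min(genes$start[si])) {
          sets[[i]] <- sort(union(si, sj))
          sets <- sets[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  sort(vapply(sets, function(s) {
    paste(genes$gene_id[sort(s)], collapse = ";")
  }, character(1)))
}

# Random small-genome trial shared by property and acceptance tests.
random_trial_bundle <- function() {
  n <- sample(4:30, 1)
  roles <- sample(c("SUSC", "SUSD", "CAZYME", "REGULATOR", "SULFATASE",
                    "UNKNOWN"),
                  n, replace = TRUE,
                  prob = c(0.18, 0.18, 0.15, 0.05, 0.04, 0.40))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gaps <- sample(c(50, 200, 500, 6000), n, replace = TRUE,
                 prob = c(0.45, 0.3, 0.2, 0.05))
  contigs <- "c1"
  if (stats::runif(1) < 0.15 && n >= 6) {
    contigs <- c(rep("c1", floor(n / 2)), rep("c2", n - floor(n / 2)))
  }
  list(bundle = make_bundle(roles, strands, gaps_bp = gaps,
                            contigs = contigs),
       roles = roles)
}

# Reverse-complement of a bundle: mirror coordinates, flip strands.
rc_bundle <- function(bundle) {
  g <- bundle$genes
  L <- max(g$end) + 100L
  new_start <- L + 1L - g$end
  new_end <- L + 1L - g$start
  g$start <- new_start
  g$end <- new_end
  g$strand <- ifelse(g$strand == "+", "-", "+")
  annotation_bundle(g, bundle$hits, provenance = "reverse complement")
}

# Mirror a span under the same transform, for comparing predictions.
rc_span <- function(start, end, L) c(L + 1L - end, L + 1L - start)

noise_free_rates <- list(lone_susc = 0, lone_susd = 0, wrong_order_pair = 0,
                         opposite_strand_pair = 0, scattered_cazyme = 0)
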