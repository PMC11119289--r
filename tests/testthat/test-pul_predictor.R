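rc_default <- role_config()
gap_default <- gap_config()

hits_for <- function(gene_id, accessions) {
  data.frame(gene_id = gene_id, source = "t", accession = accessions,
             evalue = NA_real_, coverage = NA_real_, stringsAsFactors = FALSE)
}

one_gene_bundle <- function(accessions) {
  genes <- data.frame(gene_id = "g1", contig = "c1", start = 1L, end = 900L,
                      strand = "+", stringsAsFactors = FALSE)
  annotation_bundle(genes, hits_for("g1", accessions))
}

test_that("default role map assigns transporter, binder, CAZyme, sulfatase, regulators", {
  expect_equal(assign_roles(one_gene_bundle(c("PF00593", "PF07715")))$role,
               "SUSC")
  # SusC needs the full linear domain architecture, not one half of it
  expect_equal(assign_roles(one_gene_bundle("PF00593"))$role, "UNKNOWN")
  expect_equal(assign_roles(one_gene_bundle("PF07980"))$role, "SUSD")
  r <- assign_roles(one_gene_bundle("GH16"))
  expect_equal(r$role, "CAZYME")
  expect_equal(r$families, "GH16")
  expect_equal(assign_roles(one_gene_bundle("PF00884"))$role, "SULFATASE")
  r <- assign_roles(one_gene_bundle(c("PF00512", "PF00072", "PF12833")))
  expect_equal(r$role, "REGULATOR")
  expect_equal(r$regulator_kind, "HTCS")
  r <- assign_roles(one_gene_bundle(c("PF04542", "PF08281")))
  expect_equal(r$regulator_kind, "ECF_SIGMA")
  expect_equal(assign_roles(one_gene_bundle("PF04773"))$regulator_kind,
               "ANTI_SIGMA")
})

test_that("role conflicts resolve by priority with a warning, over all two-role combinations", {
  sig <- list(SUSC = c("PF00593", "PF07715"), SUSD = "PF07980",
              CAZYME = "GH16", SULFATASE = "PF00884",
              REGULATOR = c("PF00512", "PF00072", "PF12833"))
  priority <- names(sig)
  for (i in seq_along(sig)) {
    for (j in seq_along(sig)) {
      if (i >= j) next
      b <- one_gene_bundle(c(sig[[i]], sig[[j]]))
      expect_warning(r <- assign_roles(b), "multiple role signatures")
      expect_equal(r$role, priority[min(i, j)],
                   label = paste(priority[i], "+", priority[j]))
    }
  }
  # families stay empty when the CAZyme signature loses the conflict
  suppressWarnings(r <- assign_roles(one_gene_bundle(c("PF07980", "GH16"))))
  expect_equal(r$role, "SUSD")
  expect_equal(r$families, "")
})

test_that("families are deduplicated, sorted, and compound labels split", {
  r <- assign_roles(one_gene_bundle(c("GH16|CBM4", "GH16", "GH3+GH3")))
  expect_equal(r$families, paste(sort(c("GH16", "CBM4", "GH3")),
                                 collapse = ";"))
})

test_that("overlapping equal-priority regulator signatures are a config error", {
  cfg_path <- tempfile()
  writeLines(c("htcs_output_domains = PF04542"), cfg_path)
  expect_error(role_config(read_run_config(cfg_path)),
               "equal-priority", class = "pulcall_config_error")
  expect_error(read_run_config(write_config <- {
    p <- tempfile(); writeLines("no_such_key = 1", p); p
  }), "unknown config key", class = "pulcall_config_error")
})

test_that("tandem pairs require SusC upstream of SusD on one strand", {
  pairs_of <- function(roles, strands) {
    b <- make_bundle(roles, strands)
    find_tandem_pairs(b$genes, assign_roles(b), gap_default)
  }
  expect_length(pairs_of(c("SUSC", "SUSD"), "+"), 1)
  expect_length(pairs_of(c("SUSC", "SUSD"), c("+", "-")), 0)
  # upstream on the minus strand means higher coordinates
  expect_length(pairs_of(c("SUSD", "SUSC"), "+"), 0)
  expect_length(pairs_of(c("SUSD", "SUSC"), "-"), 1)
  # duplications absorb into one block
  blk <- pairs_of(c("SUSC", "SUSC", "SUSD", "SUSD"), "+")
  expect_length(blk, 1)
  expect_length(blk[[1]]$susc_gene_ids, 2)
  expect_length(blk[[1]]$susd_gene_ids, 2)
})

test_that("pair detection matches the window oracle exhaustively for <= 4 transporter genes", {
  for (n in 2:4) {
    combos <- expand.grid(rep(list(1:4), n))
    for (ri in seq_len(nrow(combos))) {
      code <- as.integer(combos[ri, ])
      roles <- c("SUSC", "SUSC", "SUSD", "SUSD")[code]
      strands <- c("+", "-", "+", "-")[code]
      b <- make_bundle(roles, strands)
      got <- find_tandem_pairs(b$genes, assign_roles(b), gap_default)
      want <- oracle_blocks(b$genes, roles)
      got_sets <- sort(vapply(got, function(x) {
        paste(sort(x$gene_ids), collapse = ",")
      }, character(1)))
      want_sets <- sort(vapply(want, function(ab) {
        paste(sort(b$genes$gene_id[ab[1]:ab[2]]), collapse = ",")
      }, character(1)))
      expect_equal(got_sets, want_sets,
                   label = paste(roles, strands, collapse = "|"))
    }
  }
})

test_that("extension absorbs flanking CAZymes and regulators but stops at gap violations", {
  roles <- c("CAZYME", "SUSC", "SUSD", "CAZYME", "REGULATOR")
  b <- make_bundle(roles, "+")
  p <- predict_puls(b, warn = FALSE)
  expect_length(p, 1)
  expect_length(p[[1]]$gene_ids, 5)
  expect_equal(sort(p[[1]]$cazyme_families), c("GH16", "GH16"))
  expect_equal(p[[1]]$regulators, "HTCS")

  # three consecutive unknowns exceed max_gap_genes = 2
  roles <- c("CAZYME", "UNKNOWN", "UNKNOWN", "UNKNOWN", "SUSC", "SUSD")
  p <- predict_puls(make_bundle(roles, "+"), warn = FALSE)
  expect_length(p, 1)
  expect_equal(length(p[[1]]$gene_ids), 2)

  # two unknowns are crossed and retained as interior members
  roles <- c("CAZYME", "UNKNOWN", "UNKNOWN", "SUSC", "SUSD")
  p <- predict_puls(make_bundle(roles, "+"), warn = FALSE)
  expect_equal(length(p[[1]]$gene_ids), 5)

  # a > max_gap_bp intergenic break stops extension even to a CAZyme
  roles <- c("CAZYME", "SUSC", "SUSD")
  p <- predict_puls(make_bundle(roles, "+", gaps_bp = c(6000, 100, 100)),
                    warn = FALSE)
  expect_equal(length(p[[1]]$gene_ids), 2)

  # isolated pair: cazyme-free flag
  p <- predict_puls(make_bundle(c("SUSC", "SUSD"), "+"), warn = FALSE)
  expect_true(p[[1]]$cazyme_free)
  expect_length(p[[1]]$cazyme_families, 0)
})

test_that("overlapping loci merge into one with concatenated pair blocks", {
  roles <- c("SUSC", "SUSD", "CAZYME", "SUSC", "SUSD")
  p <- predict_puls(make_bundle(roles, "+"), warn = FALSE)
  expect_length(p, 1)
  expect_length(p[[1]]$pair_blocks, 2)
  expect_equal(length(p[[1]]$gene_ids), 5)
})

test_that("predictions are numbered in coordinate order and contain a pair block each", {
  sim <- generate_genome(genome_sim_spec(n_puls = 6, genes_per_contig = 150,
                                         n_contigs = 2, seed = 9))
  p <- predict_puls(sim$bundle, warn = FALSE)
  expect_equal(vapply(p, `[[`, character(1), "pul_id"),
               paste0("PUL", seq_along(p)))
  expect_true(all(vapply(p, function(x) length(x$pair_blocks) >= 1,
                         logical(1))))
  df <- as.data.frame(p)
  for (ct in unique(df$contig)) {
    d <- df[df$contig == ct, ]
    if (nrow(d) > 1) {
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))  # no overlap
    }
  }
  # determinism
  expect_identical(as.data.frame(predict_puls(sim$bundle, warn = FALSE)), df)
})

test_that("genome with no SusC genes yields no loci", {
  b <- make_bundle(c("SUSD", "CAZYME", "UNKNOWN", "SUSD"), "+")
  expect_length(predict_puls(b, warn = FALSE), 0)
})

test_that("random genomes agree with the brute-force oracle", {
  set.seed(202)
  for (trial in 1:100) {
    tr <- random_trial_bundle()
    got <- canon_puls(predict_puls(tr$bundle, warn = FALSE))
    want <- oracle_puls(tr$bundle, assign_roles(tr$bundle))
    expect_equal(got, want, label = paste("trial", trial))
  }
})

test_that("reverse-complementing the genome mirrors the predictions", {
  sim <- generate_genome(genome_sim_spec(n_puls = 5, genes_per_contig = 120,
                                         seed = 13))
  p_fwd <- predict_puls(sim$bundle, warn = FALSE)
  p_rev <- predict_puls(rc_bundle(sim$bundle), warn = FALSE)
  expect_equal(length(p_fwd), length(p_rev))
  # same member sets, mirrored spans
  expect_equal(sort(vapply(p_fwd, function(p) {
    paste(sort(p$gene_ids), collapse = ";")
  }, character(1))),
  sort(vapply(p_rev, function(p) {
    paste(sort(p$gene_ids), collapse = ";")
  }, character(1))))
  L <- max(sim$bundle$genes$end) + 100L
  fwd_spans <- lapply(p_fwd, function(p) c(p$start, p$end))
  rev_spans <- lapply(p_rev, function(p) rc_span(p$start, p$end, L))
  expect_setequal(vapply(fwd_spans, paste, character(1), collapse = "-"),
                  vapply(rev_spans, paste, character(1), collapse = "-"))
})
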