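write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("parse_gff reads genes with coordinates and attributes intact", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1;product=susC homolog"),
    ".gff3")
  b <- parse_gff(gff)
  expect_s3_class(b, "annotation_bundle")
  expect_equal(nrow(b$genes), 1)
  expect_equal(b$genes$gene_id, "g1")
  expect_equal(b$genes$start, 100L)
  expect_equal(b$genes$end, 400L)
  expect_equal(b$genes$strand, "+")
  expect_equal(b$genes$product, "susC homolog")
})

test_that("parse_gff rejects malformed lines, naming the line number", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t500\t400\t.\t+\t.\tID=g1"), ".gff3")
  expect_error(parse_gff(gff), "line 2", class = "pulcall_parse_error")

  gff2 <- write_tmp(c("chr1\tsrc\tgene\t100\t400\t+\tID=g1"), ".gff3")
  expect_error(parse_gff(gff2), "9 tab-separated",
               class = "pulcall_parse_error")

  gff3 <- write_tmp(c("chr1\tsrc\tgene\t100\t400\t.\t+\t.\tNote=x"), ".gff3")
  expect_error(parse_gff(gff3), "no ID=, locus_tag= or Name=",
               class = "pulcall_parse_error")
})

test_that("parse_gff sorts interleaved contigs and falls back through id attributes", {
  # deliberately shuffled file order; expected order computed independently
  rows <- data.frame(
    contig = c("c2", "c1", "c2", "c1"),
    start = c(900L, 500L, 100L, 100L),
    id_attr = c("ID=b2", "locus_tag=a2", "Name=b1", "ID=a1"))
  lines <- sprintf("%s\tsrc\tgene\t%d\t%d\t.\t+\t.\t%s",
                   rows$contig, rows$start, rows$start + 50L, rows$id_attr)
  b <- parse_gff(write_tmp(lines, ".gff3"))
  ord <- order(rows$contig, rows$start)
  expect_equal(b$genes$contig, rows$contig[ord])
  expect_equal(b$genes$start, rows$start[ord])
  expect_equal(b$genes$gene_id, c("a1", "a2", "b1", "b2"))
})

test_that("parse_gff prefers CDS features and agrees with rtracklayer", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t90\t420\t.\t+\t.\tID=gene1",
    "c1\tsrc\tCDS\t100\t400\t.\t+\t.\tID=cds1",
    "c1\tsrc\tCDS\t600\t900\t.\t-\t.\tID=cds2"), ".gff3")
  b <- parse_gff(gff)
  expect_equal(b$genes$gene_id, c("cds1", "cds2"))
  bg <- parse_gff(gff, feature_type = "gene")
  expect_equal(bg$genes$gene_id, "gene1")

  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  expect_equal(b$genes$start, BiocGenerics::start(gr))
  expect_equal(b$genes$end, BiocGenerics::end(gr))
  expect_equal(b$genes$gene_id, gr$ID)
})

test_that("gff round-trips through write_gff3", {
  sim <- generate_genome(genome_sim_spec(n_puls = 2, genes_per_contig = 40,
                                         seed = 7,
                                         decoy_rates = noise_free_rates))
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$bundle, path)
  b2 <- parse_gff(path)
  expect_equal(b2$genes[, c("gene_id", "contig", "start", "end", "strand")],
               sim$bundle$genes[, c("gene_id", "contig", "start", "end",
                                    "strand")])
})

test_that("parse_domain_tsv expands accession lists and validates fields", {
  tsv <- write_tmp(c("gene_id\taccessions", "g1\tGH16;GH3"))
  hits <- parse_domain_tsv(tsv)
  expect_equal(hits$gene_id, c("g1", "g1"))
  expect_equal(hits$accession, c("GH16", "GH3"))

  expect_error(
    parse_domain_tsv(write_tmp(c("gene_id\taccessions\tevalue",
                                 "g1\tGH16\t-1"))),
    "negative evalue", class = "pulcall_parse_error")
  expect_error(parse_domain_tsv(write_tmp(c("gene\tacc", "g1\tGH16"))),
               "header", class = "pulcall_parse_error")

  empty <- parse_domain_tsv(write_tmp("gene_id\taccessions"))
  expect_equal(nrow(empty), 0)

  expect_warning(
    parse_domain_tsv(write_tmp(c("gene_id\taccessions", "g1\tGH16;;GH3"))),
    "empty accession token")
})

test_that("domain TSV write/parse is the identity on hit tables", {
  sim <- generate_genome(genome_sim_spec(n_puls = 3, genes_per_contig = 150,
                                         seed = 11))
  path <- tempfile(fileext = ".tsv")
  write_domain_tsv(sim$bundle$hits, path)
  hits2 <- parse_domain_tsv(path, source = "pfam")
  expect_equal(hits2$gene_id, sim$bundle$hits$gene_id)
  expect_equal(hits2$accession, sim$bundle$hits$accession)
  expect_equal(hits2$evalue, sim$bundle$hits$evalue)
})

test_that("PUL table round-trips and BED uses 0-based half-open coordinates", {
  b <- make_bundle(c("CAZYME", "SUSC", "SUSD"), "+", gaps_bp = c(49, 49, 49),
                   families = c("PL8", "", ""))
  puls <- annotate_substrates(predict_puls(b, warn = FALSE))
  tab <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  write_pul_table(puls, tab)
  write_pul_bed(puls, bed)

  puls2 <- read_pul_table(tab)
  expect_equal(canon_puls(puls2), canon_puls(puls))
  expect_equal(puls2[[1]]$start, puls[[1]]$start)
  expect_equal(puls2[[1]]$end, puls[[1]]$end)
  expect_equal(sort(puls2[[1]]$cazyme_families),
               sort(puls[[1]]$cazyme_families))
  expect_equal(puls2[[1]]$substrate_calls, puls[[1]]$substrate_calls)

  bed_df <- read.table(bed, sep = "\t")
  expect_equal(bed_df$V2, puls[[1]]$start - 1L)
  expect_equal(bed_df$V3, puls[[1]]$end)
  # BED span length equals the 1-based inclusive span length
  expect_equal(bed_df$V3 - bed_df$V2, puls[[1]]$end - puls[[1]]$start + 1L)
})

test_that("empty PUL sets serialise as header-only table and empty BED", {
  empty <- structure(list(), class = "pul_set")
  tab <- tempfile()
  bed <- tempfile()
  write_pul_table(empty, tab)
  write_pul_bed(empty, bed)
  expect_equal(length(readLines(tab)), 1)
  expect_equal(length(readLines(bed)), 0)
  expect_equal(length(read_pul_table(tab)), 0)
})

test_that("gc_skew matches (G-C)/(G+C) with sentinel on GC-free windows", {
  expect_equal(gc_skew("GGGG", 4)$skew, 1)
  expect_equal(gc_skew("GCGC", 4)$skew, 0)
  at <- gc_skew("AATT", 4)
  expect_equal(at$skew, 0)
  expect_true(at$zero_denominator)

  # hand-count oracle on a random sequence, overlapping windows
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
               collapse = "")
  res <- gc_skew(seq, window = 25, step = 7)
  for (i in seq_len(nrow(res))) {
    win <- strsplit(substr(seq, res$start[i], res$start[i] + 24), "")[[1]]
    g <- sum(win == "G")
    cc <- sum(win == "C")
    expected <- if (g + cc == 0) 0 else (g - cc) / (g + cc)
    expect_equal(res$skew[i], expected)
  }
  expect_true(all(res$skew >= -1 & res$skew <= 1))
  expect_error(gc_skew("", 4), class = "pulcall_parse_error")
  expect_error(gc_skew("ACGT", 10), "window", class = "pulcall_parse_error")
})
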