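# Synthetic annotated genomes with planted, truth-tagged PULs, and
# fermentation time series with the statistical shape the analysis assumes.
# Everything is deterministic given the seed; the caller's RNG state is
# saved and restored so generation never perturbs global reproducibility.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() interprets a length-1 numeric first argument as 1:n; use explicit
# index sampling everywhere.
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

#' Specification for a synthetic annotated genome
#'
#' Parameters of the generator that emulates an annotated *Bacteroides*-like
#' genome containing planted PULs with the canonical structural grammar:
#' optional regulator, flanking CAZymes, a tandem SusC/SusD pair with
#' optional duplication of either member, all co-oriented, plus decoy
#' arrangements that must not be called (lone SusC, lone SusD, wrong-order
#' pairs, strand-split pairs, scattered CAZymes).
#'
#' @param n_contigs Number of contigs (`>= 1`).
#' @param genes_per_contig Total genes per contig, including filler genes of
#'   unknown function.
#' @param n_puls Number of planted loci (`>= 0`).
#' @param pul_cazyme_range `(min, max)` flanking CAZyme genes per locus.
#' @param p_duplicated_pair Probability that the SusC (and, independently,
#'   the SusD) member of a pair is duplicated.
#' @param p_regulator Probability that a locus carries a regulator gene
#'   (HTCS or ECF-sigma, equally likely).
#' @param decoy_rates Named list of expected counts per genome
#'   (Poisson-distributed) for `lone_susc`, `lone_susd`,
#'   `wrong_order_pair`, `opposite_strand_pair`, `scattered_cazyme`.
#' @param mean_gene_len Mean gene length, bp (sd = 20%, clamped).
#' @param mean_intergenic Mean intergenic distance, bp (sd = 50%, clamped to
#'   at least 1 bp).
#' @param seed Mandatory integer seed.
#' @return A validated `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(n_contigs = 1, genes_per_contig = 300,
                            n_puls = 10, pul_cazyme_range = c(1, 4),
                            p_duplicated_pair = 0.3, p_regulator = 0.5,
                            decoy_rates = list(lone_susc = 2, lone_susd = 2,
                                               wrong_order_pair = 2,
                                               opposite_strand_pair = 2,
                                               scattered_cazyme = 5),
                            mean_gene_len = 1200, mean_intergenic = 150,
                            seed) {
  if (missing(seed)) abort_config("genome_sim_spec: seed is mandatory")
  if (n_contigs < 1 || genes_per_contig < 1 || n_puls < 0) {
    abort_config("n_contigs, genes_per_contig must be >= 1 and n_puls >= 0")
  }
  if (length(pul_cazyme_range) != 2 || pul_cazyme_range[1] < 0 ||
      pul_cazyme_range[2] < pul_cazyme_range[1]) {
    abort_config("pul_cazyme_range must be (min, max) with 0 <= min <= max")
  }
  if (p_duplicated_pair < 0 || p_duplicated_pair > 1 ||
      p_regulator < 0 || p_regulator > 1) {
    abort_config("probabilities must lie in [0, 1]")
  }
  req <- c("lone_susc", "lone_susd", "wrong_order_pair",
           "opposite_strand_pair", "scattered_cazyme")
  if (!all(req %in% names(decoy_rates)) ||
      any(unlist(decoy_rates[req]) < 0)) {
    abort_config("decoy_rates must name all decoy types with rates >= 0")
  }
  if (mean_gene_len <= 0 || mean_intergenic <= 0) {
    abort_config("lengths must be > 0")
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 genes_per_contig = as.integer(genes_per_contig),
                 n_puls = as.integer(n_puls),
                 pul_cazyme_range = as.integer(pul_cazyme_range),
                 p_duplicated_pair = p_duplicated_pair,
                 p_regulator = p_regulator,
                 decoy_rates = decoy_rates[req],
                 mean_gene_len = mean_gene_len,
                 mean_intergenic = mean_intergenic,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

# Domain hits that the default role map resolves back to the planted role.
role_domain_accessions <- function(role, families, regulator_kind, rc) {
  switch(role,
    SUSC = list(acc = rc$susc, src = "pfam"),
    SUSD = list(acc = rc$susd[1], src = "pfam"),
    CAZYME = list(acc = families, src = "cazyme"),
    SULFATASE = list(acc = rc$sulfatase[1], src = "pfam"),
    REGULATOR = switch(regulator_kind,
      HTCS = list(acc = c(rc$htcs$sensor[1], rc$htcs$response[1],
                          rc$htcs$output[1]), src = "pfam"),
      ECF_SIGMA = list(acc = c(rc$ecf$r2[1], rc$ecf$r4[1]), src = "pfam"),
      ANTI_SIGMA = list(acc = rc$anti_sigma[1], src = "pfam")),
    UNKNOWN = list(acc = character(0), src = "pfam"))
}

cassette_entry <- function(role, strand, families = "",
                           regulator_kind = "NONE") {
  data.frame(role = role, strand = strand, families = families,
             regulator_kind = regulator_kind, stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated genome with planted PULs
#'
#' Builds a gene annotation (bundle of gene records plus domain hits
#' consistent with the default role map), a truth table of planted locus
#' spans and substrates, and the planted per-gene role table.  Planted loci
#' are separated from each other and from decoys by runs of
#' filler genes of unknown function longer than the extension gap rule, so
#' that on a decoy-free genome the predictor must recover the planted spans
#' exactly.
#'
#' @param spec A [genome_sim_spec()].
#' @param config A `pul_config` supplying the role map and substrate
#'   signatures the emitted hits conform to.
#' @return A `synthetic_genome`: list with `bundle`
#'   ([annotation_bundle()]), `truth` (`data.frame`: `pul_ordinal`,
#'   `contig`, `start`, `end`, `strand`, `substrate`, `gene_ids`) and
#'   `roles` (planted role table in [assign_roles()] layout).
#' @examples
#' sim <- generate_genome(genome_sim_spec(n_puls = 2, seed = 42))
#' sim$truth
#' @export
generate_genome <- function(spec, config = read_run_config()) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  rc <- role_config(config)
  gapc <- gap_config(config)
  sigs <- default_signatures(config)
  sig_by_name <- stats::setNames(sigs, vapply(sigs, `[[`, character(1),
                                              "substrate"))
  all_core <- sort(unique(unlist(lapply(sigs, `[[`, "core"))))
  pad <- as.integer(gapc$max_gap_genes) + 2L  # filler run that blocks extension

  with_seed(spec$seed, {
    substrates <- rep(names(sig_by_name), length.out = spec$n_puls)
    cassettes <- list()
    for (p in seq_len(spec$n_puls)) {
      s <- resample(c("+", "-"), 1)
      rng <- spec$pul_cazyme_range
      n_caz <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      n_left <- stats::rbinom(1, n_caz, 0.5)
      core <- sig_by_name[[substrates[p]]]$core
      entries <- list()
      if (stats::runif(1) < spec$p_regulator) {
        kind <- resample(c("HTCS", "ECF_SIGMA"), 1)
        entries <- c(entries, list(cassette_entry("REGULATOR", s,
                                                  regulator_kind = kind)))
      }
      for (f in if (n_left > 0) resample(core, n_left, replace = TRUE)
           else character(0)) {
        entries <- c(entries, list(cassette_entry("CAZYME", s, families = f)))
      }
      n_susc <- 1L + (stats::runif(1) < spec$p_duplicated_pair)
      n_susd <- 1L + (stats::runif(1) < spec$p_duplicated_pair)
      for (k in seq_len(n_susc)) {
        entries <- c(entries, list(cassette_entry("SUSC", s)))
      }
      for (k in seq_len(n_susd)) {
        entries <- c(entries, list(cassette_entry("SUSD", s)))
      }
      for (f in if (n_caz - n_left > 0)
           resample(core, n_caz - n_left, replace = TRUE) else character(0)) {
        entries <- c(entries, list(cassette_entry("CAZYME", s, families = f)))
      }
      if (substrates[p] == "fucoidan" && stats::runif(1) < 0.5) {
        entries <- c(entries, list(cassette_entry("SULFATASE", s)))
      }
      ent <- do.call(rbind, entries)
      if (s == "-") ent <- ent[rev(seq_len(nrow(ent))), , drop = FALSE]
      cassettes[[length(cassettes) + 1L]] <-
        list(type = "pul", substrate = substrates[p], entries = ent)
    }

    decoy_builders <- list(
      lone_susc = function(s) cassette_entry("SUSC", s),
      lone_susd = function(s) cassette_entry("SUSD", s),
      wrong_order_pair = function(s) {
        # laid out so the pattern is invalid for the chosen strand
        if (s == "+") rbind(cassette_entry("SUSD", s), cassette_entry("SUSC", s))
        else rbind(cassette_entry("SUSC", s), cassette_entry("SUSD", s))
      },
      opposite_strand_pair = function(s) {
        rbind(cassette_entry("SUSC", s),
              cassette_entry("SUSD", if (s == "+") "-" else "+"))
      },
      scattered_cazyme = function(s) {
        cassette_entry("CAZYME", s, families = resample(all_core, 1))
      })
    for (ty in names(decoy_builders)) {
      k <- stats::rpois(1, spec$decoy_rates[[ty]])
      for (q in seq_len(k)) {
        s <- resample(c("+", "-"), 1)
        cassettes[[length(cassettes) + 1L]] <-
          list(type = ty, substrate = NA_character_,
               entries = decoy_builders[[ty]](s))
      }
    }

    # distribute cassettes over contigs and check the gene budget
    assign_ct <- if (length(cassettes)) {
      sort(rep_len(seq_len(spec$n_contigs), length(cassettes)))
    } else integer(0)
    gene_rows <- list()
    role_rows <- list()
    hit_rows <- list()
    truth_rows <- list()
    for (ct_i in seq_len(spec$n_contigs)) {
      contig <- sprintf("ctg%02d", ct_i)
      cs <- cassettes[assign_ct == ct_i]
      if (length(cs) > 1) cs <- cs[sample.int(length(cs))]
      need <- sum(vapply(cs, function(x) nrow(x$entries), integer(1))) +
        pad * (length(cs) + 1L)
      if (need > spec$genes_per_contig) {
        abort_config(sprintf(
          "capacity error: contig %s needs %d genes (cassettes + spacing) but genes_per_contig = %d",
          contig, need, spec$genes_per_contig))
      }
      spare <- spec$genes_per_contig - need
      extra <- if (length(cs) + 1L > 1L) {
        as.integer(stats::rmultinom(1, spare, rep(1, length(cs) + 1L)))
      } else spare
      filler_runs <- pad + extra

      seq_entries <- list()
      cass_of_gene <- integer(0)
      add_filler <- function(k) {
        for (q in seq_len(k)) {
          seq_entries[[length(seq_entries) + 1L]] <<-
            cassette_entry("UNKNOWN", resample(c("+", "-"), 1))
          cass_of_gene[length(seq_entries)] <<- 0L
        }
      }
      add_filler(filler_runs[1])
      for (ci in seq_along(cs)) {
        ent <- cs[[ci]]$entries
        for (ri in seq_len(nrow(ent))) {
          seq_entries[[length(seq_entries) + 1L]] <- ent[ri, , drop = FALSE]
          cass_of_gene[length(seq_entries)] <- ci
        }
        add_filler(filler_runs[ci + 1L])
      }

      ent <- do.call(rbind, seq_entries)
      ng <- nrow(ent)
      len_sd <- 0.2 * spec$mean_gene_len
      gaps_sd <- 0.5 * spec$mean_intergenic
      lens <- round(stats::rnorm(ng, spec$mean_gene_len, len_sd))
      lens <- pmin(pmax(lens, 90), spec$mean_gene_len + 3 * len_sd)
      gaps <- round(stats::rnorm(ng, spec$mean_intergenic, gaps_sd))
      gaps <- pmin(pmax(gaps, 1), spec$mean_intergenic + 3 * gaps_sd)
      starts <- cumsum(c(1, lens[-ng] + gaps[-ng]))
      ends <- starts + lens - 1
      ids <- sprintf("%s_g%04d", contig, seq_len(ng))

      gene_rows[[ct_i]] <- data.frame(
        gene_id = ids, contig = contig, start = starts, end = ends,
        strand = ent$strand, product = NA_character_,
        stringsAsFactors = FALSE)
      role_rows[[ct_i]] <- data.frame(
        gene_id = ids, role = ent$role, families = ent$families,
        regulator_kind = ent$regulator_kind, stringsAsFactors = FALSE)
      for (gi in seq_len(ng)) {
        hd <- role_domain_accessions(ent$role[gi], ent$families[gi],
                                     ent$regulator_kind[gi], rc)
        if (length(hd$acc)) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            gene_id = ids[gi], source = hd$src, accession = hd$acc,
            evalue = NA_real_, coverage = NA_real_, stringsAsFactors = FALSE)
        }
      }
      for (ci in seq_along(cs)) {
        if (cs[[ci]]$type != "pul") next
        gidx <- which(cass_of_gene == ci)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          contig = contig, start = min(starts[gidx]), end = max(ends[gidx]),
          strand = cs[[ci]]$entries$strand[1],
          substrate = cs[[ci]]$substrate,
          gene_ids = paste(ids[gidx], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }

    genes <- do.call(rbind, gene_rows)
    roles <- do.call(rbind, role_rows)
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      empty_domain_hits()
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), substrate = character(0),
                 gene_ids = character(0), stringsAsFactors = FALSE)
    if (nrow(truth)) {
      truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
      truth <- cbind(pul_ordinal = seq_len(nrow(truth)), truth)
      rownames(truth) <- NULL
    } else {
      truth <- cbind(pul_ordinal = integer(0), truth)
    }
    # planted families column: normalise to the assign_roles layout
    roles$families[roles$role != "CAZYME"] <- ""
    bundle <- annotation_bundle(
      genes, hits,
      provenance = sprintf("synthetic genome (seed %d, %d planted PULs)",
                           spec$seed, spec$n_puls))
    structure(list(bundle = bundle, truth = truth, roles = roles,
                   spec = spec),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d genes, %d planted PUL(s), seed %d\n",
              nrow(x$bundle$genes), nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.gff3`, `domains.tsv` and `truth.tsv` in the package's
#' dialects.  Output is byte-identical across reruns with the same spec.
#'
#' @param sim A `synthetic_genome` from [generate_genome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "genome.gff3")
  dom <- file.path(dir, "domains.tsv")
  tru <- file.path(dir, "truth.tsv")
  write_gff3(sim$bundle, gff)
  write_domain_tsv(sim$bundle$hits, dom)
  utils::write.table(sim$truth, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gff3 = gff, domains = dom, truth = tru))
}

# Per-substrate fermentation defaults.  Initial and final molecular weights
# follow the observed fermentation endpoints for each substrate; the decay
# constant is chosen so the 72 h mean hits the final value.  Growth
# parameters encode the qualitative phenotype: fucoidan supports the lowest
# cell density, the red-algal galactan peaks latest.
fermentation_defaults <- function(substrate) {
  tab <- list(
    laminarin       = list(K = 0.8,  r = 0.4, t0 = 14, m0 = 23598.8,
                           m72 = 18203.04),
    sodium_alginate = list(K = 0.8,  r = 0.4, t0 = 14, m0 = 5927.23,
                           m72 = 4770.658),
    fucoidan        = list(K = 0.5,  r = 0.4, t0 = 14, m0 = 23017.67,
                           m72 = 20680.52),
    PHP             = list(K = 0.75, r = 0.3, t0 = 18, m0 = 433812.2,
                           m72 = 178095.5))
  if (!substrate %in% names(tab)) {
    abort_config(paste0("unknown fermentation substrate: ", substrate))
  }
  d <- tab[[substrate]]
  d$mw_k <- log(d$m0 / d$m72) / 72
  d
}

#' Generate synthetic fermentation time series
#'
#' Emulates a batch fermentation read-out: OD600 follows a logistic curve
#' `K / (1 + exp(-r (t - t0)))`, total sugar decays exponentially from `s0`,
#' and the residual-polysaccharide molecular weight decays exponentially
#' from `mw0`.  Replicates receive independent multiplicative Gaussian
#' noise and values are floored at zero.  Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param substrate One of `"laminarin"`, `"sodium_alginate"`,
#'   `"fucoidan"`, `"PHP"`; selects growth and molecular-weight defaults.
#' @param times Sampling times in hours (default the fermentation sampling
#'   design `0, 12, 24, 48, 72`).
#' @param n_replicates Independent replicates per analyte (default 3).
#' @param K,r,t0 Logistic growth parameters (OD units, 1/h, h).
#' @param sugar_s0 Initial total sugar, mg/mL (`> 0`).
#' @param sugar_k Total-sugar decay rate, 1/h.
#' @param mw0 Initial molecular weight, Da (`> 0`).
#' @param mw_k Molecular-weight decay rate, 1/h.
#' @param noise_sd Multiplicative noise standard deviation (0.02 = 2%).
#' @return Long-format `data.frame`: `analyte` (`OD600`, `total_sugar`,
#'   `Mw`), `substrate`, `replicate`, `time_h`, `value`.
#' @examples
#' fer <- generate_fermentation(1, "laminarin", noise_sd = 0)
#' subset(fer, analyte == "Mw" & replicate == 1)
#' @export
generate_fermentation <- function(seed, substrate = "laminarin",
                                  times = c(0, 12, 24, 48, 72),
                                  n_replicates = 3,
                                  K = NULL, r = NULL, t0 = NULL,
                                  sugar_s0 = 10, sugar_k = 0.02,
                                  mw0 = NULL, mw_k = NULL,
                                  noise_sd = 0.02) {
  d <- fermentation_defaults(substrate)
  K <- K %||% d$K; r <- r %||% d$r; t0 <- t0 %||% d$t0
  mw0 <- mw0 %||% d$m0; mw_k <- mw_k %||% d$mw_k
  if (sugar_s0 <= 0 || mw0 <= 0) {
    abort_config("sugar_s0 and mw0 must be > 0")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort_config("times must be non-negative and strictly increasing")
  }
  means <- list(OD600 = K / (1 + exp(-r * (times - t0))),
                total_sugar = sugar_s0 * exp(-sugar_k * times),
                Mw = mw0 * exp(-mw_k * times))
  with_seed(seed, {
    rows <- list()
    for (an in names(means)) {
      for (rep_i in seq_len(n_replicates)) {
        noise <- stats::rnorm(length(times), 0, noise_sd)
        val <- pmax(0, means[[an]] * (1 + noise))
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = an, substrate = substrate, replicate = rep_i,
          time_h = times, value = val, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
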