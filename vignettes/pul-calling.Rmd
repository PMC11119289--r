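---
title: "Calling polysaccharide utilization loci and validating the marine-glycan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling polysaccharide utilization loci and validating the marine-glycan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulcall)
```

## The problem

Gut *Bacteroides* degrade complex glycans through polysaccharide
utilization loci (PULs): co-located, co-oriented gene clusters that couple
an outer-membrane TonB-dependent transporter (a SusC homolog) and a
glycan-binding lipoprotein (a SusD homolog) with the carbohydrate-active
enzymes (CAZymes), sulfatases and regulators needed to sense, bind, import
and depolymerise a specific substrate. Because the SusC/SusD tandem pair is
the one structural element shared by essentially all Bacteroidetes PULs, it
is the standard anchor for predicting loci from an annotated genome.

`pulcall` implements that prediction as a deterministic, rule-based
procedure over two plain inputs -- a GFF3 gene annotation and a per-gene
domain/CAZyme hit table (the tabular output of tools like dbCAN or a Pfam
scan) -- and adds the downstream steps a fermentation study of marine algal
polysaccharides needs: substrate signatures for alginate, fucoidan,
laminarin and porphyran; CAZyme-class and functional-category tabulation;
and the wet-lab calibration maths (glucose standard curve, size-exclusion
molecular-weight calibration, growth-phase and degradation summaries).

## The locus-calling procedure

1. **Role assignment** (`assign_roles`). Each gene's domain hits are mapped
   to one role. A SusC-like gene must carry the full linear architecture of
   a TonB-dependent transporter (plug + beta-barrel; both `PF00593` and
   `PF07715` by default), whereas a SusD-like gene matches on any one of a
   small family of binding-protein domains. CAZyme family labels (GH, GT,
   PL, CE, AA, CBM prefixes) are carried through verbatim; compound labels
   (`GH16|CBM4`) are split. Regulators are recognised as hybrid
   two-component systems (sensor kinase + response regulator + AraC-type
   output fused on one gene), ECF sigma factors (region 2 + region 4) or
   anti-sigma factors. When one gene matches several signatures the role is
   resolved by the fixed priority SusC > SusD > CAZyme > sulfatase >
   regulator, with a warning: the transporter signatures are the anchors of
   the whole procedure, so they must win. All accession sets are
   configuration keys, not code.

2. **Tandem-pair detection** (`find_tandem_pairs`). A pair block is a
   maximal run of SusC genes followed immediately by a run of SusD genes,
   all on one contig and one strand, with SusC *upstream* in transcription
   order -- on the minus strand this means the SusD run comes first in
   plus-coordinate order. Runs longer than one gene capture the tandem
   duplications common in real loci. "Immediately" means zero intervening
   genes by default (`pair_max_gap_genes = 0`); whether upstream should
   instead be read in plus-coordinate order on both strands is genuinely
   ambiguous, so a `pair_orientation = coordinate` switch preserves the
   alternative reading.

3. **Extension** (`extend_to_pul`). From each block the caller walks
   outward, absorbing neighbours whose role is CAZyme, sulfatase,
   regulator, SusC or SusD. A direction stops at a contig end, after more
   than `max_gap_genes` (default 2) consecutive genes of unknown function,
   or across an intergenic gap larger than `max_gap_bp` (default 5000 bp).
   Unknown genes interior to the final span stay members. The defaults
   follow common PUL-calling practice; no published boundary rule exists
   for this genome, so both are configuration keys, and loci without any
   CAZyme are reported with a `cazyme_free` flag rather than silently
   dropped.

4. **Merging and numbering** (`predict_puls`). Loci whose genomic spans
   overlap are merged (member union, pair blocks concatenated); the result
   is sorted by coordinate and numbered `PUL1`, `PUL2`, ... per run. The
   numbering is an artifact of each genome and never meant to match any
   external catalogue.

Coordinates are GFF3-style 1-based inclusive everywhere inside the package;
the 0-based half-open convention appears only when writing BED.

## Substrate signatures

The four signature sets encode which CAZyme families are implicated in each
substrate's depolymerisation: alginate lyases in PL6/PL7/PL8;
alpha-L-fucosidases in GH29/GH95/GH141 with sulfatase co-occurrence as
accessory evidence (the fucan is sulfated); laminarin
endo-beta-1,3-glucanases in GH3/GH16/GH51; porphyran beta-porphyranase and
endo-beta-1,3-galactanase activity in the GH16/GH86 context with GH2 as
accessory. Scoring is deliberately simple and monotone: each *distinct*
matched core family contributes 1.0, each distinct accessory family 0.5;
family multiplicity never raises a score, ties order alphabetically, and a
locus matching nothing yields no call rather than a zero-score call. The
literature names the families but no scoring rule, so this weighting is a
package decision chosen for determinism and monotonicity -- both properties
are enforced by tests -- and the sets live in the editable configuration,
not in code.

```{r substrates}
sim <- generate_genome(genome_sim_spec(n_puls = 4, seed = 11))
puls <- annotate_substrates(predict_puls(sim$bundle, warn = FALSE))
as.data.frame(puls)[, c("pul_id", "n_pairs", "cazyme_families",
                        "substrate_calls")]
```

## Tabulation arithmetic

`category_share` and `subcategory_share` reproduce the percentage
arithmetic of genome-annotation reports: `100 * count / total`, rounded
half-up to two decimals (the printed precision of such reports). For GO
namespaces the denominator is the sum of the three namespace counts --
that convention reproduces published namespace percentages exactly, while
percentages quoted against undocumented denominators are documented as
non-reconstructible rather than approximated. `cazyme_class_profile`
derives the class of each family from its letter prefix and counts a gene
once per class it touches; labels with unknown prefixes go to a logged
"other" bucket and are excluded from proportions.

## Calibration and fermentation models

* **Glucose standard curve.** Absorbance at 490 nm is regressed on the
  standard dilution series (0--0.1 mg/mL) with ordinary least squares
  (`stats::lm`); sample concentrations come from inverse prediction times
  the dilution factor. Negative inverse predictions are clipped to zero
  and flagged, because concentrations are physical quantities. A fitted
  slope of exactly zero rejects the curve for calibration use.
* **SEC molecular weight.** Retention time is modelled as affine in
  `log10(Mw)`. Pure proportionality through the origin cannot fit a
  realistic dextran standard ladder (4.66--496 kDa), so the relationship
  is implemented with slope and intercept; the expected negative slope
  (larger molecules elute earlier) is recorded, not enforced. Queries
  outside the fitted retention-time domain, extended by
  `extrapolation_margin` (default 10% of the domain width), raise an error
  naming the domain rather than extrapolating silently.
* **Degradation metrics.** Percent drop is `100 (v_first - v_last) /
  v_first` -- invariant under rescaling of the value axis -- and the
  steepest-decline interval is the consecutive pair maximising the per-hour
  loss, earliest interval on ties.
* **Growth phases.** Lag ends at the last sampled time before the curve
  first exceeds its initial value by `baseline_delta` (default 0.05 OD);
  stationary phase starts at the earliest time after which every
  successive increase is below `plateau_eps` (default 0.02 OD). Published
  descriptions of such phases are qualitative, so both thresholds are
  configuration keys; flat series are flagged `no_growth` and monotone
  rises `no_plateau` instead of producing misleading boundaries.
  Replicates are averaged (mean, sd) before phase detection.

## What the synthetic generator emulates -- and what it does not

`generate_genome` plants loci with the canonical grammar -- optional
regulator, flanking CAZymes drawn from the planted substrate's signature,
SusC (x1 or x2), SusD (x1 or x2), more CAZymes, occasionally a sulfatase
for fucoidan loci -- on random strands, surrounded by decoys that exercise
every exclusion branch of the pair rule: lone SusC, lone SusD, wrong-order
pairs, strand-split pairs and scattered CAZymes. Cassettes are separated
by runs of `max_gap_genes + 2` unknown-function filler genes, so planted
spans are exactly recoverable by construction and recovery tests are
sharp: any deviation of predicted from planted spans is an algorithmic
defect, not generator noise. Gene lengths are clamped normal (mean 1200
bp, sd 20%), intergenic gaps clamped normal (mean 150 bp, sd 50%, minimum
1 bp). Decoy rates are expected counts per genome, Poisson-drawn.

`generate_fermentation` produces logistic OD600, exponentially decaying
total sugar and exponentially decaying molecular weight at the sampling
design 0/12/24/48/72 h, three replicates with multiplicative Gaussian
noise (2% default). Per-substrate molecular-weight trajectories are
anchored to the observed fermentation endpoints for the four substrates
(initial value = the 0 h observation; decay rate solving the 72 h
observation), and the growth defaults encode the reported phase structure:
lag through the first 6 h sample, stationary from roughly 24 h, the
red-algal galactan peaking latest (48 h) and fucoidan supporting the
lowest maximum density (~0.5 OD). Initial sugar is 10 mg/mL from the 1%
(w/v) substrate loading.

What passing tests on this material does **not** show about real data:
the generator emits clean, complete domain annotations -- no missed or
spurious domain calls, no fragmented genes, no assembly artifacts -- and
real intergenic structure is not 150 bp on average. Recovery of planted
loci therefore validates the *rules*, not robustness to annotation error;
on a real genome the quality of the domain scan bounds the quality of the
calls. Sequence content is not simulated at all.

## Numerical and design choices

* Percent rounding is half-up at two decimals (`floor(100 x + 0.5) / 100`),
  matching report conventions rather than R's banker's rounding.
* Family lists are sorted with R's default C-locale string order, so
  `GH16` sorts before `GH3`; the order is deterministic, which is what the
  serialisation contract needs.
* `r2` of a least-squares fit is defined as 1 when both the residual and
  total sums of squares vanish.
* All randomness (generator and CLI) flows from a single mandatory seed
  through one stream per call; the caller's `.Random.seed` is saved and
  restored, and outputs carry no timestamps, so same-seed runs are
  byte-identical.
* Contig boundaries are hard locus boundaries: no evidence can span an
  assembly break.
* Problem sizes used by the shipped verification material: recovery runs
  use 20 genomes of 10--50 planted loci (~200--800 genes each), oracle
  cross-checks use 1000 random genomes of at most 30 genes -- small enough
  that the exhaustive window oracle is feasible, large enough to hit every
  rule interaction -- and fermentation law-of-large-numbers checks use 200
  replicates.

## Known limitations

* The caller is annotation-driven: it never sees sequence and cannot
  rescue genes the upstream domain scan missed.
* Substrate scores are evidence tallies, not probabilities; they rank
  candidate substrates but do not calibrate confidence, and quantitative
  enzymology is out of scope.
* Expression data (which loci are actually induced by a substrate) is out
  of scope; a predicted locus is a genomic hypothesis.
* The shipped Pfam accession defaults are sensible for Bacteroidetes but
  are deliberately a configuration file: other phyla, or updated Pfam
  releases, will need edited sets.
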