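# pulcall default run configuration.
# Syntax: key = value.  List values are ';'-separated.  '#' starts a comment.
# Every key recognised by the pipeline appears here; user config files may
# override any subset but may not introduce new keys.

# ---- gene role signatures ------------------------------------------------
# SusC-like TonB-dependent transporters carry a linear plug + beta-barrel
# domain architecture: both accessions below must co-occur on one gene.
susc_domains = PF00593;PF07715
# SusD-like glycan-binding lipoproteins match on any single accession.
susd_domains = PF07980;PF12741;PF12771;PF14322
sulfatase_domains = PF00884;SULFATASE
# Hybrid two-component system regulators: sensor kinase + response regulator
# + AraC-type output domain fused on one gene (one hit from each group).
htcs_sensor_domains = PF00512
htcs_response_domains = PF00072
htcs_output_domains = PF12833
# Extracytoplasmic-function sigma factor: region 2 + region 4 domains.
ecf_sigma_r2_domains = PF04542
ecf_sigma_r4_domains = PF08281
anti_sigma_domains = PF04773
# Family-label prefixes recognised as CAZyme classes.
cazyme_class_prefixes = GH;GT;PL;CE;AA;CBM

# ---- locus extension (gap rule) ------------------------------------------
# Stop extending a locus after this many consecutive unannotated genes ...
max_gap_genes = 2
# ... or when two neighbouring genes are separated by more than this many bp.
max_gap_bp = 5000
# Genes allowed between the SusC run and the SusD run of a tandem pair.
pair_max_gap_genes = 0
# 'transcription': upstream/downstream follow the coding strand (on the minus
# strand SusD precedes SusC in plus-coordinate order).  'coordinate': the
# SusC-before-SusD pattern is required in plus-coordinate order on both
# strands.
pair_orientation = transcription

# ---- substrate signatures ------------------------------------------------
substrate.alginate.core = PL6;PL7;PL8
substrate.alginate.accessory =
substrate.fucoidan.core = GH29;GH95;GH141
substrate.fucoidan.accessory = SULFATASE
substrate.laminarin.core = GH3;GH16;GH51
substrate.laminarin.accessory =
substrate.porphyran.core = GH16;GH86
substrate.porphyran.accessory = GH2
core_weight = 1.0
accessory_weight = 0.5

# ---- growth phase detection (OD600 units) --------------------------------
baseline_delta = 0.05
plateau_eps = 0.02

# ---- SEC molecular-weight calibration ------------------------------------
# Allowed extrapolation beyond the fitted retention-time domain, as a
# fraction of the domain width.
extrapolation_margin = 0.1
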