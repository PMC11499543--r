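# Default isgscore pipeline configuration.
#
# The isg / nfkb / ifng gene lists are PLACEHOLDER panels assembled from the
# published interferon-score literature; they define a working codeset for the
# pipeline and the simulator.  Laboratories must substitute their own
# validated panels for clinically comparable scores.
schema_version: 1
batch_policy: per_batch      # normalization factor scope: per_batch | global
pseudocount: 1.0             # floor applied before any geometric mean / log
log_base: 2.0                # Z-score log transform base
reference_band: [2.5, 97.5]  # healthy band percentiles
band_type: percentile        # percentile | minmax
induction_threshold: 2.0     # stimulated/unstimulated ratio for "responsive"
z_truncate: 10.0             # per-gene |z| cap; Inf disables ("strict" mode)
sd_floor_frac: 0.1           # sd floor as fraction of panel-median reference sd
sd_floor_abs: 0.01           # absolute sd floor for degenerate references
hk_factor_on_raw: false      # true reproduces both-factors-from-raw variants
panels:
  isg:
    code_class: endogenous
    genes: [IFI27, IFI44, IFI44L, IFI6, IFIT1, IFIT2, IFIT3, IFIT5,
            ISG15, LY6E, MX1, MX2, OAS1, OAS2, OAS3, OASL,
            RSAD2, SIGLEC1, USP18, EPSTI1, HERC5, HERC6, LAMP3, SPATS2L,
            DDX60, BST2, CMPK2, XAF1, IRF7, STAT1]
  nfkb:
    code_class: endogenous
    genes: [NFKB1, NFKBIA, TNF, IL1B, IL6, CXCL8, CCL2, TNFAIP3, ICAM1, BIRC3]
  ifng:
    code_class: endogenous
    genes: [CXCL9, CXCL10, CXCL11, GBP1, GBP5, IDO1, CIITA, HLA-DRA, IRF1, SOCS1]
  lineage:
    code_class: endogenous
    genes: [CD3E, CD19, CD14, NCAM1, FOXP3, GATA3]
  housekeeping:
    code_class: housekeeping
    genes: [NRDC, OTUD5, TUBB]
  positive_control:
    code_class: positive_control
    genes: [POS_A, POS_B, POS_C, POS_D, POS_E, POS_F]
  negative_control:
    code_class: negative_control
    genes: [NEG_A, NEG_B, NEG_C, NEG_D, NEG_E, NEG_F, NEG_G, NEG_H]
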