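make_normalized <- function(values, genes, batch = NULL) {
  # build a normalized container directly (factors of 1) for score unit tests
  batch <- batch %||% setNames(rep("B1", ncol(values)), colnames(values))
  structure(list(values = values, genes = genes, batch = batch,
                 factors = data.frame(sample_id = colnames(values),
                                      batch = unname(batch),
                                      pos_factor = 1, hk_factor = 1,
                                      n_in_scope = ncol(values)),
                 provenance = list(batch_policy = "global", pseudocount = 1,
                                   hk_factor_on_raw = FALSE)),
            class = "ncounter_normalized")
}

toy_normalized <- function(panel_values) {
  # panel_values: 4 x n matrix of toy ISG gene values
  n <- ncol(panel_values)
  genes <- toy_matrix()$genes
  values <- rbind(panel_values,
                  matrix(100, 3, n), matrix(500, 6, n), matrix(2, 2, n))
  colnames(values) <- colnames(panel_values) %||% paste0("S", seq_len(n))
  rownames(values) <- genes$symbol
  make_normalized(values, genes)
}

test_that("geomean score reduces to hand values and obeys equivariances", {
  panel <- toy_panels()$isg
  nm <- toy_normalized(matrix(100, 4, 3, dimnames = list(NULL, paste0("S", 1:3))))
  expect_equal(unname(geomean_score(nm, panel)), rep(100, 3))
  nm2 <- toy_normalized(matrix(c(10, 1000, 10, 1000), 4, 1,
                               dimnames = list(NULL, "S1")))
  expect_equal(unname(geomean_score(nm2, gene_panel("p2", c("G1", "G2")))),
               100)
  # scale equivariance: scaling one sample by c scales its score by c
  v <- matrix(rlnorm(12, 4, 1), 4, 3, dimnames = list(NULL, paste0("S", 1:3)))
  base <- geomean_score(toy_normalized(v), panel)
  v2 <- v; v2[, 2] <- v2[, 2] * 3.7
  expect_equal(geomean_score(toy_normalized(v2), panel)[2], base[2] * 3.7)
  # permutation invariance over panel gene order
  perm <- gene_panel("isg_perm", c("G3", "G1", "G4", "G2"))
  expect_equal(unname(geomean_score(toy_normalized(v), perm)),
               unname(geomean_score(toy_normalized(v), panel)))
  # monotonicity: raising one gene strictly increases the score
  v3 <- v; v3[2, 1] <- v3[2, 1] + 50
  expect_gt(geomean_score(toy_normalized(v3), panel)[1], base[1])
})

test_that("reference fitting validates inputs and handles degeneracy", {
  panel <- toy_panels()$isg
  cfg <- toy_config()
  v <- matrix(rep(c(10, 20, 40, 80), 4), 4, 4,
              dimnames = list(NULL, paste0("H", 1:4)))
  nm <- toy_normalized(v)
  ann <- toy_annotations(paste0("H", 1:4))
  expect_error(fit_reference(nm, ann[1, , drop = FALSE], panel, cfg),
               "at least 2")
  # identical references: every sd hits the configured floor, band is a point
  expect_warning(ref <- fit_reference(nm, ann, panel, cfg), "floored")
  expect_true(all(ref$gene_stats$sd == cfg$sd_floor_abs))
  expect_equal(ref$band[1], ref$band[2])
  # a sample exactly at the reference means scores z = 0
  expect_equal(unname(z_score(nm, panel, ref)), rep(0, 4))
})

test_that("the healthy band covers the requested percentile range", {
  panel <- toy_panels()$isg
  cfg <- toy_config()
  cfg$reference_band <- c(0, 100)
  v <- matrix(rep(c(10, 12, 14, 16), each = 4), 4, 4,
              dimnames = list(NULL, paste0("H", 1:4)))
  v <- v * matrix(exp(c(-.1, .1, -.1, .1) %o% c(1, -1, 1, -1)), 4, 4)
  nm <- toy_normalized(v)
  ref <- fit_reference(nm, toy_annotations(paste0("H", 1:4)), panel, cfg)
  scores <- geomean_score(nm, panel)
  expect_equal(ref$band, range(scores))
  cfg$band_type <- "minmax"
  ref2 <- fit_reference(nm, toy_annotations(paste0("H", 1:4)), panel, cfg)
  expect_equal(ref2$band, range(scores))
})

test_that("z-scores are standardized panel means with linear response", {
  panel <- toy_panels()$isg
  cfg <- toy_config()
  set.seed(9)
  v <- matrix(rlnorm(4 * 10, 5, 0.8), 4, 10,
              dimnames = list(NULL, paste0("H", 1:10)))
  nm <- toy_normalized(v)
  ann <- toy_annotations(paste0("H", 1:10))
  ref <- fit_reference(nm, ann, panel, cfg)
  # pooled healthy references have mean z of 0 against their own reference
  expect_lt(abs(mean(z_score(nm, panel, ref))), 1e-9)
  # a sample two reference sds above every gene mean scores exactly 2
  lv <- log2(v + 1)
  target <- 2^(rowMeans(lv) + 2 * apply(lv, 1, sd)) - 1
  nm2 <- toy_normalized(matrix(target, 4, 1, dimnames = list(NULL, "X")))
  expect_equal(unname(z_score(nm2, panel, ref)), 2)
  expect_equal(unname(predict(ref, nm2)), 2)
  # provenance: a reference fitted on another panel is rejected
  other <- gene_panel("other", c("G1", "G2"))
  expect_error(z_score(nm, other, ref), "different gene list|fitted on panel")
})

test_that("patient cohorts with ISG elevation score above healthy donors", {
  cfg <- default_config()
  coh <- simulate_cohort(n_patients = 20, n_healthy = 20, isg_elevation = 8,
                         seed = 13)
  norm <- normalize_counts(coh$matrix, cfg)
  sc <- score_samples(norm, coh$annotations, cfg, panels = "isg")
  pat <- sc$sample_id %in%
    coh$annotations$sample_id[coh$annotations$group == "patient"]
  expect_lt(wilcox.test(sc$z_score[pat], sc$z_score[!pat],
                        alternative = "greater")$p.value, 0.01)
})

test_that("reference gene means recover simulation truth", {
  # lane noise off and near-Poisson dispersion: the fitted per-gene means
  # must sit within 3 standard errors of log2(baseline + 1)
  cfg <- default_config()
  coh <- simulate_cohort(n_patients = 0, n_healthy = 20, sigma_lane = 0,
                         dispersion = 1e6, seed = 17)
  norm <- normalize_counts(coh$matrix, cfg)
  ref <- fit_reference(norm, coh$annotations, cfg$panels$isg, cfg)
  truth_mean <- log2(coh$truth$baselines[cfg$panels$isg$genes] + 1)
  se <- ref$gene_stats$sd / sqrt(ref$n_reference)
  expect_true(all(abs(ref$gene_stats$mean - truth_mean) < 3 * se))
})

test_that("score_samples composes panels deterministically", {
  cfg <- default_config()
  coh <- simulate_cohort(n_patients = 1, n_healthy = 2, seed = 19,
                         batch_size = 3)
  norm <- normalize_counts(coh$matrix, cfg)
  # two reference donors: sd floors are expected to engage for some genes
  sc <- suppressWarnings(score_samples(norm, coh$annotations, cfg))
  expect_identical(nrow(sc), 9L)  # 3 samples x 3 panels
  expect_identical(sort(unique(sc$panel)), c("ifng", "isg", "nfkb"))
  sc2 <- suppressWarnings(score_samples(norm, coh$annotations, cfg))
  expect_identical(sc, sc2)
  # orphan samples are refused
  expect_error(score_samples(norm, coh$annotations[-1, ], cfg),
               "missing from annotations")
})

test_that("end-to-end toy scores match a brute-force oracle", {
  mat <- toy_matrix()
  cfg <- toy_config()
  ann <- toy_annotations(colnames(mat$counts))
  norm <- normalize_counts(mat, cfg)
  oracle <- brute_force_normalize(mat$counts, pos_rows = 8:13, hk_rows = 5:7)
  sc <- score_samples(norm, ann, cfg, panels = "isg")
  expected_gm <- apply(pmax(oracle$values[1:4, ], 1), 2,
                       function(v) prod(v)^(1 / length(v)))
  expect_equal(sc$geomean_score, unname(expected_gm), tolerance = 1e-9)
  lv <- log2(pmax(oracle$values[1:4, ], 0) + 1)
  mu <- rowMeans(lv); sdev <- apply(lv, 1, sd)
  expected_z <- colMeans((lv - mu) / sdev)
  expect_equal(sc$z_score, unname(expected_z), tolerance = 1e-9)
})
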