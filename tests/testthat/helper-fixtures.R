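# Shared in-code fixtures: a small codeset (4 toy ISG genes, the standard
# control sets) and a 3-sample raw matrix whose positive-control geometric
# means are exactly 100 / 200 / 400, with housekeeping counts proportional so
# the housekeeping factor is exactly 1 after the positive-control step.

toy_panels <- function() {
  list(
    isg = gene_panel("isg", c("G1", "G2", "G3", "G4")),
    housekeeping = gene_panel("housekeeping", c("NRDC", "OTUD5", "TUBB"),
                              "housekeeping"),
    positive_control = gene_panel("positive_control",
                                  paste0("POS_", LETTERS[1:6]),
                                  "positive_control"),
    negative_control = gene_panel("negative_control", c("NEG_A", "NEG_B"),
                                  "negative_control")
  )
}

toy_config <- function() {
  cfg <- default_config()
  cfg$panels <- toy_panels()
  cfg
}

toy_matrix <- function(pos_levels = c(100, 200, 400),
                       hk_base = c(50, 200, 800),
                       hk_scale = c(1, 2, 4),
                       endo = matrix(c(10, 20, 40, 80,
                                       30, 60, 120, 240,
                                       50, 100, 200, 400),
                                     nrow = 4),
                       batch = c("B1", "B1", "B1")) {
  n <- length(pos_levels)
  counts <- rbind(
    endo,
    outer(hk_base, hk_scale),
    matrix(rep(pos_levels, each = 6), nrow = 6),
    matrix(2, nrow = 2, ncol = n)
  )
  colnames(counts) <- paste0("S", seq_len(n))
  genes <- data.frame(
    symbol = c(paste0("G", 1:4), "NRDC", "OTUD5", "TUBB",
               paste0("POS_", LETTERS[1:6]), "NEG_A", "NEG_B"),
    code_class = c(rep("endogenous", 4), rep("housekeeping", 3),
                   rep("positive_control", 6), rep("negative_control", 2)),
    accession = NA_character_, stringsAsFactors = FALSE)
  ncounter_counts(counts, genes, setNames(batch, colnames(counts)))
}

toy_annotations <- function(ids, group = "healthy_reference",
                            stimulation = "none", subject = NULL,
                            batch = "B1",
                            date = as.Date("2023-01-01") + seq_along(ids)) {
  data.frame(sample_id = ids,
             subject_id = subject %||% paste0("SUBJ_", ids),
             date = date,
             group = rep_len(group, length(ids)),
             batch = rep_len(batch, length(ids)),
             stimulation = rep_len(stimulation, length(ids)),
             days_since_last_infusion = NA_integer_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force transcription of the control-factor formula:
# factor_i = ((1/n) * sum_i geomean_i) / geomean_i, geomean via prod()^(1/k).
brute_force_factors <- function(count_mat, control_rows, pseudocount = 1) {
  gm <- numeric(ncol(count_mat))
  for (i in seq_len(ncol(count_mat))) {
    v <- pmax(count_mat[control_rows, i], pseudocount)
    gm[i] <- prod(v)^(1 / length(v))
  }
  sapply(seq_along(gm), function(i) (sum(gm) / length(gm)) / gm[i])
}

# Brute-force two-step normalization of a single-scope raw matrix.
brute_force_normalize <- function(count_mat, pos_rows, hk_rows,
                                  pseudocount = 1) {
  f_pos <- brute_force_factors(count_mat, pos_rows, pseudocount)
  step1 <- count_mat
  for (i in seq_len(ncol(step1))) step1[, i] <- step1[, i] * f_pos[i]
  f_hk <- brute_force_factors(step1, hk_rows, pseudocount)
  out <- step1
  for (i in seq_len(ncol(out))) out[, i] <- out[, i] * f_hk[i]
  list(pos_factor = f_pos, hk_factor = f_hk, values = out)
}
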