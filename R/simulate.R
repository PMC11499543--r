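#' Simulate an nCounter cohort with known ground truth
#'
#' Generates a raw count matrix, sample sheet and truth object emulating the
#' structure the normalization and scoring stages assume:
#' \itemize{
#'   \item per-lane technical scaling factors, lognormal(0, `sigma_lane`);
#'   \item a six-step geometric positive-control ladder (concentrations
#'     proportional to 128/32/8/2/0.5/0.125), Poisson-distributed around
#'     `lane * concentration * pos_scale`;
#'   \item three housekeeping genes whose biological level is
#'     sample-independent (lane scaling only);
#'   \item endogenous genes (the default 56-gene immune codeset) with
#'     negative-binomial counts of mean `lane * baseline * effect` and size
#'     `dispersion`;
#'   \item ISG-panel elevation `isg_elevation^suppression` in patient
#'     samples (`suppression` = 1 is untreated, 0 fully suppressed, between
#'     values model partial treatment response on the log scale);
#'   \item paired in-vitro aliquots (unstimulated-cultured and
#'     IFN-beta-stimulated) whose ISG genes are multiplied by
#'     `stim_multiplier` in the stimulated member.
#' }
#' Samples are allocated to cartridge batches of `batch_size` lanes, each
#' batch receiving at least `min_healthy_per_batch` healthy references (an
#' error if too few healthy samples are requested, since downstream
#' reference fitting would be impossible). All randomness flows from the
#' explicit `seed`; the caller's RNG state is untouched.
#'
#' @param n_patients,n_healthy numbers of single-draw patient and healthy
#'   reference samples.
#' @param isg_elevation multiplier theta >= 1 on ISG-panel genes in patients;
#'   1 makes patients statistically exchangeable with healthy donors.
#' @param suppression residual fraction s in `[0, 1]` of the log elevation
#'   per patient sample (scalar or vector of length `n_patients`): the
#'   realized effect is `isg_elevation^s`.
#' @param n_stim_pairs number of stimulated/unstimulated aliquot pairs to
#'   add; drawn from `stim_group` subjects.
#' @param stim_multiplier multiplier m >= 1 on ISG genes in stimulated
#'   aliquots (1 models complete receptor blockade).
#' @param stim_group `"healthy"` or `"patient"` donors for the pairs.
#' @param sigma_lane lognormal sd of the lane factors.
#' @param dispersion negative-binomial size parameter of endogenous counts.
#' @param pos_scale counts per concentration unit of the control ladder.
#' @param neg_mean Poisson background mean of negative-control probes.
#' @param batch_size lanes per cartridge batch (platform: 12).
#' @param min_healthy_per_batch healthy references required in every batch.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of endogenous
#'   gene baseline means.
#' @param config a [pipeline_config][load_config] defining the codeset.
#' @param seed integer seed; required.
#' @return Object of class `synthetic_cohort`: `matrix`
#'   ([ncounter_counts]), `annotations` (sample sheet data.frame) and
#'   `truth` (class `synthetic_truth`: lane factors, baselines, per-sample
#'   effects, generator parameters).
#' @export
simulate_cohort <- function(n_patients = 20, n_healthy = 20,
                            isg_elevation = 8, suppression = 1,
                            n_stim_pairs = 0, stim_multiplier = 5,
                            stim_group = c("healthy", "patient"),
                            sigma_lane = 0.3, dispersion = 10,
                            pos_scale = 60, neg_mean = 2,
                            batch_size = 12, min_healthy_per_batch = 2,
                            baseline_meanlog = log(200), baseline_sdlog = 1,
                            config = default_config(), seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stim_group <- match.arg(stim_group)
  stopifnot(isg_elevation >= 1, stim_multiplier >= 1, sigma_lane >= 0,
            dispersion > 0, n_healthy >= 0, n_patients >= 0)
  suppression <- rep_len(suppression, n_patients)
  stopifnot(all(suppression >= 0 & suppression <= 1))
  if (n_stim_pairs > 0) {
    n_donors <- if (stim_group == "healthy") n_healthy else n_patients
    if (n_stim_pairs > n_donors)
      stop("n_stim_pairs exceeds available ", stim_group, " subjects",
           call. = FALSE)
  }

  with_seed(seed, {
    panels <- config$panels
    isg <- panels[["isg"]]$genes
    hk <- panels[["housekeeping"]]$genes
    pos <- panels[["positive_control"]]$genes
    neg <- panels[["negative_control"]]$genes
    endo <- unlist(lapply(panels, function(p)
      if (p$code_class == "endogenous") p$genes), use.names = FALSE)
    endo <- unique(endo)

    # --- sample bookkeeping -------------------------------------------------
    pat_ids <- sprintf("P%02d_T1", seq_len(n_patients))
    hea_ids <- sprintf("H%02d", seq_len(n_healthy))
    subj <- c(sprintf("P%02d", seq_len(n_patients)),
              sprintf("HC%02d", seq_len(n_healthy)))
    grp <- c(rep("patient", n_patients), rep("healthy_reference", n_healthy))
    stim <- rep("none", n_patients + n_healthy)
    ids <- c(pat_ids, hea_ids)
    if (n_stim_pairs > 0) {
      donor_subj <- if (stim_group == "healthy")
        sprintf("HC%02d", seq_len(n_stim_pairs))
      else sprintf("P%02d", seq_len(n_stim_pairs))
      for (k in seq_len(n_stim_pairs)) {
        ids <- c(ids, paste0(donor_subj[k], "_U"), paste0(donor_subj[k], "_S"))
        subj <- c(subj, donor_subj[k], donor_subj[k])
        grp <- c(grp, rep(if (stim_group == "healthy") "healthy_reference"
                          else "patient", 2))
        stim <- c(stim, "unstimulated_cultured", "IFNb_stimulated")
      }
    }
    n <- length(ids)
    dates <- as.Date("2023-01-01") + 7 * (seq_len(n) - 1)
    # paired aliquots share the draw date
    if (n_stim_pairs > 0)
      for (k in seq_len(n_stim_pairs)) {
        i <- n_patients + n_healthy + 2 * k - 1
        dates[i + 1] <- dates[i]
      }

    # --- batch allocation: >= min_healthy_per_batch healthy refs per batch --
    n_batches <- ceiling(n / batch_size)
    healthy_idx <- which(grp == "healthy_reference" & stim == "none")
    if (length(healthy_idx) < min_healthy_per_batch * n_batches)
      stop("cohort of ", n, " samples needs ", n_batches, " batch(es) of ",
           batch_size, " with >= ", min_healthy_per_batch,
           " healthy references each, but only ", length(healthy_idx),
           " healthy samples were requested", call. = FALSE)
    batch <- integer(n)
    take <- healthy_idx[seq_len(min_healthy_per_batch * n_batches)]
    batch[take] <- rep(seq_len(n_batches), each = min_healthy_per_batch)
    rest <- which(batch == 0L)
    free <- batch_size - tabulate(batch[take], n_batches)
    slot <- rep(seq_len(n_batches), times = free)[seq_along(rest)]
    batch[rest] <- slot
    batch_id <- sprintf("CART%02d", batch)

    # --- ground truth -------------------------------------------------------
    lane <- setNames(rlnorm(n, 0, sigma_lane), ids)
    baselines <- setNames(rlnorm(length(endo), baseline_meanlog,
                                 baseline_sdlog), endo)
    hk_base <- setNames(c(300, 500, 1500), hk)  # stable biological levels
    effects <- matrix(1, length(endo), n, dimnames = list(endo, ids))
    if (n_patients > 0 && isg_elevation > 1)
      for (k in seq_len(n_patients))
        effects[isg, k] <- isg_elevation^suppression[k]
    stim_mult <- setNames(rep(1, n), ids)
    if (n_stim_pairs > 0)
      for (k in seq_len(n_stim_pairs)) {
        i <- n_patients + n_healthy + 2 * k  # stimulated member
        stim_mult[i] <- stim_multiplier
        disease <- if (stim_group == "patient")
          isg_elevation^suppression[k] else 1
        effects[isg, i - 1] <- disease
        effects[isg, i] <- disease * stim_multiplier
      }

    ladder <- c(128, 32, 8, 2, 0.5, 0.125)

    # --- counts -------------------------------------------------------------
    endo_mu <- baselines * effects * rep(lane, each = length(endo))
    endo_counts <- matrix(rnbinom(length(endo_mu), mu = endo_mu,
                                  size = dispersion),
                          length(endo), n, dimnames = list(endo, ids))
    hk_mu <- outer(hk_base, lane)
    hk_counts <- matrix(rnbinom(length(hk_mu), mu = hk_mu, size = dispersion),
                        length(hk), n, dimnames = list(hk, ids))
    pos_mu <- outer(ladder * pos_scale, lane)
    pos_counts <- matrix(rpois(length(pos_mu), pos_mu), length(pos), n,
                         dimnames = list(pos, ids))
    neg_counts <- matrix(rpois(length(neg) * n, neg_mean * rep(lane,
                                                               each = length(neg))),
                         length(neg), n, dimnames = list(neg, ids))

    counts <- rbind(endo_counts, hk_counts, pos_counts, neg_counts)
    genes <- data.frame(
      symbol = c(endo, hk, pos, neg),
      code_class = c(rep("endogenous", length(endo)),
                     rep("housekeeping", length(hk)),
                     rep("positive_control", length(pos)),
                     rep("negative_control", length(neg))),
      accession = paste0("SYN_", seq_len(length(endo) + length(hk) +
                                           length(pos) + length(neg))),
      stringsAsFactors = FALSE)
    mat <- ncounter_counts(counts, genes, setNames(batch_id, ids))

    annotations <- data.frame(
      sample_id = ids, subject_id = subj, date = dates, group = grp,
      batch = batch_id, stimulation = stim,
      days_since_last_infusion = NA_integer_, stringsAsFactors = FALSE)
    annotations$therapy <- vector("list", n)

    truth <- structure(list(
      seed = seed, lane = lane, baselines = c(baselines, hk_base),
      effects = effects, dispersion = dispersion,
      isg_elevation = isg_elevation,
      suppression = setNames(c(suppression, rep(NA_real_, n - n_patients)),
                             ids),
      stim_multiplier = stim_mult, ladder = ladder, pos_scale = pos_scale,
      neg_mean = neg_mean, sigma_lane = sigma_lane), class = "synthetic_truth")

    structure(list(matrix = mat, annotations = annotations, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", ncol(x$matrix$counts), " samples (",
      sum(x$annotations$group == "patient"), " patient, ",
      sum(x$annotations$group == "healthy_reference"), " healthy), seed ",
      x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Analytic expected panel scores of a simulated cohort
#'
#' The noise-free oracle for recovery tests: the expected geomean score of
#' each sample computed directly from the generator's mean structure
#' (`baseline * effect`) with lane factors removed, i.e. what a perfect
#' normalization followed by scoring would return on average. For a healthy
#' sample this is the geometric mean of the panel baselines; an untreated
#' patient with elevation theta scores theta times that; a treated patient
#' with residual fraction s scores theta^s times that.
#'
#' @param truth a `synthetic_truth` (from [simulate_cohort()]).
#' @param config a [pipeline_config][load_config].
#' @param panel panel name (default `"isg"`).
#' @return Named numeric vector of expected scores per sample.
#' @export
expected_scores <- function(truth, config = default_config(), panel = "isg") {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- config$panels[[panel]]$genes
  mu <- truth$baselines[genes] * truth$effects[genes, , drop = FALSE]
  apply(mu, 2, geometric_mean)
}

#' Write a simulated cohort as RCC files plus a sample sheet
#'
#' Emits one format-conformant RCC file per sample (Header,
#' Sample_Attributes, Lane_Attributes with the batch as CartridgeID,
#' Code_Summary with vendor code-class spellings, Messages), `sheet.csv`, and
#' `truth.csv` (sample, lane factor, realized ISG effect). [read_rcc()] on
#' the output reproduces the count matrix exactly.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param out_dir output directory, created if needed.
#' @return Invisible list with `rcc` (file paths), `sheet`, `truth` paths.
#' @export
write_synthetic_rcc <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- cohort$matrix
  vendor_class <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
                    positive_control = "Positive",
                    negative_control = "Negative")
  lane_no <- stats::ave(seq_along(mat$batch), mat$batch,
                        FUN = seq_along)
  paths <- character(0)
  for (j in seq_len(ncol(mat$counts))) {
    sid <- colnames(mat$counts)[j]
    f <- file.path(out_dir, paste0(sid, ".RCC"))
    rows <- paste(vendor_class[mat$genes$code_class], mat$genes$symbol,
                  mat$genes$accession, format(mat$counts[, j], scientific = FALSE,
                                              trim = TRUE),
                  sep = ",")
    writeLines(c(
      "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
      "<Sample_Attributes>", paste0("ID,", sid),
      paste0("Date,", format(cohort$annotations$date[j], "%Y%m%d")),
      "</Sample_Attributes>",
      "<Lane_Attributes>", paste0("ID,", lane_no[j]),
      paste0("CartridgeID,", mat$batch[j]), "</Lane_Attributes>",
      "<Code_Summary>", "CodeClass,Name,Accession,Count", rows,
      "</Code_Summary>", "<Messages>", "</Messages>"), f)
    paths <- c(paths, f)
  }
  sheet_path <- file.path(out_dir, "sheet.csv")
  ann <- cohort$annotations
  sheet <- ann[c("sample_id", "subject_id", "date", "group", "batch",
                 "stimulation", "days_since_last_infusion")]
  write.csv(sheet, sheet_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.csv")
  write.csv(data.frame(sample_id = names(cohort$truth$lane),
                       lane_factor = unname(cohort$truth$lane),
                       isg_effect = apply(cohort$truth$effects, 2, max),
                       stringsAsFactors = FALSE),
            truth_path, row.names = FALSE)
  invisible(list(rcc = paths, sheet = sheet_path, truth = truth_path))
}
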