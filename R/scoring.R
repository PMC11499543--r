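#' Panel geomean score
#'
#' The per-sample geometric mean of normalized counts over a panel's genes —
#' for the default 30-gene ISG panel this is the ISG score used to track
#' type-I interferon pathway activity. Values are floored at the pseudocount
#' so an undetected gene contributes the floor rather than breaking the mean.
#'
#' @param matrix an `ncounter_normalized` (or raw `ncounter_counts`) object.
#' @param panel a [gene_panel] of endogenous genes.
#' @param pseudocount positive floor.
#' @param allow_partial score the panel even if some genes are absent from
#'   the matrix (off by default; the score is then over the present genes).
#' @return Named numeric vector of scores, one per sample.
#' @export
geomean_score <- function(matrix, panel, pseudocount = 1,
                          allow_partial = FALSE) {
  stopifnot(pseudocount > 0)
  rows <- panel_rows(matrix, panel, allow_partial = allow_partial)
  if (!length(rows))
    stop("panel '", panel$name, "': no genes present in matrix", call. = FALSE)
  v <- pmax(value_matrix(matrix)[rows, , drop = FALSE], pseudocount)
  apply(v, 2, geometric_mean)
}

#' Fit healthy-reference statistics for a panel
#'
#' Estimates, from unstimulated healthy-reference samples, each panel gene's
#' location and scale on the log scale (mean and sd of
#' `log_base(value + pseudocount)`) and the healthy band of geomean scores
#' (by default the 2.5th–97.5th percentile; min–max via
#' `config$band_type = "minmax"`). These are the standardization constants of
#' the Z-score and the shaded normality region of trajectory plots.
#'
#' Genes with (near-)zero variance across the references would produce
#' unbounded z values, so reference sds are floored at
#' `sd_floor_frac * median(sd)` of the panel (and at `sd_floor_abs`
#' absolutely); floored genes are reported with a warning.
#'
#' @param matrix an `ncounter_normalized` object.
#' @param annotations sample sheet data.frame (see [read_sample_sheet()]).
#' @param panel a [gene_panel].
#' @param config a [pipeline_config][load_config].
#' @return Object of class `isg_reference` with elements `panel`,
#'   `gene_stats` (gene, mean, sd), `n_reference`, `band`, `log_base`,
#'   `pseudocount`.
#' @export
fit_reference <- function(matrix, annotations, panel,
                          config = default_config()) {
  ref_ids <- annotations$sample_id[annotations$group == "healthy_reference" &
                                     annotations$stimulation == "none"]
  ref_ids <- intersect(colnames(value_matrix(matrix)), ref_ids)
  if (length(ref_ids) < 2)
    stop("need at least 2 unstimulated healthy_reference samples to fit a ",
         "reference (found ", length(ref_ids), ")", call. = FALSE)
  rows <- panel_rows(matrix, panel)
  lv <- log(value_matrix(matrix)[rows, ref_ids, drop = FALSE] +
              config$pseudocount, base = config$log_base)
  mu <- rowMeans(lv)
  sdev <- apply(lv, 1, sd)
  floor_val <- max(config$sd_floor_frac * median(sdev), config$sd_floor_abs)
  floored <- sdev < floor_val
  if (any(floored))
    warning("reference sd floored at ", signif(floor_val, 4), " for gene(s): ",
            paste(panel$genes[floored], collapse = ", "), call. = FALSE)
  sdev[floored] <- floor_val
  scores <- geomean_score(matrix, panel, config$pseudocount)[ref_ids]
  band <- if (identical(config$band_type, "minmax")) range(scores)
  else unname(quantile(scores, config$reference_band / 100, type = 7))
  structure(list(panel = panel,
                 gene_stats = data.frame(gene = panel$genes, mean = unname(mu),
                                         sd = unname(sdev),
                                         stringsAsFactors = FALSE),
                 n_reference = length(ref_ids),
                 reference_ids = ref_ids,
                 band = band, band_type = config$band_type,
                 log_base = config$log_base,
                 pseudocount = config$pseudocount,
                 z_truncate = config$z_truncate),
            class = "isg_reference")
}

#' @export
print.isg_reference <- function(x, ...) {
  cat("<isg_reference> panel '", x$panel$name, "' (",
      nrow(x$gene_stats), " genes), fitted on ", x$n_reference,
      " healthy reference samples\n", sep = "")
  cat("  healthy geomean-score band (", x$band_type, "): [",
      signif(x$band[1], 4), ", ", signif(x$band[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Panel Z-score against a healthy reference
#'
#' Per sample, each panel gene's `log_base(value + pseudocount)` is
#' standardized by the reference mean and sd for that gene; the Z-score is the
#' arithmetic mean of the per-gene z values over the panel. Per-gene z values
#' are truncated at `±z_truncate` (default 10) to bound the influence of a
#' single extreme probe.
#'
#' @param matrix an `ncounter_normalized` object.
#' @param panel a [gene_panel]; must be the panel the reference was fitted on.
#' @param reference an [isg_reference][fit_reference].
#' @return Named numeric vector of Z-scores per sample.
#' @export
z_score <- function(matrix, panel, reference) {
  stopifnot(inherits(reference, "isg_reference"))
  if (!identical(panel$genes, reference$panel$genes) ||
      !identical(panel$name, reference$panel$name))
    stop("reference was fitted on panel '", reference$panel$name,
         "' with a different gene list; refit the reference", call. = FALSE)
  rows <- panel_rows(matrix, panel)
  lv <- log(value_matrix(matrix)[rows, , drop = FALSE] +
              reference$pseudocount, base = reference$log_base)
  z <- (lv - reference$gene_stats$mean) / reference$gene_stats$sd
  z <- pmin(pmax(z, -reference$z_truncate), reference$z_truncate)
  colMeans(z)
}

#' @export
#' @rdname z_score
#' @param object an `isg_reference`.
#' @param ... unused.
predict.isg_reference <- function(object, matrix, ...) {
  z_score(matrix, object$panel, object)
}

#' Score all samples on the configured panels
#'
#' Composes [geomean_score()] and [z_score()] over the configured score
#' panels (by default `isg`, `nfkb`, `ifng`), producing one row per
#' (sample, panel). References are fitted on the matrix's own unstimulated
#' healthy samples unless supplied.
#'
#' @param matrix an `ncounter_normalized` object.
#' @param annotations sample sheet data.frame.
#' @param config a [pipeline_config][load_config].
#' @param references optional named list of [isg_reference][fit_reference]
#'   objects keyed by panel name; fitted on the fly when omitted.
#' @param panels character vector of panel names to score.
#' @return data.frame: sample_id, subject_id, date, panel, geomean_score,
#'   z_score, n_genes_used, batch, stimulation, days_since_last_infusion.
#' @export
score_samples <- function(matrix, annotations, config = default_config(),
                          references = NULL,
                          panels = c("isg", "nfkb", "ifng")) {
  stopifnot(inherits(matrix, "ncounter_normalized"))
  panels <- intersect(panels, names(config$panels))
  if (!length(panels)) stop("no scoreable panels configured", call. = FALSE)
  samples <- colnames(matrix$values)
  ann <- annotations[match(samples, annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id))
    stop("samples missing from annotations: ",
         paste(samples[is.na(ann$sample_id)], collapse = ", "), call. = FALSE)
  if (is.null(references))
    references <- lapply(setNames(panels, panels), function(nm)
      fit_reference(matrix, annotations, config$panels[[nm]], config))
  out <- do.call(rbind, lapply(panels, function(nm) {
    panel <- config$panels[[nm]]
    gm <- geomean_score(matrix, panel, config$pseudocount)
    zz <- z_score(matrix, panel, references[[nm]])
    data.frame(sample_id = samples, subject_id = ann$subject_id,
               date = ann$date, panel = nm,
               geomean_score = unname(gm[samples]),
               z_score = unname(zz[samples]),
               n_genes_used = length(panel$genes),
               batch = unname(matrix$batch[samples]),
               stimulation = ann$stimulation,
               days_since_last_infusion = ann$days_since_last_infusion,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
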