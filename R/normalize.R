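#' Geometric mean
#'
#' The aggregation used throughout the pipeline: in the control-based
#' normalization factors and in the panel geomean score. Defined as
#' `exp(mean(log(x)))`; zeros must be floored by the caller's pseudocount
#' policy before calling.
#'
#' @param values nonempty numeric vector of positive values.
#' @return The geometric mean, a positive scalar.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("geometric mean of empty input", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric mean requires positive values; floor zeros with the ",
         "pseudocount policy first", call. = FALSE)
  exp(mean(log(values)))
}

#' Per-sample geometric mean of a control panel
#'
#' For each sample, the geometric mean of `max(count, pseudocount)` over the
#' panel genes. With the positive-control panel this is the quantity the
#' lane normalization factor is built from; with the housekeeping panel, the
#' input-amount factor.
#'
#' @param matrix an `ncounter_counts` or `ncounter_normalized` object.
#' @param panel a [gene_panel].
#' @param pseudocount positive floor applied before the geometric mean.
#' @return Named numeric vector, one value per sample.
#' @export
control_geomeans <- function(matrix, panel, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  rows <- panel_rows(matrix, panel)
  v <- pmax(value_matrix(matrix)[rows, , drop = FALSE], pseudocount)
  apply(v, 2, geometric_mean)
}

#' Control-based normalization factor
#'
#' For sample i in a scope of n samples with control geometric mean g_i, the
#' factor is `mean(g) / g_i` — the ratio of the scope-average control
#' geometric mean to the sample's own. Multiplying each sample's counts by its
#' factor equalizes the control geometric means across the scope while
#' conserving their arithmetic mean.
#'
#' @param geomeans positive numeric vector of per-sample control geometric
#'   means (the scope: one batch, or the whole cohort).
#' @return Numeric vector of factors, same names as `geomeans`.
#' @export
normalization_factor <- function(geomeans) {
  if (length(geomeans) == 0L) stop("empty normalization scope", call. = FALSE)
  if (any(!is.finite(geomeans)) || any(geomeans <= 0))
    stop("normalization factors require positive geometric means",
         call. = FALSE)
  mean(geomeans) / geomeans
}

#' Two-step nCounter normalization
#'
#' Step 1 computes a positive-control factor per sample from the raw
#' positive-control geometric means and rescales all counts by it, removing
#' lane-to-lane technical variation. Step 2 computes a housekeeping factor
#' from the housekeeping geometric means of the step-1-scaled counts and
#' rescales again, removing RNA-input variation. The normalized value is
#' `raw * pos_factor * hk_factor`. Factor scope follows
#' `config$batch_policy`: per cartridge batch (default) or global.
#'
#' After step 1 all samples in a scope share the same positive-control
#' geometric mean; after step 2 they share the same housekeeping geometric
#' mean (each equal to the scope mean at the time of its computation).
#' Setting `config$hk_factor_on_raw` computes the housekeeping factor from
#' raw instead of step-1 counts, for reproduction of analyses that took both
#' factors from raw data.
#'
#' @param matrix an [ncounter_counts] object.
#' @param config a [pipeline_config][load_config] providing the
#'   `positive_control` and `housekeeping` panels, batch policy and
#'   pseudocount.
#' @return An object of class `ncounter_normalized`: normalized `values`
#'   (same shape as the input), the input's `genes` and `batch`, a `factors`
#'   data.frame (sample_id, batch, pos_factor, hk_factor, n_in_scope) and a
#'   `provenance` list.
#' @export
normalize_counts <- function(matrix, config = default_config()) {
  if (inherits(matrix, "ncounter_normalized"))  # re-normalization: values as raw
    matrix <- structure(list(counts = matrix$values, genes = matrix$genes,
                             batch = matrix$batch),
                        class = "ncounter_counts")
  stopifnot(inherits(matrix, "ncounter_counts"),
            inherits(config, "pipeline_config"))
  pos_panel <- config$panels[["positive_control"]]
  hk_panel <- config$panels[["housekeeping"]]
  if (is.null(pos_panel) || is.null(hk_panel))
    stop("config must define 'positive_control' and 'housekeeping' panels",
         call. = FALSE)
  ps <- config$pseudocount
  samples <- colnames(matrix$counts)
  scopes <- if (config$batch_policy == "per_batch")
    split(samples, matrix$batch[samples]) else list(all = samples)

  pos_g <- control_geomeans(matrix, pos_panel, ps)
  pos_factor <- setNames(numeric(length(samples)), samples)
  n_scope <- setNames(integer(length(samples)), samples)
  for (sc in scopes) {
    pos_factor[sc] <- normalization_factor(pos_g[sc])
    n_scope[sc] <- length(sc)
  }
  step1 <- sweep(matrix$counts, 2, pos_factor, `*`)

  hk_rows <- panel_rows(matrix, hk_panel)
  hk_source <- if (config$hk_factor_on_raw) matrix$counts else step1
  hk_g <- apply(pmax(hk_source[hk_rows, , drop = FALSE], ps), 2,
                geometric_mean)
  hk_factor <- setNames(numeric(length(samples)), samples)
  for (sc in scopes) hk_factor[sc] <- normalization_factor(hk_g[sc])
  if (any(!is.finite(pos_factor)) || any(!is.finite(hk_factor)))
    stop("non-finite normalization factor", call. = FALSE)

  values <- sweep(step1, 2, hk_factor, `*`)
  factors <- data.frame(sample_id = samples,
                        batch = unname(matrix$batch[samples]),
                        pos_factor = unname(pos_factor),
                        hk_factor = unname(hk_factor),
                        n_in_scope = unname(n_scope),
                        stringsAsFactors = FALSE)
  structure(list(values = values, genes = matrix$genes, batch = matrix$batch,
                 factors = factors,
                 provenance = list(batch_policy = config$batch_policy,
                                   pseudocount = ps,
                                   hk_factor_on_raw = config$hk_factor_on_raw)),
            class = "ncounter_normalized")
}

#' @export
print.ncounter_normalized <- function(x, ...) {
  cat("<ncounter_normalized> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples | policy: ", x$provenance$batch_policy, "\n", sep = "")
  f <- x$factors
  cat("  pos_factor range [", signif(min(f$pos_factor), 4), ", ",
      signif(max(f$pos_factor), 4), "], hk_factor range [",
      signif(min(f$hk_factor), 4), ", ", signif(max(f$hk_factor), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ncounter_normalized <- function(x) dim(x$values)
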