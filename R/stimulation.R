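#' Pair stimulated and unstimulated aliquots of the same blood draw
#'
#' The in-vitro responsiveness assay cultures two aliquots of one draw, one
#' stimulated with IFN-beta, and compares their panel scores: under intact
#' type-I IFN signaling the stimulated aliquot's ISG score rises severalfold,
#' while under effective receptor blockade the induction ratio stays near 1.
#' Pairs are matched exactly on (subject, draw date); a stimulated sample
#' whose draw has both an uncultured and a cultured unstimulated aliquot is
#' ambiguous and raises an error (choose the denominator by filtering the
#' annotations first).
#'
#' @param scores score table from [score_samples()].
#' @param annotations sample sheet data.frame.
#' @param panel panel name to take scores from (default `"isg"`).
#' @param threshold induction ratio at or above which a pair is called
#'   responsive (default 2).
#' @return data.frame of pairs: subject_id, date, unstim_sample_id,
#'   stim_sample_id, unstim_score, stim_score, induction_ratio, responsive,
#'   days_since_last_infusion. Unmatched stimulated samples are dropped with
#'   a warning.
#' @export
pair_samples <- function(scores, annotations, panel = "isg", threshold = 2) {
  sc <- scores[scores$panel == panel, , drop = FALSE]
  ann <- annotations[match(sc$sample_id, annotations$sample_id), ,
                     drop = FALSE]
  stim_idx <- which(ann$stimulation == "IFNb_stimulated")
  pairs <- list()
  for (i in stim_idx) {
    cand <- which(ann$subject_id == ann$subject_id[i] &
                    ann$date == ann$date[i] &
                    ann$stimulation %in% c("none", "unstimulated_cultured"))
    if (length(cand) == 0L) {
      warning("stimulated sample ", ann$sample_id[i],
              " has no same-date unstimulated partner; not paired",
              call. = FALSE)
      next
    }
    if (length(cand) > 1L)
      stop("ambiguous pairing for stimulated sample ", ann$sample_id[i],
           ": unstimulated candidates ",
           paste(ann$sample_id[cand], collapse = ", "), call. = FALSE)
    j <- cand
    ratio <- sc$geomean_score[i] / sc$geomean_score[j]
    pairs[[length(pairs) + 1L]] <- data.frame(
      subject_id = ann$subject_id[i], date = ann$date[i],
      unstim_sample_id = ann$sample_id[j], stim_sample_id = ann$sample_id[i],
      unstim_score = sc$geomean_score[j], stim_score = sc$geomean_score[i],
      induction_ratio = ratio, responsive = ratio >= threshold,
      days_since_last_infusion = ann$days_since_last_infusion[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(subject_id = character(), date = as.Date(character()),
               unstim_sample_id = character(), stim_sample_id = character(),
               unstim_score = numeric(), stim_score = numeric(),
               induction_ratio = numeric(), responsive = logical(),
               days_since_last_infusion = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify IFN-beta responsiveness from the induction ratio
#'
#' A pair is responsive when its stimulated/unstimulated score ratio meets
#' the threshold. The raw ratio should always be reported alongside the call;
#' the binary call is a convenience, not a substitute.
#'
#' @param pairs data.frame from [pair_samples()] (or any frame with an
#'   `induction_ratio` column).
#' @param threshold positive ratio, > 1 (default 2).
#' @return `pairs` with the `responsive` column recomputed at `threshold`.
#' @export
classify_response <- function(pairs, threshold = 2) {
  stopifnot(is.numeric(threshold), threshold > 1)
  pairs$responsive <- pairs$induction_ratio >= threshold
  pairs
}
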