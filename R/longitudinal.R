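#' Assemble per-subject score trajectories
#'
#' Builds one time-ordered trajectory per (subject, panel) from unstimulated
#' samples, attaching the healthy reference band and optional subject-level
#' clinical annotations: therapy intervals, infusion dates and free-text
#' events (infections, flares). Stimulated and cultured aliquots belong to
#' the in-vitro assay and are excluded. Samples sharing a date are kept, tie
#' broken by sample id.
#'
#' @param scores score table from [score_samples()].
#' @param annotations sample sheet data.frame.
#' @param reference optional [isg_reference][fit_reference] supplying the
#'   healthy band.
#' @param therapy optional data.frame (subject_id, drug, dose, start, stop).
#' @param infusions optional data.frame (subject_id, drug, date). An infusion
#'   outside every therapy interval for its drug is flagged with a warning.
#' @param events optional data.frame (subject_id, date, label).
#' @param panels panel names to assemble (default: all panels in `scores`).
#' @return Object of class `isg_trajectories`: a list of trajectories, each
#'   with `subject_id`, `panel`, `points` (date-ordered data.frame),
#'   `therapy`, `infusions`, `events`, `band`.
#' @export
assemble_trajectories <- function(scores, annotations, reference = NULL,
                                  therapy = NULL, infusions = NULL,
                                  events = NULL, panels = NULL) {
  orphans <- setdiff(scores$sample_id, annotations$sample_id)
  if (length(orphans))
    stop("score rows without sample annotation: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  ann <- annotations[match(scores$sample_id, annotations$sample_id), ,
                     drop = FALSE]
  keep <- ann$stimulation == "none"
  sc <- scores[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  if (is.null(panels)) panels <- unique(sc$panel)
  band <- if (!is.null(reference)) reference$band else c(NA_real_, NA_real_)
  if (!is.null(infusions) && !is.null(therapy)) {
    for (k in seq_len(nrow(infusions))) {
      iv <- therapy[therapy$subject_id == infusions$subject_id[k] &
                      therapy$drug == infusions$drug[k], , drop = FALSE]
      covered <- nrow(iv) > 0 && any(iv$start <= infusions$date[k] &
                                       (is.na(iv$stop) |
                                          infusions$date[k] <= iv$stop))
      if (!covered)
        warning("infusion of ", infusions$drug[k], " on ",
                infusions$date[k], " for subject ", infusions$subject_id[k],
                " lies outside every therapy interval for that drug",
                call. = FALSE)
    }
  }
  trajs <- list()
  for (subj in sort(unique(ann$subject_id))) {
    for (pn in panels) {
      idx <- which(ann$subject_id == subj & sc$panel == pn)
      if (!length(idx)) next
      pts <- data.frame(date = sc$date[idx], sample_id = sc$sample_id[idx],
                        geomean_score = sc$geomean_score[idx],
                        z_score = sc$z_score[idx], batch = sc$batch[idx],
                        stringsAsFactors = FALSE)
      pts <- pts[order(pts$date, pts$sample_id), , drop = FALSE]
      rownames(pts) <- NULL
      sub_tab <- function(tab) {
        if (is.null(tab)) return(NULL)
        out <- tab[tab$subject_id == subj, , drop = FALSE]
        rownames(out) <- NULL
        out
      }
      trajs[[paste(subj, pn, sep = ".")]] <- structure(
        list(subject_id = subj, panel = pn, points = pts,
             therapy = sub_tab(therapy), infusions = sub_tab(infusions),
             events = sub_tab(events), band = band),
        class = "isg_trajectory")
    }
  }
  structure(trajs, class = "isg_trajectories")
}

#' @export
print.isg_trajectory <- function(x, ...) {
  cat("<isg_trajectory> subject ", x$subject_id, ", panel '", x$panel, "', ",
      nrow(x$points), " timepoints\n", sep = "")
  invisible(x)
}

#' @export
print.isg_trajectories <- function(x, ...) {
  cat("<isg_trajectories> ", length(x), " trajectories\n", sep = "")
  for (t in x)
    cat("  ", t$subject_id, " / ", t$panel, ": ", nrow(t$points),
        " points\n", sep = "")
  invisible(x)
}

#' Cohort summary of trajectories
#'
#' One row per trajectory: baseline (first) and latest score, their
#' fold-change (latest/baseline, exactly as in the trajectory table) and the
#' fraction of points whose geomean score lies inside the healthy band.
#'
#' @param trajectories an [isg_trajectories][assemble_trajectories] object.
#' @return data.frame: subject_id, panel, n_points, baseline_score,
#'   latest_score, fold_change, frac_in_band.
#' @export
summarize_trajectories <- function(trajectories) {
  rows <- lapply(trajectories, function(t) {
    s <- t$points$geomean_score
    in_band <- if (anyNA(t$band)) NA_real_ else
      mean(s >= t$band[1] & s <= t$band[2])
    data.frame(subject_id = t$subject_id, panel = t$panel,
               n_points = length(s), baseline_score = s[1],
               latest_score = s[length(s)],
               fold_change = s[length(s)] / s[1],
               frac_in_band = in_band, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(subject_id = character(), panel = character(),
                      n_points = integer(), baseline_score = numeric(),
                      latest_score = numeric(), fold_change = numeric(),
                      frac_in_band = numeric(), stringsAsFactors = FALSE)
  out
}

#' Plot one trajectory
#'
#' Score-versus-date line plot with the shaded healthy band, therapy interval
#' ribbons with dose labels, vertical infusion markers (pink) and event
#' labels — the standard visual grammar for longitudinal interferon-signature
#' monitoring.
#'
#' @param x an `isg_trajectory`.
#' @param log_y plot the score axis on a log scale (default TRUE).
#' @param band_col,infusion_col fill/line colors.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.isg_trajectory <- function(x, log_y = TRUE, band_col = "grey80",
                                infusion_col = "hotpink", ...) {
  pts <- x$points
  ylim <- range(c(pts$geomean_score, x$band), na.rm = TRUE)
  plot(pts$date, pts$geomean_score, type = "n", log = if (log_y) "y" else "",
       xlab = "date", ylab = paste(x$panel, "geomean score"),
       main = paste("subject", x$subject_id), ylim = ylim, ...)
  if (!anyNA(x$band)) {
    usr <- par("usr")
    graphics::rect(usr[1], x$band[1], usr[2], x$band[2],
                   col = adjustcolor(band_col, 0.6), border = NA)
  }
  if (!is.null(x$infusions) && nrow(x$infusions))
    abline(v = as.numeric(x$infusions$date), col = infusion_col, lwd = 1.5)
  if (!is.null(x$therapy) && nrow(x$therapy)) {
    yb <- ylim[1]
    for (k in seq_len(nrow(x$therapy))) {
      iv <- x$therapy[k, ]
      stop_d <- if (is.na(iv$stop)) max(pts$date) else iv$stop
      graphics::segments(as.numeric(iv$start), yb, as.numeric(stop_d), yb,
                         lwd = 4, col = adjustcolor("steelblue", 0.7))
      text(as.numeric(iv$start), yb, paste0(iv$drug, " ", iv$dose),
           pos = 3, cex = 0.6)
    }
  }
  if (!is.null(x$events) && nrow(x$events))
    text(as.numeric(x$events$date), ylim[2], x$events$label, srt = 90,
         adj = 1, cex = 0.6)
  lines(pts$date, pts$geomean_score, col = "grey30")
  points(pts$date, pts$geomean_score, pch = 19)
  invisible(x)
}

#' Render trajectory figures and a cohort summary
#'
#' Writes one PNG per trajectory plus `summary.csv` (see
#' [summarize_trajectories()]). Deterministic: re-rendering the same
#' trajectories reproduces an identical summary file.
#'
#' @param trajectories an [isg_trajectories][assemble_trajectories] object.
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config][load_config] (reserved for style
#'   options).
#' @return Invisible list with `figures` (paths) and `summary` (path).
#' @export
render_report <- function(trajectories, out_dir, config = default_config()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  figs <- character()
  for (t in trajectories) {
    f <- file.path(out_dir, paste0(t$subject_id, "_", t$panel, ".png"))
    png(f, width = 900, height = 500)
    plot(t)
    dev.off()
    figs <- c(figs, f)
  }
  summary_path <- file.path(out_dir, "summary.csv")
  write.csv(summarize_trajectories(trajectories), summary_path,
            row.names = FALSE)
  invisible(list(figures = figs, summary = summary_path))
}
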