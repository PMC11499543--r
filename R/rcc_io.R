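#' Raw nCounter count matrix
#'
#' Container for a gene x sample table of raw probe counts together with probe
#' metadata (symbol, code class, accession) and the cartridge/batch membership
#' of every sample. One nCounter cartridge holds up to 12 lanes, so a batch
#' with more than 12 samples is suspicious and triggers a warning.
#'
#' @param counts numeric matrix, genes in rows, samples in columns; all values
#'   must be nonnegative integers.
#' @param genes data.frame with columns `symbol`, `code_class`, `accession`,
#'   one row per row of `counts`.
#' @param batch character vector of batch ids, one per sample, named by
#'   sample id (or unnamed in column order).
#' @return An object of class `ncounter_counts`.
#' @export
ncounter_counts <- function(counts, genes, batch) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  stopifnot(is.data.frame(genes), nrow(genes) == nrow(counts),
            all(c("symbol", "code_class", "accession") %in% names(genes)))
  for (cc in unique(genes$code_class)) {
    sym <- genes$symbol[genes$code_class == cc]
    if (anyDuplicated(sym))
      stop("duplicate gene symbol within code class '", cc, "': ",
           paste(unique(sym[duplicated(sym)]), collapse = ", "),
           call. = FALSE)
  }
  samples <- colnames(counts)
  if (is.null(names(batch))) names(batch) <- samples
  if (!setequal(names(batch), samples) || length(batch) != length(samples))
    stop("batch must map every sample to exactly one batch id", call. = FALSE)
  batch <- batch[samples]
  tab <- table(batch)
  if (any(tab > 12))
    warning("batch(es) with more than 12 samples: ",
            paste(names(tab)[tab > 12], collapse = ", "), call. = FALSE)
  rownames(counts) <- make.unique(genes$symbol)
  structure(list(counts = counts, genes = genes, batch = batch),
            class = "ncounter_counts")
}

#' @export
print.ncounter_counts <- function(x, ...) {
  cat("<ncounter_counts> ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples in ", length(unique(x$batch)), " batch(es)\n", sep = "")
  print(table(x$genes$code_class))
  invisible(x)
}

#' @export
dim.ncounter_counts <- function(x) dim(x$counts)

# Matrix of values from either raw or normalized containers.
value_matrix <- function(x) {
  if (inherits(x, "ncounter_counts")) x$counts
  else if (inherits(x, "ncounter_normalized")) x$values
  else stop("expected an ncounter_counts or ncounter_normalized object")
}

# Row indices of a panel's genes in a matrix; errors on any missing gene
# unless allow_partial.
panel_rows <- function(x, panel, allow_partial = FALSE) {
  g <- x$genes
  idx <- which(g$code_class == panel$code_class & g$symbol %in% panel$genes)
  found <- g$symbol[idx]
  miss <- setdiff(panel$genes, found)
  if (length(miss) && !allow_partial)
    stop("panel '", panel$name, "': gene(s) missing from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx[match(intersect(panel$genes, found), found)]
}

parse_rcc_sections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("^<[A-Za-z_]+>\\s*$", lines)
  close <- grep("^</[A-Za-z_]+>\\s*$", lines)
  sections <- list()
  for (i in seq_along(open)) {
    nm <- sub("^<([A-Za-z_]+)>\\s*$", "\\1", lines[open[i]])
    end <- close[close > open[i]][1]
    if (is.na(end)) stop("RCC '", path, "': unterminated section <", nm, ">",
                         call. = FALSE)
    sections[[nm]] <- lines[seq(open[i] + 1L, end - 1L)]
  }
  sections
}

attr_field <- function(section, key) {
  if (is.null(section)) return(NA_character_)
  hit <- grep(paste0("^", key, ","), section, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", key, ","), "", hit[1])
}

#' Read NanoString RCC files into a count matrix
#'
#' Each RCC file holds one lane (one sample): bracket-delimited sections with
#' the probe counts in `Code_Summary` as `CodeClass,Name,Accession,Count` rows.
#' Code classes are mapped case-insensitively onto
#' endogenous/housekeeping/positive_control/negative_control, accepting the
#' vendor dialect spellings `Endogenous1/2`, `Positive`, `Negative`; probes
#' with an unrecognized class are retained but never enter any computation.
#'
#' @param paths character vector of RCC file paths.
#' @param batch_map optional named character vector mapping file path (or
#'   basename) to a batch id; by default the batch is the cartridge ID from
#'   `Lane_Attributes` (one cartridge = one batch of up to 12 lanes).
#' @return An [ncounter_counts] object with samples sorted by sample id, so
#'   that the result does not depend on the order of `paths`.
#' @export
read_rcc <- function(paths, batch_map = NULL) {
  stopifnot(length(paths) > 0)
  parsed <- lapply(paths, function(p) {
    sec <- parse_rcc_sections(p)
    if (is.null(sec$Code_Summary))
      stop("RCC '", p, "': missing Code_Summary section", call. = FALSE)
    rows <- sec$Code_Summary
    rows <- rows[nzchar(trimws(rows))]
    header <- strsplit(rows[1], ",")[[1]]
    if (!all(c("CodeClass", "Name", "Count") %in% header))
      stop("RCC '", p, "': Code_Summary header must contain CodeClass, Name, ",
           "Count", call. = FALSE)
    body <- rows[-1]
    parts <- strsplit(body, ",")
    tab <- do.call(rbind, lapply(seq_along(parts), function(i) {
      f <- parts[[i]]
      if (length(f) < length(header))
        stop("RCC '", p, "': malformed Code_Summary row ", i + 1L,
             call. = FALSE)
      f[seq_along(header)]
    }))
    colnames(tab) <- header
    cnt <- suppressWarnings(as.numeric(tab[, "Count"]))
    bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 0)
    if (length(bad))
      stop("RCC '", p, "': non-integer count in Code_Summary row ",
           bad[1] + 1L, " ('", tab[bad[1], "Count"], "')", call. = FALSE)
    key <- paste(tab[, "CodeClass"], tab[, "Name"])
    if (anyDuplicated(key))
      stop("RCC '", p, "': duplicate (CodeClass, Name) entry: ",
           key[duplicated(key)][1], call. = FALSE)
    sid <- attr_field(sec$Sample_Attributes, "ID")
    if (is.na(sid) || !nzchar(sid))
      sid <- sub("\\.[Rr][Cc][Cc]$", "", basename(p))
    cart <- attr_field(sec$Lane_Attributes, "CartridgeID")
    acc <- if ("Accession" %in% header) tab[, "Accession"] else NA_character_
    list(path = p, sample = sid, cartridge = cart,
         genes = data.frame(symbol = tab[, "Name"],
                            code_class = map_code_class(tab[, "CodeClass"]),
                            accession = acc, stringsAsFactors = FALSE),
         counts = cnt)
  })
  sids <- vapply(parsed, `[[`, "", "sample")
  if (anyDuplicated(sids))
    stop("duplicate sample id across RCC files: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "), call. = FALSE)
  parsed <- parsed[order(sids)]
  # union of probes, order stabilized by first appearance
  genes <- parsed[[1]]$genes
  for (p in parsed[-1]) {
    key <- paste(genes$code_class, genes$symbol)
    new <- !(paste(p$genes$code_class, p$genes$symbol) %in% key)
    if (any(new)) genes <- rbind(genes, p$genes[new, , drop = FALSE])
  }
  gkey <- paste(genes$code_class, genes$symbol)
  counts <- matrix(0, nrow(genes), length(parsed),
                   dimnames = list(NULL, vapply(parsed, `[[`, "", "sample")))
  for (j in seq_along(parsed)) {
    p <- parsed[[j]]
    counts[match(paste(p$genes$code_class, p$genes$symbol), gkey), j] <-
      p$counts
  }
  batch <- vapply(parsed, function(p) {
    if (!is.null(batch_map)) {
      if (p$path %in% names(batch_map)) return(batch_map[[p$path]])
      if (basename(p$path) %in% names(batch_map))
        return(batch_map[[basename(p$path)]])
    }
    if (!is.na(p$cartridge)) p$cartridge else "batch1"
  }, "")
  names(batch) <- colnames(counts)
  ncounter_counts(counts, genes, batch)
}

#' Read a gene x sample count table from CSV
#'
#' Alternative to [read_rcc()] for counts already exported as a flat table:
#' one row per probe, one column per sample, plus a gene-symbol column and a
#' code-class column (vendor dialect spellings accepted).
#'
#' @param path CSV file path.
#' @param gene_column,code_class_column,accession_column names of the metadata
#'   columns; `accession_column` may be absent from the file.
#' @param batch optional named character vector sample id -> batch id (e.g.
#'   from the sample sheet); defaults to a single batch.
#' @return An [ncounter_counts] object.
#' @export
read_count_table <- function(path, gene_column = "gene",
                             code_class_column = "code_class",
                             accession_column = "accession",
                             batch = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(gene_column, code_class_column))
    if (!col %in% names(df))
      stop("count table '", path, "': missing column '", col, "'",
           call. = FALSE)
  meta_cols <- intersect(c(gene_column, code_class_column, accession_column),
                         names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols))
    stop("count table '", path, "': no sample columns", call. = FALSE)
  counts <- as.matrix(df[sample_cols])
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("count table '", path, "': counts must be nonnegative integers",
         call. = FALSE)
  cc_raw <- df[[code_class_column]]
  unknown <- !(tolower(trimws(cc_raw)) %in% names(CODE_CLASS_DIALECTS))
  if (any(unknown))
    stop("count table '", path, "': unknown code class '",
         cc_raw[unknown][1], "'; accepted values: ",
         paste(sort(unique(names(CODE_CLASS_DIALECTS))), collapse = ", "),
         call. = FALSE)
  genes <- data.frame(symbol = df[[gene_column]],
                      code_class = map_code_class(cc_raw),
                      accession = if (accession_column %in% names(df))
                        df[[accession_column]] else NA_character_,
                      stringsAsFactors = FALSE)
  if (is.null(batch)) batch <- setNames(rep("batch1", ncol(counts)),
                                        colnames(counts))
  ncounter_counts(counts, genes, batch)
}

#' Write a count matrix to CSV (inverse of [read_count_table()])
#' @param matrix an [ncounter_counts] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "ncounter_counts"))
  df <- data.frame(gene = matrix$genes$symbol,
                   code_class = matrix$genes$code_class,
                   accession = matrix$genes$accession,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(matrix$counts, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

GROUP_ALIASES <- c(patient = "patient", healthy = "healthy_reference",
                   healthy_reference = "healthy_reference",
                   healthy_control = "healthy_reference",
                   control = "healthy_reference")
STIM_ALIASES <- c(none = "none",
                  unstimulated_cultured = "unstimulated_cultured",
                  cultured = "unstimulated_cultured",
                  ifnb_stimulated = "IFNb_stimulated",
                  stimulated = "IFNb_stimulated")

parse_iso_date <- function(x, what, rows) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & nzchar(x) & !is.na(x))
  if (length(bad))
    stop(what, ": unparseable ISO-8601 date '", x[bad[1]], "' in row ",
         rows[bad[1]], call. = FALSE)
  d
}

# therapy column entries: "drug|dose|start|stop[;...]"; stop may be empty
# (open interval).
parse_therapy <- function(x, row) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  recs <- strsplit(x, ";", fixed = TRUE)[[1]]
  out <- do.call(rbind, lapply(recs, function(r) {
    f <- strsplit(r, "|", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("sample sheet row ", row,
           ": therapy record must be 'drug|dose|start[|stop]'", call. = FALSE)
    data.frame(drug = trimws(f[1]), dose = as.numeric(f[2]),
               start = parse_iso_date(f[3], "therapy", row),
               stop = if (length(f) >= 4 && nzchar(trimws(f[4])))
                 parse_iso_date(f[4], "therapy", row) else as.Date(NA),
               stringsAsFactors = FALSE)
  }))
  bad <- !is.na(out$stop) & out$stop < out$start
  if (any(bad))
    stop("sample sheet row ", row, ": therapy record with stop before start",
         call. = FALSE)
  out
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `subject_id`, `date` (ISO-8601), `group`
#' (patient / healthy), `batch`, `stimulation` (none /
#' unstimulated_cultured / IFNb_stimulated). Optional:
#' `days_since_last_infusion` and `therapy`
#' (`drug|dose|start|stop` records separated by `;`, stop empty for ongoing).
#' Group and stimulation labels are normalized case-insensitively.
#'
#' @param path CSV file path.
#' @return data.frame of sample annotations with a `therapy` list column.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "date", "group", "batch", "stimulation")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet '", path, "': missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample sheet '", path, "': duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  rows <- seq_len(nrow(df)) + 1L
  grp <- unname(GROUP_ALIASES[tolower(trimws(df$group))])
  if (any(is.na(grp)))
    stop("sample sheet '", path, "': unknown group '",
         df$group[is.na(grp)][1], "'", call. = FALSE)
  stim <- unname(STIM_ALIASES[tolower(trimws(df$stimulation))])
  if (any(is.na(stim)))
    stop("sample sheet '", path, "': unknown stimulation '",
         df$stimulation[is.na(stim)][1], "'", call. = FALSE)
  out <- data.frame(sample_id = as.character(df$sample_id),
                    subject_id = as.character(df$subject_id),
                    date = parse_iso_date(as.character(df$date),
                                          paste0("sample sheet '", path, "'"),
                                          rows),
                    group = grp, batch = as.character(df$batch),
                    stimulation = stim, stringsAsFactors = FALSE)
  out$days_since_last_infusion <-
    if ("days_since_last_infusion" %in% names(df))
      as.integer(df$days_since_last_infusion) else NA_integer_
  if (any(!is.na(out$days_since_last_infusion) &
          out$days_since_last_infusion < 0))
    stop("sample sheet '", path, "': negative days_since_last_infusion",
         call. = FALSE)
  out$therapy <- if ("therapy" %in% names(df))
    lapply(seq_len(nrow(df)), function(i) parse_therapy(df$therapy[i],
                                                        rows[i]))
  else vector("list", nrow(df))
  out
}

#' Write a score table to CSV
#'
#' One row per (sample, panel) with full-precision scores; columns in a fixed
#' documented order so downstream tooling can rely on it.
#'
#' @param scores a score table from [score_samples()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  cols <- c("sample_id", "subject_id", "date", "panel", "geomean_score",
            "z_score", "batch", "stimulation", "days_since_last_infusion")
  out <- scores[intersect(cols, names(scores))]
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out <- out[cols]
  for (col in c("geomean_score", "z_score"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", as.numeric(out[[col]])))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path CSV file path.
#' @return data.frame with numeric scores and `Date` dates.
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$geomean_score <- as.numeric(df$geomean_score)
  df$z_score <- as.numeric(df$z_score)
  df
}
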