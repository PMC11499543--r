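#' Gene panels and pipeline configuration
#'
#' A gene panel is a named, ordered set of gene symbols that is aggregated into
#' a single per-sample score (or used as a normalization control set). The
#' pipeline distinguishes four probe code classes: `endogenous`,
#' `housekeeping`, `positive_control` and `negative_control`.
#'
#' @param name short panel label, e.g. `"isg"`.
#' @param genes character vector of gene symbols, nonempty, no duplicates.
#' @param code_class probe class the panel genes belong to.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes,
                       code_class = c("endogenous", "housekeeping",
                                      "positive_control", "negative_control")) {
  code_class <- match.arg(code_class)
  genes <- as.character(genes)
  if (length(genes) == 0L)
    stop("panel '", name, "': gene list is empty", call. = FALSE)
  if (anyDuplicated(genes))
    stop("panel '", name, "': duplicated gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  structure(list(name = name, genes = genes, code_class = code_class),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, " (", x$code_class, "), ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

CODE_CLASSES <- c("endogenous", "housekeeping", "positive_control",
                  "negative_control")

# Accepted vendor spellings of the probe code class, mapped case-insensitively.
# Unknown classes are retained in the matrix but excluded from computation.
CODE_CLASS_DIALECTS <- c(
  endogenous = "endogenous", endogenous1 = "endogenous",
  endogenous2 = "endogenous", endogenous3 = "endogenous",
  housekeeping = "housekeeping",
  positive = "positive_control", positive_control = "positive_control",
  negative = "negative_control", negative_control = "negative_control"
)

map_code_class <- function(x) {
  key <- tolower(trimws(x))
  mapped <- unname(CODE_CLASS_DIALECTS[key])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning("unknown code class(es) kept but excluded from analysis: ",
            paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    mapped[unknown] <- key[unknown]
  }
  mapped
}

validate_config <- function(cfg, where = "config") {
  chk <- function(ok, key, msg)
    if (!ok) stop(where, ": key '", key, "' ", msg, call. = FALSE)
  chk(is.numeric(cfg$pseudocount) && cfg$pseudocount > 0,
      "pseudocount", "must be a positive number")
  chk(is.numeric(cfg$induction_threshold) && cfg$induction_threshold > 1,
      "induction_threshold", "must be > 1")
  band <- cfg$reference_band
  chk(is.numeric(band) && length(band) == 2 && band[1] >= 0 &&
        band[1] < band[2] && band[2] <= 100,
      "reference_band", "must be percentiles 0 <= lower < upper <= 100")
  chk(is.numeric(cfg$log_base) && cfg$log_base > 1,
      "log_base", "must be > 1")
  chk(cfg$batch_policy %in% c("per_batch", "global"),
      "batch_policy", "must be 'per_batch' or 'global'")
  chk(is.list(cfg$panels) && length(cfg$panels) > 0, "panels",
      "must be a nonempty list")
  for (p in cfg$panels) {
    chk(inherits(p, "gene_panel"), "panels", "entries must be gene panels")
  }
  nm <- vapply(cfg$panels, `[[`, "", "name")
  chk(!anyDuplicated(nm), "panels", "must have unique names")
  hk <- cfg$panels[["housekeeping"]]
  if (!is.null(hk))
    chk(length(hk$genes) == 3L, "panels.housekeeping",
        "must contain exactly 3 genes")
  pos <- cfg$panels[["positive_control"]]
  if (!is.null(pos))
    chk(length(pos$genes) == 6L, "panels.positive_control",
        "must contain exactly 6 genes")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' The configuration collects the gene panels and the numeric policy of the
#' pipeline: batch scope of the normalization factors, the pseudocount used to
#' floor zeros before geometric means, the healthy reference band percentiles,
#' the stimulation induction threshold and the Z-score log base. Panel gene
#' lists may be given inline (`genes:`) or as a path to a one-symbol-per-line
#' text file (`genes_file:`, resolved relative to the config file).
#'
#' @param path path to a YAML configuration file with a `schema_version` field.
#' @return A validated object of class `pipeline_config`.
#' @seealso [default_config()] for the bundled configuration,
#'   [write_config()] for the round-trip writer.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw$schema_version))
    stop("config: key 'schema_version' is missing", call. = FALSE)
  if (!identical(as.integer(raw$schema_version), 1L))
    stop("config: key 'schema_version' must be 1", call. = FALSE)
  if (is.null(raw$panels) || !length(raw$panels))
    stop("config: key 'panels' is missing or empty", call. = FALSE)
  panels <- lapply(names(raw$panels), function(nm) {
    spec <- raw$panels[[nm]]
    genes <- spec[["genes"]]
    if (is.null(genes) && !is.null(spec[["genes_file"]])) {
      gf <- spec[["genes_file"]]
      if (!file.exists(gf)) gf <- file.path(dirname(path), spec[["genes_file"]])
      if (!file.exists(gf))
        stop("config: key 'panels.", nm, ".genes_file' not found: ",
             spec[["genes_file"]], call. = FALSE)
      genes <- trimws(readLines(gf, warn = FALSE))
      genes <- genes[nzchar(genes)]
    }
    if (is.null(genes))
      stop("config: key 'panels.", nm, "' has neither 'genes' nor 'genes_file'",
           call. = FALSE)
    cc <- spec[["code_class"]] %||% "endogenous"
    if (!cc %in% CODE_CLASSES)
      stop("config: key 'panels.", nm, ".code_class' must be one of ",
           paste(CODE_CLASSES, collapse = ", "), call. = FALSE)
    gene_panel(nm, genes, cc)
  })
  names(panels) <- names(raw$panels)
  cfg <- structure(list(
    schema_version = 1L,
    batch_policy = raw$batch_policy %||% "per_batch",
    pseudocount = as.numeric(raw$pseudocount %||% 1),
    log_base = as.numeric(raw$log_base %||% 2),
    reference_band = as.numeric(unlist(raw$reference_band %||% c(2.5, 97.5))),
    band_type = raw$band_type %||% "percentile",
    induction_threshold = as.numeric(raw$induction_threshold %||% 2),
    z_truncate = as.numeric(raw$z_truncate %||% 10),
    sd_floor_frac = as.numeric(raw$sd_floor_frac %||% 0.1),
    sd_floor_abs = as.numeric(raw$sd_floor_abs %||% 0.01),
    hk_factor_on_raw = isTRUE(raw$hk_factor_on_raw),
    panels = panels
  ), class = "pipeline_config")
  validate_config(cfg)
}

#' Bundled default configuration
#'
#' Default panels: a 30-gene ISG panel, 10-gene NF-kB and IFN-gamma panels,
#' the housekeeping trio NRDC/OTUD5/TUBB and the six-step positive-control
#' ladder probes. The ISG, NF-kB and IFN-gamma gene lists are documented
#' placeholders drawn from the published interferon-score literature; clinical
#' use requires supplying the laboratory's own validated lists via
#' [load_config()].
#'
#' @return A `pipeline_config`.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "isgscore", mustWork = TRUE))
}

#' Write a pipeline configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` reproduces
#' `cfg`.
#'
#' @param config a `pipeline_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(
    schema_version = config$schema_version,
    batch_policy = config$batch_policy,
    pseudocount = config$pseudocount,
    log_base = config$log_base,
    reference_band = config$reference_band,
    band_type = config$band_type,
    induction_threshold = config$induction_threshold,
    z_truncate = config$z_truncate,
    sd_floor_frac = config$sd_floor_frac,
    sd_floor_abs = config$sd_floor_abs,
    hk_factor_on_raw = config$hk_factor_on_raw,
    panels = lapply(config$panels, function(p)
      list(code_class = p$code_class, genes = p$genes))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> schema", x$schema_version,
      "| batch_policy:", x$batch_policy,
      "| pseudocount:", x$pseudocount, "\n")
  for (p in x$panels)
    cat("  panel ", format(p$name, width = 18), length(p$genes),
        " genes (", p$code_class, ")\n", sep = "")
  invisible(x)
}

#' Report panel genes missing from a count matrix
#'
#' Scoring refuses to run on a panel with absent genes unless explicitly
#' allowed, so this check is the first thing to run against a new codeset.
#'
#' @param panels a list of `gene_panel` objects (or a `pipeline_config`).
#' @param matrix an `ncounter_counts` or `ncounter_normalized` object.
#' @return Named list: for each panel, the character vector of genes absent
#'   from the matrix (empty vectors omitted).
#' @export
validate_panels_against_matrix <- function(panels, matrix) {
  if (inherits(panels, "pipeline_config")) panels <- panels$panels
  genes <- matrix$genes
  out <- list()
  for (p in panels) {
    present <- genes$symbol[genes$code_class == p$code_class]
    miss <- setdiff(p$genes, present)
    if (length(miss)) out[[p$name]] <- miss
  }
  out
}
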