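#' Analysis configuration
#'
#' Collects every tunable parameter of the digital-analysis pipeline and the
#' downstream statistics in one object, so that a run can be reproduced from
#' its logged configuration alone. None of the defaults are optimized per
#' dataset; they are fixed, documented choices.
#'
#' @param mpp Default microns per pixel used when an image does not carry its
#'   own scale. The default 0.25 um/px corresponds to a 20x brightfield scan
#'   (100 px = 25 um).
#' @param margin_px Edge margin of the region of interest, in pixels: every
#'   ROI pixel must lie at least this far from the nearest non-tissue pixel.
#'   Guards against edge staining artifacts.
#' @param min_roi_area_um2 Minimum ROI area (strictly exceeded) for a spot to
#'   be analyzed, in square microns. 37000 um^2 is about 5% of the ROI of an
#'   intact 1-mm spot.
#' @param tissue_od_floor Mean per-channel optical density above which a
#'   pixel counts as tissue rather than bare glass.
#' @param tissue_min_speck_px Connected tissue components smaller than this
#'   many pixels are discarded as dust.
#' @param stain_vectors 3 x 2 matrix of unit optical-density vectors
#'   (columns: hematoxylin, DAB). Defaults to [stain_vectors_hdab()].
#' @param ridge_scale_um Width scale of the curvilinear-structure filter in
#'   microns (order of a cell-membrane thickness).
#' @param min_dab_od Minimum DAB optical density for a pixel to enter the
#'   membrane mask, regardless of its ridge response.
#' @param gap_px Maximum gap, in pixels, bridged when linking skeleton
#'   fragments that are not perfectly connected.
#' @param min_fragment_px Skeleton fragments smaller than this many pixels
#'   are pruned before the connectivity computation.
#' @param c_low,c_high Low/high fragment-size cut-offs (skeleton pixels) of
#'   the connectivity statistic: fragments at or below `c_low` contribute
#'   weight 0, fragments at or above `c_high` weight 1.
#' @param score_low,score_high Connectivity thresholds of the ordinal HER2
#'   score: `C <= score_low` is 0/1+, `score_low < C <= score_high` is 2+,
#'   larger values are 3+.
#' @param kappa_weights Disagreement weighting of the kappa statistic:
#'   `"linear"`, `"quadratic"` or `"unweighted"`.
#' @param aggregate Per-patient aggregation of spot scores: `"max"` (default),
#'   `"median"` or `"mode"`.
#' @param min_spots Minimum number of adequate spots for a patient to enter
#'   the per-patient analysis.
#' @param seed Optional integer seed recorded with the run.
#'
#' @return An object of class `mc_config` (a validated named list).
#' @examples
#' cfg <- mc_config(gap_px = 5)
#' cfg$gap_px
#' @export
mc_config <- function(mpp = 0.25,
                      margin_px = 100,
                      min_roi_area_um2 = 37000,
                      tissue_od_floor = 0.1,
                      tissue_min_speck_px = 100,
                      stain_vectors = stain_vectors_hdab(),
                      ridge_scale_um = 1.0,
                      min_dab_od = 0.15,
                      gap_px = 3,
                      min_fragment_px = 10,
                      c_low = 50,
                      c_high = 500,
                      score_low = 0.12,
                      score_high = 0.56,
                      kappa_weights = "linear",
                      aggregate = "max",
                      min_spots = 2,
                      seed = NULL) {
  cfg <- list(
    mpp = mpp, margin_px = margin_px, min_roi_area_um2 = min_roi_area_um2,
    tissue_od_floor = tissue_od_floor, tissue_min_speck_px = tissue_min_speck_px,
    stain_vectors = stain_vectors, ridge_scale_um = ridge_scale_um,
    min_dab_od = min_dab_od, gap_px = gap_px,
    min_fragment_px = min_fragment_px, c_low = c_low, c_high = c_high,
    score_low = score_low, score_high = score_high,
    kappa_weights = kappa_weights, aggregate = aggregate,
    min_spots = min_spots, seed = seed
  )
  class(cfg) <- "mc_config"
  validate_config(cfg)
}

#' Validate a configuration object
#'
#' @param cfg An `mc_config` object (or plain list with the same fields).
#' @return The validated configuration, invisibly classed `mc_config`.
#' @export
validate_config <- function(cfg) {
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("configuration error: `", field, "` must be a positive number",
           call. = FALSE)
  }
  num_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("configuration error: `", field, "` must be a non-negative number",
           call. = FALSE)
  }
  for (f in c("mpp", "min_roi_area_um2", "tissue_od_floor", "ridge_scale_um",
              "c_low", "c_high")) num_pos(f)
  for (f in c("margin_px", "tissue_min_speck_px", "min_dab_od", "gap_px",
              "min_fragment_px")) num_nonneg(f)
  sv <- cfg$stain_vectors
  if (!is.matrix(sv) || nrow(sv) != 3 || ncol(sv) < 2)
    stop("configuration error: `stain_vectors` must be a 3 x 2 matrix",
         call. = FALSE)
  if (cfg$c_low >= cfg$c_high)
    stop("configuration error: need c_low < c_high", call. = FALSE)
  if (!(cfg$score_low > 0 && cfg$score_low < cfg$score_high &&
        cfg$score_high <= 1))
    stop("configuration error: need 0 < score_low < score_high <= 1",
         call. = FALSE)
  if (!cfg$kappa_weights %in% c("linear", "quadratic", "unweighted"))
    stop("configuration error: unknown kappa_weights `", cfg$kappa_weights,
         "`", call. = FALSE)
  if (!cfg$aggregate %in% c("max", "median", "mode"))
    stop("configuration error: unknown aggregate `", cfg$aggregate, "`",
         call. = FALSE)
  if (cfg$min_spots < 1)
    stop("configuration error: `min_spots` must be >= 1", call. = FALSE)
  class(cfg) <- "mc_config"
  cfg
}

#' Read a configuration from a JSON file
#'
#' Missing keys fall back to the defaults of [mc_config()]; unknown keys are
#' rejected so that typos cannot silently change a run.
#'
#' @param path Path to a JSON file; an empty object `{}` yields the defaults.
#' @return An `mc_config` object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  known <- names(formals(mc_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$stain_vectors)) {
    sv <- raw$stain_vectors
    # stored as a list of 3-vector columns; jsonlite may simplify it to a
    # (columns x 3) matrix
    raw$stain_vectors <- if (is.matrix(sv)) t(sv) else
      matrix(unlist(sv), nrow = 3)
  }
  do.call(mc_config, raw)
}

#' Write a configuration to a JSON file
#'
#' @param cfg An `mc_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$stain_vectors <- unname(apply(out$stain_vectors, 2, as.numeric,
                                    simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Structured run log header
#'
#' Returns (and optionally prints) a structured record of the effective
#' configuration, package version and inputs of a run. Every command-line
#' entry point emits this header so that no analysis runs with undocumented
#' parameters.
#'
#' @param cfg An `mc_config` object.
#' @param inputs Named character vector or list describing the run inputs.
#' @return A list with elements `timestamp`, `package`, `version`, `inputs`
#'   and `config`, classed `mc_run_log`.
#' @export
run_log <- function(cfg, inputs = list()) {
  structure(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "memconn",
    version = as.character(utils::packageVersion("memconn")),
    inputs = inputs,
    config = cfg
  ), class = "mc_run_log")
}

#' @export
print.mc_run_log <- function(x, ...) {
  cat("# memconn", x$version, "run at", x$timestamp, "\n")
  if (length(x$inputs))
    cat("# inputs:", paste(names(x$inputs), unlist(x$inputs), sep = "=",
                           collapse = " "), "\n")
  cfg <- unclass(x$config)
  cfg$stain_vectors <- paste(round(as.numeric(cfg$stain_vectors), 4),
                             collapse = " ")
  cat("# config:",
      paste(names(cfg), vapply(cfg, function(v)
        if (is.null(v)) "NULL" else paste(v, collapse = ","), ""),
        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.mc_config <- function(x, ...) {
  cat("<mc_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    if (is.matrix(v)) v <- paste(round(as.numeric(v), 4), collapse = " ")
    if (is.null(v)) v <- "NULL"
    cat("  ", f, ": ", paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
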