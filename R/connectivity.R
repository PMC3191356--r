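#' Ordinal HER2 score levels
#'
#' The three-category HER2 IHC scale used throughout the package, with 0 and
#' 1+ merged into the negative category.
#'
#' @return Character vector `c("0/1+", "2+", "3+")`.
#' @export
her2_levels <- function() c("0/1+", "2+", "3+")

#' Coerce to an ordered HER2 score
#'
#' Accepts the category labels themselves, the internal 0/1/2 coding, or the
#' 1/2/3 coding used by some tabulations (`code_base = 1`).
#'
#' @param x Character, factor or integer vector.
#' @param code_base Origin of an integer coding: 0 means 0/1/2, 1 means
#'   1/2/3.
#' @return Ordered factor with levels `0/1+ < 2+ < 3+`.
#' @export
her2_score <- function(x, code_base = 0) {
  lev <- her2_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    idx <- as.integer(x) - as.integer(code_base) + 1L
    if (any(!is.na(idx) & (idx < 1L | idx > 3L)))
      stop("input error: integer HER2 codes out of range", call. = FALSE)
    x <- lev[idx]
  } else {
    x <- as.character(x)
    x[x %in% c("0", "1", "1+", "0/1")] <- "0/1+"
    x[x %in% c("2")] <- "2+"
    x[x %in% c("3")] <- "3+"
    if (any(!is.na(x) & !x %in% lev))
      stop("input error: unrecognized HER2 score label(s): ",
           paste(unique(x[!is.na(x) & !x %in% lev]), collapse = ", "),
           call. = FALSE)
  }
  factor(x, levels = lev, ordered = TRUE)
}

#' Membrane connectivity statistic
#'
#' The size-weighted mean of a per-fragment ramp weight,
#' \deqn{C = \sum_i a_i w(a_i) / \sum_i a_i, \quad
#'       w(a) = \mathrm{clamp}((a - c_{low})/(c_{high} - c_{low}), 0, 1),}
#' where \eqn{a_i} are skeleton-pixel sizes of the membrane fragments.
#' `C = 0` when no fragment exceeds the low cut-off (including the empty
#' case) and `C = 1` when every fragment is at or above the high cut-off;
#' between the cut-offs it interpolates continuously, and it is
#' non-decreasing in every fragment size.
#'
#' @param sizes Positive fragment sizes (skeleton pixels); may be empty.
#' @param c_low,c_high Low and high fragment-size cut-offs,
#'   `0 < c_low < c_high`.
#' @return Connectivity value in \[0, 1\].
#' @examples
#' connectivity(c(100, 600), c_low = 50, c_high = 550)  # 0.8714...
#' @export
connectivity <- function(sizes, c_low = 50, c_high = 500) {
  if (!(c_low > 0 && c_high > c_low))
    stop("input error: need 0 < c_low < c_high", call. = FALSE)
  if (!length(sizes)) return(0)
  if (any(sizes <= 0)) stop("input error: fragment sizes must be positive",
                            call. = FALSE)
  w <- pmin(1, pmax(0, (sizes - c_low) / (c_high - c_low)))
  sum(sizes * w) / sum(sizes)
}

#' HER2 score from a connectivity value
#'
#' Fixed thresholds with the boundary belonging to the lower category:
#' 0/1+ for `C <= low`, 2+ for `low < C <= high`, 3+ for `high < C <= 1`.
#'
#' @param C Connectivity value(s) in \[0, 1\].
#' @param low,high Score thresholds (defaults 0.12 and 0.56).
#' @return Ordered factor of HER2 scores (see [her2_levels()]).
#' @examples
#' score_from_connectivity(c(0.12, 0.56, 0.561))
#' @export
score_from_connectivity <- function(C, low = 0.12, high = 0.56) {
  if (any(!is.finite(C)) || any(C < 0 | C > 1))
    stop("input error: connectivity must lie in [0, 1]", call. = FALSE)
  lev <- her2_levels()
  her2_score(ifelse(C <= low, lev[1], ifelse(C <= high, lev[2], lev[3])))
}

#' Full connectivity measurement on a membrane mask
#'
#' Convenience composition of the skeleton post-processing chain:
#' [skeletonize_mask()], [link_fragments()], [prune_fragments()],
#' [connectivity()] and [score_from_connectivity()].
#'
#' @param mask Logical membrane mask.
#' @param config An [mc_config()] providing `gap_px`, `min_fragment_px`,
#'   `c_low`, `c_high`, `score_low`, `score_high`.
#' @return Object of class `connectivity_result`: list with `connectivity`,
#'   `her2_score`, `n_fragments`, `total_skeleton_px`, `sizes`.
#' @export
measure_connectivity <- function(mask, config = mc_config()) {
  frags <- skeletonize_mask(mask)
  frags <- link_fragments(frags, config$gap_px)
  frags <- prune_fragments(frags, config$min_fragment_px)
  C <- connectivity(frags$sizes, config$c_low, config$c_high)
  structure(list(
    connectivity = C,
    her2_score = score_from_connectivity(C, config$score_low,
                                         config$score_high),
    n_fragments = length(frags$sizes),
    total_skeleton_px = sum(frags$sizes),
    sizes = unname(frags$sizes)
  ), class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(
    "<connectivity_result> C = %.6f -> %s (%d fragments, %d skeleton px)\n",
    x$connectivity, as.character(x$her2_score), x$n_fragments,
    x$total_skeleton_px))
  invisible(x)
}
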