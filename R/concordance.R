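# Agreement and FISH-concordance statistics for ordinal HER2 scores.
#
# The weighted kappa and its large-sample variance are implemented from the
# defining sums (no installed package provides weighted kappa with a CI);
# the test suite checks them against a brute-force oracle.

#' Aggregate one patient's spot records
#'
#' Per-patient summaries are taken over the patient's *adequate* spots:
#' the maximum score per rater (the default patient score: the maximum is
#' more sensitive than the mode or median when tissue is heterogeneous and
#' sampling is limited), the score range per rater, and the maximum
#' connectivity value.
#'
#' @param records Data frame of one patient's spots with columns
#'   `patient_id`, `spot_id`, `ve1`, `ve2`, `da` (HER2 scores in any coding
#'   accepted by [her2_score()]), `connectivity` (optional) and `adequate`
#'   (logical, optional: missing means all adequate).
#' @param min_spots Minimum number of adequate spots; patients below it are
#'   rejected (return `NULL`).
#' @return A one-row data frame with `patient_id`, `n_spots`, `ve1max`,
#'   `ve2max`, `damax`, `ve1range`, `ve2range`, `darange`, `connect_max`;
#'   or `NULL` when rejected.
#' @export
aggregate_patient <- function(records, min_spots = 2) {
  if (!nrow(records))
    stop("input error: no spot records supplied", call. = FALSE)
  if (length(unique(records$patient_id)) != 1)
    stop("input error: records span multiple patients", call. = FALSE)
  adequate <- if (is.null(records$adequate)) rep(TRUE, nrow(records))
              else as.logical(records$adequate)
  rec <- records[adequate, , drop = FALSE]
  if (nrow(rec) < min_spots) return(NULL)
  score_stats <- function(col) {
    s <- as.integer(her2_score(rec[[col]])) - 1L   # 0/1/2 coding
    c(max = max(s), range = max(s) - min(s))
  }
  v1 <- score_stats("ve1"); v2 <- score_stats("ve2"); da <- score_stats("da")
  cmax <- if (is.null(rec$connectivity) || all(is.na(rec$connectivity)))
    NA_real_ else max(rec$connectivity, na.rm = TRUE)
  data.frame(
    patient_id = rec$patient_id[1], n_spots = nrow(rec),
    ve1max = her2_score(v1["max"]), ve2max = her2_score(v2["max"]),
    damax = her2_score(da["max"]),
    ve1range = unname(v1["range"]), ve2range = unname(v2["range"]),
    darange = unname(da["range"]),
    connect_max = cmax, stringsAsFactors = FALSE
  )
}

#' Aggregate a cohort of spot records to patients
#'
#' Applies [aggregate_patient()] per patient and optionally joins per-patient
#' FISH results. When a FISH table provides both copy numbers and a ratio,
#' the ratio is taken from the input; rows where it disagrees with
#' `her2_mean / cep17_mean` by more than `ratio_tol` are reported. A missing
#' ratio is computed from the copy numbers.
#'
#' @param spots Data frame of spot records (see [aggregate_patient()]).
#' @param fish Optional data frame with columns `patient_id`, `her2_mean`,
#'   `cep17_mean` and optionally `ratio`.
#' @param min_spots Minimum adequate spots per patient (default 2).
#' @param ratio_tol Tolerance for the ratio consistency check (default 0.05,
#'   matching 1-decimal rounding of reported ratios).
#' @return Data frame of patient records, one row per retained patient.
#' @export
aggregate_patients <- function(spots, fish = NULL, min_spots = 2,
                               ratio_tol = 0.05) {
  parts <- lapply(split(spots, spots$patient_id), aggregate_patient,
                  min_spots = min_spots)
  patients <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  if (is.null(patients)) return(NULL)
  rownames(patients) <- NULL
  if (!is.null(fish)) {
    if (is.null(fish$ratio)) fish$ratio <- NA_real_
    computed <- fish$her2_mean / fish$cep17_mean
    off <- which(!is.na(fish$ratio) &
                   abs(fish$ratio - computed) > ratio_tol + 1e-9)
    if (length(off))
      message("aggregate_patients: ", length(off),
              " FISH ratio(s) differ from her2/cep17 by > ", ratio_tol,
              " (patient ", paste(fish$patient_id[off], collapse = ", "), ")")
    fish$ratio[is.na(fish$ratio)] <- computed[is.na(fish$ratio)]
    m <- match(patients$patient_id, fish$patient_id)
    patients$fish_her2 <- fish$her2_mean[m]
    patients$fish_cep17 <- fish$cep17_mean[m]
    patients$fish_ratio <- fish$ratio[m]
  }
  patients
}

#' Cross-tabulate two raters' ordinal scores
#'
#' @param records Data frame containing the two rater columns.
#' @param rater_a,rater_b Column names; `rater_a` indexes rows of the table.
#' @return 3 x 3 integer matrix of counts with HER2 levels as dimnames,
#'   classed `contingency_table`. Records with a missing score in either
#'   column are skipped (with a message giving the count).
#' @export
build_contingency <- function(records, rater_a, rater_b) {
  a <- her2_score(records[[rater_a]])
  b <- her2_score(records[[rater_b]])
  drop <- is.na(a) | is.na(b)
  if (any(drop))
    message("build_contingency: skipped ", sum(drop),
            " record(s) with missing scores")
  counts <- table(a[!drop], b[!drop])
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(her2_levels(), her2_levels()))
  structure(m, row_rater = rater_a, col_rater = rater_b,
            class = c("contingency_table", "matrix"))
}

kappa_weight_matrix <- function(k, weights = "linear") {
  d <- abs(outer(seq_len(k) - 1, seq_len(k) - 1, "-")) / (k - 1)
  switch(weights,
         linear = 1 - d,
         quadratic = 1 - d^2,
         unweighted = (d == 0) * 1,
         stop("configuration error: unknown kappa weights `", weights, "`",
              call. = FALSE))
}

#' Weighted kappa with asymptotic confidence interval
#'
#' Chance-corrected ordinal agreement
#' \deqn{\kappa_w = (p_{o,w} - p_{e,w}) / (1 - p_{e,w})}
#' with agreement weights `w_ij = 1 - |i - j| / (k - 1)` (linear, the
#' default), observed weighted agreement from the table proportions and
#' expected agreement from the marginal products. The standard error is the
#' Fleiss-Cohen-Everitt large-sample value and the confidence interval is
#' `kappa +/- z * SE`.
#'
#' @param table 3 x 3 (or k x k) contingency matrix of counts.
#' @param weights `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `agreement_result`: list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `percent_agreement`, `po_w`, `pe_w`, `n`,
#'   `weights`.
#' @examples
#' tab <- matrix(c(475, 0, 0, 15, 21, 4, 0, 4, 56), 3)
#' weighted_kappa(tab)
#' @export
weighted_kappa <- function(table, weights = "linear", conf_level = 0.95) {
  tab <- unclass(as.matrix(table))
  if (nrow(tab) != ncol(tab)) stop("input error: table must be square",
                                   call. = FALSE)
  n <- sum(tab)
  if (n <= 0) stop("input error: empty contingency table", call. = FALSE)
  k <- nrow(tab)
  w <- kappa_weight_matrix(k, weights)
  p <- tab / n
  r <- rowSums(p)
  cc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cc))
  if (1 - pe < 1e-12)
    stop("undefined kappa: degenerate marginals (expected agreement 1)",
         call. = FALSE)
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  wi <- as.numeric(w %*% cc)      # row-wise expected weights
  wj <- as.numeric(t(w) %*% r)    # column-wise expected weights
  wb <- outer(wi, rep(1, k)) + outer(rep(1, k), wj)
  v <- (sum(p * (w * (1 - pe) - wb * (1 - po))^2) -
          (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(0, v))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kap, se = se,
                 ci_low = kap - z * se, ci_high = kap + z * se,
                 percent_agreement = 100 * sum(diag(tab)) / n,
                 po_w = po, pe_w = pe, n = n, weights = weights),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> kappa %.3f (%s weights), 95%% CI %.3f - %.3f, agreement %.1f%% (n = %d)\n",
    x$kappa, x$weights, x$ci_low, x$ci_high, x$percent_agreement, x$n))
  invisible(x)
}

#' Percent agreement of a contingency table
#'
#' @param table Square contingency matrix of counts.
#' @return `100 * trace / total`, conventionally reported to one decimal.
#' @export
percent_agreement <- function(table) {
  tab <- unclass(as.matrix(table))
  n <- sum(tab)
  if (n <= 0) stop("input error: empty contingency table", call. = FALSE)
  100 * sum(diag(tab)) / n
}

#' FISH positivity by the HER2/CEP17 ratio
#'
#' HER2 gene amplification is called at a ratio strictly greater than 2.
#'
#' @param ratio HER2/CEP17 ratio(s), >= 0; `NA` propagates.
#' @return Logical vector.
#' @examples
#' fish_positive(c(2.0, 2.1))  # FALSE, TRUE
#' @export
fish_positive <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE))
    stop("input error: ratio must be non-negative", call. = FALSE)
  ratio > 2.0
}

#' CEP17 polysomy flag
#'
#' @param cep17 Mean CEP17 copies per cell (>= 0).
#' @return `TRUE` when strictly above 3 copies per cell.
#' @export
polysomy_flag <- function(cep17) {
  if (any(cep17 < 0, na.rm = TRUE))
    stop("input error: cep17 must be non-negative", call. = FALSE)
  cep17 > 3
}

#' HER2 amplification flag by absolute copy number
#'
#' @param her2 Mean HER2 copies per cell (>= 0).
#' @return `TRUE` when strictly above 6 copies per cell.
#' @export
amplification_flag <- function(her2) {
  if (any(her2 < 0, na.rm = TRUE))
    stop("input error: her2 must be non-negative", call. = FALSE)
  her2 > 6
}

#' FISH-positive proportions per IHC score category
#'
#' For each HER2 score category of the chosen rater, counts the
#' FISH-positive patients (ratio strictly above 2) and the category total.
#'
#' @param patients Patient records with the rater column and `fish_ratio`.
#' @param rater One of `"ve1max"`, `"ve2max"`, `"damax"` (any HER2-score
#'   column works).
#' @return Data frame with `category`, `positives`, `total`, `percent`
#'   (1 decimal; `NA` for an empty category).
#' @export
fish_category_table <- function(patients, rater = "damax") {
  score <- her2_score(patients[[rater]])
  pos <- fish_positive(patients$fish_ratio)
  keep <- !is.na(score) & !is.na(pos)
  score <- score[keep]; pos <- pos[keep]
  out <- lapply(her2_levels(), function(lv) {
    sel <- score == lv
    tot <- sum(sel)
    np <- sum(pos[sel])
    data.frame(category = lv, positives = np, total = tot,
               percent = if (tot > 0) round(100 * np / tot, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation on (optionally) log-transformed values
#'
#' @param x,y Numeric vectors of equal length; pairs with an `NA` are
#'   dropped.
#' @param log_x,log_y Apply a natural log before correlating? Non-positive
#'   values under a log are an input error (the offenders are listed).
#' @return List with `r`, `p` (two-sided, from the t distribution), `n`,
#'   classed `log_pearson_result`.
#' @export
log_pearson <- function(x, y, log_x = TRUE, log_y = TRUE) {
  if (length(x) != length(y))
    stop("input error: x and y lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("input error: need at least 3 complete pairs", call. = FALSE)
  check_pos <- function(v, name) {
    bad <- which(v <= 0)
    if (length(bad))
      stop("input error: non-positive ", name, " value(s) under log at ",
           "index ", paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  if (log_x) { check_pos(x, "x"); x <- log(x) }
  if (log_y) { check_pos(y, "y"); y <- log(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "log_pearson_result")
}

#' @export
print.log_pearson_result <- function(x, ...) {
  cat(sprintf("<log_pearson_result> r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}
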