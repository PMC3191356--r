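# Agreement statistics, FISH concordance, correlations.

make_records <- function(tab, rater_a = "ve1", rater_b = "da") {
  lv <- her2_levels()
  rows <- list()
  for (i in 1:3) for (j in 1:3) {
    if (tab[i, j] > 0)
      rows[[length(rows) + 1]] <- data.frame(
        a = rep(lv[i], tab[i, j]), b = rep(lv[j], tab[i, j]))
  }
  out <- do.call(rbind, rows)
  names(out) <- c(rater_a, rater_b)
  out
}

test_that("patient aggregation takes max and range over adequate spots", {
  rec <- data.frame(patient_id = "p", spot_id = 1:3,
                    ve1 = c("0/1+", "2+", "3+"), ve2 = "2+", da = "2+",
                    connectivity = c(0.05, 0.3, 0.9), adequate = TRUE)
  agg <- aggregate_patient(rec)
  expect_equal(as.character(agg$ve1max), "3+")
  expect_equal(agg$ve1range, 2)
  expect_equal(agg$connect_max, 0.9)
  expect_equal(agg$n_spots, 3)

  rec2 <- data.frame(patient_id = "p", spot_id = 1:4,
                     ve1 = "2+", ve2 = "2+",
                     da = c("3+", "0/1+", "0/1+", "0/1+"), adequate = TRUE)
  agg2 <- aggregate_patient(rec2)
  expect_equal(as.character(agg2$damax), "3+")
  expect_equal(agg2$darange, 2)
  expect_equal(agg2$ve1range, 0)

  single <- rec[1, ]
  expect_null(aggregate_patient(single, min_spots = 2))
  expect_error(aggregate_patient(rec[0, ]), "no spot records")

  # inadequate spots are ignored
  rec$adequate <- c(TRUE, TRUE, FALSE)
  expect_equal(as.character(aggregate_patient(rec)$ve1max), "2+")
})

test_that("cohort aggregation joins FISH and flags inconsistent ratios", {
  spots <- data.frame(
    patient_id = rep(c("a", "b"), each = 2), spot_id = 1:4,
    ve1 = "2+", ve2 = "2+", da = "2+",
    connectivity = c(0.2, 0.4, 0.5, 0.3), adequate = TRUE)
  fish <- data.frame(patient_id = c("a", "b"),
                     her2_mean = c(4, 10), cep17_mean = c(2, 2),
                     ratio = c(2.0, 9.9))  # b's ratio inconsistent
  expect_message(pat <- aggregate_patients(spots, fish), "differ")
  expect_equal(pat$fish_ratio, c(2.0, 9.9))  # input ratio is kept
  expect_equal(pat$connect_max, c(0.4, 0.5))

  fish$ratio <- NA_real_
  pat2 <- aggregate_patients(spots, fish)
  expect_equal(pat2$fish_ratio, c(2, 5))     # computed when missing
})

test_that("contingency tables reproduce engineered cross-tabulations", {
  target <- agreement_tables()$spot_ve1_ve2
  rec <- make_records(target, "ve1", "ve2")
  tab <- build_contingency(rec, "ve1", "ve2")
  expect_equal(unclass(tab), unclass(target), ignore_attr = TRUE)

  one <- build_contingency(data.frame(ve1 = "2+", da = "2+"), "ve1", "da")
  expect_equal(sum(one), 1)
  expect_equal(one["2+", "2+"], 1)

  empty <- build_contingency(data.frame(ve1 = character(0),
                                        da = character(0)), "ve1", "da")
  expect_true(all(empty == 0))
  expect_error(weighted_kappa(empty), "empty")
  expect_error(percent_agreement(empty), "empty")

  expect_message(
    build_contingency(data.frame(ve1 = c("2+", NA), da = c("2+", "3+")),
                      "ve1", "da"),
    "skipped 1")
})

test_that("weighted kappa has its textbook fixed points", {
  expect_equal(weighted_kappa(diag(c(10, 10, 10)))$kappa, 1)
  indep <- outer(c(4, 2, 2), c(4, 2, 2)) / 2  # independence table
  expect_equal(weighted_kappa(indep)$kappa, 0, tolerance = 1e-12)
  # symmetric under transposition
  set.seed(17)
  for (i in 1:10) {
    tab <- matrix(sample(0:15, 9, replace = TRUE), 3)
    if (sum(tab) == 0) next
    a <- try(weighted_kappa(tab), silent = TRUE)
    b <- try(weighted_kappa(t(tab)), silent = TRUE)
    if (inherits(a, "try-error")) {
      expect_s3_class(b, "try-error")
    } else {
      expect_equal(a$kappa, b$kappa, tolerance = 1e-12)
      expect_lte(a$kappa, 1)
      expect_equal(abs(a$kappa - 1) < 1e-12, sum(tab) == sum(diag(tab)))
      expect_true(a$ci_low <= a$kappa && a$kappa <= a$ci_high)
    }
  }
  degenerate <- matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_error(weighted_kappa(degenerate), "degenerate")
})

test_that("weighted kappa matches a brute-force enumeration oracle", {
  brute <- function(tab, weights) {
    k <- nrow(tab); n <- sum(tab)
    w <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k) {
      d <- abs(i - j) / (k - 1)
      w[i, j] <- if (weights == "linear") 1 - d else
        if (weights == "quadratic") 1 - d^2 else as.numeric(i == j)
    }
    po <- 0; pe <- 0
    for (i in 1:k) for (j in 1:k) {
      po <- po + w[i, j] * tab[i, j] / n
      pe <- pe + w[i, j] * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(31)
  for (i in 1:40) {
    tab <- matrix(stats::rmultinom(1, sample(5:50, 1),
                                   prob = runif(9, 0.2, 1)), 3)
    for (wt in c("linear", "quadratic", "unweighted")) {
      ref <- brute(tab, wt)
      if (!is.finite(ref)) next
      expect_equal(weighted_kappa(tab, weights = wt)$kappa, ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("percent agreement is trace over total", {
  tabs <- agreement_tables()
  expect_equal(round(percent_agreement(tabs$spot_ve1_ve2), 1), 96.0)
  expect_equal(round(percent_agreement(tabs$spot_ve1_da), 1), 93.2)
  expect_equal(percent_agreement(diag(c(3, 2, 1))), 100)
})

test_that("FISH thresholds are strict as specified", {
  expect_identical(fish_positive(c(2.0, 2.1, 0, NA)),
                   c(FALSE, TRUE, FALSE, NA))
  expect_error(fish_positive(-1), "non-negative")
  expect_identical(polysomy_flag(c(3.0, 3.01, 0)), c(FALSE, TRUE, FALSE))
  expect_identical(amplification_flag(c(6, 6.01, 0, 9)),
                   c(FALSE, TRUE, FALSE, TRUE))
  # amplification by copies with a ratio below the positivity cut
  expect_true(amplification_flag(9.0) && !fish_positive(9.0 / 5.2))
})

test_that("FISH category proportions work on a constructed cohort", {
  pat <- data.frame(
    damax = c("3+", "3+", "2+", "0/1+", "0/1+"),
    fish_ratio = c(4, 1.5, 2.5, 1, NA))
  tab <- fish_category_table(pat, "damax")
  expect_equal(tab$category, her2_levels())
  expect_equal(tab$positives, c(0, 1, 1))
  expect_equal(tab$total, c(1, 1, 2))
  expect_equal(tab$percent, c(0, 100, 50))
  none <- fish_category_table(
    data.frame(damax = c("3+"), fish_ratio = 4), "damax")
  expect_true(is.na(none$percent[1]))   # empty 0/1+ category
  # totals over categories equal the patients with FISH data
  expect_equal(sum(tab$total), sum(!is.na(pat$fish_ratio)))
})

test_that("log-scale Pearson correlation behaves and validates input", {
  x <- c(1, 2, 4, 8, 16)
  r <- log_pearson(x, 2 * x)
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(12)
  ind <- log_pearson(runif(1000), runif(1000), log_x = FALSE, log_y = FALSE)
  expect_lt(abs(ind$r), 0.1)
  expect_error(log_pearson(c(-1, 2, 3), c(1, 2, 3)), "non-positive")
  expect_error(log_pearson(c(1, 2), c(1, 2)), "at least 3")
  expect_error(log_pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
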