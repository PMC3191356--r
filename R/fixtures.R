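#' Bundled reference FISH/IHC cohort
#'
#' A reference cohort of 54 breast-cancer TMA patients bundled with the
#' package: per-patient dual-probe FISH counts (mean HER2 copies per cell,
#' mean CEP17 copies per cell, HER2/CEP17 ratio from a manual 20-cell
#' count) together with the maximum-spot HER2 IHC score from two visual
#' reads (`ve1max`, `ve2max`) and from digital analysis (`damax`). The
#' cohort comprises the patients scored 2+ or 3+ by any rater and/or with
#' ratio > 2 and/or CEP17 > 3; FISH-negative 0/1+ patients are not part of
#' it. The original 1/2/3 score coding and decimal commas are normalized on
#' read.
#'
#' @return Data frame with columns `patient_id`, `fish_ratio`, `fish_her2`,
#'   `fish_cep17`, `ve1max`, `ve2max`, `damax` (ordered HER2 factors).
#' @examples
#' head(fish_cohort())
#' @export
fish_cohort <- function() {
  path <- system.file("extdata", "fish_cohort.csv", package = "memconn",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    patient_id = raw$patient_id,
    fish_ratio = raw$her2_cep17_ratio,
    fish_her2 = raw$her2_mean,
    fish_cep17 = raw$cep17_mean,
    ve1max = her2_score(raw$ve1max, code_base = 1),
    ve2max = her2_score(raw$ve2max, code_base = 1),
    damax = her2_score(raw$damax, code_base = 1),
    stringsAsFactors = FALSE
  )
}

#' Reference agreement cross-tabulations
#'
#' The six 3 x 3 cross-tabulations of HER2 scores from the same reference
#' breast-cancer TMA study as [fish_cohort()]: two visual reads (VE1, VE2)
#' and digital analysis (DA) compared pairwise, at the spot level (575
#' adequate spots) and at the patient level (maximum score over 2-4
#' adequate spots, 161 patients). Rows index the first-named rater.
#'
#' @return Named list of six integer matrices: `spot_ve1_ve2`,
#'   `spot_ve1_da`, `spot_ve2_da`, `patient_ve1_ve2`, `patient_ve1_da`,
#'   `patient_ve2_da`.
#' @examples
#' weighted_kappa(agreement_tables()$spot_ve1_ve2)
#' @export
agreement_tables <- function() {
  lv <- her2_levels()
  mk <- function(...) matrix(c(...), nrow = 3, byrow = TRUE,
                             dimnames = list(lv, lv))
  list(
    spot_ve1_ve2    = mk(475, 15, 0,   0, 21, 4,   0, 4, 56),
    spot_ve1_da     = mk(458, 32, 0,   4, 18, 3,   0, 0, 60),
    spot_ve2_da     = mk(454, 21, 0,   8, 26, 6,   0, 3, 57),
    patient_ve1_ve2 = mk(129, 7, 0,    0, 7, 1,    0, 1, 16),
    patient_ve1_da  = mk(122, 14, 0,   0, 5, 3,    0, 0, 17),
    patient_ve2_da  = mk(121, 8, 0,    1, 11, 3,   0, 0, 17)
  )
}
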