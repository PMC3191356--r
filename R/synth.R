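# Synthetic data generators: IHC spot images with ground-truth membrane
# structure, and score/FISH cohorts with controllable discordance. These
# are first-class, tested components: they define the conditions under
# which the image pipeline and the statistics are validated.

#' Parameters of the synthetic spot-image generator
#'
#' The generator emulates a hematoxylin + DAB-stained TMA spot: a 1-mm
#' tissue disc on bright glass holding round tumour cells grouped into
#' nests of heterogeneous sizes (confluent patches on a hexagonal lattice,
#' surrounded by unstained stroma), each cell carrying a hematoxylin
#' nucleus and a DAB membrane arc covering a controllable fraction of its
#' perimeter. Within a nest adjacent cells share their membrane, so
#' complete membranes weld into long fragments while small nests keep the
#' fragment-size distribution spread. Pixels are rendered through the
#' forward Beer-Lambert model and quantized to 8-bit RGB.
#'
#' @param n_cells Number of cells placed (error if the disc cannot hold
#'   them).
#' @param n_nests Number of tumour nests the cells are grouped into;
#'   `NULL` (default) uses about one nest per 10 cells. Nest sizes are
#'   drawn heterogeneously (exponential weights), each nest holding at
#'   least 3 cells.
#' @param cell_radius_um Cell radius in microns (default 8, a breast
#'   carcinoma cell of about 16 um diameter).
#' @param membrane_completeness Fraction of each cell perimeter rendered as
#'   DAB membrane, in \[0, 1\]. The arc is contiguous per cell - the worst
#'   case for connectivity at a fixed stained fraction.
#' @param dab_intensity DAB optical density of membrane pixels (default
#'   0.8).
#' @param membrane_thickness_um Membrane thickness in microns (default 1).
#' @param hema_base_od Hematoxylin OD of the tissue background (default
#'   0.25).
#' @param nucleus_od Additional hematoxylin OD of nuclei (default 0.55).
#' @param background_noise_sd Gaussian OD noise, in OD units (default
#'   0.02).
#' @param mpp Microns per pixel (default 0.25, a 20x scan).
#' @param spot_diameter_um Tissue-spot diameter in microns (default 1000,
#'   a 1-mm TMA core).
#' @param seed Integer seed; the generated image is bit-identical per
#'   (params, seed).
#' @param spot_id,patient_id Identifiers for the generated image.
#' @return A validated parameter list of class `spot_sim_params`.
#' @export
spot_sim_params <- function(n_cells = 150,
                            n_nests = NULL,
                            cell_radius_um = 8,
                            membrane_completeness = 1,
                            dab_intensity = 0.8,
                            membrane_thickness_um = 1,
                            hema_base_od = 0.25,
                            nucleus_od = 0.55,
                            background_noise_sd = 0.02,
                            mpp = 0.25,
                            spot_diameter_um = 1000,
                            seed = 1,
                            spot_id = "synthetic_spot",
                            patient_id = "synthetic_patient") {
  p <- as.list(environment())
  stopifnot(p$n_cells >= 0, p$cell_radius_um > 0,
            p$membrane_completeness >= 0, p$membrane_completeness <= 1,
            p$dab_intensity >= 0, p$membrane_thickness_um > 0,
            p$background_noise_sd >= 0, p$mpp > 0, p$spot_diameter_um > 0)
  class(p) <- "spot_sim_params"
  p
}

#' Generate a synthetic IHC spot image with ground truth
#'
#' See [spot_sim_params()] for the model. Cells sit on a hexagonal lattice
#' at one cell-diameter spacing: adjacent cells within a nest share their
#' membrane band while the cell interiors stay disjoint. Nest seed sites
#' are drawn at random and each nest fills the available lattice sites
#' nearest its seed, so nests are compact. Each cell's membrane arc starts
#' at an independent random angle. The random draws for cell placement and arc angles are made
#' before the completeness value is used, so images generated at the same
#' seed but different completeness share cell layout and arc anchors (the
#' stained pixel set grows monotonically with completeness).
#'
#' @param params A [spot_sim_params()].
#' @return List with `image` (a [spot_image()]) and `truth`: the membrane
#'   pixel mask, the tissue-disc mask, and a per-cell data frame
#'   (`x`, `y` in pixels, `radius_px`, `start_angle`, `completeness`).
#' @export
generate_spot_image <- function(params = spot_sim_params()) {
  stopifnot(inherits(params, "spot_sim_params"))
  p <- params
  r_px <- p$cell_radius_um / p$mpp
  th_px <- max(1, p$membrane_thickness_um / p$mpp)
  R_px <- p$spot_diameter_um / 2 / p$mpp
  pad <- 10
  side <- ceiling(2 * R_px) + 2 * pad
  cy0 <- cx0 <- side / 2

  # Hexagonal lattice with spacing equal to the cell diameter: adjacent
  # occupied sites share their membranes (the bands overlap robustly),
  # while cell interiors (inside the membrane) stay disjoint.
  s <- 2 * r_px
  dy <- s * sqrt(3) / 2
  rows <- seq(cy0 - R_px, cy0 + R_px, by = dy)
  sites <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    xs <- seq(cx0 - R_px + off, cx0 + R_px, by = s)
    cbind(x = xs, y = rows[i])
  }))
  d_center <- sqrt((sites[, "x"] - cx0)^2 + (sites[, "y"] - cy0)^2)
  keep <- d_center <= R_px - r_px - th_px
  sites <- sites[keep, , drop = FALSE]
  d_center <- d_center[keep]
  if (nrow(sites) < p$n_cells)
    stop("infeasible packing: the spot holds at most ", nrow(sites),
         " cells of this size; reduce `n_cells` or `cell_radius_um`",
         call. = FALSE)

  withr::with_seed(p$seed, {
    k <- if (is.null(p$n_nests)) max(1L, round(p$n_cells / 10)) else
      as.integer(p$n_nests)
    min_nest <- min(3L, p$n_cells)  # a nest is multicellular
    k <- max(1L, min(k, p$n_cells %/% max(1L, min_nest)))
    wts <- stats::rexp(k)
    nsz <- pmax(min_nest, round(wts / sum(wts) * p$n_cells))
    while (sum(nsz) > p$n_cells) {
      j <- which.max(nsz); nsz[j] <- nsz[j] - 1L
    }
    while (sum(nsz) < p$n_cells) {
      j <- which.min(nsz); nsz[j] <- nsz[j] + 1L
    }
    seeds <- sample.int(nrow(sites), k)
    avail <- rep(TRUE, nrow(sites))
    pick <- integer(0)
    for (j in seq_len(k)) {
      dj <- sqrt((sites[, "x"] - sites[seeds[j], "x"])^2 +
                   (sites[, "y"] - sites[seeds[j], "y"])^2)
      ord <- order(dj)
      ord <- ord[avail[ord]]
      take <- ord[seq_len(nsz[j])]
      avail[take] <- FALSE
      pick <- c(pick, take)
    }
    cells <- data.frame(x = sites[pick, "x"], y = sites[pick, "y"],
                        radius_px = r_px,
                        start_angle = stats::runif(p$n_cells, 0, 2 * pi),
                        completeness = p$membrane_completeness)
    noise_h <- matrix(stats::rnorm(side * side, 0, p$background_noise_sd),
                      side, side)
    noise_d <- matrix(stats::rnorm(side * side, 0, p$background_noise_sd),
                      side, side)
  })

  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  tissue <- (xx - cx0)^2 + (yy - cy0)^2 <= R_px^2

  membrane <- matrix(FALSE, side, side)
  nuclei <- matrix(FALSE, side, side)
  arc_len <- p$membrane_completeness * 2 * pi
  for (i in seq_len(nrow(cells))) {
    cxi <- cells$x[i]; cyi <- cells$y[i]
    w <- ceiling(r_px + th_px)
    rs <- max(1, floor(cyi) - w):min(side, ceiling(cyi) + w)
    cs <- max(1, floor(cxi) - w):min(side, ceiling(cxi) + w)
    dxl <- outer(rep(1, length(rs)), cs - cxi)
    dyl <- outer(rs - cyi, rep(1, length(cs)))
    d <- sqrt(dxl^2 + dyl^2)
    nuclei[rs, cs] <- nuclei[rs, cs] | (d <= 0.45 * r_px)
    if (arc_len > 0) {
      ang <- (atan2(dyl, dxl) - cells$start_angle[i]) %% (2 * pi)
      on_ring <- abs(d - r_px) <= th_px / 2 & ang <= arc_len
      membrane[rs, cs] <- membrane[rs, cs] | on_ring
    }
  }

  hema <- ifelse(tissue, p$hema_base_od, 0) + ifelse(nuclei, p$nucleus_od, 0)
  dab <- ifelse(membrane, p$dab_intensity, 0)
  hema <- matrix(pmax(0, hema + noise_h), side, side)
  dab <- matrix(pmax(0, dab + noise_d), side, side)
  px <- stain_od_to_rgb(hema, dab, quantize = TRUE)
  img <- spot_image(px, mpp = p$mpp, spot_id = p$spot_id,
                    patient_id = p$patient_id)
  list(image = img,
       truth = list(membrane_mask = membrane, tissue_mask = tissue,
                    cells = cells))
}

#' Parameters of the synthetic cohort generator
#'
#' Emulates the structure of a TMA concordance study: a latent per-patient
#' HER2 burden drives a true ordinal score; each patient contributes 1-4
#' spots; three raters (two visual reads and digital analysis) observe the
#' spot score with independent one-category flip probabilities (two-category
#' flips never occur); digital analysis additionally carries a continuous
#' connectivity value per spot, drawn from a bimodal category-conditional
#' logit-normal model; and per-patient FISH counts are lognormal, coupled
#' to the patient's maximum log-connectivity through a Gaussian copula with
#' target correlation `rho`.
#'
#' @param n_patients Number of patients (default 177; with the default
#'   spot-count distribution this yields about 575 spots).
#' @param spots_per_patient_probs Probabilities of 1, 2, 3 or 4 spots per
#'   patient (default 16/15/55/91 out of 177).
#' @param score_probs Marginal probabilities of the true 0/1+, 2+ and 3+
#'   categories (default c(0.845, 0.050, 0.105)).
#' @param spot_heterogeneity Probability that one spot's true score deviates
#'   one category from the patient's (default 0.02 - inter-spot variation
#'   is low and concentrated around 2+).
#' @param flip_ve1,flip_ve2,flip_da One-category observation flip
#'   probabilities of the three raters. The visual defaults (0.02) put the
#'   two visual reads at about 96% raw agreement, i.e. a linear-weighted
#'   kappa near 0.91 at these marginals; the digital default (0.05)
#'   reproduces the looser visual-digital operating point (kappa about
#'   0.86).
#' @param connectivity_band_centers Logit-scale centers of the
#'   connectivity distribution per digital score category.
#' @param connectivity_band_sd Logit-scale spread within a category.
#' @param rho Target correlation between `log(connect_max)` and
#'   `log(fish_her2)` (default 0.67).
#' @param cep17_coupling Copula loading of CEP17 on the connectivity latent
#'   (default 0.4, putting the CEP17 correlation near 0.39).
#' @param her2_meanlog,her2_sdlog Lognormal parameters of HER2 copies per
#'   cell.
#' @param cep17_meanlog,cep17_sdlog Lognormal parameters of CEP17 copies
#'   per cell.
#' @param seed Integer seed.
#' @return A validated parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 177,
                              spots_per_patient_probs =
                                c(16, 15, 55, 91) / 177,
                              score_probs = c(0.845, 0.050, 0.105),
                              spot_heterogeneity = 0.02,
                              flip_ve1 = 0.02,
                              flip_ve2 = 0.02,
                              flip_da = 0.05,
                              connectivity_band_centers =
                                qlogis(c(0.03, 0.30, 0.92)),
                              connectivity_band_sd = 0.8,
                              rho = 0.67,
                              cep17_coupling = 0.4,
                              her2_meanlog = log(3.5),
                              her2_sdlog = 0.8,
                              cep17_meanlog = log(2.6),
                              cep17_sdlog = 0.3,
                              seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_patients >= 1,
            length(p$spots_per_patient_probs) == 4,
            abs(sum(p$spots_per_patient_probs) - 1) < 1e-8,
            length(p$score_probs) == 3,
            abs(sum(p$score_probs) - 1) < 1e-8,
            p$rho >= -1, p$rho <= 1,
            p$flip_ve1 >= 0, p$flip_ve1 <= 1,
            p$flip_ve2 >= 0, p$flip_ve2 <= 1,
            p$flip_da >= 0, p$flip_da <= 1)
  class(p) <- "cohort_sim_params"
  p
}

# one-category ordinal flip on the 0/1/2 scale
flip_score <- function(s, prob) {
  do <- stats::runif(length(s)) < prob
  dir <- ifelse(s == 0L, 1L, ifelse(s == 2L, -1L,
                                    ifelse(stats::runif(length(s)) < 0.5,
                                           -1L, 1L)))
  ifelse(do, s + dir, s)
}

#' Generate a synthetic score/FISH cohort
#'
#' See [cohort_sim_params()] for the model. Deterministic per (params,
#' seed).
#'
#' @param params A [cohort_sim_params()].
#' @return List with `spots` (data frame: `patient_id`, `spot_id`, `ve1`,
#'   `ve2`, `da`, `connectivity`, `adequate`), `fish` (data frame:
#'   `patient_id`, `her2_mean`, `cep17_mean`, `ratio`) and `truth`
#'   (per-patient latent scores and connectivity maxima).
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    np <- p$n_patients
    u <- stats::rnorm(np)
    true_score <- findInterval(stats::pnorm(u),
                               cumsum(p$score_probs)[1:2]) # 0,1,2
    n_spots <- sample(1:4, np, replace = TRUE,
                      prob = p$spots_per_patient_probs)
    pid <- sprintf("SP%03d", seq_len(np))

    spot_pat <- rep(seq_len(np), n_spots)
    spot_ix <- sequence(n_spots)
    s_true <- flip_score(true_score[spot_pat], p$spot_heterogeneity)
    ve1 <- flip_score(s_true, p$flip_ve1)
    ve2 <- flip_score(s_true, p$flip_ve2)
    da <- flip_score(s_true, p$flip_da)
    conn <- stats::plogis(stats::rnorm(
      length(da), p$connectivity_band_centers[da + 1L],
      p$connectivity_band_sd))
    spots <- data.frame(patient_id = pid[spot_pat],
                        spot_id = sprintf("%s_s%d", pid[spot_pat], spot_ix),
                        ve1 = her2_score(ve1), ve2 = her2_score(ve2),
                        da = her2_score(da), connectivity = conn,
                        adequate = TRUE, stringsAsFactors = FALSE)

    connect_max <- vapply(split(conn, spot_pat), max, 0)
    zx <- as.numeric(scale(log(connect_max)))
    z_h <- p$rho * zx + sqrt(max(0, 1 - p$rho^2)) * stats::rnorm(np)
    z_c <- p$cep17_coupling * zx +
      sqrt(max(0, 1 - p$cep17_coupling^2)) * stats::rnorm(np)
    her2 <- exp(p$her2_meanlog + p$her2_sdlog * z_h)
    cep17 <- exp(p$cep17_meanlog + p$cep17_sdlog * z_c)
    fish <- data.frame(patient_id = pid, her2_mean = her2,
                       cep17_mean = cep17, ratio = her2 / cep17,
                       stringsAsFactors = FALSE)
  })
  list(spots = spots, fish = fish,
       truth = list(patient_id = pid, true_score = her2_score(true_score),
                    connect_max = unname(connect_max)))
}
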