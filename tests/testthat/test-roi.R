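# Tissue detection, ROI margin, area control and the per-spot pipeline.

test_that("blank glass yields no tissue and specks are removed", {
  white <- spot_image(array(255, c(60, 60, 3)), mpp = 1)
  expect_false(any(detect_tissue(white)))

  # a 10-px dust speck falls below the 100-px floor
  speck_od <- matrix(0, 60, 60)
  speck_od[30:34, 30:31] <- 0.6
  img <- od_spot(matrix(0, 60, 60), hema_od = speck_od, mpp = 1)
  expect_false(any(detect_tissue(img)))
  # but it is detected when the floor allows it
  expect_true(any(detect_tissue(img, min_speck_px = 5)))
})

test_that("tissue detection recovers the generated spot disc", {
  g <- generate_spot_image(spot_sim_params(n_cells = 20,
                                           spot_diameter_um = 150,
                                           mpp = 1, seed = 2))
  tissue <- detect_tissue(g$image)
  truth <- g$truth$tissue_mask
  iou <- sum(tissue & truth) / sum(tissue | truth)
  expect_gte(iou, 0.95)
})

test_that("the ROI margin erodes by Euclidean distance", {
  disc_small <- draw_disc(200, 200, 100, 100, 90)
  expect_false(any(apply_margin(disc_small, 100, mpp = 1)$mask))

  disc <- draw_disc(640, 640, 320, 320, 300)
  roi <- apply_margin(disc, 100, mpp = 1)
  expect_true(all(roi$mask <= disc))                 # anti-extensive
  d <- EBImage::distmap(disc * 1)
  expect_true(all(d[roi$mask] >= 100))
  # radius shrinks to about 200 px
  expect_equal(sum(roi$mask), pi * 200^2, tolerance = 0.02)

  identity_roi <- apply_margin(disc, 0, mpp = 1)
  expect_identical(identity_roi$mask, disc)

  # monotone decreasing in the margin
  a50 <- apply_margin(disc, 50, mpp = 1)$mask
  a150 <- apply_margin(disc, 150, mpp = 1)$mask
  expect_true(all(a150 <= a50))
})

test_that("area control is strict and consistent with spot geometry", {
  expect_false(area_control(37000))
  expect_true(area_control(37000.1))
  expect_false(area_control(0))
  # intact 1-mm spot at 0.25 um/px after a 25-um margin: radius 475 um
  intact_area <- pi * 475^2
  expect_true(area_control(intact_area))
  expect_equal(37000 / intact_area, 0.05, tolerance = 0.05)
  roi <- apply_margin(draw_disc(120, 120, 60, 60, 50), 10, mpp = 1)
  expect_equal(roi$area_um2, sum(roi$mask))
  expect_false(roi$adequate)  # ~5000 um^2
})

test_that("analyze_spot routes exclusions before analysis", {
  blank <- spot_image(array(255, c(80, 80, 3)), mpp = 1,
                      spot_id = "b", patient_id = "p")
  r <- analyze_spot(blank, mc_config())
  expect_equal(r$status, "excluded_area")
  expect_null(r$connectivity_result)

  r2 <- analyze_spot(blank, mc_config(), manual_exclude = TRUE,
                     exclude_reason = "DCIS")
  expect_equal(r2$status, "excluded_manual")
  expect_null(r2$roi)
  expect_equal(r2$exclude_reason, "DCIS")

  df <- as.data.frame(r2)
  expect_equal(df$status, "excluded_manual")
  expect_true(is.na(df$connectivity))
})

test_that("a complete-membrane spot is analyzed and scored 3+", {
  g <- generate_spot_image(spot_sim_params(
    n_cells = 80, membrane_completeness = 1, spot_diameter_um = 400,
    mpp = 0.5, seed = 8))
  r <- analyze_spot(g$image, mc_config())
  expect_equal(r$status, "analyzed")
  expect_true(r$roi$adequate)
  expect_equal(as.character(r$connectivity_result$her2_score), "3+")

  # determinism: identical image and config give identical results
  r2 <- analyze_spot(g$image, mc_config())
  expect_identical(as.data.frame(r), as.data.frame(r2))
})

test_that("batch analysis survives unreadable images", {
  dir <- withr::local_tempdir()
  g <- generate_spot_image(spot_sim_params(
    n_cells = 40, membrane_completeness = 0, spot_diameter_um = 300,
    mpp = 1, seed = 4))
  ok_path <- file.path(dir, "ok.png")
  png::writePNG(g$image$pixels / 255, ok_path)
  manifest <- data.frame(
    spot_id = c("s1", "s2", "s3"),
    patient_id = c("p1", "p1", "p2"),
    image_path = c(ok_path, file.path(dir, "missing.png"), ok_path),
    mpp = 1,
    manual_exclude = c(0, 0, 1),
    exclude_reason = c(NA, NA, "inadequate sample"),
    stringsAsFactors = FALSE
  )
  res <- analyze_batch(manifest, mc_config(margin_px = 25))
  expect_equal(nrow(res), 3)
  expect_equal(res$status, c("analyzed", "error", "excluded_manual"))
  expect_match(res$exclude_reason[2], "missing.png")
  expect_equal(as.character(res$her2_score[1]), "0/1+")
})
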