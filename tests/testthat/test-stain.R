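# Stain separation and membrane segmentation.

test_that("pure white carries zero stain and forward synthesis inverts", {
  img <- spot_image(array(255, c(4, 4, 3)), mpp = 0.25)
  s <- rgb_to_stain_od(img)
  expect_equal(max(s$dab_od), 0)
  expect_equal(max(s$hema_od), 0)

  # forward Beer-Lambert pixel with known ODs, recovered by the inverse
  px <- stain_od_to_rgb(matrix(0, 1, 1), matrix(0.8, 1, 1))
  img2 <- spot_image(px, mpp = 0.25)
  s2 <- rgb_to_stain_od(img2)
  expect_equal(s2$dab_od[1, 1], 0.8, tolerance = 1e-6)
  expect_lt(abs(s2$hema_od[1, 1]), 1e-6)

  px3 <- stain_od_to_rgb(matrix(1.0, 1, 1), matrix(0, 1, 1))
  s3 <- rgb_to_stain_od(spot_image(px3, mpp = 0.25))
  expect_lte(s3$dab_od[1, 1], 1e-6)
  expect_equal(s3$hema_od[1, 1], 1.0, tolerance = 1e-6)
})

test_that("stain decomposition round-trips random OD pairs to 1e-6", {
  set.seed(11)
  hema <- matrix(runif(64, 0, 1.5), 8, 8)
  dab <- matrix(runif(64, 0, 1.5), 8, 8)
  px <- stain_od_to_rgb(hema, dab)
  s <- rgb_to_stain_od(spot_image(pmax(px, 0), mpp = 0.25))
  expect_equal(s$hema_od, hema, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(s$dab_od, dab, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("invalid stain configuration and inputs are rejected", {
  img <- spot_image(array(128, c(2, 2, 3)), mpp = 0.25)
  collinear <- cbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(rgb_to_stain_od(img, collinear), "singular")
  expect_error(spot_image(matrix(0, 2, 2), mpp = 0.25), "RGB")
  expect_error(spot_image(array(300, c(2, 2, 3)), mpp = 0.25), "255")
  expect_error(spot_image(array(1, c(2, 2, 3)), mpp = -1), "mpp")
})

test_that("ridge response prefers lines over blobs and flats", {
  n <- 100
  flat <- matrix(0.7, 50, 50)
  expect_lt(max(linear_structure_response(flat, 1, mpp = 0.5)), 1e-10)

  img <- matrix(0, n, n)
  img[20:21, 10:90] <- 1                       # 2-px-wide line
  disc <- draw_disc(n, n, 60, 50, 10)
  img[disc] <- 1
  r <- linear_structure_response(img, 1, mpp = 0.5)
  interior <- draw_disc(n, n, 60, 50, 8)
  expect_gt(max(r[20:21, 10:90]), max(r[interior]))

  ring <- draw_ring(120, 120, 60, 60, 30, 2)
  rr <- linear_structure_response(ring * 1, 1, mpp = 0.5)
  expect_gte(mean(rr[ring] >= 0.5 * max(rr)), 0.9)
})

test_that("ridge response is shift-equivariant and offset-invariant", {
  set.seed(7)
  base <- matrix(0, 80, 80)
  base[draw_ring(80, 80, 40, 40, 15, 2)] <- 1
  r0 <- linear_structure_response(base, 1, mpp = 0.5)
  shifted <- matrix(0, 80, 80)
  shifted[11:80, 6:80] <- base[1:70, 1:75]      # shift by (+10, +5)
  r1 <- linear_structure_response(shifted, 1, mpp = 0.5)
  expect_equal(r1[31:60, 26:65], r0[21:50, 21:60], tolerance = 1e-8)

  r2 <- linear_structure_response(base + 0.4, 1, mpp = 0.5)
  expect_equal(r2, r0, tolerance = 1e-8)

  expect_warning(linear_structure_response(base, 0.2, mpp = 0.5),
                 "clamping")
  expect_error(linear_structure_response(base, -1, mpp = 0.5), "scale_um")
})

test_that("membrane segmentation recovers a stained ring and honors the OD floor", {
  # stained ring over tissue carrying a faint diffuse DAB wash (below the
  # OD floor), as real sections do: the wash anchors the low response mode
  ring <- draw_ring(160, 160, 80, 80, 40, 2)
  img <- od_spot(ifelse(ring, 0.8, 0.05), hema_od = matrix(0.2, 160, 160))
  stain <- rgb_to_stain_od(img)
  resp <- linear_structure_response(stain, 1.0)
  mask <- segment_membrane(resp, stain)
  expect_gte(mean(mask[ring]), 0.9)
  expect_lte(mean(mask[!ring]), 0.01)

  # same ring below the DAB floor vanishes
  img_lo <- od_spot(ifelse(ring, 0.10, 0), hema_od = matrix(0.2, 160, 160))
  stain_lo <- rgb_to_stain_od(img_lo)
  resp_lo <- linear_structure_response(stain_lo, 1.0)
  expect_false(any(segment_membrane(resp_lo, stain_lo, min_dab_od = 0.15)))

  # degenerate response: empty mask
  flat <- rgb_to_stain_od(flat_spot(32, 32, hema = 0.3, dab = 0))
  resp0 <- linear_structure_response(flat, 1.0)
  expect_message(m0 <- segment_membrane(resp0, flat), "degenerate")
  expect_false(any(m0))
})

test_that("raising the DAB floor never adds mask pixels", {
  ring <- draw_ring(120, 120, 60, 60, 30, 2)
  img <- od_spot(ifelse(ring, 0.5, 0), hema_od = matrix(0.25, 120, 120))
  stain <- rgb_to_stain_od(img)
  resp <- linear_structure_response(stain, 1.0)
  prev <- segment_membrane(resp, stain, min_dab_od = 0)
  for (floor in c(0.1, 0.3, 0.6)) {
    cur <- segment_membrane(resp, stain, min_dab_od = floor)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})
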