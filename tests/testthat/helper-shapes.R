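# Programmatic shape generators used as ground truth across the image tests.

draw_disc <- function(h, w, cy, cx, r) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  d2 <= r^2
}

draw_ring <- function(h, w, cy, cx, r, thickness) {
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
  abs(d - r) <= thickness / 2
}

draw_hsegment <- function(h, w, row, col_from, col_to, thickness = 1) {
  m <- matrix(FALSE, h, w)
  r0 <- row - (thickness - 1) %/% 2
  m[r0:(r0 + thickness - 1), col_from:col_to] <- TRUE
  m
}

# number of 8-neighbors of each TRUE pixel
neighbor_counts <- function(mask) {
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- nrow(mask); nc <- ncol(mask)
    shifted <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    shifted[okr, okc] <- mask[rs[okr], cs[okc]]
    s <- s + shifted
  }
  s[mask]
}

# spot image with constant stain ODs everywhere (for degenerate cases)
flat_spot <- function(h = 32, w = 32, hema = 0, dab = 0, mpp = 0.5) {
  px <- stain_od_to_rgb(matrix(hema, h, w), matrix(dab, h, w),
                        quantize = TRUE)
  spot_image(px, mpp = mpp)
}

# render a DAB OD matrix (plus optional hema) into a quantized spot image
od_spot <- function(dab_od, hema_od = 0 * dab_od, mpp = 0.5) {
  spot_image(stain_od_to_rgb(hema_od, dab_od, quantize = TRUE), mpp = mpp)
}
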