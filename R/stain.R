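#' Hematoxylin / DAB stain vectors
#'
#' Standard published unit optical-density vectors for hematoxylin and DAB
#' (Ruifrok-Johnston color deconvolution), the default color model for
#' brightfield IHC with a DAB chromogen on a hematoxylin counterstain.
#'
#' @return A 3 x 2 numeric matrix; rows are the R, G, B channels, columns
#'   the hematoxylin and DAB stains, each column a unit vector.
#' @examples
#' stain_vectors_hdab()
#' @export
stain_vectors_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  m <- cbind(hema = h / sqrt(sum(h^2)), dab = d / sqrt(sum(d^2)))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Construct a spot image
#'
#' The unit of digital analysis: an 8-bit RGB brightfield image of one
#' tissue-microarray spot together with its physical pixel scale.
#'
#' @param pixels H x W x 3 numeric array of intensities in \[0, 255\].
#' @param mpp Microns per pixel (positive).
#' @param spot_id,patient_id Opaque identifiers carried through the analysis.
#' @return An object of class `spot_image`.
#' @export
spot_image <- function(pixels, mpp, spot_id = NA_character_,
                       patient_id = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("input error: `pixels` must be an H x W x 3 RGB array", call. = FALSE)
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("input error: empty image", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("input error: channel values must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(mpp) || length(mpp) != 1 || !is.finite(mpp) || mpp <= 0)
    stop("input error: `mpp` must be a positive number", call. = FALSE)
  structure(list(pixels = pixels, mpp = mpp,
                 spot_id = as.character(spot_id),
                 patient_id = as.character(patient_id)),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spot_image> %s (patient %s): %d x %d px at %.3g um/px\n",
              x$spot_id, x$patient_id, d[1], d[2], x$mpp))
  invisible(x)
}

#' Read a spot image from TIFF or PNG
#'
#' @param path Path to an 8-bit RGB TIFF or PNG file.
#' @param mpp Microns per pixel of the image.
#' @param spot_id,patient_id Identifiers; default to the file name.
#' @return A [spot_image()].
#' @export
read_spot_image <- function(path, mpp = 0.25,
                            spot_id = basename(path),
                            patient_id = NA_character_) {
  if (!file.exists(path))
    stop("input error: no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("input error: unsupported image format `.", ext,
         "` (use 8-bit RGB TIFF or PNG)", call. = FALSE))
  if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("input error: ", path, " is not an RGB image", call. = FALSE)
  spot_image(round(px * 255), mpp = mpp, spot_id = spot_id,
             patient_id = patient_id)
}

#' Separate hematoxylin and DAB optical densities
#'
#' Converts RGB intensities to per-channel optical densities by the
#' Beer-Lambert model, `OD_c = -log10((I_c + eps) / 255)`, and decomposes
#' each pixel's OD vector onto the stain vectors (plus their orthogonal
#' complement as a residual). Negative decomposition coefficients are
#' clipped to zero, so a pure-white pixel carries zero stain.
#'
#' @param image A [spot_image()].
#' @param stain_vectors 3 x 2 (or 3 x 3) matrix of linearly independent
#'   stain OD vectors; columns hematoxylin, DAB (and optionally a residual).
#' @param epsilon Intensity offset avoiding `log(0)`; default 1 intensity
#'   unit.
#' @return An object of class `stain_map`: list with H x W matrices
#'   `hema_od`, `dab_od`, `residual_od`, plus `mpp`.
#' @examples
#' img <- spot_image(array(255, c(2, 2, 3)), mpp = 0.25)
#' s <- rgb_to_stain_od(img)
#' max(s$dab_od)  # pure white carries no DAB
#' @export
rgb_to_stain_od <- function(image, stain_vectors = stain_vectors_hdab(),
                            epsilon = 1) {
  if (!inherits(image, "spot_image"))
    stop("input error: `image` must be a spot_image", call. = FALSE)
  M <- stain_matrix(stain_vectors)
  px <- image$pixels
  d <- dim(px)
  od <- -log10((matrix(px, ncol = 3) + epsilon) / 255)  # n x 3, cols R,G,B
  coef <- t(solve(M, t(od)))                            # n x 3
  coef[coef < 0] <- 0
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(hema_od = shape(coef[, 1]), dab_od = shape(coef[, 2]),
                 residual_od = shape(coef[, 3]), mpp = image$mpp),
            class = "stain_map")
}

# Complete a 3 x 2 stain basis with the unit normal; check invertibility.
stain_matrix <- function(stain_vectors) {
  sv <- stain_vectors
  if (!is.matrix(sv) || nrow(sv) != 3 || !ncol(sv) %in% c(2, 3))
    stop("configuration error: stain_vectors must be 3 x 2 or 3 x 3",
         call. = FALSE)
  if (ncol(sv) == 2) {
    r <- c(sv[2, 1] * sv[3, 2] - sv[3, 1] * sv[2, 2],
           sv[3, 1] * sv[1, 2] - sv[1, 1] * sv[3, 2],
           sv[1, 1] * sv[2, 2] - sv[2, 1] * sv[1, 2])
    nr <- sqrt(sum(r^2))
    if (nr < 1e-8)
      stop("configuration error: singular stain matrix (collinear stain vectors)",
           call. = FALSE)
    sv <- cbind(sv, residual = r / nr)
  }
  if (abs(det(sv)) < 1e-8)
    stop("configuration error: singular stain matrix", call. = FALSE)
  sv
}

#' Render stain optical densities back to RGB (forward model)
#'
#' Inverse of [rgb_to_stain_od()]: given per-pixel hematoxylin and DAB
#' optical densities, computes the transmitted intensities
#' `I_c = 255 * 10^(-OD_c) - eps`. With `quantize = FALSE` the returned
#' intensities are continuous, so the round trip through
#' [rgb_to_stain_od()] is exact to numerical precision; with
#' `quantize = TRUE` they are rounded and clamped to 8-bit.
#'
#' @param hema_od,dab_od Matrices (or scalars) of non-negative optical
#'   densities, same shape.
#' @param stain_vectors As in [rgb_to_stain_od()].
#' @param epsilon As in [rgb_to_stain_od()].
#' @param quantize Round and clamp to integers in \[0, 255\]?
#' @return H x W x 3 array of intensities.
#' @export
stain_od_to_rgb <- function(hema_od, dab_od,
                            stain_vectors = stain_vectors_hdab(),
                            epsilon = 1, quantize = FALSE) {
  hema_od <- as.matrix(hema_od); dab_od <- as.matrix(dab_od)
  stopifnot(all(dim(hema_od) == dim(dab_od)))
  M <- stain_matrix(stain_vectors)
  od <- cbind(as.numeric(hema_od), as.numeric(dab_od), 0) %*% t(M)  # n x 3
  I <- 255 * 10^(-od) - epsilon
  if (quantize) I <- pmin(255, pmax(0, round(I)))
  array(I, c(nrow(hema_od), ncol(hema_od), 3))
}

#' Curvilinear structure response
#'
#' Enhances thin curvilinear ridges (stained membranes) in the DAB optical
#' density and suppresses isotropic blobs and flat regions, via the
#' eigenvalues of the scale-normalized Gaussian Hessian at a single scale.
#' For a bright ridge the cross-ridge eigenvalue `l2` is strongly negative
#' while the along-ridge eigenvalue `l1` is near zero; the response is
#' `sigma^2 * max(0, -l2)` damped by a blobness factor
#' `exp(-(l1/l2)^2 / (2 * 0.5^2))` so that isotropic structures
#' (`l1 = l2`) are attenuated.
#'
#' @param stain A `stain_map` from [rgb_to_stain_od()], or a plain numeric
#'   matrix taken as the DAB OD.
#' @param scale_um Ridge width scale in microns (> 0).
#' @param mpp Microns per pixel; defaults to the stain map's own value.
#' @return Non-negative H x W response matrix; identically zero on constant
#'   input.
#' @export
linear_structure_response <- function(stain, scale_um = 1.0,
                                      mpp = NULL) {
  dab <- if (inherits(stain, "stain_map")) stain$dab_od else as.matrix(stain)
  if (is.null(mpp)) {
    mpp <- if (inherits(stain, "stain_map")) stain$mpp else
      stop("input error: `mpp` required when `stain` is a plain matrix",
           call. = FALSE)
  }
  if (!is.numeric(scale_um) || scale_um <= 0)
    stop("input error: `scale_um` must be > 0", call. = FALSE)
  sigma <- scale_um / mpp
  if (sigma < 1) {
    warning("ridge scale below one pixel; clamping to 1 px")
    sigma <- 1
  }
  gxx <- conv_sep(dab, gauss_kernel(sigma, 2), gauss_kernel(sigma, 0))
  gyy <- conv_sep(dab, gauss_kernel(sigma, 0), gauss_kernel(sigma, 2))
  gxy <- conv_sep(dab, gauss_kernel(sigma, 1), gauss_kernel(sigma, 1))
  tr <- gxx + gyy
  dif <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
  l1 <- (tr + dif) / 2
  l2 <- (tr - dif) / 2                       # l2 <= l1
  resp <- sigma^2 * pmax(0, -l2) *
    exp(-(l1 / pmin(l2, -.Machine$double.eps))^2 / 0.5)
  resp[l2 >= 0] <- 0
  resp
}

# 1-D Gaussian kernel or its first/second derivative; second-derivative
# kernels are mean-corrected so a constant image yields exactly zero.
gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
              "0" = g,
              "1" = -x / sigma^2 * g,
              "2" = (x^2 - sigma^2) / sigma^4 * g)
  if (order == 2) k <- k - mean(k)
  k
}

# Separable convolution (kx along columns/x, ky along rows/y) with
# replicated borders, via EBImage's 2-D filter.
conv_sep <- function(m, kx, ky) {
  EBImage::filter2(m, outer(ky, kx), boundary = "replicate")
}

#' Segment stained membrane pixels
#'
#' Chooses a single global threshold on the ridge response by Otsu's
#' two-class criterion, evaluated over pixels that carry any DAB stain, and
#' intersects the thresholded response with a minimum-DAB-OD floor so that
#' chromogen-free ridges cannot enter the mask. A degenerate (constant)
#' response yields an empty mask.
#'
#' @param response Response matrix from [linear_structure_response()].
#' @param stain The matching `stain_map`.
#' @param min_dab_od DAB OD floor (default 0.15).
#' @return Logical H x W membrane mask with the chosen threshold in
#'   attribute `"threshold"` (NA when degenerate).
#' @export
segment_membrane <- function(response, stain, min_dab_od = 0.15) {
  dab <- stain$dab_od
  if (!all(dim(response) == dim(dab)))
    stop("input error: response and stain dimensions differ", call. = FALSE)
  vals <- response[dab > 0]
  if (length(vals) < 2 || diff(range(vals)) < 1e-12) {
    message("segment_membrane: degenerate response histogram; empty mask")
    return(structure(matrix(FALSE, nrow(response), ncol(response)),
                     threshold = NA_real_))
  }
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1)),
                       range = range(vals), levels = 256)
  mask <- response >= thr & dab >= min_dab_od
  structure(mask, threshold = thr)
}
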