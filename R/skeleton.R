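# Skeletonization and fragment bookkeeping for membrane masks.
#
# The thinning operator is a vectorized Guo-Hall two-subiteration scheme:
# no installed package offers 2-D topology-preserving thinning, and the
# fragment-size statistic downstream depends on a 1-px-wide,
# connectivity-preserving skeleton, so the operator is implemented here and
# pinned by regression tests on programmatic shapes.

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Topology-preserving morphological thinning (Guo-Hall, two subiterations
#' per pass, iterated to convergence). Connected components stay connected,
#' closed loops stay closed, and the result is at most one pixel wide.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      # p2..p9 = N, NE, E, SE, S, SW, W, NW neighbors
      p2 <- shift_mask(m, -1,  0); p3 <- shift_mask(m, -1,  1)
      p4 <- shift_mask(m,  0,  1); p5 <- shift_mask(m,  1,  1)
      p6 <- shift_mask(m,  1,  0); p7 <- shift_mask(m,  1, -1)
      p8 <- shift_mask(m,  0, -1); p9 <- shift_mask(m, -1, -1)
      C  <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
            (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N  <- pmin(n1, n2)
      g  <- if (iter == 0) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      del <- m & C == 1 & N >= 2 & N <= 3 & !g
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-connected labeling of a sparse skeleton mask. EBImage::bwlabel is
# 4-connected, which would split diagonal skeleton runs, so components are
# taken over the 8-neighbor pixel graph instead.
label_components8 <- function(mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(labels)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    if (!any(ok)) next
    nb <- pos[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has))
      edges <- c(edges, rbind(pos[idx[ok][has]], nb[has]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  labels[idx] <- as.integer(memb)
  labels
}

#' Fragment set from a labeled skeleton
#'
#' @param labels Integer H x W matrix: 0 background, k > 0 fragment id.
#' @return Object of class `fragment_set`: list with `labels` and `sizes`
#'   (named integer vector of skeleton-pixel counts per fragment).
#' @export
fragment_set <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- labels[labels > 0L]
  sizes <- if (length(ids)) {
    tb <- tabulate(ids)
    stats::setNames(as.integer(tb[tb > 0L]), which(tb > 0L))
  } else integer(0)
  structure(list(labels = labels, sizes = sizes), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments, %d skeleton px\n",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

#' Skeletonize a membrane mask into labeled fragments
#'
#' Thins the mask to a one-pixel skeleton ([thin_mask()]) and labels its
#' 8-connected components.
#'
#' @param mask Logical membrane mask (e.g. from [segment_membrane()]).
#' @return A [fragment_set()].
#' @export
skeletonize_mask <- function(mask) {
  fragment_set(label_components8(thin_mask(mask)))
}

#' Link nearly-touching skeleton fragments
#'
#' Merges fragments whose skeletons approach within `gap_px` of each other
#' (membranes that are not perfectly connected), by dilating the skeleton
#' with a disc of radius `ceiling(gap_px / 2)`, re-thinning, and relabeling.
#' `gap_px = 0` is the identity.
#'
#' @param frags A [fragment_set()].
#' @param gap_px Maximum bridged gap in pixels (>= 0).
#' @return A [fragment_set()] with merged fragments.
#' @export
link_fragments <- function(frags, gap_px = 3) {
  stopifnot(inherits(frags, "fragment_set"), gap_px >= 0)
  if (gap_px == 0 || !length(frags$sizes)) return(frags)
  r <- ceiling(gap_px / 2)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  fat <- EBImage::dilate(frags$labels > 0L, brush) > 0
  fragment_set(label_components8(thin_mask(fat)))
}

#' Prune small skeleton fragments
#'
#' Removes every fragment whose skeleton-pixel count is below
#' `min_fragment_px`; larger fragments are untouched.
#'
#' @param frags A [fragment_set()].
#' @param min_fragment_px Pruning threshold (>= 0); 0 is the identity.
#' @return A [fragment_set()].
#' @export
prune_fragments <- function(frags, min_fragment_px = 10) {
  stopifnot(inherits(frags, "fragment_set"), min_fragment_px >= 0)
  if (min_fragment_px == 0 || !length(frags$sizes)) return(frags)
  drop_ids <- as.integer(names(frags$sizes)[frags$sizes < min_fragment_px])
  if (!length(drop_ids)) return(frags)
  labels <- frags$labels
  labels[labels %in% drop_ids] <- 0L
  fragment_set(labels)
}
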