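#' Extract a sub-pixel closed contour from a single-component mask
#'
#' Boundary pixels are traced in order, the polygon is refined to sub-pixel
#' positions by a few iterations of shrinkage-free (Taubin) smoothing, and a
#' periodic cubic spline is fitted through the nodes (one node per boundary
#' pixel). Node parameters are cumulative chord arclengths in pixels.
#' Contours are oriented so that the boundary normal
#' (rotated tangent) points out of the cell.
#'
#' @param mask logical matrix with a single 4-connected foreground
#'   component of area >= 25 pixels.
#' @param smooth_iters Taubin smoothing iterations (lambda = 0.5,
#'   mu = -0.53).
#' @return A `cell_contour`: list with `nodes` (n-by-2 sub-pixel positions),
#'   `p` (arclength parameters, `p[1] = 0`), `length` (closed-curve length),
#'   `normals` (outward unit normals per node), and spline evaluators.
#' @export
extract_contour <- function(mask, smooth_iters = 5L) {
  mask <- mask > 0
  area <- sum(mask)
  if (area < 25) abort("mask area too small for contour extraction (< 25 px)")
  lab <- label_components4(mask)
  if (max(lab) > 1L) abort("mask has multiple connected components")
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1
  if (nrow(pts) < 4) abort("boundary trace too short")
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)

  # Taubin lambda/mu smoothing: removes pixel staircase without shrinkage.
  lap <- function(P) {
    k <- nrow(P)
    0.5 * (P[c(2:k, 1), , drop = FALSE] + P[c(k, 1:(k - 1)), , drop = FALSE]) - P
  }
  sm <- pts
  for (i in seq_len(smooth_iters)) {
    sm <- sm + 0.5 * lap(sm)
    sm <- sm - 0.53 * lap(sm)
  }

  # Outward normals from the tangent; orientation fixed by probing the mask.
  tg <- sm[c(2:n, 1), , drop = FALSE] - sm[c(n, 1:(n - 1)), , drop = FALSE]
  tl <- sqrt(rowSums(tg^2))
  tl[tl == 0] <- NA_real_
  nrm <- cbind(tg[, 2], -tg[, 1]) / tl
  probe_in <- function(d) {
    px <- round(sm + d * nrm)
    px[, 1] <- pmin(pmax(px[, 1], 1), nrow(mask))
    px[, 2] <- pmin(pmax(px[, 2], 1), ncol(mask))
    mask[px]
  }
  ok <- !is.na(tl)
  # outward means: inside behind the normal, outside ahead of it
  score <- sum(probe_in(-1.5)[ok] & !probe_in(1.5)[ok])
  if (score < sum(ok) / 2) {
    sm <- sm[n:1, , drop = FALSE]
    pts <- pts[n:1, , drop = FALSE]
    tg <- sm[c(2:n, 1), , drop = FALSE] - sm[c(n, 1:(n - 1)), , drop = FALSE]
    tl <- sqrt(rowSums(tg^2)); tl[tl == 0] <- NA_real_
    nrm <- cbind(tg[, 2], -tg[, 1]) / tl
  }

  arc <- polygon_arclength(sm)
  fx <- splinefun(c(arc$p, arc$total), c(sm[, 1], sm[1, 1]), method = "periodic")
  fy <- splinefun(c(arc$p, arc$total), c(sm[, 2], sm[1, 2]), method = "periodic")
  structure(
    list(nodes = sm, pixels = pts, p = arc$p, length = arc$total,
         normals = nrm, fx = fx, fy = fy, mask_dim = dim(mask)),
    class = "cell_contour"
  )
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> %d nodes, arclength %.1f px\n",
              nrow(x$nodes), x$length))
  invisible(x)
}

# Evaluate contour position at (possibly wrapped) arclength parameters.
contour_point <- function(ct, s) {
  s <- s %% ct$length
  cbind(ct$fx(s), ct$fy(s))
}

# Nearest arclength parameter on `ct` to each query point, by dense sampling.
contour_nearest_param <- function(ct, pts, oversample = 4L) {
  m <- max(64L, as.integer(oversample * nrow(ct$nodes)))
  sgrid <- seq(0, ct$length, length.out = m + 1L)[-(m + 1L)]
  ref <- contour_point(ct, sgrid)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2
    out[i] <- sgrid[which.min(d2)]
  }
  out
}
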