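#' Segmentation configuration
#'
#' Parameters for single-cell segmentation of a fluorescence frame. The
#' image is pre-filtered with a Gaussian approximation of the microscope
#' point spread function, thresholded at the first histogram valley after
#' the background mode, and cleaned by morphological post-processing.
#'
#' @param psf_sigma Gaussian prefilter sigma in pixels (0 disables).
#' @param threshold_override optional fixed intensity threshold; when set,
#'   the histogram analysis is bypassed entirely.
#' @param closure_radius radius (pixels) of the disc used for morphological
#'   closure of small edge gaps.
#' @param max_hole_area intracellular holes up to this area (pixels^2) are
#'   filled.
#' @param histogram_bins number of histogram bins (>= 32).
#' @param spline_smoothing smoothing parameter (`spar` of
#'   [stats::smooth.spline()]) for the histogram smoothing spline.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(psf_sigma = 1.5, threshold_override = NULL,
                                closure_radius = 3, max_hole_area = 100,
                                histogram_bins = 256, spline_smoothing = 0.6) {
  if (psf_sigma < 0) abort("`psf_sigma` must be >= 0")
  if (histogram_bins < 32) abort("`histogram_bins` must be >= 32")
  structure(
    list(psf_sigma = psf_sigma, threshold_override = threshold_override,
         closure_radius = closure_radius, max_hole_area = max_hole_area,
         histogram_bins = as.integer(histogram_bins),
         spline_smoothing = spline_smoothing),
    class = "segmentation_config"
  )
}

#' Automatic intensity threshold from the histogram valley
#'
#' Fits a smoothing spline to the image intensity histogram and returns the
#' intensity of the first local minimum located after the lowest-intensity
#' local maximum, separating the background mode from cellular fluorescence.
#'
#' @param image numeric matrix.
#' @param config a [segmentation_config].
#' @return Intensity threshold (scalar). Errors with advice to set
#'   `threshold_override` when the smoothed histogram is unimodal.
#' @export
auto_threshold <- function(image, config = segmentation_config()) {
  if (!is.null(config$threshold_override)) return(config$threshold_override)
  v <- as.vector(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) {
    abort("smoothed intensity histogram is unimodal; select a threshold manually via `threshold_override`")
  }
  brk <- seq(rng[1], rng[2], length.out = config$histogram_bins + 1L)
  counts <- tabulate(findInterval(v, brk, rightmost.closed = TRUE),
                     nbins = config$histogram_bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  # the spline is fitted to log counts: sharp background peaks otherwise
  # induce ringing through empty valleys, creating spurious extrema
  fit <- smooth.spline(mids, log1p(counts), spar = config$spline_smoothing)
  s <- predict(fit, mids)$y
  d <- diff(s)
  # local maxima / minima of the smoothed histogram (sign changes of slope)
  sign_d <- sign(d)
  turn <- which(sign_d[-1] != sign_d[-length(sign_d)] & sign_d[-length(sign_d)] != 0) + 1L
  maxima <- turn[sign_d[turn - 1L] > 0]
  minima <- turn[sign_d[turn - 1L] < 0]
  if (length(maxima) == 0 || length(minima) == 0) {
    abort("smoothed intensity histogram is unimodal; select a threshold manually via `threshold_override`")
  }
  first_max <- min(maxima)
  after <- minima[minima > first_max]
  if (length(after) == 0 || !any(maxima > min(after))) {
    abort("smoothed intensity histogram is unimodal; select a threshold manually via `threshold_override`")
  }
  # the first valley after the background mode; when the valley is an
  # extended flat stretch (well-separated modes), use its centre
  tail_idx <- min(after):length(s)
  next_max <- tail_idx[which.max(s[tail_idx])]
  span <- min(after):next_max
  vmin <- min(s[span])
  tol <- 0.02 * (max(s) - vmin)
  flat <- span[s[span] <= vmin + tol]
  mean(mids[flat])
}

# Fill background holes (8-connected) of area <= max_area that do not touch
# the image border.
fill_small_holes <- function(mask, max_area) {
  if (max_area <= 0) return(mask)
  inv <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
  inv <- as.matrix(EBImage::imageData(inv))
  if (max(inv) == 0) return(mask)
  border_labs <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
  areas <- tabulate(inv[inv > 0])
  fill <- setdiff(which(areas <= max_area), border_labs)
  if (length(fill)) mask[inv %in% fill] <- TRUE
  mask
}

#' Segment a single frame into a one-component cell mask
#'
#' Pipeline: Gaussian prefilter, intensity threshold ([auto_threshold] or
#' `threshold_override`), filling of intracellular holes up to
#' `max_hole_area`, morphological closure with a disc of
#' `closure_radius`, and retention of the largest connected component
#' (4-connectivity for foreground, 8-connectivity for background holes).
#'
#' @inheritParams auto_threshold
#' @return Logical matrix with exactly one foreground component.
#' @export
segment_frame <- function(image, config = segmentation_config()) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    abort("`image` must be a finite numeric matrix")
  }
  img <- image
  if (config$psf_sigma > 0) {
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = config$psf_sigma)
    ))
  }
  thr <- auto_threshold(img, config)
  mask <- img > thr
  if (!any(mask)) abort("empty foreground after thresholding")
  mask <- fill_small_holes(mask, config$max_hole_area)
  if (config$closure_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(config$closure_radius) + 1L,
                                shape = "disc")
    mask <- as.matrix(EBImage::imageData(
      EBImage::closing(EBImage::Image(mask * 1), brush)
    )) > 0.5
  }
  mask <- largest_component(mask)
  if (!any(mask)) abort("empty foreground after post-processing")
  mask
}

# Keep the largest 4-connected foreground component.
largest_component <- function(mask) {
  lab <- label_components4(mask)
  if (max(lab) <= 1L) return(mask)
  areas <- tabulate(lab[lab > 0])
  lab == which.max(areas)
}

# 4-connected labeling via two-pass union on run-length columns; EBImage's
# bwlabel is 8-connected, so do it directly.
label_components4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      if (!mask[i, j]) next
      up <- if (i > 1L) lab[i - 1L, j] else 0L
      left <- if (j > 1L) lab[i, j - 1L] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        if (ru != rl) parent[ru] <- rl
        lab[i, j] <- rl
      } else {
        lab[i, j] <- max(up, left)
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, unique(roots))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Segment every frame of a movie
#'
#' @param stack numeric array (x, y, frame).
#' @param config a [segmentation_config].
#' @return Logical array of masks with the same dimensions.
#' @export
segment_movie <- function(stack, config = segmentation_config()) {
  out <- array(FALSE, dim(stack))
  for (k in seq_len(dim(stack)[3])) {
    out[, , k] <- tryCatch(segment_frame(stack[, , k], config),
      error = function(e) abort(sprintf("frame %d: %s", k, conditionMessage(e)))
    )
  }
  out
}
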