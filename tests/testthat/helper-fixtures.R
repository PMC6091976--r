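# Shared fixtures and independent oracles for the test suite.

# Binary disk mask of radius r centred in an n x n frame.
disk_mask <- function(n = 96, r = 25, cx = (n + 1) / 2, cy = cx) {
  xg <- matrix(rep(seq_len(n), n), n)
  yg <- t(xg)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}

# Small global-mode blob movie reused across tests.
small_blob <- function(n_frames = 60, seed = 3, noise_sd = 0.02) {
  blob_movie_spec(
    image_size = 96, n_frames = n_frames, dt = 10, pixel_size = 0.3,
    base_radius = 9, noise_sd = noise_sd, seed = seed,
    modes = list(
      list(freq = 0.005, amp = 1.2, phase = 0, window = NULL),
      list(freq = 0.002, amp = 0.8, phase = 1, window = c(0, pi))
    )
  )
}

# Canonical two-block planted map for recovery tests (blocks split along
# the sector axis; SNR = amp / noise_sd = 5).
two_block_spec <- function(seed = 1, n_frames = 180) {
  planted_map_spec(
    n_sectors = 64, n_frames = n_frames, dt = 10,
    blocks = list(
      list(sectors = c(1, 32), frames = c(1, n_frames),
           freq = 0.02, amp = 2, phase = 0),
      list(sectors = c(33, 64), frames = c(1, n_frames),
           freq = 0.005, amp = 2, phase = 0)
    ),
    noise_sd = 0.4, seed = seed
  )
}

# Brute-force two-sample K-S statistic by scanning the pooled support.
ks_D_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Brute-force minimization of the segment-mapping objective over all
# monotone candidate assignments on the same grid/omega the solver used.
dp_oracle <- function(pair, ct, ct1, omega, G) {
  og <- seq(pair$e1, pair$en, length.out = G)
  n <- length(pair$src_param)
  src <- contour_eval(ct, pair$src_param)
  tg <- contour_eval(ct1, og)
  dp <- diff(pair$src_param)
  best <- Inf
  combs <- utils::combn(2:(G - 1), n - 2)
  for (ci in seq_len(ncol(combs))) {
    j <- c(1L, combs[, ci], G)
    suma <- sum((tg[j, 1] - src[, 1])^2 + (tg[j, 2] - src[, 2])^2)
    sumb <- sum((diff(og[j]) / dp)^2)
    best <- min(best, suma + omega * sumb)
  }
  best
}

# Evaluate a cell_contour's spline at arbitrary arclength parameters.
contour_eval <- function(ct, s) {
  s <- s %% ct$length
  cbind(ct$fx(s), ct$fy(s))
}

# Analytic circle "contour" object for mapping tests.
circle_contour <- function(r, c0, n = 40) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(c0 + r * cos(th), c0 + r * sin(th))
  seg <- sqrt(rowSums((pts[c(2:n, 1), ] - pts)^2))
  p <- c(0, cumsum(seg[-n]))
  L <- sum(seg)
  fx <- stats::splinefun(c(p, L), c(pts[, 1], pts[1, 1]), method = "periodic")
  fy <- stats::splinefun(c(p, L), c(pts[, 2], pts[1, 2]), method = "periodic")
  structure(list(nodes = pts, p = p, length = L, fx = fx, fy = fy),
            class = "cell_contour")
}

# Adjusted Rand index between two labelings (independent of the package).
ari <- function(a, b) mclust::adjustedRandIndex(as.vector(a), as.vector(b))

# Single-region labeling helper for coupling tests.
whole_map_labeling <- function(n_sectors, n_frames) {
  structure(list(labels = matrix(1L, n_sectors, n_frames), n_regions = 1L),
            class = "region_labeling")
}
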