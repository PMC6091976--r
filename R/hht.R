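#' Empirical mode decomposition by iterative sifting
#'
#' Decomposes a series into intrinsic mode functions (IMFs) plus a
#' residual: local extrema are bridged by cubic-spline envelopes (end
#' extrema mirrored about the series ends), the envelope mean is
#' subtracted, and sifting repeats until the candidate satisfies the IMF
#' conditions (extrema and zero-crossing counts differ by at most one)
#' and a Cauchy-type stop criterion
#' `SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol`. The number of
#' components is fixed at `n_imf` so decompositions are comparable across
#' cells; when the residual terminates early (constant, monotonic, or a
#' single max/min pair) the remaining components are all-zero and flagged.
#'
#' @param x numeric series (length >= 8; missing values are linearly
#'   interpolated and flagged).
#' @param n_imf number of components to return (default 6).
#' @param sd_tol sift stop threshold (default 0.2).
#' @param max_sift sift cap per component (default 100).
#' @return An `imf_set`: list with `imfs` (length-by-`n_imf` matrix),
#'   `residual`, `n_sift` (per component; `NA` for padded zero
#'   components), `padded` (logical), `interpolated` (logical).
#' @export
emd <- function(x, n_imf = 6L, sd_tol = 0.2, max_sift = 100L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) abort("series too short for EMD (need >= 8 samples)")
  interpolated <- anyNA(x)
  if (interpolated) {
    if (all(is.na(x))) abort("series is all missing")
    x <- approx(seq_len(n), x, xout = seq_len(n), rule = 2)$y
  }
  imfs <- matrix(0, n, n_imf)
  n_sift <- rep(NA_integer_, n_imf)
  resid <- x
  for (i in seq_len(n_imf)) {
    if (residual_done(resid)) break
    sift <- sift_imf(resid, sd_tol, max_sift)
    imfs[, i] <- sift$imf
    n_sift[i] <- sift$n_sift
    resid <- resid - sift$imf
  }
  structure(
    list(x = x, imfs = imfs, residual = resid, n_sift = n_sift,
         padded = is.na(n_sift), interpolated = interpolated),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d samples, %d IMFs (%d active), residual sd %.3g\n",
              length(x$x), ncol(x$imfs), sum(!x$padded), sd(x$residual)))
  invisible(x)
}

#' @export
tidy.imf_set <- function(x, ...) {
  k <- ncol(x$imfs)
  tibble(
    t = rep(seq_along(x$x), k + 1L),
    component = rep(c(paste0("imf", seq_len(k)), "residual"),
                    each = length(x$x)),
    value = c(as.vector(x$imfs), x$residual)
  )
}

# Indices of local maxima/minima; plateaus contribute their midpoint.
local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  # collapse plateaus: sign changes of the nonzero slopes
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  idx_max <- integer(0); idx_min <- integer(0)
  for (c0 in chg) {
    left <- nz[c0]           # last index before the turn
    right <- nz[c0 + 1]      # first index where slope resumes
    mid <- as.integer(floor((left + 1 + right) / 2))
    if (s[c0] > 0) idx_max <- c(idx_max, mid) else idx_min <- c(idx_min, mid)
  }
  list(max = idx_max, min = idx_min)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# IMF condition: extrema count and zero-crossing count differ by <= 1.
is_imf <- function(x) {
  ex <- local_extrema(x)
  ne <- length(ex$max) + length(ex$min)
  abs(ne - count_zero_crossings(x)) <= 1L
}

# Residual termination: constant, monotonic, or single max/min pair.
residual_done <- function(r) {
  ex <- local_extrema(r)
  length(ex$max) < 2L || length(ex$min) < 2L
}

# Cubic-spline envelope through extrema, with the two nearest extrema
# mirrored about each series end to suppress end swings.
envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) == 0) return(rep(0, n))
  if (length(idx) == 1) return(rep(x[idx], n))
  k <- min(2L, length(idx))
  pre_i <- 2 - idx[seq_len(k)]              # mirror about position 1
  post_i <- 2 * n - idx[length(idx) - seq_len(k) + 1L] # mirror about n
  xi <- c(pre_i, idx, post_i)
  yi <- c(x[idx[seq_len(k)]], x[idx], x[idx[length(idx) - seq_len(k) + 1L]])
  ord <- order(xi)
  xi <- xi[ord]; yi <- yi[ord]
  dup <- duplicated(xi)
  splinefun(xi[!dup], yi[!dup], method = "fmm")(seq_len(n))
}

sift_imf <- function(x, sd_tol, max_sift) {
  h <- x
  for (k in seq_len(max_sift)) {
    ex <- local_extrema(h)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    m <- (envelope(h, ex$max) + envelope(h, ex$min)) / 2
    h_new <- h - m
    sd_k <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_k < sd_tol && is_imf(h)) break
  }
  list(imf = h, n_sift = k)
}

#' Hilbert transform of a real series (analytic-signal imaginary part)
#'
#' @param x numeric series.
#' @return Numeric vector `H[x]` such that `x + i H[x]` is the discrete
#'   analytic signal.
#' @export
hilbert_transform <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(fft(X * h, inverse = TRUE) / n)
}

#' Instantaneous frequency and amplitude of one IMF
#'
#' The analytic signal `c + i H[c]` yields the instantaneous phase
#' `arctan(H[c]/c)`; the instantaneous frequency is the unwrapped phase
#' derivative over `2 pi` (central differences in the interior, one-sided
#' at the ends) and the amplitude is `sqrt(c^2 + H[c]^2)`. The first and
#' last samples are marked invalid.
#'
#' @param imf numeric IMF series.
#' @param dt sample interval (seconds for temporal series; 1 sector for
#'   spatial series, giving cycles/sector).
#' @return A `spectrum_series`: list with `frequency`, `amplitude`,
#'   `valid` (logical mask).
#' @export
hilbert_spectrum <- function(imf, dt) {
  n <- length(imf)
  if (all(imf == 0)) {
    return(structure(
      list(frequency = rep(NA_real_, n), amplitude = rep(NA_real_, n),
           valid = rep(FALSE, n), empty = TRUE),
      class = "spectrum_series"
    ))
  }
  h <- hilbert_transform(imf)
  phase <- atan2(h, imf)
  # unwrap
  dp <- diff(phase)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  phase <- cumsum(c(phase[1], dp))
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  dphi[1] <- phase[2] - phase[1]
  dphi[n] <- phase[n] - phase[n - 1]
  freq <- dphi / (2 * pi * dt)
  amp <- sqrt(imf^2 + h^2)
  valid <- rep(TRUE, n)
  valid[c(1, n)] <- FALSE
  structure(
    list(frequency = freq, amplitude = amp, valid = valid, empty = FALSE),
    class = "spectrum_series"
  )
}

#' Decompose an activity map into a spectral field
#'
#' Runs EMD plus Hilbert spectral analysis on every row (temporal axis,
#' frequencies in Hz) and every column (spatial axis along the closed cell
#' boundary, frequencies in cycles/sector) of the map, producing per
#' (sector, time, IMF order) instantaneous frequency and amplitude values.
#' The spatial axis is treated as circular by default: each column is
#' periodically tiled three times, decomposed, and the centre third kept,
#' avoiding artificial boundary extrema.
#'
#' @param map an [activity_map] with >= 8 rows and columns.
#' @param n_imf IMF orders per axis (default 6).
#' @param spatial_boundary `"periodic"` (default) or `"open"`.
#' @param axes `"both"` (default), `"temporal"`, or `"spatial"`: which
#'   axes to decompose (row-only analyses can skip the spatial pass).
#' @param ... passed to [emd()].
#' @return A `spectral_field`: list of arrays `freq_t`, `amp_t`, `freq_s`,
#'   `amp_s` (n_imf-by-sectors-by-frames), the temporal/spatial IMF arrays
#'   `imf_t`, `imf_s`, residual maps, and metadata.
#' @export
decompose_map <- function(map, n_imf = 6L, spatial_boundary = c("periodic", "open"),
                          axes = c("both", "temporal", "spatial"), ...) {
  spatial_boundary <- match.arg(spatial_boundary)
  axes <- match.arg(axes)
  S <- nrow(map); Tn <- ncol(map)
  if (S < 8 || Tn < 8) abort("map must have at least 8 rows and 8 columns")
  dt <- attr(map, "dt")
  dims <- c(n_imf, S, Tn)
  freq_t <- array(NA_real_, dims); amp_t <- array(NA_real_, dims)
  freq_s <- array(NA_real_, dims); amp_s <- array(NA_real_, dims)
  imf_t <- array(0, dims); imf_s <- array(0, dims)
  resid_t <- matrix(NA_real_, S, Tn); resid_s <- matrix(NA_real_, S, Tn)
  valid_t <- array(FALSE, dims); valid_s <- array(FALSE, dims)

  if (axes != "spatial") for (s in seq_len(S)) {
    dec <- emd(unclass(map)[s, ], n_imf = n_imf, ...)
    imf_t[, s, ] <- t(dec$imfs)
    resid_t[s, ] <- dec$residual
    for (i in seq_len(n_imf)) {
      if (dec$padded[i]) next
      sp <- hilbert_spectrum(dec$imfs[, i], dt)
      freq_t[i, s, ] <- sp$frequency
      amp_t[i, s, ] <- sp$amplitude
      valid_t[i, s, ] <- sp$valid
    }
  }

  if (axes != "temporal") for (tt in seq_len(Tn)) {
    col <- unclass(map)[, tt]
    if (spatial_boundary == "periodic") {
      dec <- emd(rep(col, 3L), n_imf = n_imf, ...)
      keep <- S + seq_len(S)
      comp <- dec$imfs[keep, , drop = FALSE]
      resid_s[, tt] <- dec$residual[keep]
      for (i in seq_len(n_imf)) {
        if (dec$padded[i]) next
        sp <- hilbert_spectrum(dec$imfs[, i], 1)
        freq_s[i, , tt] <- sp$frequency[keep]
        amp_s[i, , tt] <- sp$amplitude[keep]
        valid_s[i, , tt] <- sp$valid[keep]
        imf_s[i, , tt] <- comp[, i]
      }
    } else {
      dec <- emd(col, n_imf = n_imf, ...)
      resid_s[, tt] <- dec$residual
      for (i in seq_len(n_imf)) {
        if (dec$padded[i]) next
        sp <- hilbert_spectrum(dec$imfs[, i], 1)
        freq_s[i, , tt] <- sp$frequency
        amp_s[i, , tt] <- sp$amplitude
        valid_s[i, , tt] <- sp$valid
        imf_s[i, , tt] <- dec$imfs[, i]
      }
    }
  }

  structure(
    list(freq_t = freq_t, amp_t = amp_t, freq_s = freq_s, amp_s = amp_s,
         valid_t = valid_t, valid_s = valid_s,
         imf_t = imf_t, imf_s = imf_s, resid_t = resid_t, resid_s = resid_s,
         n_imf = n_imf, dt = dt, map = map,
         spatial_boundary = spatial_boundary),
    class = "spectral_field"
  )
}

#' @export
print.spectral_field <- function(x, ...) {
  cat(sprintf(
    "<spectral_field> %d sectors x %d frames, %d IMF orders per axis (dt = %gs)\n",
    dim(x$freq_t)[2], dim(x$freq_t)[3], x$n_imf, x$dt
  ))
  invisible(x)
}

#' Tidy a spectral field into a long tibble
#'
#' @param x a `spectral_field`.
#' @param ... unused.
#' @return Tibble with columns `axis` (`"temporal"`/`"spatial"`), `imf`,
#'   `sector`, `frame`, `frequency`, `amplitude`, `valid`.
#' @export
tidy.spectral_field <- function(x, ...) {
  grid <- expand.grid(
    imf = seq_len(x$n_imf), sector = seq_len(dim(x$freq_t)[2]),
    frame = seq_len(dim(x$freq_t)[3])
  )
  dplyr::bind_rows(
    tibble(axis = "temporal", grid,
           frequency = as.vector(x$freq_t), amplitude = as.vector(x$amp_t),
           valid = as.vector(x$valid_t)),
    tibble(axis = "spatial", grid,
           frequency = as.vector(x$freq_s), amplitude = as.vector(x$amp_s),
           valid = as.vector(x$valid_s))
  )
}

#' Reconstruct the activity and displacement map of one IMF order
#'
#' Arranges the temporal IMF components of one order back on the
#' (sector, time) grid and integrates each sector's velocity over time into
#' a cumulative edge-displacement series.
#'
#' @param field a `spectral_field` from [decompose_map()].
#' @param imf_index IMF order (1..n_imf).
#' @return List with `velocity` (an [activity_map], um/min) and
#'   `displacement` (an [activity_map], um).
#' @export
reconstruct_imf_map <- function(field, imf_index) {
  stopifnot(inherits(field, "spectral_field"))
  if (imf_index < 1 || imf_index > field$n_imf) abort("invalid `imf_index`")
  v <- field$imf_t[imf_index, , , drop = TRUE]
  vmap <- activity_map(v, dt = field$dt, units = attr(field$map, "units"),
                       times = attr(field$map, "times"))
  disp <- t(apply(v * field$dt / 60, 1, cumsum))
  dmap <- activity_map(disp, dt = field$dt, units = "um",
                       times = attr(field$map, "times"))
  list(velocity = vmap, displacement = dmap)
}
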