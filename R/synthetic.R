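#' Specify a synthetic deforming-blob movie
#'
#' The generator produces a star-convex "blob" cell whose boundary radius
#' oscillates per angular sector at known frequencies and amplitudes:
#' \deqn{\rho(\theta, t) = R_0 + \sum_k a_k w_k(\theta) \sin(2\pi f_k t + \phi_k)}
#' where each angular window \eqn{w_k} is raised-cosine tapered so the
#' analytic normal velocity \eqn{\partial\rho/\partial t} is continuous.
#' Images are foreground/background intensities plus i.i.d. Gaussian noise.
#'
#' @param image_size side length of the square frame in pixels.
#' @param n_frames number of frames.
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @param base_radius resting cell radius, micrometres.
#' @param modes list of modes; each a list with `freq` (Hz), `amp` (um),
#'   `phase` (rad) and optional `window = c(lo, hi)` (radians; `NULL` for a
#'   global mode acting on the whole boundary).
#' @param noise_sd Gaussian image noise standard deviation (intensity units).
#' @param fg_intensity,bg_intensity foreground / background intensity in
#'   `[0, 1]` (16-bit TIFF convention).
#' @param seed integer RNG seed; identical specs give bit-identical movies.
#'
#' @return A `blob_movie_spec` list.
#' @export
blob_movie_spec <- function(image_size = 128, n_frames = 90, dt = 10,
                            pixel_size = 0.3, base_radius = 12,
                            modes = list(), noise_sd = 0.02,
                            fg_intensity = 0.8, bg_intensity = 0.1,
                            seed = 1L) {
  for (nm in c("image_size", "n_frames", "dt", "pixel_size", "base_radius",
               "noise_sd", "fg_intensity", "bg_intensity")) {
    stopifnot_scalar(get(nm), nm)
  }
  total_amp <- sum(vapply(modes, function(m) m$amp, numeric(1)), 0)
  if (base_radius - total_amp <= 0) {
    abort("total mode amplitude must be smaller than `base_radius` (mask must never vanish)")
  }
  for (m in modes) {
    if (m$freq >= 1 / (2 * dt)) {
      abort(sprintf(
        "mode frequency %g Hz violates the Nyquist limit %g Hz for dt = %gs",
        m$freq, 1 / (2 * dt), dt
      ))
    }
  }
  structure(
    list(
      image_size = as.integer(image_size), n_frames = as.integer(n_frames),
      dt = dt, pixel_size = pixel_size, base_radius = base_radius,
      modes = modes, noise_sd = noise_sd, fg_intensity = fg_intensity,
      bg_intensity = bg_intensity, seed = as.integer(seed)
    ),
    class = "blob_movie_spec"
  )
}

# Raised-cosine angular taper for one mode, vectorized over theta.
mode_window <- function(theta, window) {
  if (is.null(window)) return(rep(1, length(theta)))
  lo <- window[1]; hi <- window[2]
  width <- (hi - lo) %% (2 * pi)
  if (width == 0) width <- 2 * pi
  centre <- lo + width / 2
  d <- atan2(sin(theta - centre), cos(theta - centre)) # wrapped to (-pi, pi]
  w <- 0.5 * (1 + cos(2 * pi * d / width))
  w[abs(d) > width / 2] <- 0
  w
}

# Analytic boundary radius (um) at angles theta and time t (s).
blob_radius <- function(spec, theta, t) {
  r <- rep(spec$base_radius, length(theta))
  for (m in spec$modes) {
    r <- r + m$amp * mode_window(theta, m$window) *
      sin(2 * pi * m$freq * t + m$phase)
  }
  r
}

# Analytic radial (normal, within discretization) velocity in um/min.
blob_velocity <- function(spec, theta, t) {
  v <- rep(0, length(theta))
  for (m in spec$modes) {
    v <- v + m$amp * mode_window(theta, m$window) *
      2 * pi * m$freq * cos(2 * pi * m$freq * t + m$phase)
  }
  v * 60
}

#' Generate a synthetic blob movie with analytic ground truth
#'
#' @param spec a [blob_movie_spec].
#' @param n_sectors number of angular sectors for the ground-truth velocity
#'   map (rows).
#' @return A list with `images` (numeric array, x-by-y-by-frame), `masks`
#'   (logical array), `velocity` (ground-truth [activity_map], um/min,
#'   `n_frames - 1` columns at frame-pair midpoint times), and `spec`.
#' @export
gen_blob_movie <- function(spec, n_sectors = 64) {
  stopifnot(inherits(spec, "blob_movie_spec"))
  n <- spec$image_size
  ctr <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), n), n)
  yg <- t(xg)
  r_px <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  theta_px <- atan2(yg - ctr, xg - ctr)

  masks <- array(FALSE, c(n, n, spec$n_frames))
  images <- array(0, c(n, n, spec$n_frames))
  with_seed(spec$seed, {
    for (k in seq_len(spec$n_frames)) {
      t_k <- (k - 1) * spec$dt
      rho_px <- blob_radius(spec, theta_px, t_k) / spec$pixel_size
      m <- r_px <= rho_px
      masks[, , k] <- m
      images[, , k] <- ifelse(m, spec$fg_intensity, spec$bg_intensity) +
        rnorm(n * n, sd = spec$noise_sd)
    }
  })

  # Ground-truth sector velocities at frame-pair midpoints, averaged over
  # a fine angular grid within each sector.
  fine <- 16L
  th <- (seq_len(n_sectors * fine) - 0.5) / (n_sectors * fine) * 2 * pi
  vel <- matrix(NA_real_, n_sectors, spec$n_frames - 1L)
  for (k in seq_len(spec$n_frames - 1L)) {
    t_mid <- (k - 0.5) * spec$dt
    v <- blob_velocity(spec, th, t_mid)
    vel[, k] <- colMeans(matrix(v, nrow = fine))
  }
  vmap <- activity_map(vel,
    dt = spec$dt, units = "um/min",
    times = (seq_len(spec$n_frames - 1L) - 0.5) * spec$dt
  )
  list(images = images, masks = masks, velocity = vmap, spec = spec)
}

#' Specify an activity channel coupled to edge velocity
#'
#' Emulates a biosensor whose near-edge signal follows the local edge
#' velocity with a fixed time lag: inside a band of depth `band_depth` from
#' the edge the activity is `baseline + gain * v(theta, t - lag)`; elsewhere
#' it equals `baseline`.
#'
#' @param blob a [blob_movie_spec].
#' @param lag delay of activity relative to motion, seconds (must be an
#'   integer multiple of `blob$dt` and smaller than the movie duration).
#' @param gain activity units per (um/min).
#' @param band_depth depth of the responsive band from the edge, um.
#' @param baseline resting activity level.
#' @return A `coupled_activity_spec` list.
#' @export
coupled_activity_spec <- function(blob, lag = 50, gain = 1, band_depth = 3,
                                  baseline = 1) {
  stopifnot(inherits(blob, "blob_movie_spec"))
  if (abs(lag / blob$dt - round(lag / blob$dt)) > 1e-9) {
    abort("`lag` must be an integer multiple of the frame interval `dt`")
  }
  if (lag >= blob$n_frames * blob$dt) {
    abort("`lag` must be smaller than the movie duration")
  }
  if (band_depth <= 0) abort("`band_depth` must be positive")
  structure(
    list(blob = blob, lag = lag, gain = gain, band_depth = band_depth,
         baseline = baseline),
    class = "coupled_activity_spec"
  )
}

#' Generate the velocity-coupled activity channel for a blob movie
#'
#' @param spec a [coupled_activity_spec].
#' @param movie optional result of [gen_blob_movie()] for `spec$blob`
#'   (regenerated if omitted).
#' @return Numeric array (x-by-y-by-frame) of activity images.
#' @export
gen_coupled_activity <- function(spec, movie = NULL) {
  stopifnot(inherits(spec, "coupled_activity_spec"))
  blob <- spec$blob
  if (is.null(movie)) movie <- gen_blob_movie(blob)
  n <- blob$image_size
  ctr <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), n), n)
  theta_px <- atan2(t(xg) - ctr, xg - ctr)
  act <- array(spec$baseline, c(n, n, blob$n_frames))
  for (k in seq_len(blob$n_frames)) {
    m <- movie$masks[, , k]
    d_px <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
    band <- m & (d_px - 0.5) * blob$pixel_size <= spec$band_depth
    t_src <- (k - 1) * blob$dt - spec$lag
    v <- blob_velocity(blob, theta_px[band], t_src)
    frame <- act[, , k]
    frame[band] <- spec$baseline + spec$gain * v
    act[, , k] <- frame
  }
  act
}

#' Specify a planted sectors-by-time velocity map
#'
#' Builds an [activity_map] from rectangular blocks that tile the grid, each
#' carrying a sinusoid of known frequency/amplitude/phase plus Gaussian
#' noise. Used as ground truth for spectral decomposition and region-merging
#' recovery tests.
#'
#' @param n_sectors,n_frames grid extents.
#' @param dt frame interval, seconds.
#' @param blocks list of blocks; each a list with `sectors = c(lo, hi)`,
#'   `frames = c(lo, hi)` (inclusive index ranges), `freq` (Hz), `amp`
#'   (um/min), `phase` (rad). Blocks must tile the grid without overlap.
#' @param noise_sd Gaussian noise sd, um/min.
#' @param seed integer RNG seed.
#' @return A `planted_map_spec` list.
#' @export
planted_map_spec <- function(n_sectors = 64, n_frames = 120, dt = 10,
                             blocks, noise_sd = 0, seed = 1L) {
  cover <- matrix(0L, n_sectors, n_frames)
  for (b in blocks) {
    if (b$freq >= 1 / (2 * dt)) abort("block frequency violates the Nyquist limit")
    cover[b$sectors[1]:b$sectors[2], b$frames[1]:b$frames[2]] <-
      cover[b$sectors[1]:b$sectors[2], b$frames[1]:b$frames[2]] + 1L
  }
  if (any(cover > 1L)) abort("blocks overlap")
  if (any(cover < 1L)) abort("blocks do not tile the full grid")
  structure(
    list(n_sectors = as.integer(n_sectors), n_frames = as.integer(n_frames),
         dt = dt, blocks = blocks, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "planted_map_spec"
  )
}

#' Generate a planted activity map
#'
#' @param spec a [planted_map_spec].
#' @return An [activity_map] with a `blocks` attribute holding the
#'   ground-truth block labeling (integer matrix).
#' @export
gen_planted_map <- function(spec) {
  stopifnot(inherits(spec, "planted_map_spec"))
  t_s <- (seq_len(spec$n_frames) - 1) * spec$dt
  v <- matrix(0, spec$n_sectors, spec$n_frames)
  lab <- matrix(0L, spec$n_sectors, spec$n_frames)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    rows <- b$sectors[1]:b$sectors[2]
    cols <- b$frames[1]:b$frames[2]
    wave <- b$amp * sin(2 * pi * b$freq * t_s[cols] + b$phase)
    v[rows, cols] <- matrix(wave, length(rows), length(cols), byrow = TRUE)
    lab[rows, cols] <- bi
  }
  if (spec$noise_sd > 0) {
    v <- v + with_seed(spec$seed,
      matrix(rnorm(length(v), sd = spec$noise_sd), nrow(v)))
  }
  out <- activity_map(v, dt = spec$dt, units = "um/min")
  attr(out, "blocks") <- lab
  out
}

#' Write a synthetic movie to disk (TIFF stacks + ground-truth sidecar)
#'
#' Images and masks are written as multi-page TIFFs (16-bit and 8-bit); the
#' ground-truth velocity map goes to CSV with a JSON sidecar echoing the
#' spec.
#'
#' @param movie result of [gen_blob_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_blob_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_stack(movie$images, file.path(dir, "movie.tif"), bits = 16L)
  write_image_stack(movie$masks * 1, file.path(dir, "masks.tif"), bits = 8L)
  write_activity_map(movie$velocity, file.path(dir, "velocity_truth.csv"))
  spec <- movie$spec
  spec$modes <- lapply(spec$modes, function(m) {
    m$window <- m$window %||% "global"; m
  })
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
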