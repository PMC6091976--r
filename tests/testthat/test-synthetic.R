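test_that("spec validation rejects impossible blob movies", {
  expect_error(
    blob_movie_spec(base_radius = 2,
                    modes = list(list(freq = 0.01, amp = 3, phase = 0, window = NULL))),
    "amplitude"
  )
  expect_error(
    blob_movie_spec(dt = 10,
                    modes = list(list(freq = 0.06, amp = 1, phase = 0, window = NULL))),
    "Nyquist"
  )
})

test_that("static blob movie has zero ground-truth velocity and same seed reproduces bits", {
  spec <- blob_movie_spec(image_size = 64, n_frames = 6, base_radius = 6,
                          modes = list(), seed = 4)
  mv <- gen_blob_movie(spec, n_sectors = 16)
  expect_true(all(mv$velocity == 0))
  expect_true(all(mv$masks[, , 1] == mv$masks[, , 6]))
  mv2 <- gen_blob_movie(spec, n_sectors = 16)
  expect_identical(mv$images, mv2$images)
})

test_that("global-mode velocity matches the analytic derivative", {
  spec <- blob_movie_spec(
    image_size = 96, n_frames = 30, dt = 10, base_radius = 10,
    modes = list(list(freq = 0.01, amp = 2, phase = 0, window = NULL)),
    seed = 1
  )
  mv <- gen_blob_movie(spec, n_sectors = 8)
  t_mid <- attr(mv$velocity, "times")
  expected <- 2 * 2 * pi * 0.01 * cos(2 * pi * 0.01 * t_mid) * 60
  for (s in 1:8) {
    expect_equal(unclass(mv$velocity)[s, ], expected, tolerance = 1e-8)
  }
})

test_that("two angular windows carry their planted frequencies (FFT oracle)", {
  spec <- blob_movie_spec(
    image_size = 96, n_frames = 100, dt = 10, base_radius = 10,
    modes = list(
      list(freq = 0.02, amp = 1, phase = 0, window = c(-pi / 2, pi / 2)),
      list(freq = 0.005, amp = 1, phase = 0, window = c(pi / 2, 3 * pi / 2))
    ),
    seed = 1
  )
  mv <- gen_blob_movie(spec, n_sectors = 16)
  v <- unclass(mv$velocity)
  dom_freq <- function(x) {
    sp <- Mod(fft(x - mean(x)))[2:(length(x) %/% 2)]
    which.max(sp) / (length(x) * 10)
  }
  bin <- 1 / (ncol(v) * 10)
  # sector centred in each window (theta ~ 0 -> sector 1; theta ~ pi -> 9)
  expect_lt(abs(dom_freq(v[1, ]) - 0.02), bin + 1e-12)
  expect_lt(abs(dom_freq(v[9, ]) - 0.005), bin + 1e-12)
})

test_that("mask area change matches the line integral of normal velocity", {
  spec <- blob_movie_spec(
    image_size = 96, n_frames = 6, dt = 10, base_radius = 9, pixel_size = 0.3,
    modes = list(list(freq = 0.005, amp = 1.5, phase = 0.3, window = NULL)),
    seed = 2
  )
  mv <- gen_blob_movie(spec, n_sectors = 32)
  areas <- apply(mv$masks, 3, sum) * spec$pixel_size^2
  # cumulative area change vs the integrated line flux of normal velocity
  th <- (seq_len(256) - 0.5) / 256 * 2 * pi
  pred <- vapply(seq_len(spec$n_frames - 1L), function(k) {
    t_mid <- (k - 0.5) * spec$dt
    r <- morphospec:::blob_radius(spec, th, t_mid)
    v <- morphospec:::blob_velocity(spec, th, t_mid) / 60 # um/s
    sum(v * r) * (2 * pi / 256) * spec$dt
  }, numeric(1))
  got <- areas[spec$n_frames] - areas[1]
  expect_lt(abs(got - sum(pred)) / abs(sum(pred)), 0.05)
})

test_that("coupled activity respects gain, lag, and band structure", {
  spec <- small_blob(n_frames = 30)
  mv <- gen_blob_movie(spec, n_sectors = 16)
  # gain 0 -> constant baseline everywhere
  a0 <- gen_coupled_activity(coupled_activity_spec(spec, lag = 0, gain = 0,
                                                   baseline = 2), mv)
  expect_true(all(a0 == 2))
  # lag must be a frame multiple and shorter than the movie
  expect_error(coupled_activity_spec(spec, lag = 15), "multiple")
  expect_error(coupled_activity_spec(spec, lag = 10 * 30), "duration")
  # lag 0, gain 1: in-band activity equals baseline + local velocity
  a1 <- gen_coupled_activity(coupled_activity_spec(spec, lag = 0, gain = 1,
                                                   band_depth = 3, baseline = 1), mv)
  k <- 10
  n <- spec$image_size; ctr <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), n), n)
  theta <- atan2(t(xg) - ctr, xg - ctr)
  m <- mv$masks[, , k]
  d <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
  band <- m & (d - 0.5) * spec$pixel_size <= 3
  vtrue <- morphospec:::blob_velocity(spec, theta[band], (k - 1) * spec$dt)
  expect_equal(a1[, , k][band], 1 + vtrue, tolerance = 1e-10)
  expect_true(all(a1[, , k][!band] == 1))
})

test_that("planted maps validate tiling and reproduce their blocks", {
  expect_error(planted_map_spec(
    n_sectors = 8, n_frames = 10, dt = 10,
    blocks = list(
      list(sectors = c(1, 5), frames = c(1, 10), freq = 0.01, amp = 1, phase = 0),
      list(sectors = c(5, 8), frames = c(1, 10), freq = 0.01, amp = 1, phase = 0)
    )
  ), "overlap")
  expect_error(planted_map_spec(
    n_sectors = 8, n_frames = 10, dt = 10,
    blocks = list(
      list(sectors = c(1, 4), frames = c(1, 10), freq = 0.01, amp = 1, phase = 0)
    )
  ), "tile")

  # noiseless single block: every row is the same sinusoid
  pm <- gen_planted_map(planted_map_spec(
    n_sectors = 8, n_frames = 40, dt = 10,
    blocks = list(list(sectors = c(1, 8), frames = c(1, 40),
                       freq = 0.01, amp = 2, phase = 0.5))
  ))
  t_s <- (0:39) * 10
  for (s in 1:8) {
    expect_equal(unclass(pm)[s, ], 2 * sin(2 * pi * 0.01 * t_s + 0.5),
                 tolerance = 1e-12)
  }

  # noise-only map: moments match the noise model
  pm2 <- gen_planted_map(planted_map_spec(
    n_sectors = 64, n_frames = 120, dt = 10,
    blocks = list(list(sectors = c(1, 64), frames = c(1, 120),
                       freq = 0.01, amp = 0, phase = 0)),
    noise_sd = 0.5, seed = 8
  ))
  expect_lt(abs(mean(pm2)), 0.02)
  expect_lt(abs(sd(pm2) - 0.5) / 0.5, 0.1)

  # row-wise dominant frequencies split exactly at the block boundary
  pm3 <- gen_planted_map(two_block_spec(seed = 3, n_frames = 120))
  v <- unclass(pm3)
  dom <- apply(v, 1, function(x) {
    sp <- Mod(fft(x - mean(x)))[2:(length(x) %/% 2)]
    which.max(sp) / (length(x) * 10)
  })
  bin <- 1 / (120 * 10)
  expect_true(all(abs(dom[1:32] - 0.02) <= bin + 1e-12))
  expect_true(all(abs(dom[33:64] - 0.005) <= bin + 1e-12))
})

test_that("blob movies round-trip through TIFF and CSV artifacts", {
  dir <- tempfile("movie")
  spec <- blob_movie_spec(image_size = 48, n_frames = 3, base_radius = 4,
                          modes = list(), seed = 5)
  mv <- gen_blob_movie(spec, n_sectors = 8)
  write_blob_movie(mv, dir)
  imgs <- read_image_stack(file.path(dir, "movie.tif"))
  expect_equal(dim(imgs), dim(mv$images))
  expect_lt(max(abs(imgs - pmin(pmax(mv$images, 0), 1))), 1 / 65535)
  vt <- read_activity_map(file.path(dir, "velocity_truth.csv"))
  expect_equal(unclass(vt), unclass(mv$velocity), ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "spec.json")))
})
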