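test_that("EMD is complete and returns valid IMFs on random series", {
  set.seed(11)
  for (rep in 1:10) {
    x <- cumsum(rnorm(180))
    d <- emd(x)
    expect_lt(max(abs(rowSums(d$imfs) + d$residual - x)) / max(abs(x)), 1e-9)
    for (i in which(!d$padded)) {
      expect_true(morphospec:::is_imf(d$imfs[, i]))
    }
  }
})

test_that("degenerate series yield zero IMFs with the series as residual", {
  d <- emd(rep(3, 50))
  expect_true(all(d$imfs == 0))
  expect_equal(d$residual, rep(3, 50))
  expect_true(all(d$padded))
  d2 <- emd(seq_len(50) * 0.1)
  expect_true(all(d2$imfs == 0))
  expect_error(emd(1:5), "short")
})

test_that("two well-separated tones are assigned to successive IMFs", {
  t <- (0:179) * 10
  x <- sin(2 * pi * 0.02 * t) + sin(2 * pi * 0.004 * t)
  d <- emd(x)
  expect_gt(cor(d$imfs[, 1], sin(2 * pi * 0.02 * t)), 0.95)
  expect_gt(cor(d$imfs[, 2], sin(2 * pi * 0.004 * t)), 0.95)
})

test_that("EMD agrees with an independent reference implementation", {
  oracle <- system.file("oracles", "emd_oracle.py", package = "morphospec")
  skip_if(oracle == "", "oracle script not installed")
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  set.seed(9)
  good <- 0L; total <- 0L
  for (rep in 1:20) {
    t <- (0:179) * 10
    x <- runif(1, 1, 3) * sin(2 * pi * runif(1, 0.015, 0.03) * t + runif(1, 0, 6)) +
      runif(1, 1, 3) * sin(2 * pi * runif(1, 0.002, 0.006) * t + runif(1, 0, 6)) +
      rnorm(180, sd = 0.2)
    fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
    write.table(x, fin, row.names = FALSE, col.names = FALSE)
    status <- system2(py, c(oracle, fin, fout), stdout = FALSE, stderr = FALSE)
    skip_if(status != 0, "reference EMD unavailable")
    ref <- as.matrix(read.csv(fout, header = FALSE))
    mine <- emd(x)
    for (i in 1:2) {
      if (sd(ref[, i]) > 0 && sd(mine$imfs[, i]) > 0) {
        total <- total + 1L
        if (cor(mine$imfs[, i], ref[, i]) > 0.9) good <- good + 1L
      }
    }
  }
  # EMD is convention-sensitive; demand agreement for nearly all components
  expect_gte(good / total, 0.9)
})

test_that("Hilbert spectrum recovers tone frequency, amplitude, and scaling", {
  t <- (0:179) * 10
  c1 <- sin(2 * pi * 0.02 * t)
  sp <- hilbert_spectrum(c1, 10)
  interior <- 19:162 # central 80%
  expect_lt(max(abs(sp$frequency[interior] - 0.02)) / 0.02, 0.02)
  expect_lt(max(abs(sp$amplitude[interior] - 1)), 0.02)
  expect_false(sp$valid[1])
  expect_false(sp$valid[180])

  sp3 <- hilbert_spectrum(3.5 * c1, 10)
  expect_equal(sp3$frequency[interior], sp$frequency[interior], tolerance = 1e-9)
  expect_equal(sp3$amplitude[interior], 3.5 * sp$amplitude[interior],
               tolerance = 1e-9)

  spz <- hilbert_spectrum(rep(0, 50), 10)
  expect_true(spz$empty)
})

test_that("a linear chirp's instantaneous frequency is tracked", {
  Tend <- 1800
  tt <- seq(0, Tend - 10, 10)
  f0 <- 0.005; f1 <- 0.02
  ph <- 2 * pi * (f0 * tt + (f1 - f0) / (2 * Tend) * tt^2)
  finst <- f0 + (f1 - f0) * tt / Tend
  sp <- hilbert_spectrum(sin(ph), 10)
  interior <- 10:170
  rmse <- sqrt(mean((sp$frequency[interior] - finst[interior])^2))
  expect_lt(rmse / mean(finst), 0.1)
})

test_that("map decomposition populates all channels and is row/column local", {
  pm <- gen_planted_map(planted_map_spec(
    n_sectors = 16, n_frames = 60, dt = 10,
    blocks = list(list(sectors = c(1, 16), frames = c(1, 60),
                       freq = 0.01, amp = 2, phase = 0)),
    noise_sd = 0.2, seed = 2
  ))
  fld <- decompose_map(pm, n_imf = 4)
  expect_equal(dim(fld$freq_t), c(4, 16, 60))
  expect_true(any(is.finite(fld$freq_t)))
  expect_true(any(is.finite(fld$freq_s)))

  # single global tone: pooled IMF1 temporal frequency concentrates at 0.01
  sam <- spectral_distributions(fld)
  med <- median(sam$value[sam$imf == 1])
  expect_lt(abs(med - 0.01) / 0.01, 0.2)

  # temporally constant map: temporal IMFs all zero, spatial unaffected
  cst <- activity_map(matrix(rep(sin(seq_len(16)), 60), 16, 60), dt = 10)
  fld2 <- decompose_map(cst, n_imf = 3)
  expect_true(all(fld2$imf_t == 0))
  expect_true(any(fld2$imf_s != 0))

  # row order independence: decomposing a row-subset map leaves rows intact
  pm_sub <- activity_map(unclass(pm)[16:1, ], dt = 10)
  fld3 <- decompose_map(pm_sub, n_imf = 4)
  expect_equal(fld3$freq_t[, 16, ], fld$freq_t[, 1, ], tolerance = 1e-12)
})

test_that("IMF map reconstruction is complete and integrates displacement", {
  pm <- gen_planted_map(two_block_spec(seed = 4, n_frames = 120))
  fld <- decompose_map(pm)
  total <- Reduce(`+`, lapply(seq_len(6), function(i) {
    unclass(reconstruct_imf_map(fld, i)$velocity)
  })) + fld$resid_t
  expect_lt(max(abs(total - unclass(pm))), 1e-9)

  rec <- reconstruct_imf_map(fld, 1)
  disp <- unclass(rec$displacement)
  # zero-mean oscillatory IMF: displacement returns near its start
  amp <- 2; period <- 1 / 0.02
  expect_lt(median(abs(disp[1:32, ncol(disp)])), amp * period / 4)

  # the fast block's energy is concentrated in the IMF1 map
  e1_fast <- mean(unclass(rec$velocity)[1:32, ]^2)
  e1_slow <- mean(unclass(rec$velocity)[33:64, ]^2)
  expect_gt(e1_fast / e1_slow, 3)
})

test_that("higher IMF orders carry lower median frequencies on broadband input", {
  set.seed(6)
  x <- as.numeric(stats::filter(rnorm(240), rep(1, 3), sides = 2))
  x[is.na(x)] <- 0
  d <- emd(x)
  med <- vapply(1:4, function(i) {
    sp <- hilbert_spectrum(d$imfs[, i], 1)
    median(sp$frequency[sp$valid & sp$frequency > 0], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
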