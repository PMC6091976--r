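test_that("K-S comparison matches the brute-force CDF sweep exactly", {
  expect_equal(ks_compare(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  expect_equal(ks_compare(1:5, 1:5)$statistic, 0)
  expect_equal(ks_compare(1:3, 7:9)$statistic, 1)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")

  # exhaustive over all multiset pairs of sizes <= 2 from {1..6}
  multisets <- unlist(lapply(1:2, function(n) {
    utils::combn(seq_len(6 + n - 1), n, simplify = FALSE)
  }), recursive = FALSE)
  multisets <- lapply(multisets, function(idx) idx - seq_along(idx) + 1L)
  for (a in multisets) {
    for (b in multisets) {
      expect_equal(ks_compare(a, b)$statistic, ks_D_oracle(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("K-S agrees with the oracle on random larger samples", {
  set.seed(12)
  for (rep in 1:500) {
    a <- sample(1:6, sample(4:8, 1), replace = TRUE)
    b <- sample(1:6, sample(4:8, 1), replace = TRUE)
    expect_equal(ks_compare(a, b)$statistic, ks_D_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("pooled spectral samples respect partitions and sector relabeling", {
  pm <- gen_planted_map(two_block_spec(seed = 5, n_frames = 120))
  fld <- decompose_map(pm)
  all_s <- spectral_distributions(fld)
  left <- matrix(FALSE, 64, 120); left[, 1:60] <- TRUE
  s1 <- spectral_distributions(fld, region = left)
  s2 <- spectral_distributions(fld, region = !left)
  for (i in 1:3) {
    expect_equal(sort(c(s1$value[s1$imf == i], s2$value[s2$imf == i])),
                 sort(all_s$value[all_s$imf == i]))
  }
  expect_error(spectral_distributions(fld, region = matrix(FALSE, 64, 120)),
               "no grid cells")

  # permutation of sectors leaves pooled distributions unchanged
  perm <- sample(64)
  fld_p <- decompose_map(activity_map(unclass(pm)[perm, ], dt = 10))
  sp <- spectral_distributions(fld_p)
  for (i in 1:2) {
    expect_equal(sort(sp$value[sp$imf == i]), sort(all_s$value[all_s$imf == i]),
                 tolerance = 1e-10)
  }
})

test_that("planted halves with different tones are separated by K-S, same tone is not", {
  pm <- gen_planted_map(two_block_spec(seed = 6, n_frames = 120))
  fld <- decompose_map(pm)
  top <- matrix(FALSE, 64, 120); top[1:32, ] <- TRUE
  a <- spectral_distributions(fld, region = top)
  b <- spectral_distributions(fld, region = !top)
  D_diff <- ks_compare(a$value[a$imf == 1], b$value[b$imf == 1])$statistic
  expect_gt(D_diff, 0.5)

  # same frequency, different phase: indistinguishable
  pm2 <- gen_planted_map(planted_map_spec(
    n_sectors = 64, n_frames = 120, dt = 10,
    blocks = list(
      list(sectors = c(1, 32), frames = c(1, 120), freq = 0.01, amp = 2, phase = 0),
      list(sectors = c(33, 64), frames = c(1, 120), freq = 0.01, amp = 2, phase = 2)
    ),
    noise_sd = 0.4, seed = 6
  ))
  fld2 <- decompose_map(pm2)
  a2 <- spectral_distributions(fld2, region = top)
  b2 <- spectral_distributions(fld2, region = !top)
  expect_lt(ks_compare(a2$value[a2$imf == 1], b2$value[b2$imf == 1])$statistic,
            0.1)
})

test_that("central frequency curves find the planted tone and decrease by order", {
  pm <- gen_planted_map(planted_map_spec(
    n_sectors = 16, n_frames = 120, dt = 10,
    blocks = list(list(sectors = c(1, 16), frames = c(1, 120),
                       freq = 0.01, amp = 2, phase = 0)),
    noise_sd = 0.1, seed = 3
  ))
  cfc <- central_frequency_curve(decompose_map(pm))
  expect_lt(abs(cfc$central_frequency[1] - 0.01) / 0.01, 0.1)
  active <- which(cfc$n_sectors > 0 & cfc$central_frequency > 0)
  expect_true(all(diff(cfc$central_frequency[active[1:3]]) < 0))

  # a single-sector map cannot yield a standard error
  one <- activity_map(matrix(sin((0:119) / 3), 1, 120), dt = 10)
  # decompose_map requires >= 8 rows; compute per-sector medians directly
  expect_error(decompose_map(one), "8 rows")
})

test_that("population heatmaps are symmetric with zero diagonal and expose orthogonality", {
  flds <- lapply(1:4, function(i) {
    scale <- c(1, 2, 3, 4)[i]
    decompose_map(gen_planted_map(planted_map_spec(
      n_sectors = 16, n_frames = 120, dt = 10,
      blocks = list(
        list(sectors = c(1, 8), frames = c(1, 120), freq = 0.02,
             amp = 2 * scale, phase = 0),
        list(sectors = c(9, 16), frames = c(1, 120), freq = 0.005,
             amp = 2 * scale, phase = 1)
      ),
      noise_sd = 0.1 * scale, seed = i
    )))
  })
  hf <- population_heatmap(flds, imf = 1, quantity = "frequency")
  ha <- population_heatmap(flds, imf = 1, quantity = "amplitude")
  expect_true(all(diag(hf$D) == 0))
  expect_equal(hf$D, t(hf$D))
  expect_lt(hf$mean_D, ha$mean_D)

  ordered <- population_heatmap(flds, imf = 1, quantity = "amplitude",
                                order = "velocity")
  expect_equal(sort(ordered$order), 1:4)
})

test_that("map perturbation is unbiased with sd linear in rate", {
  pm <- gen_planted_map(planted_map_spec(
    n_sectors = 16, n_frames = 60, dt = 10,
    blocks = list(list(sectors = c(1, 16), frames = c(1, 60),
                       freq = 0.01, amp = 2, phase = 0)),
    noise_sd = 0.1, seed = 3
  ))
  expect_error(perturb_map(pm, 0), "rate")
  eps <- replicate(200, {
    mean(unclass(perturb_map(pm, 0.5, seed = sample.int(1e6, 1))) - unclass(pm))
  })
  expect_lt(abs(mean(eps)), 0.005)

  rates <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  sds <- vapply(rates, function(r) {
    sd(unclass(perturb_map(pm, r, seed = 99)) - unclass(pm))
  }, numeric(1))
  expect_gt(cor(rates, sds), 0.99)
  # seed-reproducible
  expect_identical(unclass(perturb_map(pm, 0.3, seed = 5)),
                   unclass(perturb_map(pm, 0.3, seed = 5)))
})
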