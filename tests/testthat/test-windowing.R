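test_that("discrete windows partition each band exactly", {
  m <- disk_mask(96, 25)
  ws <- discrete_windows(m, b_edges = c(0, 3, 6), n_slices = 8,
                         pixel_size = 0.3)
  px <- unlist(ws$windows$pixels)
  expect_equal(anyDuplicated(px), 0L)
  # union of band-1 windows == all interior pixels with 0 < d <= 3 um
  idx <- which(m)
  ux <- ((idx - 1L) %% 96) + 1L
  uy <- ((idx - 1L) %/% 96) + 1L
  bp <- ws$chain$pixels
  nb <- morphospec:::nearest_boundary(ux, uy, bp)
  d_um <- nb$dist * 0.3
  in_band1 <- idx[d_um > 0 & d_um <= 3]
  got <- sort(unlist(ws$windows$pixels[ws$windows$band == 1]))
  expect_identical(got, sort(in_band1))
})

test_that("every pixel's nearest boundary point lies in its own slice range", {
  m <- disk_mask(64, 20)
  ws <- discrete_windows(m, b_edges = c(0, 3), n_slices = 6, pixel_size = 0.3)
  l_chain <- ws$chain$arclength * 0.3
  for (i in seq_len(nrow(ws$windows))) {
    px <- ws$windows$pixels[[i]]
    if (length(px) == 0) next
    ux <- ((px - 1L) %% 64) + 1L
    uy <- ((px - 1L) %/% 64) + 1L
    nb <- morphospec:::nearest_boundary(ux, uy, ws$chain$pixels)
    l <- l_chain[nb$index]
    s_lo <- ws$s_edges[ws$windows$slice[i]]
    s_hi <- ws$s_edges[ws$windows$slice[i] + 1L]
    expect_true(all((l > s_lo & l <= s_hi) | (l == 0 & ws$windows$slice[i] == 1L)))
  }
})

test_that("disk windows are congruent and window areas behave", {
  m <- disk_mask(96, 25)
  dw <- discrete_windows(m, b_edges = c(0, 3), n_slices = 4, pixel_size = 0.3)
  a <- dw$windows$area
  expect_lt(max(abs(a - mean(a))) / mean(a), 0.05)

  sw <- subpixel_windows(m, b_values = c(0, 3), n_slices = 4, pixel_size = 0.3)
  expect_lt(max(abs(sw$windows$area - mean(sw$windows$area))) /
              mean(sw$windows$area), 0.02)
})

test_that("sub-pixel isocontours of a disk are concentric circles", {
  m <- disk_mask(96, 25)
  sw <- subpixel_windows(m, b_values = c(0, 3, 6), n_slices = 6,
                         pixel_size = 0.3)
  ctr <- c(48.5, 48.5)
  for (j in seq_along(sw$isocontours)) {
    iso <- sw$isocontours[[j]]
    r <- sqrt(rowSums((iso - rep(ctr, each = nrow(iso)))^2))
    expected <- 25 - sw$b_edges[j] / 0.3
    expect_lt(max(abs(r - expected)), 0.5 + 0.05)
    expect_lt(sd(r), 0.25)
  }
})

test_that("sub-pixel window areas tile the band area", {
  m <- disk_mask(96, 25)
  sw <- subpixel_windows(m, b_values = c(0, 3), n_slices = 8, pixel_size = 0.3)
  iso0 <- sw$isocontours[[1]]; iso1 <- sw$isocontours[[2]]
  band_area <- (abs(morphospec:::polygon_signed_area(iso0)) -
                  abs(morphospec:::polygon_signed_area(iso1))) * 0.3^2
  expect_lt(abs(sum(sw$windows$area) - band_area) / band_area, 0.01)
})

test_that("masks touching the image border yield excluded windows", {
  m <- disk_mask(60, 25, cx = 28, cy = 5) # touches the y = 1 border
  m[, 1] <- m[, 1] # keep as is; disk extends past border and is clipped
  sw <- subpixel_windows(m, b_values = c(0, 3), n_slices = 8, pixel_size = 0.3)
  expect_gt(sum(sw$windows$excluded), 0)
})

test_that("window propagation methods behave on static and growing disks", {
  m <- disk_mask(96, 25)
  ws <- discrete_windows(m, b_edges = c(0, 3), n_slices = 8, pixel_size = 0.3)
  again <- propagate_windows(ws, m, method = "constant_slice_count")
  expect_identical(
    lapply(ws$windows$pixels, sort),
    lapply(again$windows$pixels, sort)
  )

  grown <- suppressWarnings(
    propagate_windows(ws, disk_mask(96, 30), method = "constant_slice_count"))
  expect_equal(length(grown$s_edges), length(ws$s_edges))
  expect_gt(diff(grown$s_edges)[1], diff(ws$s_edges)[1])
  expect_lt(abs(diff(grown$s_edges)[1] / diff(ws$s_edges)[1] - 30 / 25), 0.06)

  # origin_by_closest_point keeps the slice width, count adapts
  wider <- suppressWarnings(
    propagate_windows(ws, disk_mask(96, 30), method = "origin_by_closest_point"))
  expect_equal(diff(wider$s_edges)[1], diff(ws$s_edges)[1], tolerance = 0.1)
  expect_gt(length(wider$s_edges), length(ws$s_edges))

  # origin follows the nearest boundary point on a translated mask
  shifted <- suppressWarnings(
    propagate_windows(ws, disk_mask(96, 25, cx = 52, cy = 48),
                      method = "origin_by_closest_point"))
  bp <- morphospec:::boundary_chain(disk_mask(96, 25, cx = 52, cy = 48))$pixels
  d2 <- (bp[, 1] - ws$origin[1])^2 + (bp[, 2] - ws$origin[2])^2
  expect_equal(as.numeric(shifted$origin), as.numeric(bp[which.min(d2), ]))
})

test_that("window sampling computes exact statistics and flags empties", {
  m <- disk_mask(64, 20)
  ws <- discrete_windows(m, b_edges = c(0, 3), n_slices = 4, pixel_size = 0.3)
  img <- matrix(7, 64, 64)
  sm <- sample_windows(img, ws, "mean")
  expect_true(all(sm$value == 7))
  expect_true(all(sm$n > 0))

  # a band beyond the cell radius is empty -> NA with count 0
  ws2 <- discrete_windows(m, b_edges = c(5.8, 7), n_slices = 4, pixel_size = 0.3)
  sm2 <- sample_windows(img, ws2, "mean")
  expect_true(any(is.na(sm2$value)))
  expect_true(all(sm2$n[is.na(sm2$value)] == 0))

  # linearity of the mean statistic
  set.seed(4)
  i1 <- matrix(rnorm(64 * 64), 64); i2 <- matrix(rnorm(64 * 64), 64)
  s1 <- sample_windows(i1, ws, "mean")$value
  s2 <- sample_windows(i2, ws, "mean")$value
  s12 <- sample_windows(2 * i1 + 3 * i2, ws, "mean")$value
  expect_equal(s12, 2 * s1 + 3 * s2, tolerance = 1e-12)
})

test_that("sector velocity maps reproduce analytic disk expansion", {
  masks <- array(FALSE, c(96, 96, 4))
  for (k in 1:4) masks[, , k] <- disk_mask(96, 29 + k)
  tr <- track_movie(masks, mapping_config(), dt = 10, pixel_size = 0.3)
  vmap <- sector_velocity_map(tr, 8, dt = 10)
  expect_equal(dim(vmap), c(8, 3))
  expect_lt(max(abs(vmap - 1.8)) / 1.8, 0.05)
  expect_true(all(attr(vmap, "counts") > 0))

  tr0 <- track_movie(masks[, , c(2, 2, 2)], mapping_config(), dt = 10,
                     pixel_size = 0.3)
  v0 <- sector_velocity_map(tr0, 8, dt = 10)
  expect_lt(max(abs(v0)), 0.05)
})
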