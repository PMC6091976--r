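#' Per-regimen activity distributions
#'
#' Groups activity-map samples by motion-regimen label and summarizes each
#' regimen's activity.
#'
#' @param amap an [activity_map] (e.g. a first-band biosensor map).
#' @param labeling a `region_labeling` aligned with the map grid (extra
#'   trailing columns of either grid are ignored so velocity-derived
#'   labelings with `n_frames - 1` columns align with activity maps).
#' @return Tibble with `regimen`, `n`, `mean`, `median`, `q25`, `q75`
#'   (`NA` summaries for regimens without valid samples).
#' @export
regimen_activity <- function(amap, labeling) {
  lab <- labeling$labels
  Tn <- min(ncol(amap), ncol(lab))
  S <- nrow(amap)
  if (nrow(lab) != S) abort("labeling and activity map have different sector counts")
  a <- unclass(amap)[, seq_len(Tn), drop = FALSE]
  l <- lab[, seq_len(Tn), drop = FALSE]
  out <- lapply(sort(unique(as.vector(l))), function(r) {
    v <- a[l == r]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      tibble(regimen = r, n = 0L, mean = NA_real_, median = NA_real_,
             q25 = NA_real_, q75 = NA_real_)
    } else {
      tibble(regimen = r, n = length(v), mean = mean(v), median = median(v),
             q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
    }
  })
  dplyr::bind_rows(out)
}

#' Lagged cross-correlation between an edge-velocity and an activity series
#'
#' Pearson correlation of the mean-subtracted series at integer-frame
#' lags. The lag axis follows the motion-centric convention: the value at
#' lag `l` is `cor(v(t), a(t + l))`, so a peak at a positive lag means the
#' activity follows (is delayed relative to) the motion.
#'
#' @param velocity,activity equal-length numeric series (pairs with
#'   missing values are dropped lag-wise).
#' @param max_lag maximum lag in seconds.
#' @param dt frame interval, seconds.
#' @param min_pairs minimum valid pairs per lag (default 20).
#' @return An `xcorr_curve` tibble with `lag` (seconds), `r`, `n`, and a
#'   `bound` column (heuristic 95% white-noise bound `1.96/sqrt(n)`).
#' @export
xcorr <- function(velocity, activity, max_lag, dt, min_pairs = 20L) {
  n <- length(velocity)
  if (length(activity) != n) abort("series must have equal length")
  valid <- sum(complete.cases(cbind(velocity, activity)))
  if (valid < min_pairs) abort("fewer than `min_pairs` valid paired samples")
  if (sd(velocity, na.rm = TRUE) < 1e-12 || sd(activity, na.rm = TRUE) < 1e-12) {
    abort("near-constant series: correlation undefined")
  }
  L <- floor(max_lag / dt)
  lags <- (-L):L
  r <- rep(NA_real_, length(lags))
  np <- integer(length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l >= 0) {
      v <- velocity[seq_len(n - l)]
      a <- activity[seq_len(n - l) + l]
    } else {
      v <- velocity[seq_len(n + l) - l]
      a <- activity[seq_len(n + l)]
    }
    ok <- complete.cases(cbind(v, a))
    np[i] <- sum(ok)
    if (np[i] >= min_pairs && sd(v[ok]) > 1e-12 && sd(a[ok]) > 1e-12) {
      r[i] <- cor(v[ok], a[ok])
    }
  }
  out <- tibble(lag = lags * dt, r = r, n = np, bound = 1.96 / sqrt(pmax(np, 1)))
  class(out) <- c("xcorr_curve", class(out))
  attr(out, "dt") <- dt
  out
}

#' @export
autoplot.xcorr_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$lag, y = .data$r)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_ribbon(aes(ymin = -.data$bound, ymax = .data$bound), alpha = 0.15) +
    geom_line() +
    labs(x = "lag (s)", y = "correlation") +
    theme_bw()
}

# Extremum lag and FWHM of the dominant significant lobe of a curve; the
# FWHM is measured by linear interpolation between lag samples. NA when no
# lag exceeds the significance bound.
lobe_summary <- function(lag, r, bound) {
  ok <- is.finite(r)
  if (!any(ok & abs(r) > bound)) {
    return(list(peak_lag = NA_real_, peak_r = NA_real_, fwhm = NA_real_))
  }
  i0 <- which.max(abs(r) * ok)
  pk <- r[i0]
  half <- abs(pk) / 2
  s <- sign(pk)
  y <- s * r
  # walk left/right to the half-maximum crossings
  left <- NA_real_; right <- NA_real_
  for (i in i0:2) {
    if (!is.finite(y[i - 1])) break
    if (y[i - 1] < half) {
      f <- (y[i] - half) / (y[i] - y[i - 1])
      left <- lag[i] - f * (lag[i] - lag[i - 1])
      break
    }
  }
  for (i in i0:(length(y) - 1)) {
    if (!is.finite(y[i + 1])) break
    if (y[i + 1] < half) {
      f <- (y[i] - half) / (y[i] - y[i + 1])
      right <- lag[i] + f * (lag[i + 1] - lag[i])
      break
    }
  }
  list(peak_lag = lag[i0], peak_r = pk,
       fwhm = if (is.finite(left) && is.finite(right)) right - left else NA_real_)
}

#' Regimen-resolved cross-correlation between edge motion and activity
#'
#' For each motion regimen and each activity band, computes per-sector
#' cross-correlation curves restricted to that sector's maximal runs of at
#' least `min_run` frames carrying the regimen label, then averages the
#' per-sector curves and summarizes the dominant significant lobe
#' (extremum lag and FWHM by linear interpolation).
#'
#' Reported lags follow the plotting convention of activity-vs-motion
#' correlation figures: a peak at a negative lag means the activity is
#' delayed relative to the motion (reported lag = minus the motion-centric
#' lag of [xcorr()]).
#'
#' @param vmap velocity [activity_map] (sectors x frames-1).
#' @param amaps named list of activity [activity_map]s, one per band.
#' @param labeling a `region_labeling` on the velocity grid.
#' @param max_lag maximum lag, seconds.
#' @param min_run minimum run length in frames (default 20).
#' @return A `regimen_xcorr` tibble with one row per (regimen, band):
#'   `curve` (list of averaged `xcorr_curve` tibbles on the reported-lag
#'   axis), `n_sectors`, `peak_lag` (s), `peak_r`, `fwhm` (s).
#' @export
regimen_xcorr <- function(vmap, amaps, labeling, max_lag, min_run = 20L) {
  if (is.null(names(amaps))) names(amaps) <- paste0("band", seq_along(amaps))
  dt <- attr(vmap, "dt")
  lab <- labeling$labels
  S <- nrow(vmap)
  rows <- list()
  for (reg in sort(unique(as.vector(lab)))) {
    for (b in names(amaps)) {
      amap <- amaps[[b]]
      Tn <- min(ncol(vmap), ncol(amap), ncol(lab))
      curves <- list()
      for (s in seq_len(S)) {
        runs <- label_runs(lab[s, seq_len(Tn)] == reg, min_run)
        for (rn in runs) {
          v <- unclass(vmap)[s, rn]
          a <- unclass(amap)[s, rn]
          cv <- tryCatch(xcorr(v, a, max_lag, dt, min_pairs = min(20L, length(rn) - 2L)),
                         error = function(e) NULL)
          if (!is.null(cv)) curves[[length(curves) + 1L]] <- cv
        }
      }
      if (length(curves) == 0) next
      lagv <- curves[[1]]$lag
      rmat <- vapply(curves, function(cv) cv$r, numeric(length(lagv)))
      rmean <- rowMeans(rmat, na.rm = TRUE)
      nbar <- rowMeans(vapply(curves, function(cv) as.numeric(cv$n),
                              numeric(length(lagv))))
      # report on the activity-delay axis (negated motion-centric lag)
      ord <- order(-lagv)
      rep_lag <- -lagv[ord]; rep_r <- rmean[ord]
      bound <- 1.96 / sqrt(pmax(nbar[ord] * length(curves), 1))
      lobe <- lobe_summary(rep_lag, rep_r, bound)
      avg <- tibble(lag = rep_lag, r = rep_r, n = nbar[ord] * length(curves),
                    bound = bound)
      class(avg) <- c("xcorr_curve", class(avg))
      rows[[length(rows) + 1L]] <- tibble(
        regimen = reg, band = b, n_sectors = length(curves),
        peak_lag = lobe$peak_lag, peak_r = lobe$peak_r, fwhm = lobe$fwhm,
        curve = list(avg)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("regimen_xcorr", class(out))
  out
}

# Maximal runs of TRUE of length >= min_run, as index vectors.
label_runs <- function(flag, min_run) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  purrr::map2(starts[keep], ends[keep], seq)
}
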