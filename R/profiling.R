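#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b numeric sample vectors (non-empty; `NA` dropped).
#' @return A one-row tibble of class `ks_result` with `statistic` (the K-S
#'   D, the supremum distance between the two empirical CDFs), asymptotic
#'   `p_value`, and sample sizes.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  out <- tibble(
    statistic = unname(kt$statistic), p_value = unname(kt$p.value),
    n_a = length(a), n_b = length(b)
  )
  class(out) <- c("ks_result", class(out))
  out
}

#' Pool instantaneous spectra into per-IMF distribution samples
#'
#' Collects the valid instantaneous frequency or amplitude values of a
#' spectral field (optionally restricted to a sub-region of the
#' sector-time grid) into one pooled sample per IMF order. Negative
#' instantaneous frequencies, which can occur at weak-amplitude samples,
#' are excluded from distribution summaries by default.
#'
#' @param field a `spectral_field`.
#' @param region optional logical matrix (sectors x frames) selecting a
#'   sub-region.
#' @param axis `"temporal"` or `"spatial"`.
#' @param quantity `"frequency"` or `"amplitude"`.
#' @param drop_negative drop negative frequencies (default `TRUE`).
#' @return Long tibble with columns `imf`, `value`.
#' @export
spectral_distributions <- function(field, region = NULL,
                                   axis = c("temporal", "spatial"),
                                   quantity = c("frequency", "amplitude"),
                                   drop_negative = TRUE) {
  axis <- match.arg(axis)
  quantity <- match.arg(quantity)
  arr <- switch(paste(axis, quantity),
    "temporal frequency" = field$freq_t, "temporal amplitude" = field$amp_t,
    "spatial frequency" = field$freq_s, "spatial amplitude" = field$amp_s
  )
  valid <- if (axis == "temporal") field$valid_t else field$valid_s
  S <- dim(arr)[2]; Tn <- dim(arr)[3]
  if (is.null(region)) region <- matrix(TRUE, S, Tn)
  if (!all(dim(region) == c(S, Tn))) abort("`region` must match the sector-time grid")
  if (!any(region)) abort("`region` selects no grid cells")
  sel <- aperm(array(region, c(S, Tn, field$n_imf)), c(3, 1, 2))
  out <- vector("list", field$n_imf)
  for (i in seq_len(field$n_imf)) {
    keep <- sel[i, , ] & valid[i, , ] & is.finite(arr[i, , ])
    v <- arr[i, , ][keep]
    if (quantity == "frequency" && drop_negative) v <- v[v >= 0]
    out[[i]] <- tibble(imf = i, value = v)
  }
  dplyr::bind_rows(out)
}

#' Central-frequency curve across IMF orders
#'
#' Per sector, the central frequency of each IMF order is the median of
#' its valid instantaneous frequencies over time; the summary is the mean
#' of these per-sector central frequencies with the standard error across
#' sectors.
#'
#' @param field a `spectral_field`.
#' @param drop_negative see [spectral_distributions()].
#' @return Tibble with `imf`, `central_frequency` (Hz), `se` (`NA` for a
#'   single sector), `n_sectors`.
#' @export
central_frequency_curve <- function(field, drop_negative = TRUE) {
  S <- dim(field$freq_t)[2]
  out <- vector("list", field$n_imf)
  for (i in seq_len(field$n_imf)) {
    med <- vapply(seq_len(S), function(s) {
      v <- field$freq_t[i, s, ][field$valid_t[i, s, ]]
      v <- v[is.finite(v)]
      if (drop_negative) v <- v[v >= 0]
      if (length(v) == 0) NA_real_ else median(v)
    }, numeric(1))
    med <- med[is.finite(med)]
    out[[i]] <- tibble(
      imf = i,
      central_frequency = mean(med),
      se = if (length(med) > 1) sd(med) / sqrt(length(med)) else NA_real_,
      n_sectors = length(med)
    )
  }
  dplyr::bind_rows(out)
}

#' Pairwise K-S heatmap across a cell population
#'
#' Computes the symmetric matrix of two-sample K-S statistics between the
#' pooled per-cell spectral distributions, optionally ordering cells by
#' their mean absolute velocity (ascending), the ordering used to reveal
#' amplitude-driven structure.
#'
#' @param fields list of `spectral_field`s (>= 2 cells).
#' @param imf IMF order to compare, or `"all"` to pool all orders.
#' @param axis,quantity see [spectral_distributions()].
#' @param order `"given"` or `"velocity"` (ascending mean |v| of each
#'   cell's source map).
#' @return A `ks_heatmap`: list with `D` (matrix), `order` (permutation),
#'   `mean_D`.
#' @export
population_heatmap <- function(fields, imf = 1, axis = "temporal",
                               quantity = "frequency",
                               order = c("given", "velocity")) {
  order <- match.arg(order)
  n <- length(fields)
  if (n < 2) abort("need at least 2 cells")
  samples <- lapply(fields, function(f) {
    d <- spectral_distributions(f, axis = axis, quantity = quantity)
    if (identical(imf, "all")) d$value else d$value[d$imf == imf]
  })
  perm <- seq_len(n)
  if (order == "velocity") {
    mv <- vapply(fields, function(f) mean(abs(f$map), na.rm = TRUE), numeric(1))
    perm <- base::order(mv)
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        ks_compare(samples[[perm[i]]], samples[[perm[j]]])$statistic
    }
  }
  structure(
    list(D = D, order = perm, mean_D = mean(D[upper.tri(D)]),
         imf = imf, axis = axis, quantity = quantity),
    class = "ks_heatmap"
  )
}

#' @export
print.ks_heatmap <- function(x, ...) {
  cat(sprintf("<ks_heatmap> %d cells, %s %s (IMF %s): mean off-diagonal D = %.3f\n",
              nrow(x$D), x$axis, x$quantity, as.character(x$imf), x$mean_D))
  invisible(x)
}

#' @export
tidy.ks_heatmap <- function(x, ...) {
  n <- nrow(x$D)
  tibble(
    cell_a = rep(seq_len(n), n), cell_b = rep(seq_len(n), each = n),
    D = as.vector(x$D)
  )
}

#' @export
autoplot.ks_heatmap <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$cell_a, y = .data$cell_b, fill = .data$D)) +
    geom_raster() +
    scale_fill_viridis_c(name = "K-S D") +
    labs(x = "cell", y = "cell") +
    theme_bw()
}

#' Perturb an activity map with a relative mapping-error model
#'
#' Emulates worst-case edge-mapping errors: each entry is jittered by
#' uniform noise on `[-rate * delta, +rate * delta]` where `delta` is a
#' local displacement scale. The default scale is the per-sector RMS
#' inter-frame velocity step, standing in for the length difference of a
#' displacement vector that targets a neighboring virtual marker; an
#' alternative scale function (map -> sectors x frames matrix) can be
#' plugged in.
#'
#' @param map an [activity_map].
#' @param rate relative error rate in (0, 1].
#' @param seed integer RNG seed.
#' @param scale_fun optional function returning the perturbation scale
#'   matrix.
#' @return A perturbed [activity_map].
#' @export
perturb_map <- function(map, rate, seed = 1L, scale_fun = NULL) {
  if (rate <= 0 || rate > 1) abort("`rate` must be in (0, 1]")
  v <- unclass(map)
  delta <- if (is.null(scale_fun)) {
    step_rms <- apply(v, 1, function(r) sqrt(mean(diff(r)^2, na.rm = TRUE)))
    matrix(step_rms, nrow(v), ncol(v))
  } else {
    scale_fun(map)
  }
  eps <- with_seed(seed, matrix(runif(length(v), -1, 1), nrow(v))) * rate * delta
  out <- activity_map(v + eps, dt = attr(map, "dt"), units = attr(map, "units"),
                      times = attr(map, "times"))
  out
}

#' Spectral robustness of a map to mapping errors
#'
#' For each error rate, perturbs the map ([perturb_map()]), re-runs the
#' temporal spectral decomposition, and reports the K-S statistic between
#' the original and perturbed instantaneous-frequency distributions per
#' IMF order, averaged over replicates.
#'
#' @param map an [activity_map].
#' @param rates ascending vector of error rates in (0, 1].
#' @param n_rep replicates per rate.
#' @param seed integer RNG seed (replicate seeds derive from it).
#' @param n_imf IMF orders to report (default 2: the orders most exposed
#'   to high-frequency perturbation).
#' @param ... passed to [decompose_map()].
#' @return Tibble with `rate`, `imf`, `mean_D`, `se`.
#' @export
robustness_curve <- function(map, rates, n_rep = 5L, seed = 1L, n_imf = 2L,
                             ...) {
  if (is.unsorted(rates)) abort("`rates` must be ascending")
  base_field <- decompose_map(map, n_imf = max(n_imf, 2L), axes = "temporal", ...)
  base_samp <- lapply(seq_len(n_imf), function(i) {
    d <- spectral_distributions(base_field)
    d$value[d$imf == i]
  })
  rows <- list()
  for (ri in seq_along(rates)) {
    Ds <- matrix(NA_real_, n_rep, n_imf)
    for (rep_i in seq_len(n_rep)) {
      pm <- perturb_map(map, rates[ri], seed = seed + 1000L * ri + rep_i)
      fld <- decompose_map(pm, n_imf = max(n_imf, 2L), axes = "temporal", ...)
      d <- spectral_distributions(fld)
      for (i in seq_len(n_imf)) {
        Ds[rep_i, i] <- ks_compare(base_samp[[i]], d$value[d$imf == i])$statistic
      }
    }
    for (i in seq_len(n_imf)) {
      rows[[length(rows) + 1L]] <- tibble(
        rate = rates[ri], imf = i, mean_D = mean(Ds[, i]),
        se = sd(Ds[, i]) / sqrt(n_rep)
      )
    }
  }
  dplyr::bind_rows(rows)
}
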