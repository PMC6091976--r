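#' Amplitude-weighted instantaneous-frequency feature field
#'
#' Builds the 12-dimensional feature vector per (sector, time) grid cell:
#' channels 1-6 are the temporal instantaneous frequencies of IMF orders
#' 1-6 weighted by their squared amplitude relative to the maximum squared
#' amplitude of that sector over time; channels 7-12 are the spatial
#' counterparts weighted relative to the maximum over sectors at that time
#' point. The quadratic weights reflect the instantaneous relative energy
#' carried by each IMF order. The normalizer carries no IMF index: by
#' default it is the maximum amplitude of the sector (or time point)
#' across all IMF orders jointly, which suppresses noise-dominated orders;
#' a per-order variant is available.
#' Missing entries (invalid boundary samples, degenerate decompositions)
#' are imputed per channel by the sector (or time-point) median and
#' flagged.
#'
#' @param field a `spectral_field` from [decompose_map()].
#' @param amax_scope `"joint"` (default): amplitude normalizers are maxima
#'   across all IMF orders; `"per_imf"`: per order.
#' @param amax_quantile quantile of the instantaneous amplitude used as
#'   the "maximum" normalizer (default 0.95). The literal maximum
#'   (`amax_quantile = 1`) is an extreme-value statistic whose
#'   sector-to-sector jitter propagates into every weight of the sector; a
#'   high quantile is a robust maximum. Weights are clipped to `[0, 1]`.
#' @return A `feature_field`: list with `phi` (12 x sectors x frames
#'   array), `imputed` (logical array), and grid metadata.
#' @export
feature_field <- function(field, amax_scope = c("joint", "per_imf"),
                          amax_quantile = 0.95) {
  stopifnot(inherits(field, "spectral_field"))
  amax_scope <- match.arg(amax_scope)
  n_imf <- field$n_imf
  if (n_imf != 6L) {
    warn("feature field is defined for 6 IMF orders per axis; using the available orders")
  }
  S <- dim(field$freq_t)[2]; Tn <- dim(field$freq_t)[3]
  phi <- array(NA_real_, c(2L * n_imf, S, Tn))
  robust_max <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NA_real_)
    unname(quantile(v, amax_quantile))
  }
  # joint normalizers: amplitude scale per sector (temporal) / per time
  # point (spatial) over all IMF orders
  Amax_joint_t <- apply(field$amp_t, 2, robust_max)
  Amax_joint_s <- apply(field$amp_s, 3, robust_max)
  for (i in seq_len(n_imf)) {
    # temporal channels: A_max for the sector along the time axis
    A <- field$amp_t[i, , ]
    Amax <- if (amax_scope == "joint") Amax_joint_t else apply(A, 1, robust_max)
    w <- pmin(A^2 / matrix(Amax^2, S, Tn), 1)
    w[!is.finite(w)] <- 0
    phi[i, , ] <- field$freq_t[i, , ] * w
    phi[i, , ][!field$valid_t[i, , ]] <- NA_real_
    # spatial channels: A_max for the time point along the sector axis
    As <- field$amp_s[i, , ]
    Amax_s <- if (amax_scope == "joint") Amax_joint_s else apply(As, 2, robust_max)
    ws <- pmin(As^2 / matrix(Amax_s^2, S, Tn, byrow = TRUE), 1)
    ws[!is.finite(ws)] <- 0
    phi[n_imf + i, , ] <- field$freq_s[i, , ] * ws
    phi[n_imf + i, , ][!field$valid_s[i, , ]] <- NA_real_
  }
  imputed <- is.na(phi)
  # impute per channel: temporal channels by sector median, spatial by
  # time-point median, then the global channel median
  for (ch in seq_len(dim(phi)[1])) {
    m <- phi[ch, , ]
    if (!anyNA(m)) next
    if (ch <= n_imf) {
      med <- apply(m, 1, median, na.rm = TRUE)
      fill <- matrix(med, S, Tn)
    } else {
      med <- apply(m, 2, median, na.rm = TRUE)
      fill <- matrix(med, S, Tn, byrow = TRUE)
    }
    m[is.na(m)] <- fill[is.na(m)]
    m[is.na(m)] <- median(m, na.rm = TRUE)
    m[is.na(m)] <- 0
    phi[ch, , ] <- m
  }
  structure(
    list(phi = phi, imputed = imputed, n_channels = dim(phi)[1],
         n_sectors = S, n_frames = Tn),
    class = "feature_field"
  )
}

#' @export
print.feature_field <- function(x, ...) {
  cat(sprintf("<feature_field> %d channels on %d sectors x %d frames (%.1f%% imputed)\n",
              x$n_channels, x$n_sectors, x$n_frames, 100 * mean(x$imputed)))
  invisible(x)
}

#' Statistical region merging configuration
#'
#' @param Q merging delicacy (>= 0): larger Q gives smaller thresholds and
#'   finer partitions.
#' @param r_max estimate of the largest merged region (feature range after
#'   rescaling); default 256.
#' @param connectivity `"circular_s"` (default; the sector axis closes on
#'   itself like the cell boundary, the time axis is open) or `"open"`.
#' @return An `srm_config` list.
#' @export
srm_config <- function(Q = 3, r_max = 256, connectivity = c("circular_s", "open")) {
  if (Q < 0) abort("`Q` must be >= 0")
  if (r_max < 1) abort("`r_max` must be >= 1")
  structure(
    list(Q = Q, r_max = r_max, connectivity = match.arg(connectivity)),
    class = "srm_config"
  )
}

#' Region-merging threshold
#'
#' Size-dependent statistical bound under which two region means are
#' considered indistinguishable:
#' \deqn{T(R) = \sqrt{\frac{R_{max}^2\, 2^{-(Q+1)}}{|R|}
#'   \ln\!\big((|R|+1)^{\min(|R|, R_{max})} \cdot 6 N_t N_s\big)}}
#' evaluated on features rescaled per channel to `[0, r_max]`. `T` halves
#' per unit of Q in squared terms (`T(Q+1)/T(Q) = 1/sqrt(2)`) and
#' penalizes large regions.
#'
#' @param region_size region size(s) `|R|` (vectorized).
#' @param cfg an [srm_config].
#' @param n_total total grid size `N_t * N_s`.
#' @return Threshold value(s).
#' @export
srm_threshold <- function(region_size, cfg, n_total) {
  g <- cfg$r_max
  sqrt(g^2 * 2^(-(cfg$Q + 1)) / region_size *
         (pmin(region_size, g) * log(region_size + 1) + log(6 * n_total)))
}

#' Cluster a feature field into motion regimens by region merging
#'
#' Greedy statistical region merging on the (sector, time) grid: edges of
#' the 4-connected grid (circular along sectors) are visited in ascending
#' order of the maximum per-channel absolute difference, and two regions
#' merge while every channel's mean difference stays within
#' `sqrt(T^2(R1) + T^2(R2))`. Features are linearly rescaled per channel
#' to `[0, r_max]` before merging; ties in the edge order are broken by
#' grid position, making the partition deterministic.
#'
#' @param ff a `feature_field` (or a bare channels x sectors x frames
#'   array).
#' @param cfg an [srm_config].
#' @param channels integer vector of feature channels to cluster on
#'   (default all). Channels 1-6 are the temporal, 7-12 the spatial
#'   amplitude-weighted frequencies; subsets mirror the practice of
#'   clustering on reduced feature vectors when some channels are known
#'   to carry no structure.
#' @return A `region_labeling`: list with `labels` (sectors x frames
#'   integer matrix, labels ordered by first occurrence), `n_regions`,
#'   per-region sizes and feature means, and the explained-variance
#'   fraction of the rescaled features.
#' @export
srm_cluster <- function(ff, cfg = srm_config(), channels = NULL) {
  phi <- if (inherits(ff, "feature_field")) ff$phi else ff
  if (!is.null(channels)) phi <- phi[channels, , , drop = FALSE]
  C <- dim(phi)[1]; S <- dim(phi)[2]; Tn <- dim(phi)[3]
  n <- S * Tn
  # per-channel rescale to [0, r_max]
  X <- matrix(0, n, C)
  for (ch in seq_len(C)) X[, ch] <- rescale_to(as.vector(phi[ch, , ]), cfg$r_max)

  # grid edges: vertical (sector axis, wrapping) and horizontal (time axis)
  id <- matrix(seq_len(n), S, Tn)
  if (cfg$connectivity == "circular_s" && S > 2) {
    va <- as.vector(id); vb <- as.vector(id[c(2:S, 1), ])
  } else {
    va <- as.vector(id[-S, ]); vb <- as.vector(id[-1, ])
  }
  ha <- as.vector(id[, -Tn]); hb <- as.vector(id[, -1])
  ea <- c(va, ha); eb <- c(vb, hb)
  # edge weight: max channel absolute difference
  wmax <- rep(0, length(ea))
  for (ch in seq_len(C)) {
    wmax <- pmax(wmax, abs(X[ea, ch] - X[eb, ch]))
  }
  ord <- order(wmax, pmin(ea, eb), pmax(ea, eb))

  parent <- seq_len(n)
  size <- rep(1L, n)
  sums <- X
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  logN <- log(6 * n)
  thr2 <- function(sz) {
    cfg$r_max^2 * 2^(-(cfg$Q + 1)) / sz *
      (pmin(sz, cfg$r_max) * log(sz + 1) + logN)
  }
  for (e in ord) {
    r1 <- find(ea[e]); r2 <- find(eb[e])
    if (r1 == r2) next
    t2 <- thr2(size[r1]) + thr2(size[r2])
    dmax2 <- max((sums[r1, ] / size[r1] - sums[r2, ] / size[r2])^2)
    if (dmax2 <= t2) {
      # union by size
      if (size[r1] < size[r2]) { tmp <- r1; r1 <- r2; r2 <- tmp }
      parent[r2] <- r1
      size[r1] <- size[r1] + size[r2]
      sums[r1, ] <- sums[r1, ] + sums[r2, ]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labs <- match(roots, unique(roots))
  labels <- matrix(labs, S, Tn)
  k <- max(labs)
  reg_size <- tabulate(labs, k)
  means <- matrix(0, k, C)
  for (ch in seq_len(C)) {
    means[, ch] <- tapply(X[, ch], labs, mean)
  }
  # explained variance fraction on the rescaled features
  totss <- sum(apply(X, 2, function(cl) sum((cl - mean(cl))^2)))
  wss <- 0
  for (ch in seq_len(C)) {
    wss <- wss + sum((X[, ch] - means[labs, ch])^2)
  }
  structure(
    list(labels = labels, n_regions = k, sizes = reg_size, means = means,
         explained = if (totss > 0) 1 - wss / totss else 0,
         cfg = cfg),
    class = "region_labeling"
  )
}

#' @export
print.region_labeling <- function(x, ...) {
  cat(sprintf("<region_labeling> %d regions on %d x %d grid (Q = %g), explained variance %.2f\n",
              x$n_regions, nrow(x$labels), ncol(x$labels), x$cfg$Q, x$explained))
  invisible(x)
}

#' @export
tidy.region_labeling <- function(x, ...) {
  tibble(
    sector = rep(seq_len(nrow(x$labels)), ncol(x$labels)),
    frame = rep(seq_len(ncol(x$labels)), each = nrow(x$labels)),
    regimen = as.vector(x$labels)
  )
}

#' @export
glance.region_labeling <- function(x, ...) {
  tibble(n_regions = x$n_regions, Q = x$cfg$Q, explained = x$explained)
}

#' @export
autoplot.region_labeling <- function(object, ...) {
  df <- tidy(object)
  df$regimen <- factor(df$regimen)
  ggplot(df, aes(x = .data$frame, y = .data$sector, fill = .data$regimen)) +
    geom_raster() +
    labs(x = "frame", y = "sector") +
    theme_bw()
}

#' Scan the merging delicacy Q and report explained variance
#'
#' Clusters the feature field at each Q and reports the fraction of
#' feature variance explained by the partition (1 minus the ratio of
#' within-region to total sum of squares, pooled over the 12 channels),
#' plus a knee estimate: the smallest Q whose marginal gain drops below
#' 5% of the curve's total rise.
#'
#' @param ff a `feature_field`.
#' @param q_values >= 2 Q values, ascending.
#' @param cfg base [srm_config] (its `Q` is overridden).
#' @param channels see [srm_cluster()].
#' @return Tibble with `Q`, `n_regions`, `explained`; the knee is attached
#'   as attribute `knee`.
#' @export
q_scan <- function(ff, q_values = 0:8, cfg = srm_config(), channels = NULL) {
  if (length(q_values) < 2) abort("need at least 2 Q values")
  rows <- lapply(q_values, function(q) {
    cfg$Q <- q
    lab <- srm_cluster(ff, cfg, channels = channels)
    tibble(Q = q, n_regions = lab$n_regions, explained = lab$explained)
  })
  out <- dplyr::bind_rows(rows)
  gain <- diff(out$explained)
  rise <- max(out$explained) - min(out$explained)
  jump <- which.max(gain)
  late <- which(gain < 0.05 * rise & seq_along(gain) > jump)
  knee <- if (rise > 0 && length(late) > 0) {
    out$Q[late[1]]
  } else {
    out$Q[length(out$Q)]
  }
  attr(out, "knee") <- knee
  out
}
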