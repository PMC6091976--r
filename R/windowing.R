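#' Edge-attached sampling windows (discrete pixel method)
#'
#' Bins every pixel of the cell interior into (band, slice) windows using
#' the Euclidean distance `d_i` to the nearest boundary pixel and the
#' arclength `l_i` from the window origin to that boundary pixel. A window
#' holds all pixels with `b_m < d <= b_{m+1}` and `s_p < l <= s_{p+1}`
#' (the first slice additionally includes `l = 0`), so windows within one
#' band partition the band exactly.
#'
#' @param mask logical matrix, single-component cell mask.
#' @param b_edges band edges in micrometres from the cell edge, ascending,
#'   starting at 0 (e.g. `c(0, 3, 6)` gives two bands).
#' @param s_edges slice edges in micrometres along the boundary from the
#'   origin; alternatively give `n_slices`.
#' @param n_slices number of equal-width slices (used when `s_edges` is
#'   `NULL`).
#' @param origin optional (x, y) position of the window origin; snapped to
#'   the nearest boundary pixel with a warning when off-boundary. Defaults
#'   to the boundary trace start.
#' @param pixel_size pixel size in micrometres.
#' @return A `window_set` with a tibble of windows (`band`, `slice`,
#'   `pixels` list-column, `area`, `excluded`), the ordered boundary chain,
#'   slice/band edges, and metadata.
#' @export
discrete_windows <- function(mask, b_edges, s_edges = NULL, n_slices = NULL,
                             origin = NULL, pixel_size = 1) {
  mask <- mask > 0
  chain <- boundary_chain(mask, origin)
  bp <- chain$pixels
  l_chain <- chain$arclength * pixel_size
  L <- chain$total * pixel_size
  if (is.null(s_edges)) {
    if (is.null(n_slices)) abort("give `s_edges` or `n_slices`")
    s_edges <- seq(0, L, length.out = n_slices + 1L)
  }
  idx <- which(mask)
  ux <- ((idx - 1L) %% nrow(mask)) + 1L
  uy <- ((idx - 1L) %/% nrow(mask)) + 1L
  nb <- nearest_boundary(ux, uy, bp)
  d <- nb$dist * pixel_size
  l <- l_chain[nb$index]

  band <- findInterval(d, b_edges, left.open = TRUE)
  band[d <= b_edges[1]] <- 0L # boundary pixels themselves fall outside band 1
  band[band >= length(b_edges)] <- 0L
  slice <- findInterval(l, s_edges, left.open = TRUE)
  slice[l == 0] <- 1L
  slice[slice >= length(s_edges) | slice < 1L] <- length(s_edges) - 1L

  keep <- band > 0L
  wins <- tibble(
    band = band[keep], slice = slice[keep], pixel = idx[keep]
  )
  wins <- dplyr::group_by(wins, .data$band, .data$slice)
  wins <- dplyr::summarise(wins, pixels = list(.data$pixel), .groups = "drop")
  full <- tidyr::expand_grid(
    band = seq_len(length(b_edges) - 1L),
    slice = seq_len(length(s_edges) - 1L)
  )
  wins <- dplyr::left_join(full, wins, by = c("band", "slice"))
  wins$pixels <- lapply(wins$pixels, function(p) p %||% integer(0))
  wins$area <- vapply(wins$pixels, length, integer(1)) * pixel_size^2
  wins$excluded <- FALSE
  structure(
    list(method = "discrete", windows = wins, chain = chain,
         b_edges = b_edges, s_edges = s_edges, pixel_size = pixel_size,
         mask_dim = dim(mask), origin = bp[1, ]),
    class = "window_set"
  )
}

# Ordered boundary pixel chain, rotated so the origin pixel comes first.
boundary_chain <- function(mask, origin = NULL) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  bp <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1
  bp <- bp[!duplicated(bp), , drop = FALSE]
  if (polygon_signed_area(bp) < 0) bp <- bp[nrow(bp):1, , drop = FALSE]
  if (!is.null(origin)) {
    d2 <- (bp[, 1] - origin[1])^2 + (bp[, 2] - origin[2])^2
    k <- which.min(d2)
    if (d2[k] > 0) {
      warn("origin is not on the boundary; snapped to the nearest boundary pixel")
    }
    if (k > 1) bp <- bp[c(k:nrow(bp), 1:(k - 1)), , drop = FALSE]
  }
  n <- nrow(bp)
  seg <- sqrt(rowSums((bp[c(2:n, 1), , drop = FALSE] - bp)^2))
  list(pixels = bp, arclength = c(0, cumsum(seg[-n])), total = sum(seg))
}

# Brute-force nearest boundary pixel for interior pixels, chunked.
nearest_boundary <- function(ux, uy, bp, chunk = 4096L) {
  n <- length(ux)
  index <- integer(n); dist <- numeric(n)
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    dx <- outer(ux[st:en], bp[, 1], "-")
    dy <- outer(uy[st:en], bp[, 2], "-")
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    index[st:en] <- j
    dist[st:en] <- sqrt(d2[cbind(seq_len(en - st + 1L), j)])
  }
  list(index = index, dist = dist)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %s method: %d bands x %d slices (%d excluded), pixel size %g um\n",
    x$method, length(x$b_edges) - 1L, length(x$s_edges) - 1L,
    sum(x$windows$excluded), x$pixel_size
  ))
  invisible(x)
}

#' @export
tidy.window_set <- function(x, ...) {
  dplyr::select(x$windows, "band", "slice", "area", "excluded")
}

#' Edge-attached sampling windows (sub-pixel method)
#'
#' Builds windows as polygons bounded by sub-pixel isocontours of the
#' Euclidean distance transform at the band values and by slice curves
#' obtained by gradient ascent of the distance transform from equally
#' spaced start positions on the master contour. Windows whose slice curve
#' stalls on a distance-transform ridge, or which come close to the image
#' border, are marked excluded.
#'
#' @inheritParams discrete_windows
#' @param b_values band isovalues in micrometres from the edge, ascending,
#'   starting at 0.
#' @param master_level isovalue of the master contour carrying the slice
#'   origin (must be one of `b_values`; default the cell edge, 0).
#' @param step gradient-ascent step length in pixels.
#' @return A `window_set` whose windows carry `polygon` list-columns.
#' @export
subpixel_windows <- function(mask, b_values, s_edges = NULL, n_slices = NULL,
                             master_level = b_values[1], origin = NULL,
                             pixel_size = 1, step = 0.5) {
  mask <- mask > 0
  if (!master_level %in% b_values) abort("`master_level` must be one of `b_values`")
  D <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  lev_px <- b_values / pixel_size + 0.5
  iso <- lapply(lev_px, function(lv) isocontour_polyline(D, lv))
  names(iso) <- as.character(b_values)

  mu <- iso[[match(master_level, b_values)]]
  if (is.null(mu)) abort("master contour level not found inside the mask")
  arc <- polygon_arclength(mu)
  L <- arc$total * pixel_size
  if (is.null(s_edges)) {
    if (is.null(n_slices)) abort("give `s_edges` or `n_slices`")
    s_edges <- seq(0, L, length.out = n_slices + 1L)
  }
  # rotate master contour so the origin-closest vertex is first
  if (!is.null(origin)) {
    k <- which.min((mu[, 1] - origin[1])^2 + (mu[, 2] - origin[2])^2)
    if (k > 1) mu <- mu[c(k:nrow(mu), 1:(k - 1)), , drop = FALSE]
    arc <- polygon_arclength(mu)
  }
  P <- length(s_edges) - 1L
  starts_px <- head(s_edges, -1L) / pixel_size
  sigma <- cbind(
    approx(c(arc$p, arc$total), c(mu[, 1], mu[1, 1]), xout = starts_px, rule = 2)$y,
    approx(c(arc$p, arc$total), c(mu[, 2], mu[1, 2]), xout = starts_px, rule = 2)$y
  )

  top <- max(lev_px)
  curves <- lapply(seq_len(P), function(p) {
    gradient_ascent(D, sigma[p, ], lev_px, top, step)
  })

  M <- length(b_values) - 1L
  rows <- vector("list", M * P)
  r <- 0L
  for (m in seq_len(M)) {
    lo <- iso[[m]]; hi <- iso[[m + 1L]]
    for (p in seq_len(P)) {
      r <- r + 1L
      p2 <- wrap_index(p + 1L, P)
      c1 <- curves[[p]]; c2 <- curves[[p2]]
      ok <- !is.null(lo) && !is.null(hi) &&
        !is.null(c1$cross[[m]]) && !is.null(c1$cross[[m + 1L]]) &&
        !is.null(c2$cross[[m]]) && !is.null(c2$cross[[m + 1L]]) &&
        !c1$stalled_before[m + 1L] && !c2$stalled_before[m + 1L]
      poly <- NULL
      if (ok) {
        side1 <- curve_between(c1, m, m + 1L)
        side2 <- curve_between(c2, m, m + 1L)
        inner <- iso_between(lo, c1$cross[[m]], c2$cross[[m]])
        outer_ <- iso_between(hi, c1$cross[[m + 1L]], c2$cross[[m + 1L]])
        poly <- rbind(inner, side2[nrow(side2):1, , drop = FALSE],
                      outer_[nrow(outer_):1, , drop = FALSE], side1)
      }
      near_border <- !is.null(poly) &&
        (min(poly) < 1.5 || max(poly[, 1]) > nrow(D) - 0.5 ||
           max(poly[, 2]) > ncol(D) - 0.5)
      rows[[r]] <- tibble(
        band = m, slice = p,
        polygon = list(poly),
        area = if (is.null(poly)) NA_real_ else abs(polygon_signed_area(poly)) * pixel_size^2,
        excluded = !ok || near_border
      )
    }
  }
  structure(
    list(method = "subpixel", windows = dplyr::bind_rows(rows),
         isocontours = iso, master = mu, curves = curves,
         b_edges = b_values, s_edges = s_edges, pixel_size = pixel_size,
         mask_dim = dim(mask), origin = sigma[1, ]),
    class = "window_set"
  )
}

# Largest closed isocontour polyline of matrix D at one level (sub-pixel,
# via marching squares). NULL when absent.
isocontour_polyline <- function(D, level) {
  cl <- grDevices::contourLines(seq_len(nrow(D)), seq_len(ncol(D)), D, levels = level)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(c0) length(c0$x), integer(1))
  c0 <- cl[[which.max(lens)]]
  pts <- cbind(c0$x, c0$y)
  closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-6
  if (closed) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 4) return(NULL)
  if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

# Gradient ascent of D from a start point: fixed step along the normalized
# bilinear-interpolated gradient, terminating at the top isovalue or a
# ridge stall. Records the crossing point of every level by interpolation.
gradient_ascent <- function(D, start, levels_px, top, step = 0.5,
                            stall_tol = 1e-3, max_steps = 4000L) {
  pt <- start
  path <- matrix(NA_real_, max_steps + 1L, 2)
  vals <- numeric(max_steps + 1L)
  path[1, ] <- pt
  vals[1] <- bilinear(D, pt[1], pt[2])
  gx <- function(x, y) (bilinear(D, x + 0.5, y) - bilinear(D, x - 0.5, y))
  gy <- function(x, y) (bilinear(D, x, y + 0.5) - bilinear(D, x, y - 0.5))
  k <- 1L
  stalled <- FALSE
  while (vals[k] < top && k <= max_steps) {
    g <- c(gx(pt[1], pt[2]), gy(pt[1], pt[2]))
    gn <- sqrt(sum(g^2))
    if (gn < stall_tol) { stalled <- TRUE; break }
    pt <- pt + step * g / gn
    k <- k + 1L
    path[k, ] <- pt
    vals[k] <- bilinear(D, pt[1], pt[2])
    if (k > 2 && vals[k] < vals[k - 1] - step) { stalled <- TRUE; break }
  }
  path <- path[seq_len(k), , drop = FALSE]
  vals <- vals[seq_len(k)]
  cross <- vector("list", length(levels_px))
  stalled_before <- logical(length(levels_px))
  for (m in seq_along(levels_px)) {
    lv <- levels_px[m]
    if (vals[1] >= lv) { cross[[m]] <- path[1, ]; next }
    hit <- which(vals >= lv)
    if (length(hit) == 0) { stalled_before[m] <- TRUE; next }
    j <- hit[1]
    f <- (lv - vals[j - 1]) / (vals[j] - vals[j - 1])
    cross[[m]] <- path[j - 1, ] + f * (path[j, ] - path[j - 1, ])
  }
  list(path = path, values = vals, cross = cross,
       stalled = stalled, stalled_before = stalled_before)
}

# Portion of an ascent path between the crossings of two levels: the path
# samples whose distance-transform values lie strictly between them.
curve_between <- function(curve, m_lo, m_hi) {
  a <- curve$cross[[m_lo]]; b <- curve$cross[[m_hi]]
  va <- point_value(curve, a); vb <- point_value(curve, b)
  mid <- curve$path[curve$values > va & curve$values < vb, , drop = FALSE]
  rbind(a, mid, b)
}

# Nearest recorded path value (crossings were interpolated on the path).
point_value <- function(curve, pt) {
  d2 <- (curve$path[, 1] - pt[1])^2 + (curve$path[, 2] - pt[2])^2
  curve$values[which.min(d2)]
}

# Sub-polyline of closed isocontour `iso` from near point a to near point b
# following the polygon orientation.
iso_between <- function(iso, a, b) {
  arc <- polygon_arclength(iso)
  pa <- arc$p[which.min((iso[, 1] - a[1])^2 + (iso[, 2] - a[2])^2)]
  pb <- arc$p[which.min((iso[, 1] - b[1])^2 + (iso[, 2] - b[2])^2)]
  if (pb < pa) pb <- pb + arc$total
  pp <- ifelse(arc$p >= pa, arc$p, arc$p + arc$total)
  sel <- which(pp > pa & pp < pb)
  sel <- sel[order(pp[sel])]
  rbind(a, iso[sel, , drop = FALSE], b)
}

#' Propagate a window set to the next frame
#'
#' The band structure (distances from the edge) is always rebuilt on the
#' new mask so bands keep their distance from the cell edge; methods differ
#' in how the slice origin and widths are carried forward.
#'
#' @param ws a `window_set`.
#' @param mask_t1 the next frame's mask.
#' @param edgemap optional `edge_map` between the two frames (required by
#'   the displacement-based methods).
#' @param method one of `"constant_slice_count"` (default; slice count
#'   preserved, widths rescale with edge length), `"origin_by_closest_point"`
#'   and `"origin_by_displacement"` (fixed slice width, count may change),
#'   or `"follow_edge_vectors"` (each slice start follows its adjacent edge
#'   displacement).
#' @return A new `window_set` on `mask_t1`.
#' @export
propagate_windows <- function(ws, mask_t1, edgemap = NULL,
                              method = c("constant_slice_count",
                                         "origin_by_closest_point",
                                         "origin_by_displacement",
                                         "follow_edge_vectors")) {
  method <- match.arg(method)
  P <- length(ws$s_edges) - 1L
  width <- diff(ws$s_edges)[1]
  old_origin <- ws$origin

  new_origin <- switch(method,
    constant_slice_count = ,
    origin_by_closest_point = old_origin,
    origin_by_displacement = ,
    follow_edge_vectors = {
      if (is.null(edgemap)) abort(sprintf("method '%s' needs `edgemap`", method))
      k <- which.min((edgemap$nodes[, 1] - old_origin[1])^2 +
                       (edgemap$nodes[, 2] - old_origin[2])^2)
      old_origin + edgemap$disp[k, ]
    }
  )

  build <- function(s_edges, n_slices, origin) {
    if (ws$method == "discrete") {
      discrete_windows(mask_t1, ws$b_edges, s_edges = s_edges,
                       n_slices = n_slices, origin = origin,
                       pixel_size = ws$pixel_size)
    } else {
      subpixel_windows(mask_t1, ws$b_edges, s_edges = s_edges,
                       n_slices = n_slices, origin = origin,
                       pixel_size = ws$pixel_size)
    }
  }

  if (method == "constant_slice_count") {
    return(build(NULL, P, new_origin))
  }
  if (method %in% c("origin_by_closest_point", "origin_by_displacement")) {
    # keep slice width; slice count adapts to the new edge length
    tmp <- boundary_chain(mask_t1, new_origin)
    L1 <- tmp$total * ws$pixel_size
    n1 <- max(1L, round(L1 / width))
    return(build(NULL, n1, new_origin))
  }
  # follow_edge_vectors: map each slice start through the displacement field
  if (is.null(edgemap)) abort("method 'follow_edge_vectors' needs `edgemap`")
  chain <- boundary_chain(mask_t1, new_origin)
  L1 <- chain$total * ws$pixel_size
  starts_old <- head(ws$s_edges, -1L)
  # positions of old slice starts on the old chain
  old_chain <- ws$chain %||% boundary_chain(!is.na(mask_t1) & mask_t1, old_origin)
  pos <- cbind(
    approx(c(old_chain$arclength, old_chain$total) * ws$pixel_size,
           c(old_chain$pixels[, 1], old_chain$pixels[1, 1]),
           xout = starts_old, rule = 2)$y,
    approx(c(old_chain$arclength, old_chain$total) * ws$pixel_size,
           c(old_chain$pixels[, 2], old_chain$pixels[1, 2]),
           xout = starts_old, rule = 2)$y
  )
  moved <- pos
  for (i in seq_len(nrow(pos))) {
    k <- which.min((edgemap$nodes[, 1] - pos[i, 1])^2 +
                     (edgemap$nodes[, 2] - pos[i, 2])^2)
    moved[i, ] <- pos[i, ] + edgemap$disp[k, ]
  }
  # project moved starts onto the new chain and rebuild slice edges
  s_new <- vapply(seq_len(nrow(moved)), function(i) {
    k <- which.min((chain$pixels[, 1] - moved[i, 1])^2 +
                     (chain$pixels[, 2] - moved[i, 2])^2)
    chain$arclength[k] * ws$pixel_size
  }, numeric(1))
  s_new <- sort(unique(c(0, s_new[s_new > 0], L1)))
  build(s_new, NULL, new_origin)
}

#' Sample an image through a window set
#'
#' Computes a per-window statistic over the pixels whose centre lies within
#' the window (discrete: binned pixel sets; sub-pixel: point-in-polygon
#' test). Empty or excluded windows yield `NA` with a sample count of 0.
#'
#' @param image numeric matrix aligned with the mask grid.
#' @param ws a `window_set`.
#' @param statistic one of `"mean"`, `"sd"`, `"max"`, `"min"`, `"median"`.
#' @return Tibble with `band`, `slice`, `value`, `n`.
#' @export
sample_windows <- function(image, ws,
                           statistic = c("mean", "sd", "max", "min", "median")) {
  statistic <- match.arg(statistic)
  fun <- switch(statistic, mean = mean, sd = sd, max = max, min = min,
                median = median)
  wins <- ws$windows
  vals <- rep(NA_real_, nrow(wins))
  ns <- integer(nrow(wins))
  if (ws$method == "discrete") {
    for (i in seq_len(nrow(wins))) {
      px <- wins$pixels[[i]]
      if (wins$excluded[i] || length(px) == 0) next
      vals[i] <- fun(image[px])
      ns[i] <- length(px)
    }
  } else {
    nx <- nrow(image); ny <- ncol(image)
    for (i in seq_len(nrow(wins))) {
      poly <- wins$polygon[[i]]
      if (wins$excluded[i] || is.null(poly)) next
      xr <- range(poly[, 1]); yr <- range(poly[, 2])
      xs <- max(1L, floor(xr[1])):min(nx, ceiling(xr[2]))
      ys <- max(1L, floor(yr[1])):min(ny, ceiling(yr[2]))
      if (length(xs) == 0 || length(ys) == 0) next
      cand <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)))
      inside <- mgcv::in.out(rbind(poly, poly[1, ]), cand)
      if (!any(inside)) next
      px <- cand[inside, , drop = FALSE]
      vals[i] <- fun(image[px])
      ns[i] <- sum(inside)
    }
  }
  tibble(band = wins$band, slice = wins$slice, value = vals, n = ns)
}

#' Sample a movie into an activity map
#'
#' @param stack numeric array (x, y, frame).
#' @param window_sets list of `window_set`s, one per frame.
#' @param band band index to extract (rows = slices of that band).
#' @param dt frame interval, seconds.
#' @param statistic see [sample_windows()].
#' @param units units label for the resulting map.
#' @return An [activity_map] (slices x frames).
#' @export
sample_movie <- function(stack, window_sets, band = 1L, dt = 10,
                         statistic = "mean", units = "a.u.") {
  Tn <- length(window_sets)
  P <- length(window_sets[[1]]$s_edges) - 1L
  m <- matrix(NA_real_, P, Tn)
  cnt <- matrix(0L, P, Tn)
  for (k in seq_len(Tn)) {
    sm <- sample_windows(stack[, , k], window_sets[[k]], statistic)
    sm <- sm[sm$band == band, ]
    m[sm$slice, k] <- sm$value
    cnt[sm$slice, k] <- sm$n
  }
  activity_map(m, dt = dt, units = units, counts = cnt)
}

#' Compile signed normal edge velocities into a sector velocity map
#'
#' Entry (s, t) is the mean signed normal velocity of the displacement
#' vectors whose source nodes fall in sector s between frames t and t+1,
#' with the contributing vector count stored alongside. Sectors are
#' defined either as equal angular bins around the mask centroid
#' (`sectors = n`, natural for star-convex synthetic cells) or as the
#' first-band slices of per-frame window sets (`sectors = list of
#' window_set`).
#'
#' @param track an `edge_track` from [track_movie()].
#' @param sectors integer (number of angular sectors) or a list of
#'   `window_set`s (one per frame; slice edges define the sectors).
#' @param dt frame interval, seconds.
#' @return An [activity_map] in um/min with `n_frames - 1` columns and
#'   per-entry counts.
#' @export
sector_velocity_map <- function(track, sectors, dt) {
  Tm <- length(track)
  angular <- is.numeric(sectors)
  S <- if (angular) as.integer(sectors) else length(sectors[[1]]$s_edges) - 1L
  m <- matrix(NA_real_, S, Tm)
  cnt <- matrix(0L, S, Tm)
  for (k in seq_len(Tm)) {
    em <- track[[k]]
    if (angular) {
      ctr <- colMeans(em$nodes)
      th <- atan2(em$nodes[, 2] - ctr[2], em$nodes[, 1] - ctr[1]) %% (2 * pi)
      bin <- pmin(floor(th / (2 * pi) * S) + 1L, S)
    } else {
      ws <- sectors[[min(k, length(sectors))]]
      ch <- ws$chain
      if (is.null(ch)) abort("window sets must come from the discrete method to define sectors")
      l_phys <- numeric(nrow(em$nodes))
      for (i in seq_len(nrow(em$nodes))) {
        j <- which.min((ch$pixels[, 1] - em$nodes[i, 1])^2 +
                         (ch$pixels[, 2] - em$nodes[i, 2])^2)
        l_phys[i] <- ch$arclength[j] * ws$pixel_size
      }
      bin <- findInterval(l_phys, ws$s_edges, left.open = TRUE)
      bin[l_phys == 0] <- 1L
      bin <- pmin(pmax(bin, 1L), S)
    }
    ok <- !is.na(em$velocity)
    sums <- tapply(em$velocity[ok], bin[ok], mean)
    m[as.integer(names(sums)), k] <- as.numeric(sums)
    tab <- table(bin[ok])
    cnt[as.integer(names(tab)), k] <- as.integer(tab)
  }
  activity_map(m, dt = dt, units = "um/min", counts = cnt,
               times = (seq_len(Tm) - 0.5) * dt)
}
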