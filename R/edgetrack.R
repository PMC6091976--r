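#' Edge-mapping configuration
#'
#' Controls the correspondence search between consecutive cell contours.
#' Virtual edge markers on the earlier contour are mapped to the later
#' contour by minimizing total squared displacement (`SUMA`) plus
#' `omega` times the lateral-strain term (`SUMB`, squared ratios of node
#' spacings), subject to the topological constraint that displacement
#' vectors must not cross. The unit-balancing factor
#' `omega = w * SUMA/SUMB` is evaluated once at a closest-point
#' initialization.
#'
#' @param w dimensionless strain weight (default 1: displacement and strain
#'   balanced; 0: displacement only; large: equalized spacing).
#' @param nmax node cap per segment, must satisfy 10 < nmax < 100; longer
#'   segments are down-sampled to `nmax` nodes and the solution up-sampled
#'   by monotone interpolation.
#' @param grid_density candidate target parameters per source node for the
#'   exact dynamic-programming solver.
#' @param smooth_iters contour smoothing iterations (see
#'   [extract_contour()]).
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(w = 1, nmax = 50L, grid_density = 4L,
                           smooth_iters = 5L) {
  if (w < 0) abort("`w` must be >= 0")
  if (!(nmax > 10 && nmax < 100)) abort("`nmax` must satisfy 10 < nmax < 100")
  structure(
    list(w = w, nmax = as.integer(nmax),
         grid_density = as.integer(grid_density),
         smooth_iters = as.integer(smooth_iters)),
    class = "mapping_config"
  )
}

# All crossings between two closed polylines. Returns a data frame with
# arclength parameters s (on a) and u (on b).
polyline_crossings <- function(a, b) {
  na <- nrow(a$nodes); nb <- nrow(b$nodes)
  A1 <- a$nodes; A2 <- a$nodes[c(2:na, 1), , drop = FALSE]
  B1 <- b$nodes; B2 <- b$nodes[c(2:nb, 1), , drop = FALSE]
  la <- sqrt(rowSums((A2 - A1)^2)); lb <- sqrt(rowSums((B2 - B1)^2))
  res_s <- numeric(0); res_u <- numeric(0)
  # vectorize over b-edges for each a-edge
  for (i in seq_len(na)) {
    r <- A2[i, ] - A1[i, ]
    sdir <- B2 - B1
    denom <- r[1] * sdir[, 2] - r[2] * sdir[, 1]
    qp1 <- B1[, 1] - A1[i, 1]; qp2 <- B1[, 2] - A1[i, 2]
    tt <- (qp1 * sdir[, 2] - qp2 * sdir[, 1]) / denom
    uu <- (qp1 * r[2] - qp2 * r[1]) / denom
    hit <- is.finite(tt) & is.finite(uu) & tt >= 0 & tt < 1 & uu >= 0 & uu < 1
    if (any(hit)) {
      res_s <- c(res_s, a$p[i] + tt[hit] * la[i])
      res_u <- c(res_u, b$p[hit] + uu[hit] * lb[hit])
    }
  }
  data.frame(s = res_s, u = res_u)
}

#' Split two consecutive contours into segment pairs at their crossings
#'
#' Each pair covers the curve portions between consecutive crossing points
#' of the two polylines. When the contours do not cross (or the crossing
#' pattern is inconsistent), a single periodic pair covering both full
#' contours is returned, with the target origin anchored at the point
#' closest to the first source node.
#'
#' @param ct,ct1 `cell_contour`s of consecutive frames.
#' @param min_gap crossings closer than this arclength (px) are merged.
#' @return List of segment pairs: each has `src_param`, `src_idx`
#'   (`NA` for virtual crossing endpoints), `e1`, `en` (target parameter
#'   range), and `periodic`.
#' @export
split_segments <- function(ct, ct1, min_gap = 2) {
  periodic_pair <- function() {
    anchor <- contour_nearest_param(ct1, ct$nodes[1, , drop = FALSE])
    list(list(src_param = ct$p, src_idx = seq_along(ct$p),
              e1 = anchor, en = anchor + ct1$length, periodic = TRUE))
  }
  cr <- polyline_crossings(ct, ct1)
  if (nrow(cr) < 2) return(periodic_pair())
  cr <- cr[order(cr$s), , drop = FALSE]
  # merge crossing clusters (tangential contacts produce bursts)
  keep <- c(TRUE, diff(cr$s) > min_gap)
  # also merge across the wrap point
  if (nrow(cr) > 1 && (cr$s[1] + ct$length - cr$s[nrow(cr)]) <= min_gap) keep[1] <- keep[1] & FALSE
  cr <- cr[keep, , drop = FALSE]
  if (nrow(cr) < 2) return(periodic_pair())
  # target parameters must advance cyclically with the source ordering
  du <- diff(cr$u) %% ct1$length
  if (any(du <= 0) || sum(du) >= ct1$length) return(periodic_pair())
  k <- nrow(cr)
  pairs <- vector("list", k)
  for (j in seq_len(k)) {
    s0 <- cr$s[j]
    s1 <- if (j < k) cr$s[j + 1] else cr$s[1] + ct$length
    u0 <- cr$u[j]
    u1 <- if (j < k) cr$u[j + 1] else cr$u[1] + ct1$length
    if (u1 <= u0) u1 <- u1 + ct1$length
    inside <- which(ct$p > s0 & ct$p < s1 |
                    (ct$p + ct$length) > s0 & (ct$p + ct$length) < s1)
    prm <- ifelse(ct$p[inside] >= s0, ct$p[inside], ct$p[inside] + ct$length)
    ord <- order(prm)
    pairs[[j]] <- list(
      src_param = c(s0, prm[ord], s1),
      src_idx = c(NA_integer_, inside[ord], NA_integer_),
      e1 = u0, en = u1, periodic = FALSE
    )
  }
  pairs
}

#' Map one segment pair by exact dynamic programming
#'
#' Solves the discrete minimization of `SUMA + omega * SUMB` over a grid of
#' candidate target parameters, subject to strictly increasing parameters
#' (displacement vectors must not cross). The chain structure of the
#' objective (each term couples adjacent nodes only) makes the dynamic
#' program exact for the chosen discretization.
#'
#' @param pair a segment pair from [split_segments()].
#' @param ct,ct1 the source and target `cell_contour`s.
#' @param cfg a [mapping_config].
#' @return List with `o` (optimal target parameters per source entry),
#'   `cost`, `suma`, `sumb`, `omega`, and `target` (mapped positions).
#' @export
map_segment <- function(pair, ct, ct1, cfg = mapping_config()) {
  p_full <- pair$src_param
  n_full <- length(p_full)
  if (n_full < 2) abort("segment needs at least 2 nodes")

  # down-sample long segments, keeping both ends
  if (n_full > cfg$nmax) {
    sel <- unique(round(seq(1, n_full, length.out = cfg$nmax)))
  } else {
    sel <- seq_len(n_full)
  }
  p <- p_full[sel]
  n <- length(p)
  src <- contour_point(ct, p)

  G <- max(cfg$grid_density * n, 24L)
  if (G < n) abort("candidate grid too coarse for strict monotonicity; increase `grid_density`")
  ogrid <- seq(pair$e1, pair$en, length.out = G)
  tgt <- contour_point(ct1, ogrid)
  # squared displacement of node i to candidate j
  nodecost <- outer(src[, 1], tgt[, 1], "-")^2 + outer(src[, 2], tgt[, 2], "-")^2

  dp_full <- p_full[n_full] - p_full[1]
  dp <- diff(p)
  # omega from the closest-point initialization (iteration-1 correspondence)
  init <- apply(nodecost, 1, which.min)
  suma0 <- sum(nodecost[cbind(seq_len(n), init)])
  sumb0 <- sum((diff(ogrid[init]) / dp)^2)
  omega <- if (sumb0 > 0) cfg$w * suma0 / sumb0 else 0

  fixed_end <- !pair$periodic
  # DP forward pass; candidate index strictly increasing
  NEG <- Inf
  cost <- matrix(NEG, n, G)
  ptr <- matrix(0L, n, G)
  if (fixed_end) cost[1, 1] <- nodecost[1, 1] else {
    cost[1, 1] <- nodecost[1, 1] # o_1 anchored for periodic pairs too
  }
  for (i in 2:n) {
    jmax <- if (fixed_end) G - (n - i) else G
    prev <- cost[i - 1, ]
    for (j in seq.int(i, jmax)) {
      k <- seq_len(j - 1L)
      trans <- prev[k] + omega * ((ogrid[j] - ogrid[k]) / dp[i - 1])^2
      b <- which.min(trans)
      cost[i, j] <- trans[b] + nodecost[i, j]
      ptr[i, j] <- b
    }
  }
  jend <- if (fixed_end) G else which.min(cost[n, ])
  if (!is.finite(cost[n, jend])) abort("no feasible monotone assignment; increase `grid_density`")
  sel_j <- integer(n)
  sel_j[n] <- jend
  for (i in n:2) sel_j[i - 1] <- ptr[i, sel_j[i]]
  o <- ogrid[sel_j]

  suma <- sum(nodecost[cbind(seq_len(n), sel_j)])
  sumb <- sum((diff(o) / dp)^2)

  # up-sample to all original entries by monotone interpolation of o(p)
  if (length(sel) < n_full) {
    o_all <- tryCatch(
      splinefun(p, o, method = "hyman")(p_full),
      error = function(e) approx(p, o, xout = p_full)$y
    )
    o_all <- pmin(pmax(o_all, pair$e1), pair$en)
    o_all <- cummax(o_all) # guard monotonicity against rounding
  } else {
    o_all <- o
  }
  list(o = o_all, cost = cost[n, jend], suma = suma, sumb = sumb,
       omega = omega, target = contour_point(ct1, o_all))
}

#' Map all markers of a contour onto the next frame's contour
#'
#' Applies [split_segments()] and [map_segment()] and assembles, for every
#' original node of `ct`, the target parameter and displacement vector.
#'
#' @inheritParams map_segment
#' @return List with `o`, `disp` (n-by-2, pixels), `omega`, `suma`, `sumb`.
#' @export
map_contours <- function(ct, ct1, cfg = mapping_config()) {
  pairs <- split_segments(ct, ct1)
  n <- nrow(ct$nodes)
  o <- rep(NA_real_, n)
  disp <- matrix(NA_real_, n, 2)
  suma <- 0; sumb <- 0; omegas <- numeric(0)
  for (pr in pairs) {
    fit <- map_segment(pr, ct, ct1, cfg)
    real <- !is.na(pr$src_idx)
    idx <- pr$src_idx[real]
    o[idx] <- fit$o[real] %% ct1$length
    disp[idx, ] <- fit$target[real, , drop = FALSE] - ct$nodes[idx, , drop = FALSE]
    suma <- suma + fit$suma; sumb <- sumb + fit$sumb
    omegas <- c(omegas, fit$omega)
  }
  list(o = o, disp = disp, omega = mean(omegas), suma = suma, sumb = sumb)
}

#' Signed normal edge velocities from a contour correspondence
#'
#' Projects each displacement vector onto the outward boundary normal;
#' protrusion (outward motion) is positive.
#'
#' @param ct source `cell_contour`.
#' @param mapping result of [map_contours()].
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @return Numeric vector of velocities in um/min (NA at degenerate nodes).
#' @export
edge_velocities <- function(ct, mapping, dt, pixel_size) {
  proj <- rowSums(mapping$disp * ct$normals)
  proj * pixel_size * 60 / dt
}

#' Track edge motion through a mask movie
#'
#' Extracts contours for every frame and maps markers across each
#' consecutive pair, yielding one `edge_map` per frame pair with node
#' positions, displacements, and signed normal velocities. Markers are
#' reset at every time step.
#'
#' @param masks logical array (x, y, frame) with >= 2 frames.
#' @param cfg a [mapping_config].
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @return A list of `edge_map` objects (class `edge_track`).
#' @export
track_movie <- function(masks, cfg = mapping_config(), dt = 10,
                        pixel_size = 0.3) {
  nt <- dim(masks)[3]
  if (is.na(nt) || nt < 2) abort("need at least 2 frames")
  cts <- vector("list", nt)
  for (k in seq_len(nt)) {
    cts[[k]] <- tryCatch(extract_contour(masks[, , k], cfg$smooth_iters),
      error = function(e) abort(sprintf("frame %d: %s", k, conditionMessage(e)))
    )
  }
  maps <- vector("list", nt - 1L)
  for (k in seq_len(nt - 1L)) {
    mp <- tryCatch(map_contours(cts[[k]], cts[[k + 1L]], cfg),
      error = function(e) abort(sprintf("frame pair %d-%d: %s", k, k + 1L, conditionMessage(e)))
    )
    v <- edge_velocities(cts[[k]], mp, dt, pixel_size)
    maps[[k]] <- structure(
      list(frame = k, nodes = cts[[k]]$nodes, p = cts[[k]]$p,
           normals = cts[[k]]$normals, o = mp$o, disp = mp$disp,
           velocity = v, omega = mp$omega, suma = mp$suma, sumb = mp$sumb,
           contour = cts[[k]], contour_next = cts[[k + 1L]],
           dt = dt, pixel_size = pixel_size),
      class = "edge_map"
    )
  }
  structure(maps, class = "edge_track")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf(
    "<edge_map> frame %d -> %d: %d markers, mean |v| = %.2f um/min, omega = %.3g\n",
    x$frame, x$frame + 1L, nrow(x$nodes), mean(abs(x$velocity), na.rm = TRUE),
    x$omega
  ))
  invisible(x)
}

#' @export
tidy.edge_map <- function(x, ...) {
  tibble(
    frame = x$frame, node = seq_len(nrow(x$nodes)),
    x = x$nodes[, 1], y = x$nodes[, 2], p = x$p, o = x$o,
    dx = x$disp[, 1], dy = x$disp[, 2], velocity = x$velocity
  )
}

#' @export
tidy.edge_track <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy))
}
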