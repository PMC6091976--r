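# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Circular (wrap-around) index into 1..n.
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# Closed-polygon arclength parameters: p[1] = 0, cumulative chord length.
polygon_arclength <- function(pts) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2))
  list(p = c(0, cumsum(seg[-n])), total = sum(seg))
}

# Signed area of a closed polygon (positive = counter-clockwise in x,y).
polygon_signed_area <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

# Bilinear interpolation of matrix `m` at continuous positions (x, y)
# where m[i, j] sits at coordinate (i, j). Positions outside are clamped.
bilinear <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

# Linear rescale of a vector to [0, hi]; constant input maps to 0.
rescale_to <- function(x, hi) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1]) * hi
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
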