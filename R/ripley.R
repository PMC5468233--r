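# Ripley's K and L functions on the unit square with isotropic edge
# correction. The estimator is
#   K(r) = lambda / (n (n - 1)) * sum_{i != j} I(d_ij <= r) e_ij
# with lambda the window area (= 1 for the unit square) and e_ij the
# reciprocal of the fraction of the circle centred at point i with radius
# d_ij that lies inside the window. Duplicate points are retained, so
# coincident pairs contribute from r = 0 onwards.

#' Construct a point pattern on the unit square
#'
#' @param x,y Coordinates in `[0, 1]` (typically unit-normalised logR and
#'   mirrored BAF).
#' @return A `point_pattern` list with `x`, `y`, `n`.
#' @export
point_pattern <- function(x, y) {
  if (length(x) != length(y)) .param_error("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .param_error("coordinates must be finite")
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    .param_error("coordinates must lie in [0, 1]")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x)),
            class = "point_pattern")
}

# Fraction of the circle centred at (x, y) with radius r that lies inside the
# unit square, via the union of the arcs excluded by each of the four sides.
# Exact for any radius; used as a fallback for r >= 0.5 where the vectorised
# two-nearest-sides formula no longer applies.
.inside_frac_general <- function(x, y, r) {
  if (r <= 0) return(1)
  sides <- rbind(c(x, 0), c(1 - x, pi), c(y, 3 * pi / 2), c(1 - y, pi / 2))
  ints <- NULL
  for (k in 1:4) {
    dd <- sides[k, 1L]
    if (dd < r) {
      a <- acos(min(1, dd / r))
      # excluded arc centred on the outward normal of that side
      centre <- c(pi, 0, pi / 2, 3 * pi / 2)[k]
      ints <- rbind(ints, c(centre - a, centre + a))
    }
  }
  if (is.null(ints)) return(1)
  # normalise to [0, 2pi), split wrapped intervals, merge
  pieces <- NULL
  for (k in seq_len(nrow(ints))) {
    lo <- ints[k, 1L] %% (2 * pi)
    hi <- lo + (ints[k, 2L] - ints[k, 1L])
    if (hi <= 2 * pi) pieces <- rbind(pieces, c(lo, hi))
    else pieces <- rbind(pieces, c(lo, 2 * pi), c(0, hi - 2 * pi))
  }
  pieces <- pieces[order(pieces[, 1L]), , drop = FALSE]
  total <- 0
  cur <- pieces[1L, ]
  if (nrow(pieces) > 1L) for (k in 2:nrow(pieces)) {
    if (pieces[k, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], pieces[k, 2L])
    else { total <- total + (cur[2L] - cur[1L]); cur <- pieces[k, ] }
  }
  total <- total + (cur[2L] - cur[1L])
  1 - total / (2 * pi)
}

# Vectorised isotropic edge-correction weights for circles centred at
# (x, y) with radii d, inside the unit square. For d < 0.5 only the two
# nearest (perpendicular) sides can cut the circle; their excluded arcs are
# 2*acos(dx/d) and 2*acos(dy/d) and overlap by
# max(0, pi/2 - asin(dx/d) - asin(dy/d)) beyond the shared corner.
.edge_weights <- function(x, y, d) {
  w <- rep(1, length(d))
  pos <- which(d > 0)
  if (!length(pos)) return(w)
  small <- pos[d[pos] < 0.5]
  if (length(small)) {
    ds <- d[small]
    dx <- pmin(x[small], 1 - x[small]) / ds
    dy <- pmin(y[small], 1 - y[small]) / ds
    a1 <- ifelse(dx < 1, acos(pmin(1, dx)), 0)
    a2 <- ifelse(dy < 1, acos(pmin(1, dy)), 0)
    overlap <- pmax(0, pi / 2 - asin(pmin(1, dx)) - asin(pmin(1, dy)))
    frac <- 1 - (2 * a1 + 2 * a2 - overlap) / (2 * pi)
    w[small] <- 1 / frac
  }
  big <- setdiff(pos, small)
  for (k in big)
    w[k] <- 1 / .inside_frac_general(x[k], y[k], d[k])
  w
}

# Pair table for a pattern, restricted to distances <= dmax: unordered pairs
# (i, j) with distance d and total ordered weight w_ij + w_ji.
.pair_weights <- function(x, y, dmax) {
  n <- length(x)
  d <- as.numeric(stats::dist(cbind(x, y)))
  keep <- which(d <= dmax)
  if (!length(keep))
    return(list(d = numeric(0), w = numeric(0)))
  ij <- which(lower.tri(matrix(FALSE, n, n)), arr.ind = TRUE)  # dist ordering
  i <- ij[keep, 1L]
  j <- ij[keep, 2L]
  dk <- d[keep]
  w <- .edge_weights(x[i], y[i], dk) + .edge_weights(x[j], y[j], dk)
  ord <- order(dk)
  list(d = dk[ord], w = w[ord])
}

.k_curve <- function(x, y, r) {
  n <- length(x)
  pw <- .pair_weights(x, y, max(r))
  csum <- c(0, cumsum(pw$w))
  csum[findInterval(r, pw$d) + 1L] / (n * (n - 1))
}

#' Ripley's K function
#'
#' Estimates K over ordered pairs of points with isotropic edge-correction
#' weights on the unit-square window (window area `lambda = 1`). Under
#' complete spatial randomness `K(r)` is approximately `pi r^2`. Monotone
#' non-decreasing in `r`; coincident points contribute from `r = 0`.
#'
#' @param pattern A [point_pattern] with at least 2 points.
#' @param r Non-negative radius (vectorised).
#' @return `K(r)`, same length as `r`.
#' @export
ripley_K <- function(pattern, r) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2L) .unscorable("Ripley's K needs at least 2 points")
  if (any(r < 0)) .param_error("radius must be >= 0")
  .k_curve(pattern$x, pattern$y, r)
}

#' Ripley's L function
#'
#' The variance-stabilised transform `L(r) = sqrt(K(r) / pi)`, which equals
#' `r` in expectation under complete spatial randomness.
#'
#' @inheritParams ripley_K
#' @return `L(r)`, same length as `r`.
#' @export
ripley_L <- function(pattern, r) {
  sqrt(ripley_K(pattern, r) / pi)
}

# Core of the R score: sum of L(r) - r over the radius grid.
.r_kernel <- function(x, y, r_grid) {
  K <- .k_curve(x, y, r_grid)
  sum(sqrt(K / pi) - r_grid)
}
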