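#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact pi to -pi; keep the +pi endpoint per convention
  w[w == -pi] <- pi
  w
}

#' Shortest signed angular difference a - b, wrapped to (-pi, pi]
#' @param a,b angles in radians.
#' @return wrapped differences.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# Linear interpolation through NA runs of a circular sequence (index wraps
# around). Values themselves are linear (e.g. firing rates); only the index
# is circular. Used to fill empty phase bins.
interp_circular_gaps <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("cannot interpolate: all values missing")
  if (length(ok) == n) return(x)
  # unwrap the index by replicating the known points one period either side
  idx <- c(ok - n, ok, ok + n)
  val <- rep(x[ok], 3L)
  x[is.na(x)] <- stats::approx(idx, val, xout = which(is.na(x)))$y
  x
}

# Principal angles (radians) between two subspaces given as matrices with
# orthonormal columns. Returned sorted increasing.
principal_angles <- function(A, B) {
  s <- svd(crossprod(A, B))$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s))
}

# Deterministic substream seeding. Streams must not collide across purposes,
# so each purpose gets a disjoint offset block.
substream_seed <- function(seed, block, i) {
  stopifnot(i >= 0, i < 1e5)
  as.integer((seed + block * 1e5 + i) %% .Machine$integer.max)
}
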