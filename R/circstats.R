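#' Circular mean, resultant length and circular standard deviation
#'
#' Computes the first trigonometric moment of a sample of angles. The
#' circular SD is \code{sqrt(-2 * log(R))} where \code{R} is the mean
#' resultant length, so it is 0 for a point mass and grows without bound as
#' the sample approaches uniformity.
#'
#' @param theta angles in radians (any range; wrapped internally).
#' @param w optional non-negative weights, recycled to \code{length(theta)}.
#' @return a list with elements \code{mean} (in (-pi, pi]; \code{NA} if the
#'   resultant length is numerically zero), \code{sd}, \code{R} (mean
#'   resultant length in [0, 1]) and \code{n}.
#' @examples
#' circ_mean_sd(c(-0.1, 0, 0.1))
#' @export
circ_mean_sd <- function(theta, w = NULL) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < 1L) stop("need at least one finite angle")
  if (is.null(w)) w <- rep(1, n) else {
    w <- rep_len(w, n)
    if (any(w < 0)) stop("weights must be non-negative")
  }
  C <- sum(w * cos(theta)) / sum(w)
  S <- sum(w * sin(theta)) / sum(w)
  R <- sqrt(C^2 + S^2)
  mu <- if (R < 1e-12) NA_real_ else wrap_angle(atan2(S, C))
  sd <- if (R < 1e-12) Inf else sqrt(-2 * log(min(R, 1)))
  list(mean = mu, sd = sd, R = R, n = n)
}

#' Rayleigh test for circular non-uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the mean resultant length.
#' The p-value uses the standard analytic approximation
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))} with
#' \code{Rn = n * R}, accurate for moderate n.
#'
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @return list with \code{z} (Rayleigh statistic \code{n * R^2}), \code{p},
#'   \code{R} and \code{n}.
#' @export
rayleigh_test <- function(theta, w = NULL) {
  cm <- circ_mean_sd(theta, w)
  n <- cm$n
  if (n < 5L) warning("Rayleigh approximation unreliable for n < 5")
  Rn <- n * cm$R
  z <- Rn^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(z = z, p = min(max(p, 0), 1), R = cm$R, n = n)
}

#' Circular-linear correlation
#'
#' Association between an angular variable and a linear variable, computed
#' from the Pearson correlations of the linear variable with the sine and
#' cosine of the angle:
#' \deqn{r = \sqrt{(r_{cs}^2 + r_{ss}^2 - 2 r_{cs} r_{ss} r_{cc}) / (1 - r_{cc}^2)}}
#' where \eqn{r_{cs} = cor(\cos\theta, s)}, \eqn{r_{ss} = cor(\sin\theta, s)}
#' and \eqn{r_{cc} = cor(\cos\theta, \sin\theta)}. Significance via the
#' chi-square approximation \code{n * r^2 ~ chisq(2)}.
#'
#' @param theta angles in radians.
#' @param s linear variable, same length.
#' @return list with \code{r} in [0, 1], \code{p} and \code{n}. Returns
#'   \code{r = NA} if the linear variable is constant.
#' @export
circ_corr_cl <- function(theta, s) {
  ok <- is.finite(theta) & is.finite(s)
  theta <- theta[ok]; s <- s[ok]
  n <- length(theta)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(s) < 1e-12) return(list(r = NA_real_, p = NA_real_, n = n))
  rcs <- stats::cor(cos(theta), s)
  rss <- stats::cor(sin(theta), s)
  rcc <- stats::cor(cos(theta), sin(theta))
  r2 <- (rcs^2 + rss^2 - 2 * rcs * rss * rcc) / (1 - rcc^2)
  r <- sqrt(max(r2, 0))
  p <- stats::pchisq(n * r^2, df = 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}
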