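# Rotational-dynamics fit: PCA to a low-dimensional space, least-squares fit
# of a skew-symmetric linear dynamics matrix to the trajectory derivative,
# and extraction of the most-rotational 2-D plane (the CI plane).

#' Closed-form skew-symmetric least-squares dynamics fit
#'
#' Finds the skew-symmetric matrix M minimising ||Xdot - M X||_F. Setting
#' the skew-projected gradient to zero gives the Lyapunov-type equation
#' S M + M S = C with S = X X' (symmetric) and C = Xdot X' - X Xdot'
#' (skew), solved in the eigenbasis of S: Mtilde_ij = Ctilde_ij /
#' (lambda_i + lambda_j).
#'
#' @param X state matrix, d x T.
#' @param Xdot derivative matrix, d x T (same T).
#' @return skew-symmetric d x d matrix.
#' @export
solve_skew_ls <- function(X, Xdot) {
  stopifnot(nrow(X) == nrow(Xdot), ncol(X) == ncol(Xdot))
  S <- tcrossprod(X)
  C <- tcrossprod(Xdot, X) - tcrossprod(X, Xdot)
  es <- eigen(S, symmetric = TRUE)
  Ct <- crossprod(es$vectors, C %*% es$vectors)
  denom <- outer(es$values, es$values, `+`)
  tol <- max(es$values) * 1e-12
  Mt <- ifelse(denom > tol, Ct / denom, 0)
  M <- es$vectors %*% Mt %*% t(es$vectors)
  (M - t(M)) / 2  # clean numerical asymmetry
}

#' Fit the condition-independent rotational plane (jPCA-style)
#'
#' Centers each unit's trajectory, projects onto the top \code{n_pc}
#' principal components, estimates the derivative by central differences,
#' fits a skew-symmetric dynamics matrix by least squares, and takes the
#' plane spanned by the (real 2-D span of the) eigenvector pair with the
#' largest imaginary eigenvalue magnitude - the plane with the most
#' rotational activity.
#'
#' @param traj units x time trajectory (typically from
#'   [ci_average_by_event()] or phase-binned averaging).
#' @param n_pc number of principal components, default 6; reduced with a
#'   warning if the trajectory has lower rank.
#' @param dt time step between trajectory columns in seconds (sets the
#'   units of the rotation eigenvalues, rad/s).
#' @param periodic if TRUE the trajectory is treated as one closed cycle
#'   and derivatives use wrap-around central differences (used for
#'   phase-binned trajectories).
#' @return a \code{ci_plane}: list with \code{center} (unit means),
#'   \code{pca_basis} (units x n_pc), \code{plane2d} (n_pc x 2,
#'   orthonormal), \code{basis} (units x 2 = pca_basis %*% plane2d),
#'   \code{M} (skew matrix in PC space), \code{eigvals}, \code{omega}
#'   (|Im| of the plane's eigenvalue, rad/s), \code{n_pc}, \code{dt},
#'   alignment fields filled by [align_plane()].
#' @export
fit_jpca <- function(traj, n_pc = 6, dt = 0.01, periodic = FALSE) {
  traj <- as.matrix(traj)
  if (ncol(traj) < 3L) stop("need at least 3 time points")
  if (nrow(traj) < n_pc)
    stop("need at least n_pc units (", n_pc, "), got ", nrow(traj))
  center <- rowMeans(traj)
  tc <- traj - center
  sv <- svd(tc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < n_pc) {
    warning("trajectory rank ", rank, " < n_pc = ", n_pc,
            "; reducing to rank")
    n_pc <- max(rank, 2L)
  }
  pca_basis <- sv$u[, seq_len(n_pc), drop = FALSE]
  X <- crossprod(pca_basis, tc)  # n_pc x T scores

  T_ <- ncol(X)
  if (periodic) {
    ip <- c(2:T_, 1L); im <- c(T_, 1:(T_ - 1L))
    Xdot <- (X[, ip, drop = FALSE] - X[, im, drop = FALSE]) / (2 * dt)
    Xc <- X
  } else {
    Xdot <- (X[, 3:T_, drop = FALSE] - X[, 1:(T_ - 2L), drop = FALSE]) / (2 * dt)
    Xc <- X[, 2:(T_ - 1L), drop = FALSE]
  }
  M <- solve_skew_ls(Xc, Xdot)
  ev <- eigen(M)
  # Rank candidate planes by rotational activity: the variance the plane
  # captures times its angular velocity |Im(lambda)|. Ranking by |Im| alone
  # can promote a low-amplitude, fast-wobbling noise pair over the
  # high-amplitude population cycle on phase-averaged trajectories.
  pair_score <- vapply(seq_along(ev$values), function(k) {
    if (abs(Im(ev$values[k])) < 1e-12) return(-Inf)
    vk <- ev$vectors[, k]
    Pk <- qr.Q(qr(cbind(Re(vk), Im(vk))))[, 1:2, drop = FALSE]
    mean(colSums(crossprod(Pk, Xc)^2)) * abs(Im(ev$values[k]))
  }, numeric(1))
  k <- which.max(pair_score)
  v <- ev$vectors[, k]
  W <- cbind(Re(v), Im(v))
  plane2d <- qr.Q(qr(W))[, 1:2, drop = FALSE]
  structure(list(
    center = center,
    pca_basis = pca_basis,
    plane2d = plane2d,
    basis = pca_basis %*% plane2d,
    M = M,
    eigvals = ev$values,
    omega = abs(Im(ev$values[k])),
    n_pc = n_pc,
    dt = dt,
    aligned = FALSE,
    align_angle = NA_real_,
    flipped = FALSE
  ), class = "ci_plane")
}

# 2 x n matrix of plane projections of the (centered) rates.
project_plane <- function(plane, rm, cols = NULL) {
  R <- rm$rates
  if (!is.null(cols)) R <- R[, cols, drop = FALSE]
  crossprod(plane$basis, R - plane$center)
}

#' Align the CI plane's axes to the population firing rate
#'
#' Fixes the within-plane rotation and orientation conventions: first the
#' rotation sign is set so the average phase velocity is positive
#' (counter-clockwise cycling, CIy lagging CIx by pi/2); then the axes are
#' rotated so +CIx points at the plane angle with the largest
#' population-average (raw, pre-sqrt) firing rate, computed by binning all
#' samples by their angle in the plane (default 36 bins of 10 degrees,
#' empty bins interpolated circularly). Because the CI phase is read off
#' the Hilbert transform rather than the geometric angle, the geometric
#' rotation is followed by \code{n_refine} refinement rotations that bin
#' the population rate by the instantaneous CI phase itself and rotate so
#' the maximum-rate phase (parabolic sub-bin interpolation around the
#' peak bin) sits at zero, making the CI-phase origin self-consistent
#' with the rate convention.
#'
#' @param plane a \code{ci_plane} from [fit_jpca()].
#' @param rm the session \code{rate_matrix}.
#' @param segments optional list of contiguous column ranges restricting
#'   which samples vote (e.g. training trials only).
#' @param n_angle_bins number of angle bins, default 36.
#' @param n_refine phase-binned refinement rotations, default 2.
#' @return the plane with rotated/flipped \code{plane2d} and \code{basis},
#'   \code{aligned = TRUE}, and the applied \code{align_angle}.
#' @export
align_plane <- function(plane, rm, segments = NULL, n_angle_bins = 36,
                        n_refine = 2) {
  if (is.null(segments)) segments <- list(seq_along(rm$bin_times))
  cols <- unlist(segments)
  pr <- rm$pop_rate[cols]
  if (stats::sd(pr) < 1e-9) {
    warning("population rate is constant; plane alignment undefined, ",
            "keeping identity")
    plane$aligned <- TRUE
    plane$align_angle <- 0
    return(plane)
  }
  P <- project_plane(plane, rm, cols)

  # rotation-sign convention: mean phase velocity must be positive
  mean_dphi <- function(P) {
    dp <- numeric(0)
    off <- 0L
    for (s in segments) {
      if (length(s) < 3L) { off <- off + length(s); next }
      ang <- atan2(P[2, off + seq_along(s)], P[1, off + seq_along(s)])
      dp <- c(dp, wrap_angle(diff(ang)))
      off <- off + length(s)
    }
    mean(dp)
  }
  if (mean_dphi(P) < 0) {
    plane$plane2d[, 2] <- -plane$plane2d[, 2]
    plane$basis <- plane$pca_basis %*% plane$plane2d
    plane$flipped <- TRUE
    P <- project_plane(plane, rm, cols)
  }

  ang <- atan2(P[2, ], P[1, ])
  theta_star <- max_rate_angle(ang, pr, n_angle_bins)
  plane <- rotate_plane(plane, theta_star)
  total <- theta_star

  # refine using the Hilbert phase so that CI phase 0 marks peak rate
  for (r in seq_len(n_refine)) {
    ph <- project_and_phase(rm, plane, segments)
    ok <- !is.na(ph$ci_phi)
    th <- max_rate_angle(ph$ci_phi[ok], rm$pop_rate[ph$col[ok]], n_angle_bins)
    plane <- rotate_plane(plane, th)
    total <- total + th
  }
  plane$align_angle <- wrap_angle(total)
  plane$aligned <- TRUE
  plane
}

# Angle of maximum mean rate: bin the rates by angle (equalising occupancy),
# interpolate empty bins, then estimate the preferred angle as the phase of
# the profile's first circular harmonic (the rate-weighted resultant). This
# is the standard preferred-phase estimator and is far less sensitive to
# bin noise on a broad peak than the raw argmax bin.
max_rate_angle <- function(ang, rate, n_bins) {
  bin <- pmin(floor((ang + pi) / (2 * pi / n_bins)) + 1L, n_bins)
  mr <- rep(NA_real_, n_bins)
  agg <- tapply(rate, bin, mean)
  mr[as.integer(names(agg))] <- agg
  mr <- interp_circular_gaps(mr)
  centers <- -pi + (seq_len(n_bins) - 0.5) * (2 * pi / n_bins)
  z <- sum((mr - mean(mr)) * exp(1i * centers))
  if (Mod(z) < 1e-12) return(centers[which.max(mr)])
  Arg(z)
}

rotate_plane <- function(plane, theta) {
  ct <- cos(theta); st <- sin(theta)
  b1 <- plane$plane2d[, 1]; b2 <- plane$plane2d[, 2]
  plane$plane2d <- cbind(ct * b1 + st * b2, -st * b1 + ct * b2)
  plane$basis <- plane$pca_basis %*% plane$plane2d
  plane
}
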