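#' Mean-square displacement over lag times
#'
#' `<|r(t0 + tau) - r(t0)|^2>` averaged over all particles and all time
#' origins, from an `n_frames x M x 3` trajectory array (e.g.
#' `samples$mnp_pos` from [run_dynamics()]).
#'
#' @param traj trajectory array, `n_frames x M x 3`, frames equally spaced.
#' @param dt time between consecutive frames (lag axis scaling).
#' @return Data frame with `lag` (in time units) and `msd`.
#' @export
msd <- function(traj, dt = 1) {
  stopifnot(length(dim(traj)) == 3)
  nf <- dim(traj)[1]
  if (nf < 2) stop("need at least 2 frames for an MSD")
  out <- numeric(nf - 1)
  for (tau in seq_len(nf - 1)) {
    d <- traj[(tau + 1):nf, , , drop = FALSE] -
      traj[seq_len(nf - tau), , , drop = FALSE]
    out[tau] <- mean(apply(d^2, c(1, 2), sum))
  }
  data.frame(lag = seq_len(nf - 1) * dt, msd = out)
}

#' Log-log slope of an MSD curve
#'
#' Least-squares slope of `log(msd)` against `log(lag)` over a lag window;
#' 1 for free diffusion, below 1 for hindered (aggregated) motion, 2 for
#' ballistic motion.
#'
#' @param series data frame with `lag` and `msd` columns (from [msd()]).
#' @param window range of lags `c(min, max)` used for the fit; `NULL` uses
#'   all positive entries.
#' @return Fitted exponent.
#' @export
msd_linearity_ratio <- function(series, window = NULL) {
  s <- series[series$lag > 0 & series$msd > 0, ]
  if (!is.null(window))
    s <- s[s$lag >= window[1] & s$lag <= window[2], ]
  if (nrow(s) < 2) stop("not enough positive lag points for a slope")
  unname(coef(stats::lm(log(msd) ~ log(lag), data = s))[2])
}

#' Aspect ratio of the vesicle cross-section
#'
#' Primary estimator: from the covariance matrix of the outer-shell node
#' positions, `sqrt(v_par / v_perp)` where `v_par` is the variance along
#' the field direction and `v_perp` the geometric mean of the two
#' transverse principal variances. 1 for a sphere; for a cloud affinely
#' stretched by a factor s along the field it returns exactly s.
#'
#' @param x an [mps_state()] (outer-shell nodes are used) or an `n x 3`
#'   position matrix.
#' @param h field direction (normalised internally).
#' @return Dimensionless aspect ratio.
#' @export
aspect_ratio <- function(x, h = c(0, 0, 1)) {
  pos <- if (inherits(x, "mps_state")) {
    if (is.null(x$pair)) stop("state has no outer shell")
    x$pair$outer$positions
  } else as.matrix(x)
  if (nrow(pos) < 4) stop("need at least 4 nodes for an aspect ratio")
  h <- h / sqrt(sum(h^2))
  C <- cov(pos)
  v_par <- drop(t(h) %*% C %*% h)
  # transverse principal variances: eigenvalues of C restricted to h-perp
  B <- diag(3) - tcrossprod(h)
  Ct <- B %*% C %*% B
  ev <- sort(eigen(Ct, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)[1:2]
  if (any(ev <= 0) || v_par <= 0)
    stop("degenerate node set: zero variance direction")
  sqrt(v_par / sqrt(ev[1] * ev[2]))
}

#' Slab (cross-section) aspect-ratio estimator
#'
#' Fidelity cross-check of [aspect_ratio()]: keeps only nodes within
#' distance `delta` of a central plane containing the field direction, and
#' returns the axis ratio of the 2D covariance ellipse of those nodes in
#' the cutting plane (field axis over transverse axis).
#'
#' @inheritParams aspect_ratio
#' @param delta slab half-thickness, reduced units.
#' @export
aspect_ratio_slab <- function(x, h = c(0, 0, 1), delta = 1.0) {
  pos <- if (inherits(x, "mps_state")) x$pair$outer$positions else as.matrix(x)
  h <- h / sqrt(sum(h^2))
  # plane normal: any direction perpendicular to h
  ref <- if (abs(h[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  nrm <- .cross3(h, ref)
  nrm <- nrm / sqrt(sum(nrm^2))
  tang <- .cross3(nrm, h)                     # in-plane transverse axis
  keep <- abs(pos %*% nrm) < delta
  if (sum(keep) < 4) stop("slab too thin: fewer than 4 nodes selected")
  q <- cbind(pos[keep, , drop = FALSE] %*% h,
             pos[keep, , drop = FALSE] %*% tang)
  ev <- diag(cov(q))
  sqrt(ev[1] / ev[2])
}

#' Cluster statistics of the particle ensemble
#'
#' Single-linkage clustering with the dipolar-fluid bond criterion
#' `r_ij < 1.3 a`: two particles belong to the same cluster if connected by
#' a path of bonded pairs. Reports the cluster-size histogram, the largest
#' cluster and the bonded fraction (particles in clusters of size >= 2).
#'
#' @param pos `M x 3` particle positions (or a [nanoparticle_ensemble()]).
#' @param a_red reduced particle diameter.
#' @param bond_factor bond criterion multiplier (default 1.3).
#' @return List with `sizes` (per-cluster sizes), `histogram` (table of
#'   sizes), `largest`, `bonded_fraction`, `n_clusters`.
#' @export
cluster_stats <- function(pos, a_red = 1.2, bond_factor = 1.3) {
  if (inherits(pos, "nanoparticle_ensemble")) {
    a_red <- pos$a_red
    pos <- pos$pos
  }
  M <- nrow(pos)
  if (M == 0)
    return(list(sizes = integer(0), histogram = table(integer(0)),
                largest = 0L, bonded_fraction = 0, n_clusters = 0L))
  if (M == 1)
    return(list(sizes = 1L, histogram = table(1L), largest = 1L,
                bonded_fraction = 0, n_clusters = 1L))
  hc <- stats::hclust(stats::dist(pos), method = "single")
  memb <- stats::cutree(hc, h = bond_factor * a_red)
  sizes <- as.integer(table(memb))
  list(sizes = sizes, histogram = table(sizes),
       largest = max(sizes),
       bonded_fraction = sum(sizes[sizes >= 2]) / M,
       n_clusters = length(sizes))
}

#' Reduced magnetization along the field
#'
#' Mean direction cosine `<e_i . h>` of the dipole orientations; lies
#' between -1 and 1.
#'
#' @param orient `M x 3` unit orientation matrix (or an ensemble).
#' @param h field direction.
#' @export
magnetization <- function(orient, h = c(0, 0, 1)) {
  if (inherits(orient, "nanoparticle_ensemble")) orient <- orient$orient
  if (nrow(orient) == 0) stop("empty ensemble")
  h <- h / sqrt(sum(h^2))
  mean(orient %*% h)
}

#' Sigmoid fit of an aspect-ratio field sweep
#'
#' Four-parameter logistic
#' `AR(xi) = ar0 + (ar_inf - ar0) / (1 + exp(-(xi - xi_half)/width))`
#' fitted by Levenberg-Marquardt least squares; this is the smooth-curve
#' model used for field-sweep summaries.
#'
#' @param xi_values field levels (>= 5 points).
#' @param ar_values measured aspect ratios.
#' @return List with `ar0`, `ar_inf`, `xi_half`, `width`, `residual_norm`,
#'   `converged`, and `degenerate` (TRUE when the data are flat and the
#'   width is unidentifiable).
#' @export
fit_sigmoid <- function(xi_values, ar_values) {
  stopifnot(length(xi_values) == length(ar_values))
  if (length(xi_values) < 5) stop("need at least 5 points for a sigmoid fit")
  span <- diff(range(ar_values))
  if (span < 1e-10 * max(abs(ar_values), 1)) {
    return(list(ar0 = mean(ar_values), ar_inf = mean(ar_values),
                xi_half = mean(range(xi_values)),
                width = NA_real_, residual_norm = 0,
                converged = TRUE, degenerate = TRUE))
  }
  start <- list(ar0 = min(ar_values), ar_inf = max(ar_values),
                xi_half = stats::approx(ar_values, xi_values,
                                        xout = mean(range(ar_values)),
                                        ties = mean)$y,
                width = diff(range(xi_values)) / 5)
  if (!is.finite(start$xi_half)) start$xi_half <- mean(range(xi_values))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ar ~ ar0 + (ar_inf - ar0) / (1 + exp(-(xi - xi_half) / width)),
      data = data.frame(xi = xi_values, ar = ar_values),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ar0 = NA_real_, ar_inf = NA_real_, xi_half = NA_real_,
                width = NA_real_, residual_norm = NA_real_,
                converged = FALSE, degenerate = FALSE))
  }
  cf <- coef(fit)
  list(ar0 = unname(cf["ar0"]), ar_inf = unname(cf["ar_inf"]),
       xi_half = unname(cf["xi_half"]), width = unname(cf["width"]),
       residual_norm = sqrt(sum(resid(fit)^2)),
       converged = TRUE, degenerate = FALSE)
}
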