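#' Kinematic feature extraction
#'
#' Converts a 3D wall-point trajectory into the 5-channel feature series the
#' network consumes: scalar speed, scalar acceleration magnitude, and the
#' smoothness-of-motion angles formed at each point by its temporal
#' neighbors, projected onto the XY, XZ and YZ coordinate planes.
#'
#' @name kinematics
NULL

#' Create a trajectory object
#'
#' @param coords `T x 3` numeric matrix of positions (mm).
#' @param rate Sampling rate in Hz.
#' @param point_id,patient_id Identifiers.
#' @param label `0` (TW), `1` (HR) or `NA` (unlabeled).
#' @return Object of class `wm_trajectory`.
#' @export
wm_trajectory <- function(coords, rate = 100, point_id = "p1",
                          patient_id = "pat1", label = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (nrow(coords) < 3) stop("trajectory needs at least 3 samples")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("label must be 0, 1 or NA (unlabeled)")
  structure(list(point_id = as.character(point_id),
                 patient_id = as.character(patient_id),
                 label = as.integer(label), coords = unname(coords),
                 rate = rate),
            class = "wm_trajectory")
}

#' @export
print.wm_trajectory <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabeled" else c("TW", "HR")[x$label + 1]
  cat(sprintf("<wm_trajectory %s / %s: %d samples @ %g Hz, %s>\n",
              x$patient_id, x$point_id, nrow(x$coords), x$rate, lab))
  invisible(x)
}

#' Cubic-spline trajectory upsampling
#'
#' Upsamples each coordinate with a natural cubic spline to `rate * factor`,
#' reproducing the original samples exactly at their time points.
#' `factor = 1` returns the input unchanged.
#'
#' @param traj A [wm_trajectory()].
#' @param factor Integer upsampling factor, >= 1.
#' @return A [wm_trajectory()] at the higher rate.
#' @export
interpolate_trajectory <- function(traj, factor = 5L) {
  stopifnot(inherits(traj, "wm_trajectory"))
  if (length(factor) != 1 || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be an integer >= 1")
  if (factor == 1) return(traj)
  TT <- nrow(traj$coords)
  if (TT < 4) stop("nonlinear interpolation needs at least 4 samples")
  t0 <- (seq_len(TT) - 1) / traj$rate
  tn <- seq(0, t0[TT], by = 1 / (traj$rate * factor))
  new <- vapply(1:3, function(j)
    stats::splinefun(t0, traj$coords[, j], method = "natural")(tn),
    numeric(length(tn)))
  out <- traj
  out$coords <- new
  out$rate <- traj$rate * factor
  out
}

#' Speed series
#'
#' Forward-difference speed: `||p[t+1] - p[t]|| * rate`, length `T - 1`,
#' units mm/s.
#'
#' @param traj A [wm_trajectory()].
#' @return Numeric vector.
#' @export
compute_speed <- function(traj) {
  stopifnot(inherits(traj, "wm_trajectory"))
  d <- diff(traj$coords)
  sqrt(rowSums(d^2)) * traj$rate
}

#' Acceleration-magnitude series
#'
#' Central second difference: `||p[t+1] - 2 p[t] + p[t-1]|| * rate^2`,
#' length `T - 2`, units mm/s^2.
#'
#' @param traj A [wm_trajectory()].
#' @return Numeric vector.
#' @export
compute_acceleration <- function(traj) {
  stopifnot(inherits(traj, "wm_trajectory"))
  p <- traj$coords
  TT <- nrow(p)
  d2 <- p[3:TT, , drop = FALSE] - 2 * p[2:(TT - 1), , drop = FALSE] +
    p[1:(TT - 2), , drop = FALSE]
  sqrt(rowSums(d2^2)) * traj$rate^2
}

# Vertex angle at b between segments b->a and b->c for 2-column matrices.
# Degenerate segments (length < 1e-9) read as "no turn": angle pi.
planar_vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  ang <- rep(pi, nrow(b))
  ok <- nu >= 1e-9 & nv >= 1e-9
  if (any(ok)) {
    cosv <- rowSums(u[ok, , drop = FALSE] * v[ok, , drop = FALSE]) /
      (nu[ok] * nv[ok])
    ang[ok] <- acos(pmin(1, pmax(-1, cosv)))
  }
  ang
}

#' Planar smoothness-of-motion angles
#'
#' For each interior point `p[t]`, the angle at the vertex `p[t]` between the
#' segments to `p[t-1]` and `p[t+1]`, after projecting the three points onto
#' the XY, XZ and YZ planes. Angles lie in `[0, pi]`; collinear (straight)
#' motion gives `pi`, and a projected segment shorter than 1e-9 mm is treated
#' as no turn (angle `pi`).
#'
#' @param traj A [wm_trajectory()].
#' @return `3 x (T - 2)` matrix with rows `angle_xy`, `angle_xz`, `angle_yz`.
#' @export
compute_planar_angles <- function(traj) {
  stopifnot(inherits(traj, "wm_trajectory"))
  p <- traj$coords
  TT <- nrow(p)
  planes <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- matrix(NA_real_, 3, TT - 2,
                dimnames = list(c("angle_xy", "angle_xz", "angle_yz"), NULL))
  for (i in seq_along(planes)) {
    q <- p[, planes[[i]], drop = FALSE]
    out[i, ] <- planar_vertex_angle(q[1:(TT - 2), , drop = FALSE],
                                    q[2:(TT - 1), , drop = FALSE],
                                    q[3:TT, , drop = FALSE])
  }
  out
}

#' Build the 5-channel feature series
#'
#' Stacks speed, acceleration and the three planar angles, aligned to a
#' common length `L = T' - 2` (the first speed sample is dropped), where `T'`
#' is the sample count after optional spline upsampling.
#'
#' @param traj A [wm_trajectory()].
#' @param factor Interpolation factor passed to [interpolate_trajectory()].
#' @return Object of class `wm_features_single`: list with `values`
#'   (`5 x L` matrix, rows `speed`, `accel`, `angle_xy`, `angle_xz`,
#'   `angle_yz`), `rate`, and the trajectory identifiers.
#' @export
build_feature_series <- function(traj, factor = 1L) {
  stopifnot(inherits(traj, "wm_trajectory"))
  traj <- interpolate_trajectory(traj, factor)
  if (nrow(traj$coords) < 3) stop("need at least 3 samples for features")
  sp <- compute_speed(traj)
  ac <- compute_acceleration(traj)
  an <- compute_planar_angles(traj)
  vals <- rbind(speed = sp[-1], accel = ac, an)
  structure(list(values = vals, rate = traj$rate, point_id = traj$point_id,
                 patient_id = traj$patient_id, label = traj$label),
            class = "wm_features_single")
}

#' Feature channel names
#' @return Character vector of the 5 channel names in order.
#' @export
feature_channels <- function() {
  c("speed", "accel", "angle_xy", "angle_xz", "angle_yz")
}

#' Build a feature batch from a list of trajectories
#'
#' @param trajs List of [wm_trajectory()] objects with equal sample counts.
#' @param factor Interpolation factor.
#' @return Object of class `wm_features`: list with `x` (array
#'   `n x 5 x L`), `y` (labels, `NA` = unlabeled), `patient`, `point_id`.
#' @export
build_feature_batch <- function(trajs, factor = 1L) {
  stopifnot(length(trajs) >= 1)
  fs <- lapply(trajs, build_feature_series, factor = factor)
  Ls <- vapply(fs, function(f) ncol(f$values), integer(1))
  if (length(unique(Ls)) != 1)
    stop("trajectories yield unequal feature lengths")
  L <- Ls[1]
  x <- array(0, c(length(fs), 5, L),
             dimnames = list(NULL, feature_channels(), NULL))
  for (i in seq_along(fs)) x[i, , ] <- fs[[i]]$values
  structure(list(
    x = x,
    y = vapply(fs, function(f) f$label, integer(1)),
    patient = vapply(fs, function(f) f$patient_id, character(1)),
    point_id = vapply(fs, function(f) f$point_id, character(1))),
    class = "wm_features")
}
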