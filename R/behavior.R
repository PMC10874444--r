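## Head-movement and gaze analyses.
##
## Head orientation is decomposed into Tait-Bryan angles in intrinsic
## y-x-z order (yaw about the vertical axis first, then pitch, then
## roll) in a right-handed frame with x right, y up, z backward.
## Angular velocities are computed per component after unwrapping;
## observers are classified dynamic/static by a velocity threshold.
## Gaze spread is summarized as the solid angle of the smallest
## density superlevel set holding a given mass of the gaze-direction
## kernel density estimate.

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Convert unit quaternions to Tait-Bryan angles (y-x-z)
#'
#' Decomposes each orientation as an intrinsic rotation sequence: yaw
#' about y (vertical, positive turning left), then pitch about x, then
#' roll about z, in a right-handed frame with y up and z backward.  At
#' gimbal lock (pitch approaching +/-90 degrees) roll is set to 0 and
#' yaw absorbs the remaining rotation.
#'
#' @param q Numeric vector `c(w, x, y, z)` or a 4-column matrix of unit
#'   quaternions (rows).
#' @param tol Unit-norm tolerance.
#' @return Matrix with columns `yaw`, `pitch`, `roll` in degrees.
#' @export
quaternion_to_tait_bryan <- function(q, tol = 1e-6) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != 4L) stopf("quaternions must have 4 components (w, x, y, z)")
  nrm <- sqrt(rowSums(q^2))
  if (any(abs(nrm - 1) > tol)) {
    stopf("non-unit quaternion (norm deviates from 1 by more than %g)", tol)
  }
  q <- q / nrm
  out <- t(apply(q, 1L, function(qi) {
    m <- quat_to_matrix(qi)
    s_pitch <- -m[2, 3]
    if (abs(s_pitch) > 1 - 1e-9) {        # gimbal lock
      pitch <- asin(max(-1, min(1, s_pitch)))
      yaw <- atan2(-m[3, 1], m[1, 1])
      roll <- 0
    } else {
      pitch <- asin(s_pitch)
      yaw <- atan2(m[1, 3], m[3, 3])
      roll <- atan2(m[2, 1], m[2, 2])
    }
    c(yaw, pitch, roll)
  }))
  out <- rad2deg(out)
  colnames(out) <- c("yaw", "pitch", "roll")
  out
}

#' @rdname quaternion_to_tait_bryan
#' @param yaw,pitch,roll Angles in degrees (vectors of equal length).
#' @return `tait_bryan_to_quaternion()` returns a 4-column matrix of
#'   unit quaternions `(w, x, y, z)` composing the y-x-z sequence.
#' @export
tait_bryan_to_quaternion <- function(yaw, pitch, roll) {
  n <- length(yaw)
  out <- matrix(NA_real_, nrow = n, ncol = 4)
  colnames(out) <- c("w", "x", "y", "z")
  hy <- deg2rad(yaw) / 2; hp <- deg2rad(pitch) / 2; hr <- deg2rad(roll) / 2
  for (i in seq_len(n)) {
    qy <- c(cos(hy[i]), 0, sin(hy[i]), 0)
    qx <- c(cos(hp[i]), sin(hp[i]), 0, 0)
    qz <- c(cos(hr[i]), 0, 0, sin(hr[i]))
    out[i, ] <- quat_multiply(quat_multiply(qy, qx), qz)
  }
  out
}

# Remove +/-360 degree jumps from an angle series.
unwrap_deg <- function(a) {
  d <- diff(a)
  jumps <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
  a + jumps
}

#' Angular velocity of a head trace
#'
#' Converts the quaternion trace to Tait-Bryan angles, unwraps each
#' component past +/-180 degree jumps, and differentiates with central
#' differences in the interior and one-sided differences at the ends.
#'
#' @param trace A `head_trace` data frame (`t`, `qw`, `qx`, `qy`, `qz`).
#' @return A data frame with columns `t`, `vyaw`, `vpitch`, `vroll` in
#'   degrees per second.
#' @export
angular_velocity <- function(trace) {
  if (nrow(trace) < 2L) stopf("need at least 2 samples")
  if (any(diff(trace$t) <= 0)) stopf("timestamps must be strictly increasing")
  ang <- quaternion_to_tait_bryan(as.matrix(trace[, c("qw", "qx", "qy", "qz")]))
  ang <- apply(ang, 2L, unwrap_deg)
  t <- trace$t
  n <- length(t)
  deriv <- function(y) {
    v <- numeric(n)
    v[1] <- (y[2] - y[1]) / (t[2] - t[1])
    v[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    if (n > 2L) {
      i <- 2:(n - 1)
      v[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
    }
    v
  }
  data.frame(t = t, vyaw = deriv(ang[, 1]), vpitch = deriv(ang[, 2]),
             vroll = deriv(ang[, 3]))
}

#' Mean absolute angular velocity per component
#'
#' @param trace A `head_trace`.
#' @return Named vector `c(yaw=, pitch=, roll=)` of mean absolute
#'   velocities in degrees per second.
#' @export
mean_abs_velocity <- function(trace) {
  v <- angular_velocity(trace)
  c(yaw = mean(abs(v$vyaw)), pitch = mean(abs(v$vpitch)),
    roll = mean(abs(v$vroll)))
}

#' Classify an observer as dynamic or static
#'
#' An observer is dynamic iff the mean absolute velocity of any rotation
#' component strictly exceeds the threshold (default 10 deg/s).
#'
#' @param mean_velocities Named or unnamed numeric vector of per-
#'   component mean absolute velocities (deg/s).
#' @param threshold Velocity threshold in deg/s (> 0).
#' @return `"dynamic"` or `"static"`.
#' @export
classify_movement <- function(mean_velocities, threshold = 10) {
  if (threshold <= 0) stopf("`threshold` must be positive")
  if (any(mean_velocities > threshold)) "dynamic" else "static"
}

# Binocular gaze direction: normalized average of the two eyes' unit
# direction vectors, expressed as (lon, lat) in degrees.
binocular_lonlat <- function(samples) {
  m <- cbind((samples$lx + samples$rx) / 2,
             (samples$ly + samples$ry) / 2,
             (samples$lz + samples$rz) / 2)
  m <- m / sqrt(rowSums(m^2))
  vec_to_lonlat(m)
}

#' Gaze-density area in the field of view
#'
#' Estimates the gaze-direction density with an isotropic Gaussian
#' kernel density estimate on the longitude/latitude plane (default
#' bandwidth 2 degrees), finds the smallest density superlevel set
#' containing the requested probability mass (default 95%), and
#' integrates that set's solid angle with cos(latitude) weighting.
#'
#' @param samples A `gaze_samples` data frame, or a two-column matrix of
#'   `(lon, lat)` in degrees.
#' @param bandwidth Kernel sd in degrees (> 0).
#' @param mass Density mass of the superlevel set, in (0, 1).
#' @param grid_spacing Evaluation-grid spacing in degrees.
#' @return Covered area as a percentage of the half-sphere (2 pi sr).
#' @export
gaze_area <- function(samples, bandwidth = 2, mass = 0.95,
                      grid_spacing = 0.5) {
  if (bandwidth <= 0) stopf("`bandwidth` must be positive")
  if (mass <= 0 || mass >= 1) stopf("`mass` must lie in (0, 1)")
  ll <- if (is.data.frame(samples) && "lx" %in% names(samples)) {
    binocular_lonlat(samples)
  } else {
    as.matrix(samples)
  }
  if (nrow(ll) < 2L) stopf("need at least 2 gaze samples")
  pad <- 4 * bandwidth
  lon <- seq(min(ll[, 1]) - pad, max(ll[, 1]) + pad, by = grid_spacing)
  lat <- seq(min(ll[, 2]) - pad, max(ll[, 2]) + pad, by = grid_spacing)
  # separable kernel: density grid = Klon %*% t(Klat) / n
  klon <- outer(lon, ll[, 1], function(g, s) dnorm(g - s, sd = bandwidth))
  klat <- outer(lat, ll[, 2], function(g, s) dnorm(g - s, sd = bandwidth))
  dens <- (klon %*% t(klat)) / nrow(ll)
  cell_mass <- as.vector(dens) * grid_spacing^2
  lat_g <- rep(lat, each = length(lon))
  o <- order(as.vector(dens), decreasing = TRUE)
  cum <- cumsum(cell_mass[o])
  k <- which(cum >= mass * sum(cell_mass))[1]
  sel <- o[seq_len(k)]
  solid <- sum(grid_spacing^2 * cos(deg2rad(lat_g[sel]))) * (pi / 180)^2
  100 * solid / (2 * pi)
}

#' @importFrom stats dnorm
NULL

#' Mann-Whitney U rank test
#'
#' Rank-sum U statistic with midranks for ties.  The two-sided p-value
#' comes from exact enumeration of all group assignments when the
#' pooled sample size is at most 12, and from the normal approximation
#' with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `u` (U statistic of `group_a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stopf("both groups must be non-empty")
  }
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_stat <- function(idx_a) sum(r[idx_a]) - na * (na + 1) / 2
  u <- u_stat(seq_len(na))
  mu <- na * nb / 2
  if (na + nb <= 12L) {
    combos <- combn(na + nb, na)
    us <- apply(combos, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(r)
    sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    # all observations tied: U is degenerate at its mean
    p <- if (sigma2 == 0) 1 else min(1, 2 * pnorm(-abs(u - mu) / sqrt(sigma2)))
    method <- "normal"
  }
  list(u = u, p = p, method = method)
}

#' Full-interaction linear model of scale value on lens and behavior
#'
#' Ordinary least squares of the normalized scale value on Sph, Add,
#' head-movement group and gaze area with all two-, three- and four-way
#' interactions.  Continuous predictors are centered; the movement
#' group enters as a 0/1 indicator (dynamic = 1).  Under the null of no
#' behavior-perception link, the behavior terms should be significant
#' only at the nominal false-positive rate.
#'
#' @param table Data frame with columns `value`, `sph`, `add`,
#'   `movement_class` (`"dynamic"`/`"static"`, logical or 0/1) and
#'   `gaze_area`.
#' @return Data frame with columns `term`, `estimate`, `se`, `t`, `p`.
#' @export
behavior_ols <- function(table) {
  need <- c("value", "sph", "add", "movement_class", "gaze_area")
  if (!all(need %in% names(table))) {
    stopf("`table` must have columns %s", paste(need, collapse = ", "))
  }
  cls <- table$movement_class
  if (is.character(cls) || is.factor(cls)) {
    cls <- as.integer(as.character(cls) == "dynamic")
  } else {
    cls <- as.integer(cls)
  }
  d <- data.frame(value = table$value,
                  sph = table$sph - mean(table$sph),
                  add = table$add - mean(table$add),
                  moving = cls,
                  gaze = table$gaze_area - mean(table$gaze_area))
  fit <- lm(value ~ sph * add * moving * gaze, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stopf("rank-deficient design; collinear terms: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL)
}
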