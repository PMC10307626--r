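# Internal rigid-body geometry: rotations, Kabsch superposition and the
# decomposition of a rigid transform into screw (helical) parameters.
# Coordinates are N x 3 matrices in Angstrom throughout.

#' @noRd
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Rodrigues rotation matrix about unit axis `u` by `theta` radians.
#' @noRd
rotation_about_axis <- function(u, theta) {
  u <- unit_vector(u)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(u)
}

# Minimal rotation taking unit vector a onto unit vector b.
#' @noRd
rotation_between <- function(a, b) {
  a <- unit_vector(a); b <- unit_vector(b)
  c_ab <- sum(a * b)
  if (c_ab > 1 - 1e-12) return(diag(3))
  if (c_ab < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit_vector(ref - sum(ref * a) * a)
    return(rotation_about_axis(perp, pi))
  }
  axis <- unit_vector(c(a[2] * b[3] - a[3] * b[2],
                        a[3] * b[1] - a[1] * b[3],
                        a[1] * b[2] - a[2] * b[1]))
  rotation_about_axis(axis, acos(max(-1, min(1, c_ab))))
}

# Apply x' = R (x - centre) + centre + shift to an N x 3 matrix.
#' @noRd
apply_rigid <- function(xyz, R, centre = c(0, 0, 0), shift = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, centre) %*% t(R), 2, centre + shift, `+`)
}

# Least-squares (Kabsch) rigid fit mapping X onto Y: y ~ R x + t.
# Returns R (proper rotation), t, and the residual RMSD.
#' @noRd
kabsch_fit <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cy - as.vector(R %*% cx)
  fitted <- sweep(X %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

# Decompose a rigid transform (R, t) into screw parameters: rotation angle
# about and translation along the screw axis, plus a point on the axis.
# The axis is oriented so that the translation component (rise) is >= 0;
# the angle sign then follows the right-hand rule about that axis.
#' @noRd
screw_decompose <- function(R, t, angle_tol = 1e-9) {
  tr <- sum(diag(R))
  cos_theta <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cos_theta)

  if (theta < angle_tol) {
    # pure translation
    rise <- sqrt(sum(t^2))
    axis <- if (rise > .Machine$double.eps) t / rise else c(0, 0, 1)
    return(list(axis = axis, angle = 0, rise = rise,
                point = c(0, 0, 0), degenerate = FALSE))
  }
  if (abs(theta - pi) < 1e-6) {
    # axis recoverable from R + I but the angle sign is ambiguous
    M <- R + diag(3)
    axis <- unit_vector(M[, which.max(colSums(M^2))])
    rise <- sum(t * axis)
    if (rise < 0) axis <- -axis
    return(list(axis = axis, angle = pi, rise = abs(rise),
                point = rep(NA_real_, 3), degenerate = TRUE))
  }

  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  rise <- sum(t * axis)
  if (rise < 0) {
    axis <- -axis
    theta <- -theta
    rise <- -rise
  }
  # point on the axis: solve (I - R) p = t_perp in the plane normal to axis
  t_perp <- t - sum(t * axis) * axis
  cross_at <- c(axis[2] * t_perp[3] - axis[3] * t_perp[2],
                axis[3] * t_perp[1] - axis[1] * t_perp[3],
                axis[1] * t_perp[2] - axis[2] * t_perp[1])
  point <- 0.5 * (t_perp + cross_at / tan(theta / 2))
  list(axis = axis, angle = theta, rise = rise, point = point,
       degenerate = FALSE)
}

# Minimum interatomic distance between two coordinate sets using a cell
# list (cells of width `cutoff`); exact for any pair closer than `cutoff`.
# Returns list(min_dist, i, j) where (i, j) index the worst pair, or
# min_dist = Inf when no pair is within cutoff.
#' @noRd
min_cross_distance <- function(A, B, cutoff = 5) {
  key <- function(M) {
    g <- floor(sweep(M, 2, orig) / cutoff)
    paste(g[, 1], g[, 2], g[, 3], sep = ",")
  }
  orig <- pmin(apply(A, 2, min), apply(B, 2, min))
  kb <- split(seq_len(nrow(B)), key(B))
  ga <- floor(sweep(A, 2, orig) / cutoff)
  best <- list(min_dist = Inf, i = NA_integer_, j = NA_integer_)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    for (k in seq_len(27)) {
      cell <- paste(ga[i, 1] + offsets[k, 1], ga[i, 2] + offsets[k, 2],
                    ga[i, 3] + offsets[k, 3], sep = ",")
      js <- kb[[cell]]
      if (is.null(js)) next
      d2 <- colSums((t(B[js, , drop = FALSE]) - A[i, ])^2)
      m <- which.min(d2)
      if (d2[m] < best$min_dist^2) {
        best <- list(min_dist = sqrt(d2[m]), i = i, j = js[m])
      }
    }
  }
  best
}

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
rad2deg <- function(x) x * 180 / pi

# Circular mean of angles in degrees.
#' @noRd
circular_mean_deg <- function(x) {
  rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x)))))
}
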