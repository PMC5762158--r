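#' Helical symmetry parameters
#'
#' A helical lattice is described by the axial rise (Angstrom) and azimuthal
#' twist (degrees) relating consecutive asymmetric units about the helix axis.
#' Actin filaments are handled as a 1-start helix with the axis along +z;
#' a negative twist is a clockwise rotation per subunit viewed from +z
#' (the left-handed 1-start genetic helix of actin).
#'
#' @param rise axial translation per subunit, Angstrom (> 0)
#' @param twist rotation per subunit, degrees; normalized to (-180, 180]
#' @return object of class `helical_symmetry` with fields `rise` and `twist`
#' @examples
#' helical_symmetry(28.06, -166.73)
#' @export
helical_symmetry <- function(rise, twist) {
  stopifnot(is.numeric(rise), length(rise) == 1L, is.finite(rise), rise > 0,
            is.numeric(twist), length(twist) == 1L, is.finite(twist))
  structure(list(rise = rise, twist = wrap_twist(twist)),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: rise %.3f A, twist %.3f deg per subunit\n",
              x$rise, x$twist))
  invisible(x)
}

#' Wrap an angle into the twist convention
#'
#' Angles are stored in the half-open interval (-180, 180], congruent to the
#' input modulo 360. Idempotent.
#'
#' @param angle_deg finite angle in degrees (vectorized)
#' @return wrapped angle(s) in (-180, 180]
#' @examples
#' wrap_twist(193.27)  # -166.73
#' wrap_twist(-180)    # 180
#' @export
wrap_twist <- function(angle_deg) {
  if (!all(is.finite(angle_deg))) stop("wrap_twist: non-finite angle")
  a <- angle_deg %% 360
  ifelse(a > 180, a - 360, ifelse(a <= -180, a + 360, a))
}

#' Rigid-body transform
#'
#' @param rotation 3x3 proper orthonormal matrix (checked to 1e-9)
#' @param translation length-3 numeric vector, Angstrom
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_axis_angle(x)
  cat(sprintf("Rigid transform: rotation %.3f deg about (%.3f, %.3f, %.3f), translation (%.3f, %.3f, %.3f) A\n",
              aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

#' Helical symmetry operator for subunit k
#'
#' Returns the rigid transform that carries the asymmetric unit at index 0 to
#' index `k`: rotation by `k * twist` about +z and translation `k * rise`
#' along +z. Operators compose additively in k and `k = -1` inverts `k = 1`.
#'
#' @param sym a [helical_symmetry()]
#' @param k integer subunit index (any sign)
#' @return a [rigid_transform()]
#' @export
symmetry_operator <- function(sym, k) {
  stopifnot(inherits(sym, "helical_symmetry"),
            length(k) == 1L, is.finite(k), k == round(k))
  rigid_transform(rot_z(k * sym$twist), c(0, 0, k * sym$rise))
}

#' Compose two rigid transforms (a after b)
#' @param a,b [rigid_transform()] objects
#' @return the composite transform `a %then after% b`: x -> a(b(x))
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()]
#' @return the inverse transform
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates, Angstrom
#' @param t a [rigid_transform()]
#' @return n x 3 matrix of transformed coordinates
#' @export
transform_points <- function(points, t) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3L) else as.matrix(points)
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  out <- p %*% t(t$rotation)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out[, 3] <- out[, 3] + t$translation[3]
  dimnames(out) <- dimnames(p)
  out
}

#' Rotation axis and angle of a rigid transform
#'
#' Axis-angle decomposition of the rotation part. The angle lies in
#' \[0, 180\] degrees; for the identity rotation the axis is undefined and
#' flagged. Reconstructing the matrix from (axis, angle) via Rodrigues'
#' formula reproduces the input to 1e-9.
#'
#' @param transform a [rigid_transform()] or a 3x3 proper rotation matrix
#' @return list with `axis` (unit 3-vector), `angle` (degrees),
#'   `axis_defined` (FALSE for angle ~ 0)
#' @export
rotation_axis_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation
       else as.matrix(transform)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation_axis_angle: not a proper rotation")
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  angle <- acos(ct) * 180 / pi
  if (angle < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = 0, axis_defined = FALSE))
  }
  if (angle > 180 - 1e-6) {
    # near 180 deg: axis from the symmetric part, R = 2 a a^T - I
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- B[, i] / sqrt(max(B[i, i], .Machine$double.eps))
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- axis / (2 * sin(angle * pi / 180))
  }
  axis <- axis / sqrt(sum(axis^2))
  list(axis = axis, angle = angle, axis_defined = TRUE)
}

#' Rotation matrix from axis and angle (Rodrigues)
#' @param axis 3-vector (normalized internally)
#' @param angle degrees
#' @return 3x3 rotation matrix
#' @export
axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ZYZ Euler rotation used for projections: R = Rz(psi) Ry(theta) Rz(phi).
# phi is azimuth about the helix (grid) axis, theta the out-of-plane angle
# (90 deg = axis in the image plane), psi the in-plane rotation.
euler_matrix <- function(phi, theta, psi) {
  rot_z(psi) %*% rot_y(theta) %*% rot_z(phi)
}
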