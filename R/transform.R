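#' Rigid transform (intrinsic ZYZ Euler angles + voxel shift)
#'
#' Angles follow the (rot, tilt, psi) intrinsic ZYZ convention used by the
#' STAR dialect this package reads and writes: the rotation matrix is
#' `Rz(rot) %*% Ry(tilt) %*% Rz(psi)`. The transform acts about the volume
#' origin voxel as rotate-then-shift: a point p (relative to the origin)
#' maps to `R p + shift`.
#'
#' @param euler_deg length-3 numeric, (rot, tilt, psi) in degrees.
#' @param shift_vox length-3 numeric, (dx, dy, dz) in voxels.
#' @return a `rigid_transform` object.
#' @export
rigid_transform <- function(euler_deg = c(0, 0, 0), shift_vox = c(0, 0, 0)) {
  stopifnot(length(euler_deg) == 3, length(shift_vox) == 3,
            all(is.finite(euler_deg)), all(is.finite(shift_vox)))
  structure(list(euler_deg = as.numeric(euler_deg),
                 shift_vox = as.numeric(shift_vox)),
            class = "rigid_transform")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix of a rigid transform
#' @param t a [rigid_transform()].
#' @return 3x3 rotation matrix `Rz(rot) Ry(tilt) Rz(psi)`.
#' @export
transform_matrix <- function(t) {
  e <- t$euler_deg
  rot_z(e[1]) %*% rot_y(e[2]) %*% rot_z(e[3])
}

#' Invert a rigid transform
#'
#' Returns the transform that undoes `t` under the rotate-then-shift
#' convention: angles `(-psi, -tilt, -rot)` and shift `-R^-1 s`.
#'
#' @param t a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  e <- t$euler_deg
  Rinv <- t(transform_matrix(t))
  rigid_transform(c(-e[3], -e[2], -e[1]),
                  as.vector(-Rinv %*% t$shift_vox))
}

#' Apply a rigid transform to a volume
#'
#' Resamples the volume with trilinear interpolation about its origin voxel;
#' samples falling outside the grid are zero. Order is rotate-then-shift.
#'
#' @param vol a cubic [density_volume()].
#' @param t a [rigid_transform()].
#' @param order only `"rotate_then_shift"` is defined.
#' @return the transformed `density_volume`.
#' @export
apply_transform <- function(vol, t, order = "rotate_then_shift") {
  stopifnot(inherits(vol, "density_volume"), inherits(t, "rigid_transform"))
  order <- match.arg(order, "rotate_then_shift")
  assert_cubic(vol, "apply_transform")
  R <- transform_matrix(t)
  c0 <- vol$origin - 1                     # 0-based center
  # out(r) = in(R^-1 (r - c - s) + c): gather matrix A = R^-1,
  # offset b = c - A (c + s)
  A <- base::t(R)
  b <- c0 - as.vector(A %*% (c0 + t$shift_vox))
  vals <- cpp_affine_sample(vol$values, dim(vol$values), A, b)
  density_volume(vals, vol$voxel_A, vol$origin)
}

# Draw n uniform random rigid transforms (uniform SO(3) via ZYZ with
# cos(tilt) ~ U(-1,1)); shifts uniform in +/- max_shift_vox per axis.
random_transforms <- function(n, max_shift_vox = 0) {
  lapply(seq_len(n), function(i) {
    rigid_transform(
      euler_deg = c(stats::runif(1, 0, 360),
                    acos(stats::runif(1, -1, 1)) * 180 / pi,
                    stats::runif(1, 0, 360)),
      shift_vox = stats::runif(3, -max_shift_vox, max_shift_vox))
  })
}
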