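#' Tilt scheme
#'
#' Angular collection geometry of a tilt series: angles
#' `theta_min, theta_min + step, ..., theta_max` in degrees about the y
#' (tilt) axis, beam along z. A limited range (e.g. +/-60 degrees) leaves
#' the familiar missing wedge in Fourier space.
#'
#' @param theta_min_deg,theta_max_deg tilt range bounds, min < max.
#' @param step_deg positive angular increment.
#' @return a `tilt_scheme` with the expanded `angles_deg` list.
#' @export
tilt_scheme <- function(theta_min_deg, theta_max_deg, step_deg) {
  if (!(theta_min_deg < theta_max_deg)) stop("theta_min must be < theta_max", call. = FALSE)
  if (step_deg <= 0) stop("step must be positive", call. = FALSE)
  structure(list(theta_min_deg = theta_min_deg, theta_max_deg = theta_max_deg,
                 step_deg = step_deg,
                 angles_deg = seq(theta_min_deg, theta_max_deg, by = step_deg)),
            class = "tilt_scheme")
}

#' Projection stack
#'
#' One image per tilt angle, stored as an (box, box, n_tilt) array with
#' image axes (x, y): x is perpendicular to the tilt axis in-plane, y is
#' the tilt axis.
#'
#' @param images (H, W, n_tilt) numeric array.
#' @param angles_deg tilt angle per image.
#' @param pixel_A pixel size in Angstrom.
#' @return a `projection_stack`.
#' @export
projection_stack <- function(images, angles_deg, pixel_A) {
  stopifnot(is.array(images), length(dim(images)) == 3,
            dim(images)[3] == length(angles_deg), pixel_A > 0)
  if (dim(images)[1] != dim(images)[2])
    stop("projection images must be square", call. = FALSE)
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 pixel_A = pixel_A),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %d images of %d x %d px @ %.3f A, tilts [%g, %g]\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2], x$pixel_A,
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Project a volume into a tilt series
#'
#' Image i is the line integral of the volume along the beam (z) axis after
#' rotating the volume by minus the tilt angle about the y axis (trilinear
#' resampling about the origin voxel).
#'
#' @param vol a cubic [density_volume()].
#' @param scheme a [tilt_scheme()].
#' @return a [projection_stack()].
#' @export
project <- function(vol, scheme) {
  stopifnot(inherits(vol, "density_volume"), inherits(scheme, "tilt_scheme"))
  assert_cubic(vol, "project")
  if (length(scheme$angles_deg) == 0) stop("empty angle list", call. = FALSE)
  imgs <- cpp_project_y(vol$values, dim(vol$values), scheme$angles_deg,
                        vol$origin - 1)
  projection_stack(imgs, scheme$angles_deg, vol$voxel_A)
}

#' Back-project a stack (adjoint of [project()])
#'
#' Smears each image back along the beam direction at its tilt angle. This
#' is the exact adjoint of the projector (no ramp filter); [wbp_reconstruct()]
#' adds the weighting.
#'
#' @param stack a [projection_stack()].
#' @param box output cube edge (defaults to the image size).
#' @return a [density_volume()].
#' @export
backproject <- function(stack, box = dim(stack$images)[1]) {
  stopifnot(inherits(stack, "projection_stack"))
  ctr <- c(box %/% 2L, box %/% 2L, box %/% 2L)
  vals <- cpp_backproject_y(stack$images, dim(stack$images),
                            stack$angles_deg, box, ctr)
  density_volume(vals, stack$pixel_A)
}

# |k| ramp filter along image x (the axis perpendicular to the tilt axis),
# optional raised-cosine rolloff starting at `rolloff` * Nyquist.
ramp_filter_stack <- function(images, rolloff = 1) {
  n <- dim(images)[1]
  k <- fft_freqs(n)                    # cycles / pixel
  w <- abs(k)
  if (rolloff < 1) {
    kn <- abs(k) / 0.5
    tapered <- kn > rolloff
    w[tapered] <- w[tapered] *
      0.5 * (1 + cos(pi * (kn[tapered] - rolloff) / (1 - rolloff)))
  }
  out <- images
  for (t in seq_len(dim(images)[3])) {
    F <- stats::mvfft(images[, , t])    # FFT along x for each y column
    out[, , t] <- Re(stats::mvfft(F * w, inverse = TRUE)) / n
  }
  out
}

# fftfreq in cycles/sample for length n
fft_freqs <- function(n) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) k[n %/% 2 + 1] <- n %/% 2   # Nyquist positive by convention
  k[seq_len(n)] / n
}

#' Weighted back-projection reconstruction
#'
#' Classic WBP: each projection is ramp-filtered (|k| along the axis
#' perpendicular to the tilt axis, optional raised-cosine rolloff), smeared
#' back along its beam direction, summed, and scaled by `pi / (2 n_tilt)`.
#' A single-tilt stack is a legal degenerate case (pure smear).
#'
#' By default the result is then projected onto the tilt scheme's Fourier
#' support ([wedge_mask()]): a limited-angle dataset carries no information
#' in the missing wedge, and discrete real-space smearing otherwise leaks a
#' few percent of spectral power into it (finite-support sinc tails). The
#' support projection removes that artifact, matching the empty wedge that
#' Fourier-inversion reconstructions of real tilt series exhibit; disable
#' with `enforce_wedge = FALSE` to obtain the raw smear-and-sum volume.
#'
#' @param stack a [projection_stack()].
#' @param scheme the [tilt_scheme()] it was collected with.
#' @param box output cube edge; must equal the image size.
#' @param rolloff ramp rolloff start as a fraction of Nyquist (1 = pure ramp).
#' @param enforce_wedge zero the missing-wedge Fourier region of the output.
#' @return a [density_volume()].
#' @export
wbp_reconstruct <- function(stack, scheme, box = dim(stack$images)[1],
                            rolloff = 1, enforce_wedge = TRUE) {
  stopifnot(inherits(stack, "projection_stack"))
  if (box != dim(stack$images)[1])
    stop("`box` must equal the projection image size", call. = FALSE)
  filtered <- ramp_filter_stack(stack$images, rolloff)
  fstack <- projection_stack(filtered, stack$angles_deg, stack$pixel_A)
  rec <- backproject(fstack, box)
  vals <- rec$values * pi / (2 * length(stack$angles_deg))
  if (enforce_wedge) {
    mask <- wedge_mask(box, scheme)
    if (!all(mask)) {
      F <- stats::fft(vals)
      F[!mask] <- 0
      vals <- Re(stats::fft(F, inverse = TRUE)) / length(vals)
    }
  }
  density_volume(vals, stack$pixel_A)
}

#' Fourier-space sampling mask of a tilt scheme
#'
#' Marks which Fourier voxels are sampled by the tilt series: the central
#' plane perpendicular to the beam, swept about the tilt axis through the
#' collection range; the complement is the missing wedge. The tilt (y) axis
#' frequency is unconstrained; the DC voxel is always sampled, the mask is
#' Friedel-symmetric, and for an even box the degenerate Nyquist planes are
#' assigned to the sampled region.
#'
#' @param box cube edge (>= 2).
#' @param scheme a [tilt_scheme()].
#' @return logical (box, box, box) array in unshifted FFT voxel order,
#'   TRUE = sampled.
#' @export
wedge_mask <- function(box, scheme) {
  if (box < 2) stop("`box` must be >= 2", call. = FALSE)
  k <- fft_freqs(box) * box              # integer-ish frequency index
  kx <- array(rep(k, times = box * box), c(box, box, box))
  kz <- array(rep(k, each = box * box), c(box, box, box))
  # plane of tilt theta: kx sin(theta) + kz cos(theta) = 0
  # -> sampled iff theta* = -atan2(kz, kx) (mod 180 into (-90, 90]) in range
  th <- -atan2(kz, kx) * 180 / pi
  th <- ifelse(th > 90, th - 180, ifelse(th <= -90, th + 180, th))
  lo <- max(-90, scheme$theta_min_deg)
  hi <- min(90, scheme$theta_max_deg)
  mask <- (th >= lo & th <= hi) | (th - 180 >= lo & th - 180 <= hi) |
    (th + 180 >= lo & th + 180 <= hi)
  mask[kx == 0 & kz == 0] <- TRUE        # DC column incl. tilt axis
  if (box %% 2 == 0) {
    nyq <- box %/% 2 + 1                 # unshifted index of Nyquist
    mask[nyq, , ] <- TRUE
    mask[, , nyq] <- TRUE
  }
  mask
}

#' Fraction of Fourier power inside the missing wedge
#'
#' Diagnostic for missing-wedge severity and its compensation: the share of
#' non-DC spectral power lying in the unsampled wedge of a tilt scheme. A
#' wedge-limited WBP reconstruction scores near 0; white noise scores the
#' wedge's voxel fraction; restoration should move a volume from the former
#' toward the latter.
#'
#' @param vol a cubic [density_volume()].
#' @param scheme a [tilt_scheme()].
#' @return scalar in \[0, 1\].
#' @export
wedge_energy_fraction <- function(vol, scheme) {
  stopifnot(inherits(vol, "density_volume"))
  assert_cubic(vol, "wedge_energy_fraction")
  box <- dim(vol$values)[1]
  P <- Mod(stats::fft(vol$values))^2
  P[1, 1, 1] <- 0                        # drop DC
  mask <- wedge_mask(box, scheme)
  tot <- sum(P)
  if (tot == 0) return(0)
  sum(P[!mask]) / tot
}
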