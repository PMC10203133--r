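#' Contrast transfer function parameters
#'
#' @param voltage_kV acceleration voltage in kV (> 0).
#' @param defocus_um defocus in micrometres, positive = underfocus.
#' @param cs_mm spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in \[0, 1\].
#' @param phase_flip whether restoration-side phase flipping (multiplying
#'   by the CTF sign after modulation) is applied.
#' @return a `ctf_params` object.
#' @export
ctf_params <- function(voltage_kV = 300, defocus_um = 3, cs_mm = 2.7,
                       amplitude_contrast = 0.07, phase_flip = TRUE) {
  if (voltage_kV <= 0) stop("voltage must be positive", call. = FALSE)
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must be in [0, 1]", call. = FALSE)
  structure(list(voltage_kV = voltage_kV, defocus_um = defocus_um,
                 cs_mm = cs_mm, amplitude_contrast = amplitude_contrast,
                 phase_flip = isTRUE(phase_flip)),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#' @param voltage_kV acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength_A <- function(voltage_kV) {
  V <- voltage_kV * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' Evaluate the CTF on a frequency grid
#'
#' `CTF(f) = -sqrt(1 - A^2) sin(chi) - A cos(chi)` with aberration phase
#' `chi(f) = pi lambda dz f^2 - (pi/2) Cs lambda^3 f^4` (dz > 0 underfocus),
#' so CTF(0) = -A: pure amplitude contrast at zero frequency.
#'
#' @param freq_A_inv numeric array of spatial frequencies in 1/Angstrom.
#' @param p a [ctf_params()].
#' @return real-valued transfer array, same shape as `freq_A_inv`.
#' @export
simulate_ctf <- function(freq_A_inv, p) {
  stopifnot(inherits(p, "ctf_params"))
  lambda <- electron_wavelength_A(p$voltage_kV)
  dz <- p$defocus_um * 1e4               # um -> A
  cs <- p$cs_mm * 1e7                    # mm -> A
  chi <- pi * lambda * dz * freq_A_inv^2 -
    (pi / 2) * cs * lambda^3 * freq_A_inv^4
  A <- p$amplitude_contrast
  -sqrt(1 - A^2) * sin(chi) - A * cos(chi)
}

# 2D radial frequency grid (1/A) for an n x n image, unshifted FFT order
freq_grid_2d <- function(n, pixel_A) {
  k <- fft_freqs(n) / pixel_A
  sqrt(outer(k^2, k^2, `+`))
}

#' CTF-modulate a projection stack
#'
#' Multiplies each image by the CTF in Fourier space. With
#' `phase_flip = TRUE` in `p` the image is afterwards multiplied by
#' `sign(CTF)`, so the net transfer is `|CTF|` — the corrected-contrast
#' convention of simulated training data. Use `stage` to apply only one of
#' the two steps, which is how the simulator reproduces the
#' modulate / add-noise / flip ordering.
#'
#' @param stack a [projection_stack()].
#' @param p a [ctf_params()].
#' @param stage `"both"` (default), `"modulate"` or `"flip"`.
#' @return the modulated [projection_stack()].
#' @export
ctf_modulate <- function(stack, p, stage = c("both", "modulate", "flip")) {
  stopifnot(inherits(stack, "projection_stack"), inherits(p, "ctf_params"))
  stage <- match.arg(stage)
  n <- dim(stack$images)[1]
  ctf <- simulate_ctf(freq_grid_2d(n, stack$pixel_A), p)
  mult <- switch(stage,
                 modulate = ctf,
                 flip = sign(ctf),
                 both = if (p$phase_flip) abs(ctf) else ctf)
  out <- stack$images
  for (t in seq_len(dim(out)[3])) {
    F <- stats::fft(stack$images[, , t])
    out[, , t] <- Re(stats::fft(F * mult, inverse = TRUE)) / n^2
  }
  projection_stack(out, stack$angles_deg, stack$pixel_A)
}

#' Add white Gaussian noise at a target SNR
#'
#' SNR is defined as the variance ratio var(signal) / var(noise) over the
#' whole stack; noise of standard deviation
#' `sqrt(var(signal) / target_snr)` is added i.i.d. per pixel.
#'
#' @param stack a [projection_stack()].
#' @param target_snr positive scalar (e.g. 0.1 or 0.01 for realistic
#'   cryo-ET contrast).
#' @param seed integer seed; the draw is reproducible.
#' @return the noisy [projection_stack()].
#' @export
add_gaussian_noise <- function(stack, target_snr, seed) {
  stopifnot(inherits(stack, "projection_stack"))
  if (target_snr <= 0) stop("`target_snr` must be positive", call. = FALSE)
  v <- stats::var(as.vector(stack$images))
  if (v == 0) stop("stack has zero signal variance", call. = FALSE)
  sigma <- sqrt(v / target_snr)
  noisy <- with_seed(seed, {
    stack$images + array(stats::rnorm(length(stack$images), sd = sigma),
                         dim(stack$images))
  })
  projection_stack(noisy, stack$angles_deg, stack$pixel_A)
}
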