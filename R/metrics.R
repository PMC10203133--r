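#' Average consecutive tomogram slices into a micrograph
#'
#' Pixel-wise mean of `n` consecutive XY slices starting at z-index `z0`
#' (1-based) — the first step of the region-based SNR protocol, which
#' averages ten slices into one micrograph before selecting regions.
#'
#' @param tomogram a [density_volume()].
#' @param z0 first slice (1-based).
#' @param n number of slices (default 10).
#' @return a 2D numeric matrix (x by y).
#' @export
slice_average <- function(tomogram, z0, n = 10) {
  stopifnot(inherits(tomogram, "density_volume"))
  nz <- dim(tomogram$values)[3]
  if (z0 < 1 || z0 + n - 1 > nz)
    stop(sprintf("slice range [%d, %d] out of bounds (nz = %d)",
                 z0, z0 + n - 1, nz), call. = FALSE)
  sl <- tomogram$values[, , z0:(z0 + n - 1), drop = FALSE]
  apply(sl, c(1, 2), mean)
}

#' Paired signal/background region on a micrograph
#'
#' Half-open axis-aligned pixel rectangles `[x0, x1) x [y0, y1)` (1-based
#' x0/y0). Signal and background must not overlap and each must contain at
#' least 16 pixels.
#'
#' @param signal,background length-4 integer vectors `c(x0, x1, y0, y1)`.
#' @return a `region_pair`.
#' @export
region_pair <- function(signal, background) {
  chk <- function(r, what) {
    if (length(r) != 4 || r[2] <= r[1] || r[4] <= r[3])
      stop(sprintf("%s region must be c(x0, x1, y0, y1) with x0 < x1, y0 < y1",
                   what), call. = FALSE)
    if ((r[2] - r[1]) * (r[4] - r[3]) < 16)
      stop(sprintf("%s region area must be >= 16 pixels", what), call. = FALSE)
    as.integer(r)
  }
  signal <- chk(signal, "signal"); background <- chk(background, "background")
  overlap <- max(0, min(signal[2], background[2]) - max(signal[1], background[1])) *
    max(0, min(signal[4], background[4]) - max(signal[3], background[3]))
  if (overlap > 0)
    stop("signal and background regions overlap", call. = FALSE)
  structure(list(signal = signal, background = background),
            class = "region_pair")
}

region_pixels <- function(micrograph, r) {
  micrograph[r[1]:(r[2] - 1L), r[3]:(r[4] - 1L)]
}

#' Region-based SNR estimate in dB
#'
#' For each signal/background region pair i: take the background mean and
#' (unbiased) variance mu_b, v_b; define the signal pixels as the signal
#' region minus mu_b and take their variance v_s; the pair contributes
#' `10 (log10 v_s - log10 v_b)` dB. The estimate is the arithmetic mean
#' over the N pairs (N = 10 in the standard protocol).
#'
#' @param micrograph 2D numeric matrix (e.g. from [slice_average()]).
#' @param regions non-empty list of [region_pair()]s.
#' @return an `snr_estimate`: `mean_db`, `per_region` tibble with the
#'   intermediates (mu_b, v_b, mu_s, v_s, snr_db).
#' @export
estimate_snr_db <- function(micrograph, regions) {
  if (length(regions) < 1) stop("need at least one region pair", call. = FALSE)
  stopifnot(all(vapply(regions, inherits, TRUE, "region_pair")))
  rows <- lapply(seq_along(regions), function(i) {
    rp <- regions[[i]]
    bg <- region_pixels(micrograph, rp$background)
    mu_b <- mean(bg); v_b <- stats::var(as.vector(bg))
    if (v_b == 0)
      stop(sprintf("background region %d has zero variance (log undefined)", i),
           call. = FALSE)
    s <- region_pixels(micrograph, rp$signal) - mu_b
    mu_s <- mean(s); v_s <- stats::var(as.vector(s))
    tibble::tibble(region = i, mu_b = mu_b, v_b = v_b, mu_s = mu_s, v_s = v_s,
                   snr_db = 10 * (log10(v_s) - log10(v_b)))
  })
  per_region <- dplyr::bind_rows(rows)
  structure(list(mean_db = mean(per_region$snr_db),
                 n_regions = nrow(per_region),
                 per_region = per_region),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("<snr_estimate> %.2f dB over %d region pairs\n",
              x$mean_db, x$n_regions))
  invisible(x)
}

#' Propose tiled signal/background region pairs
#'
#' Convenience extension of the manual-selection protocol: tiles the
#' micrograph and pairs each even tile (signal) with the following odd tile
#' (background) along x.
#'
#' @param micrograph 2D matrix.
#' @param n number of pairs.
#' @param size tile edge in pixels.
#' @return list of [region_pair()]s.
#' @export
propose_region_pairs <- function(micrograph, n = 10, size = 20) {
  d <- dim(micrograph)
  per_row <- max(1L, (d[1] - 1L) %/% (2L * size))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% per_row
    col <- (i - 1L) %% per_row
    x0 <- 1L + col * 2L * size
    y0 <- 1L + row * size
    if (x0 + 2L * size > d[1] + 1L || y0 + size > d[2] + 1L)
      stop("micrograph too small for the requested region tiling", call. = FALSE)
    out[[i]] <- region_pair(c(x0, x0 + size, y0, y0 + size),
                            c(x0 + size, x0 + 2L * size, y0, y0 + size))
  }
  out
}

# ---- template matching ------------------------------------------------------

#' Template matching by rotational + translational normalized correlation
#'
#' Scans a uniform intrinsic-ZYZ orientation grid; for each orientation the
#' template is rigidly rotated, zero-meaned and unit-normed, and correlated
#' against the tomogram in Fourier space with local contrast normalization
#' (true normalized cross-correlation). Peaks above `cc_threshold` are kept
#' after greedy non-maximum suppression at `min_separation_vox` (higher cc
#' wins; exact ties break by lexicographic coordinate order). Peak centers
#' are reported at the template-center voxel and are restricted to
#' placements where the template fits inside the tomogram.
#'
#' @param tomogram a [density_volume()].
#' @param template a cubic [density_volume()] smaller than the tomogram.
#' @param angular_step_deg grid step in degrees; 360 scans only the identity
#'   orientation. (rot, psi) cover \[0, 360); tilt covers \[0, 180\].
#' @param cc_threshold keep peaks with cc above this (>= 1 returns an empty
#'   result with a warning).
#' @param min_separation_vox suppression radius between accepted peaks.
#' @param orientations optional explicit data frame (rot, tilt, psi)
#'   overriding the grid.
#' @return a tibble of matches: x, y, z (1-based voxel), rot, tilt, psi, cc.
#' @export
template_match <- function(tomogram, template, angular_step_deg = 90,
                           cc_threshold = 0.2, min_separation_vox = 8,
                           orientations = NULL) {
  stopifnot(inherits(tomogram, "density_volume"),
            inherits(template, "density_volume"))
  assert_cubic(template, "template_match")
  tb <- dim(template$values)[1]
  td <- dim(tomogram$values)
  if (any(tb > td)) stop("template must be smaller than the tomogram", call. = FALSE)
  empty <- tibble::tibble(x = integer(), y = integer(), z = integer(),
                          rot = numeric(), tilt = numeric(), psi = numeric(),
                          cc = numeric())
  if (cc_threshold >= 1) {
    warning("cc_threshold >= 1: no peaks possible", call. = FALSE)
    return(empty)
  }
  if (is.null(orientations)) {
    s <- angular_step_deg
    rots <- seq(0, 360 - s, by = s)
    tilts <- seq(0, 180, by = s); tilts <- tilts[tilts <= 180]
    psis <- seq(0, 360 - s, by = s)
    orientations <- expand.grid(rot = rots, tilt = tilts, psi = psis)
    # at tilt 0 (or 180), rot and psi are degenerate: keep rot = 0 only
    degen <- orientations$tilt %in% c(0, 180) & orientations$rot != 0
    orientations <- orientations[!degen, , drop = FALSE]
  }
  tvox <- prod(rep(tb, 3))
  Ft <- stats::fft(tomogram$values)
  ones <- array(0, td); ones[seq_len(tb), seq_len(tb), seq_len(tb)] <- 1
  Fones <- stats::fft(ones)
  S1 <- Re(stats::fft(Ft * Conj(Fones), inverse = TRUE)) / prod(td)
  Ft2 <- stats::fft(tomogram$values^2)
  S2 <- Re(stats::fft(Ft2 * Conj(Fones), inverse = TRUE)) / prod(td)
  local_var <- pmax(S2 - S1^2 / tvox, 0)
  denom <- sqrt(local_var)
  denom[denom < 1e-9 * max(denom)] <- Inf     # flat regions: no match
  best_cc <- array(-Inf, td)
  best_ori <- array(0L, td)
  for (o in seq_len(nrow(orientations))) {
    tr <- rigid_transform(c(orientations$rot[o], orientations$tilt[o],
                            orientations$psi[o]))
    tpl <- if (all(abs(unlist(orientations[o, ])) < 1e-12)) template
           else apply_transform(template, tr)
    tv <- tpl$values - mean(tpl$values)
    nrm <- sqrt(sum(tv^2))
    if (nrm == 0) next
    tv <- tv / nrm
    padded <- array(0, td)
    padded[seq_len(tb), seq_len(tb), seq_len(tb)] <- tv
    num <- Re(stats::fft(Ft * Conj(stats::fft(padded)), inverse = TRUE)) / prod(td)
    cc <- num / denom
    upd <- cc > best_cc
    best_cc[upd] <- cc[upd]
    best_ori[upd] <- o
  }
  # corr lag L means template corner at voxel L+1; valid placements keep the
  # template inside; center = corner + tb/2
  half <- tb %/% 2L
  valid <- array(FALSE, td)
  valid[seq_len(td[1] - tb + 1L), seq_len(td[2] - tb + 1L),
        seq_len(td[3] - tb + 1L)] <- TRUE
  cand <- which(valid & best_cc > cc_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cc_val <- best_cc[valid & best_cc > cc_threshold]
  ord <- order(-cc_val, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]; cc_val <- cc_val[ord]
  keep <- logical(nrow(cand))
  acc <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        min(sqrt(rowSums(sweep(acc, 2, p)^2))) >= min_separation_vox) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand <- cand[keep, , drop = FALSE]; cc_val <- cc_val[keep]
  oid <- best_ori[cbind(cand[, 1], cand[, 2], cand[, 3])]
  tibble::tibble(x = unname(cand[, 1]) + half, y = unname(cand[, 2]) + half,
                 z = unname(cand[, 3]) + half,
                 rot = orientations$rot[oid], tilt = orientations$tilt[oid],
                 psi = orientations$psi[oid], cc = cc_val)
}

#' Offsets between matched peaks and ground-truth coordinates
#'
#' Pairs each template-matching peak (greedily, best cc first) with its
#' nearest unclaimed ground-truth point within `match_radius_vox`, then
#' reports per-particle coordinate offsets (calculated minus true) in x, y
#' and z with per-axis mean and RMS summaries.
#'
#' @param matches tibble from [template_match()].
#' @param truth n x 3 matrix (or data frame) of true centers, no duplicates.
#' @param match_radius_vox pairing radius (default: half the typical
#'   particle radius works well).
#' @return an `offset_stats`: `offsets` tibble (one row per matched truth),
#'   `unmatched_truth` indices, `summary` tibble of per-axis mean/RMS.
#' @export
offset_statistics <- function(matches, truth, match_radius_vox) {
  truth <- as.matrix(truth)
  if (nrow(truth) == 0) stop("`truth` must be non-empty", call. = FALSE)
  if (anyDuplicated(truth)) stop("duplicate truth points", call. = FALSE)
  claimed <- rep(FALSE, nrow(truth))
  rows <- list()
  if (nrow(matches) > 0) {
    ord <- order(-matches$cc, matches$x, matches$y, matches$z)
    for (i in ord) {
      p <- c(matches$x[i], matches$y[i], matches$z[i])
      d <- sqrt(colSums((t(truth) - p)^2))
      d[claimed] <- Inf
      j <- which.min(d)
      if (d[j] <= match_radius_vox) {
        claimed[j] <- TRUE
        rows[[length(rows) + 1]] <- tibble::tibble(
          truth_index = j, x_true = truth[j, 1], y_true = truth[j, 2],
          z_true = truth[j, 3], dx = p[1] - truth[j, 1],
          dy = p[2] - truth[j, 2], dz = p[3] - truth[j, 3],
          cc = matches$cc[i])
      }
    }
  }
  offsets <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(truth_index = integer(), x_true = numeric(),
                   y_true = numeric(), z_true = numeric(), dx = numeric(),
                   dy = numeric(), dz = numeric(), cc = numeric())
  summary <- tibble::tibble(
    axis = c("x", "y", "z"),
    mean = c(mean(offsets$dx), mean(offsets$dy), mean(offsets$dz)),
    rms = c(sqrt(mean(offsets$dx^2)), sqrt(mean(offsets$dy^2)),
            sqrt(mean(offsets$dz^2))))
  structure(list(offsets = offsets,
                 unmatched_truth = which(!claimed),
                 n_matched = sum(claimed),
                 summary = summary),
            class = "offset_stats")
}

#' @export
print.offset_stats <- function(x, ...) {
  cat(sprintf("<offset_stats> %d truth points matched, %d unmatched\n",
              x$n_matched, length(x$unmatched_truth)))
  if (x$n_matched > 0)
    cat(sprintf("  RMS offset (x, y, z) = (%.2f, %.2f, %.2f) vox\n",
                x$summary$rms[1], x$summary$rms[2], x$summary$rms[3]))
  invisible(x)
}

# brute-force spatial-domain normalized correlation, the oracle used by the
# test suite to validate the FFT path on tiny instances
template_match_brute <- function(tomogram, template) {
  tv <- template$values - mean(template$values)
  tv <- tv / sqrt(sum(tv^2))
  td <- dim(tomogram$values); tb <- dim(template$values)[1]
  nx <- td[1] - tb + 1L; ny <- td[2] - tb + 1L; nz <- td[3] - tb + 1L
  cc <- array(NA_real_, c(nx, ny, nz))
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    w <- tomogram$values[i:(i + tb - 1L), j:(j + tb - 1L), k:(k + tb - 1L)]
    wc <- w - mean(w)
    n2 <- sqrt(sum(wc^2))
    cc[i, j, k] <- if (n2 == 0) 0 else sum(wc * tv) / n2
  }
  cc
}

#' Read / write region pairs as a JSON list of rectangles
#'
#' Each entry holds `signal` and `background` rectangles as
#' `[x0, x1, y0, y1]` (half-open, 1-based corners).
#'
#' @param regions list of [region_pair()]s.
#' @param path JSON file path.
#' @return `read_region_pairs` returns a list of [region_pair()]s.
#' @export
write_region_pairs <- function(regions, path) {
  jsonlite::write_json(lapply(regions, function(r)
    list(signal = r$signal, background = r$background)), path)
  invisible(path)
}

#' @rdname write_region_pairs
#' @export
read_region_pairs <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    region_pair(unlist(r$signal), unlist(r$background)))
}
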