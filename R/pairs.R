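#' Orientation record for one particle
#'
#' Carries the alignment parameters of a subtomogram: its rigid transform
#' (reference-to-particle by default, the direction in which an averaged
#' map is rotated and shifted back onto each raw particle), the source
#' tomogram identifier and the particle center in that tomogram.
#'
#' @param particle_id unique identifier.
#' @param transform a [rigid_transform()].
#' @param source_tomogram identifier string.
#' @param center_vox optional (x, y, z) center in the source tomogram.
#' @return an `orientation_record`.
#' @export
orientation_record <- function(particle_id, transform,
                               source_tomogram = NA_character_,
                               center_vox = c(NA, NA, NA)) {
  stopifnot(inherits(transform, "rigid_transform"))
  structure(list(particle_id = particle_id, transform = transform,
                 source_tomogram = source_tomogram,
                 center_vox = center_vox),
            class = "orientation_record")
}

#' Training pair (low-quality input, high-quality target)
#'
#' @param input_vol,target_vol `density_volume`s of equal shape and voxel
#'   size.
#' @param provenance list tagging the generating strategy and parameters.
#' @param normalized whether both volumes are z-score normalized.
#' @return a `training_pair`.
#' @export
training_pair <- function(input_vol, target_vol, provenance = list(),
                          normalized = FALSE) {
  stopifnot(inherits(input_vol, "density_volume"),
            inherits(target_vol, "density_volume"))
  if (!identical(dim(input_vol$values), dim(target_vol$values)))
    stop("pair volumes must have equal shapes", call. = FALSE)
  if (abs(input_vol$voxel_A - target_vol$voxel_A) > 1e-6 * input_vol$voxel_A)
    stop("pair volumes must have equal voxel sizes", call. = FALSE)
  structure(list(input_vol = input_vol, target_vol = target_vol,
                 provenance = provenance, normalized = isTRUE(normalized)),
            class = "training_pair")
}

#' Per-particle ground truth from an averaged map (strategy 1)
#'
#' Rotates and shifts a (CTF- and wedge-corrected) averaged reference map
#' into the orientation of one raw particle, producing that particle's
#' high-quality ground truth. With `inverse = TRUE` the stored transform is
#' interpreted in the particle-to-reference direction instead (subtomogram-
#' averaging packages differ on this).
#'
#' @param reference_map cubic [density_volume()].
#' @param rec an [orientation_record()].
#' @param inverse flip the transform direction.
#' @return the transformed [density_volume()].
#' @export
make_ground_truth_strategy1 <- function(reference_map, rec, inverse = FALSE) {
  stopifnot(inherits(reference_map, "density_volume"),
            inherits(rec, "orientation_record"))
  assert_cubic(reference_map, "make_ground_truth_strategy1")
  t <- if (inverse) invert_transform(rec$transform) else rec$transform
  apply_transform(reference_map, t)
}

#' Build strategy-1 training pairs
#'
#' Pairs each raw subtomogram (the low-quality input) with the averaged
#' reference transformed into its orientation (the high-quality target),
#' matching records to subtomograms by `particle_id`.
#'
#' @param subtomograms named list of `density_volume`s (names =
#'   particle ids) or unnamed list matched positionally to `records`.
#' @param reference_map cubic [density_volume()], same voxel size as the
#'   particles (1% tolerance).
#' @param records list of [orientation_record()]s, one per subtomogram.
#' @param normalize z-score both members of every pair.
#' @param inverse see [make_ground_truth_strategy1()].
#' @return list of [training_pair()]s, in subtomogram order.
#' @export
build_pairs_strategy1 <- function(subtomograms, reference_map, records,
                                  normalize = TRUE, inverse = FALSE) {
  if (length(subtomograms) == 0) return(list())
  ids <- if (!is.null(names(subtomograms))) names(subtomograms)
         else as.character(seq_along(subtomograms))
  rec_ids <- vapply(records, function(r) as.character(r$particle_id), "")
  missing <- setdiff(ids, rec_ids)
  if (length(missing))
    stop("no orientation record for particle id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vx <- subtomograms[[1]]$voxel_A
  if (abs(reference_map$voxel_A - vx) > 0.01 * vx)
    stop(sprintf("voxel size mismatch: reference %.4g A vs particles %.4g A",
                 reference_map$voxel_A, vx), call. = FALSE)
  lapply(seq_along(subtomograms), function(i) {
    rec <- records[[match(ids[i], rec_ids)]]
    gt <- make_ground_truth_strategy1(reference_map, rec, inverse)
    inp <- subtomograms[[i]]
    if (normalize) { gt <- normalize_volume(gt); inp <- normalize_volume(inp) }
    training_pair(inp, gt,
                  provenance = list(strategy = 1, particle_id = ids[i]),
                  normalized = normalize)
  })
}

#' Build strategy-2 (simulation-based) training pairs
#'
#' For every conformation and repeat: draw a random rigid transform, render
#' the conformation as density and transform it (the ground truth), then
#' run the full degradation chain — tilt-series projection, CTF modulation,
#' Gaussian noise at the target SNR, CTF phase flip, WBP reconstruction —
#' to produce the low-quality input. Every random draw is recorded in the
#' returned manifest, from which the pair set regenerates bit-identically.
#'
#' @param conformations list of [pseudo_atom_model()]s (centered).
#' @param box cube edge in voxels (e.g. 64 at 4.44 A for nucleosome-scale
#'   work; 32 for desk-scale runs).
#' @param voxel_A voxel size in Angstrom.
#' @param scheme a [tilt_scheme()].
#' @param ctf a [ctf_params()].
#' @param snr target SNR of the projections.
#' @param n_per_conf repeats per conformation (>= 1).
#' @param seed master seed.
#' @param resolution_A rendering resolution for [model_to_density()].
#' @param max_shift_vox random shift range per axis.
#' @param normalize z-score both members of each pair.
#' @return list with `pairs` (list of [training_pair()]) and `manifest`
#'   (a tibble, one row per pair).
#' @export
build_pairs_strategy2 <- function(conformations, box, voxel_A, scheme, ctf,
                                  snr, n_per_conf = 1, seed = 1,
                                  resolution_A = 4 * voxel_A,
                                  max_shift_vox = 2, normalize = TRUE) {
  if (n_per_conf < 1) stop("`n_per_conf` must be >= 1", call. = FALSE)
  grid <- expand.grid(conf = seq_along(conformations),
                      rep = seq_len(n_per_conf))
  grid <- grid[order(grid$conf, grid$rep), , drop = FALSE]
  draws <- with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      t <- random_transforms(1, max_shift_vox)[[1]]
      list(transform = t, noise_seed = sample.int(2^31 - 1, 1))
    })
  })
  pairs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pairs[[i]] <- simulate_pair(conformations[[grid$conf[i]]],
                                draws[[i]]$transform, draws[[i]]$noise_seed,
                                box, voxel_A, scheme, ctf, snr,
                                resolution_A, normalize,
                                provenance = list(strategy = 2,
                                                  conformation = grid$conf[i],
                                                  rep = grid$rep[i]))
  }
  manifest <- tibble::tibble(
    pair = seq_len(nrow(grid)),
    conformation = grid$conf,
    rep = grid$rep,
    rot = vapply(draws, function(d) d$transform$euler_deg[1], 0),
    tilt = vapply(draws, function(d) d$transform$euler_deg[2], 0),
    psi = vapply(draws, function(d) d$transform$euler_deg[3], 0),
    dx = vapply(draws, function(d) d$transform$shift_vox[1], 0),
    dy = vapply(draws, function(d) d$transform$shift_vox[2], 0),
    dz = vapply(draws, function(d) d$transform$shift_vox[3], 0),
    noise_seed = vapply(draws, function(d) as.numeric(d$noise_seed), 0),
    box = box, voxel_A = voxel_A, snr = snr,
    theta_min = scheme$theta_min_deg, theta_max = scheme$theta_max_deg,
    theta_step = scheme$step_deg,
    defocus_um = ctf$defocus_um, voltage_kV = ctf$voltage_kV,
    cs_mm = ctf$cs_mm, amplitude_contrast = ctf$amplitude_contrast,
    phase_flip = ctf$phase_flip,
    resolution_A = resolution_A, normalized = normalize,
    format_version = "tomorest-manifest-1")
  list(pairs = pairs, manifest = manifest)
}

# one simulated pair: GT = transformed rendered density; input = WBP of the
# modulated/noisy/phase-flipped tilt series of the GT
simulate_pair <- function(conf, transform, noise_seed, box, voxel_A, scheme,
                          ctf, snr, resolution_A, normalize, provenance) {
  gt <- model_to_density(center_model(conf), voxel_A, box, resolution_A,
                         warn_clip = FALSE)
  gt <- apply_transform(gt, transform)
  stack <- project(gt, scheme)
  stack <- ctf_modulate(stack, ctf, stage = "modulate")
  stack <- add_gaussian_noise(stack, snr, noise_seed)
  if (ctf$phase_flip) stack <- ctf_modulate(stack, ctf, stage = "flip")
  inp <- wbp_reconstruct(stack, scheme, box)
  if (normalize) { gt <- normalize_volume(gt); inp <- normalize_volume(inp) }
  training_pair(inp, gt, provenance = provenance, normalized = normalize)
}

#' Regenerate strategy-2 pairs from a manifest
#'
#' Rebuilds every pair recorded in a [build_pairs_strategy2()] manifest,
#' bit-identically (same transforms, same noise seeds).
#'
#' @param conformations the same conformation list the manifest was built
#'   from.
#' @param manifest the manifest tibble.
#' @return list of [training_pair()]s.
#' @export
regenerate_pairs <- function(conformations, manifest) {
  stopifnot(all(manifest$format_version == "tomorest-manifest-1"))
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    simulate_pair(conformations[[m$conformation]],
                  rigid_transform(c(m$rot, m$tilt, m$psi),
                                  c(m$dx, m$dy, m$dz)),
                  m$noise_seed, m$box, m$voxel_A,
                  tilt_scheme(m$theta_min, m$theta_max, m$theta_step),
                  ctf_params(m$voltage_kV, m$defocus_um, m$cs_mm,
                             m$amplitude_contrast, m$phase_flip),
                  m$snr, m$resolution_A, m$normalized,
                  provenance = list(strategy = 2, conformation = m$conformation,
                                    rep = m$rep))
  })
}

#' Split a pair manifest into training and validation subsets
#'
#' @param manifest a pair manifest tibble.
#' @param validation_fraction fraction held out (default 0.1).
#' @param seed split seed.
#' @return the manifest with a logical `validation` column added.
#' @export
split_manifest <- function(manifest, validation_fraction = 0.1, seed = 1) {
  n <- nrow(manifest)
  n_val <- floor(n * validation_fraction)
  val <- with_seed(seed, sample.int(n, n_val))
  manifest$validation <- seq_len(n) %in% val
  manifest
}
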