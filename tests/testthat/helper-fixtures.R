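# Shared fixtures, built in code. Heavy artifacts (the desk-scale training
# run used by several restoration tests) are computed once per session and
# cached in `.fixture_env`.

.fixture_env <- new.env(parent = emptyenv())

# smooth gaussian-mixture phantom
make_phantom <- function(box, centers, sigmas, amps = rep(1, length(sigmas))) {
  i <- seq_len(box) - 1
  vals <- array(0, c(box, box, box))
  for (j in seq_along(sigmas)) {
    ctr <- centers[[j]]
    vals <- vals + amps[j] * exp(-outer(outer((i - ctr[1])^2, (i - ctr[2])^2,
                                              `+`), (i - ctr[3])^2, `+`) /
                                   (2 * sigmas[j]^2))
  }
  density_volume(vals, 1)
}

default_phantom <- function(box = 48) {
  make_phantom(box,
               centers = list(c(box / 2, box / 2 - 4, box / 2 + 2),
                              c(box / 2 - 10, box / 2 + 6, box / 2 - 4)),
               sigmas = c(4, 3), amps = c(1, 0.5))
}

toy_nucleosome <- function() {
  if (is.null(.fixture_env$toy)) {
    model <- center_model(generate_toy_model("disc_with_arms", 220, 1))
    modes <- compute_enm_modes(model, cutoff_A = 16, n_modes = 20)
    .fixture_env$toy <- list(model = model, modes = modes)
  }
  .fixture_env$toy
}

# The desk-scale closed-loop study: 220 conformations of the toy nucleosome,
# 200 training + 20 held-out strategy-2 pairs at 32 voxels / 8.88 A (2x-binned desk scale) / SNR 0.1
# / +-40 degrees, desk U-Net. Shared by the restoration, wedge-filling and
# template-matching tests.
desk_conditions <- function() {
  list(box = 32L, voxel_A = 8.88, scheme = tilt_scheme(-40, 40, 2),
       ctf = ctf_params(), snr = 0.1, resolution_A = 4 * 8.88)
}

desk_run <- function() {
  if (is.null(.fixture_env$desk_run)) {
    toy <- toy_nucleosome()
    cond <- desk_conditions()
    confs <- sample_conformations(toy$model, toy$modes, n = 220,
                                  mode_indices = c(7, 13),
                                  amplitude_range = c(-250, 250), seed = 11)
    built <- build_pairs_strategy2(confs, box = cond$box,
                                   voxel_A = cond$voxel_A,
                                   scheme = cond$scheme, ctf = cond$ctf,
                                   snr = cond$snr, seed = 42,
                                   resolution_A = cond$resolution_A)
    fit <- train_restorer(built$pairs[1:200], unet_preset("desk"),
                          training_config(iterations = 150, batch_size = 4,
                                          seed = 5,
                                          validation_fraction = 0.1))
    held_out <- built$pairs[201:220]
    restored <- lapply(held_out, function(p)
      density_volume(predict_patch(fit, p$input_vol$values), cond$voxel_A))
    .fixture_env$desk_run <- list(
      conformations = confs, built = built, fit = fit,
      held_out = held_out, restored = restored,
      cc_input = vapply(held_out, function(p)
        pearson_cc(p$input_vol, p$target_vol), 0),
      cc_restored = vapply(seq_along(held_out), function(i)
        pearson_cc(restored[[i]], held_out[[i]]$target_vol), 0))
  }
  .fixture_env$desk_run
}

# spearman permutation test (fixed seed), returns p-value for rho != 0
spearman_perm_p <- function(x, y, n_perm = 2000, seed = 99) {
  rho <- stats::cor(x, y, method = "spearman")
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  perm <- with_seed(seed, replicate(n_perm, {
    stats::cor(x, sample(y), method = "spearman")
  }))
  mean(abs(perm) >= abs(rho))
}
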