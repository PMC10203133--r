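test_that("normalization is a z-score with the degenerate-constant convention", {
  ph <- default_phantom(16)
  n1 <- normalize_volume(ph)
  expect_lt(abs(mean(n1$values)), 1e-6)
  expect_lt(abs(stats::sd(as.vector(n1$values)) - 1), 1e-6)
  n2 <- normalize_volume(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-6)
  expect_warning(flat <- normalize_volume(density_volume(array(5, rep(8, 3)), 1)),
                 "constant")
  expect_true(all(flat$values == 0))
  expect_true(attr(flat, "degenerate"))
})

test_that("subvolume extraction crops, pads and round-trips", {
  tomo <- default_phantom(32)
  whole <- extract_subvolumes(tomo, matrix(c(17, 17, 17), 1), 32)[[1]]
  expect_equal(whole$values, tomo$values)
  corner <- extract_subvolumes(tomo, matrix(c(1, 1, 1), 1), 16,
                               pad_policy = "zero")[[1]]
  expect_true(all(corner$values[1:7, , ] == 0))
  expect_error(extract_subvolumes(tomo, matrix(c(1, 1, 1), 1), 16,
                                  pad_policy = "reject"),
               "out of bounds")
  crop <- extract_subvolumes(tomo, matrix(c(16, 14, 20), 1), 8)[[1]]
  pasted <- tomo$values
  pasted[12:19, 10:17, 16:23] <- crop$values
  expect_identical(pasted, tomo$values)
})

test_that("strategy-1 ground truth reproduces the particle frame", {
  ref <- default_phantom(32)
  ident <- make_ground_truth_strategy1(ref, orientation_record("p", rigid_transform()))
  expect_equal(ident$values, ref$values)
  # closed loop: particle = transformed reference, noise-free
  t <- rigid_transform(c(40, 25, -15), c(1, 0, -1))
  particle <- apply_transform(ref, t)
  gt <- make_ground_truth_strategy1(ref, orientation_record("p", t))
  expect_gt(pearson_cc(gt, particle), 0.99)
  # shift-only records differ by a one-voxel roll
  r0 <- orientation_record("a", rigid_transform(shift_vox = c(0, 0, 0)))
  r1 <- orientation_record("a", rigid_transform(shift_vox = c(1, 0, 0)))
  g0 <- make_ground_truth_strategy1(ref, r0)$values
  g1 <- make_ground_truth_strategy1(ref, r1)$values
  rolled <- g0[c(32, 1:31), , ]
  interior <- 2:31
  expect_lt(max(abs(g1[interior, interior, interior] -
                    rolled[interior, interior, interior])), 1e-6)
})

test_that("strategy-1 pair building matches records by id, order-independently", {
  expect_identical(build_pairs_strategy1(list(), default_phantom(16), list()),
                   list())
  ref <- default_phantom(24)
  ts <- list(rigid_transform(c(10, 20, 30)), rigid_transform(c(-40, 60, 5)),
             rigid_transform(c(0, 90, 0)))
  subs <- lapply(ts, function(t) apply_transform(ref, t))
  names(subs) <- c("p1", "p2", "p3")
  recs <- lapply(1:3, function(i)
    orientation_record(paste0("p", i), ts[[i]]))
  pairs <- build_pairs_strategy1(subs, ref, recs, normalize = FALSE)
  ccs <- vapply(pairs, function(p) pearson_cc(p$input_vol, p$target_vol), 0)
  expect_true(all(ccs > 0.99))       # noise-free: target reproduces input
  shuffled <- build_pairs_strategy1(subs, ref, recs[c(3, 1, 2)],
                                    normalize = FALSE)
  expect_equal(lapply(pairs, `[[`, "target_vol"),
               lapply(shuffled, `[[`, "target_vol"))
  expect_error(build_pairs_strategy1(subs, ref, recs[1:2]), "p3")
  small <- density_volume(ref$values, ref$voxel_A * 1.5)
  expect_error(build_pairs_strategy1(subs, small, recs), "voxel size mismatch")
})

test_that("strategy-2 pairs degrade with noise and coverage, and regenerate", {
  toy <- toy_nucleosome()
  confs <- sample_conformations(toy$model, toy$modes, n = 4,
                                mode_indices = c(7, 13),
                                amplitude_range = c(-120, 120), seed = 2)
  # benign CTF (pure amplitude contrast, no zero crossing in band): the
  # degenerate high-quality simulation should be a near-perfect round trip
  benign <- ctf_params(defocus_um = 0.5, amplitude_contrast = 1)
  clean <- build_pairs_strategy2(confs, box = 24, voxel_A = 8.88,
                                 scheme = tilt_scheme(-90, 90, 1),
                                 ctf = benign, snr = 1e9, seed = 4)
  cc_clean <- vapply(clean$pairs, function(p)
    pearson_cc(p$input_vol, p$target_vol), 0)
  expect_gt(mean(cc_clean), 0.9)
  dirty <- build_pairs_strategy2(confs, box = 24, voxel_A = 8.88,
                                 scheme = tilt_scheme(-40, 40, 3),
                                 ctf = ctf_params(), snr = 0.1, seed = 4)
  cc_dirty <- vapply(dirty$pairs, function(p)
    pearson_cc(p$input_vol, p$target_vol), 0)
  expect_lt(mean(cc_dirty), mean(cc_clean))
  regen <- regenerate_pairs(confs, dirty$manifest)
  expect_identical(lapply(regen, function(p) p$input_vol$values),
                   lapply(dirty$pairs, function(p) p$input_vol$values))
  expect_identical(lapply(regen, function(p) p$target_vol$values),
                   lapply(dirty$pairs, function(p) p$target_vol$values))
})

test_that("pair quality is monotone in noise and angular coverage", {
  toy <- toy_nucleosome()
  confs <- sample_conformations(toy$model, toy$modes, n = 5,
                                mode_indices = c(7, 13),
                                amplitude_range = c(-120, 120), seed = 6)
  snrs <- c(0.03, 0.1, 0.3, 1, 10)
  cc_by_snr <- unlist(lapply(seq_along(snrs), function(i) {
    built <- build_pairs_strategy2(confs, box = 20, voxel_A = 8.88,
                                   scheme = tilt_scheme(-60, 60, 4),
                                   ctf = ctf_params(), snr = snrs[i],
                                   seed = 10 + i)
    vapply(built$pairs, function(p) pearson_cc(p$input_vol, p$target_vol), 0)
  }))
  lev <- rep(snrs, each = 5)
  expect_gt(stats::cor(log(lev), cc_by_snr, method = "spearman"), 0)
  expect_lt(spearman_perm_p(log(lev), cc_by_snr), 0.01)
  covers <- c(20, 40, 60, 80, 90)
  cc_by_cov <- unlist(lapply(seq_along(covers), function(i) {
    built <- build_pairs_strategy2(confs, box = 20, voxel_A = 8.88,
                                   scheme = tilt_scheme(-covers[i], covers[i], 4),
                                   ctf = ctf_params(), snr = 0.5,
                                   seed = 20 + i)
    vapply(built$pairs, function(p) pearson_cc(p$input_vol, p$target_vol), 0)
  }))
  lev2 <- rep(covers, each = 5)
  expect_gt(stats::cor(lev2, cc_by_cov, method = "spearman"), 0)
  expect_lt(spearman_perm_p(lev2, cc_by_cov), 0.01)
})

test_that("normalization commutes with pair construction", {
  toy <- toy_nucleosome()
  confs <- sample_conformations(toy$model, toy$modes, n = 2,
                                mode_indices = 7,
                                amplitude_range = c(-50, 50), seed = 3)
  raw <- build_pairs_strategy2(confs, box = 16, voxel_A = 8.88,
                               scheme = tilt_scheme(-50, 50, 10),
                               ctf = ctf_params(), snr = 1, seed = 9,
                               normalize = FALSE)
  norm <- build_pairs_strategy2(confs, box = 16, voxel_A = 8.88,
                                scheme = tilt_scheme(-50, 50, 10),
                                ctf = ctf_params(), snr = 1, seed = 9,
                                normalize = TRUE)
  for (i in seq_along(raw$pairs)) {
    expect_identical(normalize_volume(raw$pairs[[i]]$input_vol)$values,
                     norm$pairs[[i]]$input_vol$values)
    expect_identical(normalize_volume(raw$pairs[[i]]$target_vol)$values,
                     norm$pairs[[i]]$target_vol$values)
  }
})

test_that("manifest splitting holds out the requested fraction, reproducibly", {
  toy <- toy_nucleosome()
  confs <- sample_conformations(toy$model, toy$modes, n = 2, mode_indices = 7,
                                amplitude_range = c(0, 0), seed = 1)
  m <- tibble::tibble(pair = 1:20)
  s1 <- split_manifest(m, 0.1, seed = 2)
  s2 <- split_manifest(m, 0.1, seed = 2)
  expect_identical(s1$validation, s2$validation)
  expect_equal(sum(s1$validation), 2)
})
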