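test_that("slice averaging reduces noise variance as 1/n", {
  vol <- default_phantom(32)
  expect_equal(slice_average(vol, 5, n = 1), vol$values[, , 5])
  const <- density_volume(array(rep(vol$values[, , 1], 32), rep(32, 3)), 1)
  expect_equal(slice_average(const, 3, n = 10), const$values[, , 1])
  set.seed(1)
  noise <- density_volume(array(rnorm(64 * 64 * 10), c(64, 64, 10)), 1)
  av <- slice_average(noise, 1, n = 10)
  expect_equal(stats::var(as.vector(av)) /
                 stats::var(as.vector(noise$values[, , 1])),
               1 / 10, tolerance = 0.2)
  expect_error(slice_average(vol, 30, n = 10), "out of bounds")
})

test_that("region pairs validate geometry", {
  expect_error(region_pair(c(1, 3, 1, 3), c(10, 20, 10, 20)), ">= 16")
  expect_error(region_pair(c(1, 11, 1, 11), c(5, 15, 5, 15)), "overlap")
  expect_s3_class(region_pair(c(1, 11, 1, 11), c(12, 22, 1, 11)),
                  "region_pair")
})

test_that("the region SNR estimator reproduces analytic dB values", {
  # deterministic construction: v_s exactly 10 x v_b -> exactly 10 dB
  base <- rep(c(-1, 1), length.out = 100)       # variance 100/99
  mg <- matrix(0, 40, 10)
  mg[1:10, 1:10] <- base * sqrt(10)             # signal region
  mg[11:20, 1:10] <- base                       # background region
  rp <- region_pair(c(1, 11, 1, 11), c(11, 21, 1, 11))
  est <- estimate_snr_db(mg, list(rp))
  expect_equal(est$mean_db, 10, tolerance = 1e-12)
  # equal variance -> 0 dB expected
  mg0 <- mg; mg0[1:10, 1:10] <- base
  expect_equal(estimate_snr_db(mg0, list(rp))$mean_db, 0, tolerance = 1e-12)
  # stochastic: background N(0,1), signal = background + N(0,3) -> v_s ~ 4
  set.seed(42)
  mgs <- matrix(rnorm(1000 * 100), 1000, 100)
  regions <- lapply(0:9, function(i) {
    x0 <- 1 + i * 100
    sig <- c(x0, x0 + 50, 1, 51)
    bg <- c(x0 + 50, x0 + 100, 1, 51)
    mgs[sig[1]:(sig[2] - 1), 1:50] <<-
      mgs[sig[1]:(sig[2] - 1), 1:50] * 0 +
      rnorm(50 * 50) + rnorm(50 * 50, sd = sqrt(3))
    region_pair(sig, bg)
  })
  est2 <- estimate_snr_db(mgs, regions)
  expect_equal(est2$mean_db, 10 * log10(4), tolerance = 0.5)
  expect_equal(est2$n_regions, 10)
  expect_equal(est2$mean_db, mean(est2$per_region$snr_db))
})

test_that("the SNR estimator is shift-invariant and scale-equivariant", {
  set.seed(3)
  mg <- matrix(rnorm(60 * 30), 60, 30)
  mg[1:10, 1:10] <- mg[1:10, 1:10] * 3
  rp <- list(region_pair(c(1, 11, 1, 11), c(21, 31, 1, 11)))
  base <- estimate_snr_db(mg, rp)$mean_db
  expect_equal(estimate_snr_db(mg + 100, rp)$mean_db, base, tolerance = 1e-9)
  expect_equal(estimate_snr_db(mg * 7, rp)$mean_db, base, tolerance = 1e-9)
  flat <- matrix(1, 60, 30)
  expect_error(estimate_snr_db(flat, rp), "zero variance")
})

test_that("pearson_cc has the affine-invariance contract", {
  v <- default_phantom(16)
  expect_equal(pearson_cc(v, v), 1)
  neg <- density_volume(-v$values, 1)
  expect_equal(pearson_cc(v, neg), -1)
  aff <- density_volume(3 * v$values + 2, 1)
  expect_equal(pearson_cc(v, aff), 1)
  set.seed(2)
  a <- density_volume(array(rnorm(32^3), rep(32, 3)), 1)
  b <- density_volume(array(rnorm(32^3), rep(32, 3)), 1)
  expect_lt(abs(pearson_cc(a, b)), 0.05)
  flat <- density_volume(array(1, rep(16, 3)), 1)
  expect_error(pearson_cc(v, flat), "zero variance")
  expect_error(pearson_cc(v, density_volume(array(0, rep(8, 3)), 1)),
               "different dimensions")
  mask <- array(FALSE, rep(16, 3)); mask[1:4, 1, 1] <- TRUE
  expect_equal(pearson_cc(v, aff, mask), 1)
})

test_that("wedge energy fraction matches flat-spectrum expectations", {
  v <- default_phantom(32)
  expect_equal(wedge_energy_fraction(v, tilt_scheme(-90, 90, 1)), 0)
  set.seed(5)
  wn <- density_volume(array(rnorm(64^3), rep(64, 3)), 1)
  sch <- tilt_scheme(-60, 60, 2)
  frac <- wedge_energy_fraction(wn, sch)
  voxfrac <- mean(!wedge_mask(64, sch))
  expect_equal(frac, voxfrac, tolerance = 0.02)
  rec <- wbp_reconstruct(project(default_phantom(48), sch), sch)
  expect_lt(wedge_energy_fraction(rec, sch), 0.05 * frac)
})

test_that("template matching finds exact copies and agrees with brute force", {
  set.seed(6)
  tpl <- make_phantom(8, list(c(4, 4, 4)), 1.4)
  tomo_vals <- array(rnorm(16^3, sd = 0.01), rep(16, 3))
  tomo_vals[5:12, 3:10, 6:13] <- tomo_vals[5:12, 3:10, 6:13] + tpl$values
  tomo <- density_volume(tomo_vals, 1)
  m <- template_match(tomo, tpl, angular_step_deg = 360, cc_threshold = 0.5,
                      min_separation_vox = 4)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x, m$y, m$z), c(5 + 4, 3 + 4, 6 + 4))
  expect_gt(m$cc, 0.99)
  # FFT path equals the brute-force spatial oracle on the valid region
  brute <- tomorest:::template_match_brute(tomo, tpl)
  Ft <- stats::fft(tomo$values)
  # recompute the fft cc map via the exported path at identity orientation
  m_all <- template_match(tomo, tpl, angular_step_deg = 360,
                          cc_threshold = -1.1, min_separation_vox = 1)
  for (r in sample(nrow(m_all), 25)) {
    i <- m_all$x[r] - 4; j <- m_all$y[r] - 4; k <- m_all$z[r] - 4
    expect_equal(m_all$cc[r], brute[i, j, k], tolerance = 1e-6)
  }
  expect_warning(res <- template_match(tomo, tpl, cc_threshold = 1),
                 "no peaks")
  expect_equal(nrow(res), 0)
})

test_that("template matching recovers a grid orientation", {
  tpl <- make_phantom(12, list(c(6, 4, 6), c(8, 8, 6)), c(1.5, 1.2))
  rot <- apply_transform(tpl, rigid_transform(c(0, 90, 0)))
  tomo_vals <- array(rnorm(24^3, sd = 0.005), rep(24, 3))
  tomo_vals[7:18, 7:18, 7:18] <- tomo_vals[7:18, 7:18, 7:18] + rot$values
  tomo <- density_volume(tomo_vals, 1)
  m <- template_match(tomo, tpl, angular_step_deg = 90, cc_threshold = 0.5,
                      min_separation_vox = 6)
  expect_gte(nrow(m), 1)
  best <- m[which.max(m$cc), ]
  expect_equal(c(best$rot, best$tilt, best$psi), c(0, 90, 0))
})

test_that("offset statistics pair greedily within the radius", {
  truth <- rbind(c(10, 10, 10), c(30, 30, 30))
  exact <- tibble::tibble(x = c(10, 30), y = c(10, 30), z = c(10, 30),
                          rot = 0, tilt = 0, psi = 0, cc = c(0.9, 0.8))
  st <- offset_statistics(exact, truth, match_radius_vox = 4)
  expect_equal(st$n_matched, 2)
  expect_true(all(st$summary$rms == 0))
  one <- tibble::tibble(x = 11, y = 12, z = 13, rot = 0, tilt = 0, psi = 0,
                        cc = 0.7)
  st1 <- offset_statistics(one, truth[1, , drop = FALSE],
                           match_radius_vox = 10)
  expect_equal(c(st1$offsets$dx, st1$offsets$dy, st1$offsets$dz), c(1, 2, 3))
  far <- tibble::tibble(x = 100, y = 100, z = 100, rot = 0, tilt = 0, psi = 0,
                        cc = 0.5)
  stf <- offset_statistics(far, truth, match_radius_vox = 5)
  expect_equal(stf$n_matched, 0)
  expect_equal(stf$unmatched_truth, 1:2)
  expect_error(offset_statistics(exact, rbind(truth, truth[1, ]), 4),
               "duplicate")
  # matched count never exceeds min(#matches, #truth)
  st2 <- offset_statistics(exact[1, ], truth, match_radius_vox = 100)
  expect_lte(st2$n_matched, 1)
})

test_that("tidiers expose per-region and history tables", {
  mg <- matrix(rnorm(60 * 30), 60, 30)
  est <- estimate_snr_db(mg, list(region_pair(c(1, 11, 1, 11),
                                              c(21, 31, 1, 11))))
  expect_s3_class(tidy(est), "tbl_df")
  expect_equal(glance(est)$n_regions, 1)
  expect_s3_class(autoplot(est), "ggplot")
})

test_that("region pairs round-trip through JSON", {
  regions <- list(region_pair(c(1, 11, 1, 11), c(12, 22, 1, 11)),
                  region_pair(c(30, 40, 5, 15), c(41, 51, 5, 15)))
  p <- tempfile(fileext = ".json")
  write_region_pairs(regions, p)
  back <- read_region_pairs(p)
  expect_equal(back, regions)
})
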