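# Tumor volume distribution, phantom rasterization, cohort and folds.

test_that("calibrated truncated log-normal reproduces the cohort moments", {
  d <- calibrate_volume_distribution(18.33, 27.20, 0.07, 167.99)
  expect_lt(abs(d$achieved_mean - 18.33), 0.01 * 18.33)
  expect_lt(abs(d$achieved_sd - 27.20), 0.05 * 27.20)
  expect_gt(d$log_sigma, 0)

  # independent check of the closed-form moments by numerical integration
  dens_norm <- stats::integrate(function(v) {
    stats::dlnorm(v, d$log_mu, d$log_sigma)
  }, 0.07, 167.99)$value
  m1 <- stats::integrate(function(v) {
    v * stats::dlnorm(v, d$log_mu, d$log_sigma)
  }, 0.07, 167.99)$value / dens_norm
  m2 <- stats::integrate(function(v) {
    v^2 * stats::dlnorm(v, d$log_mu, d$log_sigma)
  }, 0.07, 167.99)$value / dens_norm
  expect_lt(abs(m1 - d$achieved_mean), 1e-4 * d$achieved_mean)
  expect_lt(abs(sqrt(m2 - m1^2) - d$achieved_sd), 1e-4 * d$achieved_sd)
})

test_that("zero-variance target gives the degenerate distribution", {
  d <- calibrate_volume_distribution(target_sd = 0)
  expect_equal(d$log_sigma, 0)
  expect_equal(sample_tumor_volume(d, 5), rep(18.33, 5))
})

test_that("volume sampling is deterministic, clipped and unbiased", {
  d <- calibrate_volume_distribution()
  set.seed(42)
  v1 <- sample_tumor_volume(d, 600)
  set.seed(42)
  v2 <- sample_tumor_volume(d, 600)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0.07 & v1 <= 167.99))
  # sample mean within two standard errors of the study mean
  expect_lt(abs(mean(v1) - 18.33), 2 * 27.20 / sqrt(600))

  set.seed(1)
  big <- sample_tumor_volume(d, 1e6)
  expect_lt(abs(mean(big) - 18.33), 0.2)
})

test_that("empirical CDF matches the truncated log-normal CDF", {
  d <- calibrate_volume_distribution()
  set.seed(9)
  v <- sample_tumor_volume(d, 1e5)
  # Kolmogorov-Smirnov distance against the analytic truncated CDF
  ks <- max(abs(seq_along(v) / length(v) -
                  volume_distribution_cdf(d, sort(v))))
  expect_lt(ks, 0.01)
})

test_that("rasterized tumor volume matches the requested volume", {
  spec <- quiet_spec(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1))
  set.seed(3)
  cs <- rasterize_case(spec, 8, case_id = "v8")
  vox_ml <- voxels_to_ml(sum(cs$labels$data == 1L), spec$spacing)
  expect_lt(abs(vox_ml - 8) / 8, 0.15)

  # monotonicity: a larger request never yields fewer voxels
  set.seed(3)
  cs2 <- rasterize_case(spec, 16, case_id = "v16")
  expect_gt(sum(cs2$labels$data == 1L), sum(cs$labels$data == 1L))
})

test_that("noiseless phantom is piecewise constant per tissue class", {
  spec <- quiet_spec()
  set.seed(4)
  cs <- rasterize_case(spec, 5)
  expect_lte(length(unique(as.vector(cs$image$data))), 4)
  expect_setequal(unique(as.vector(cs$image$data)),
                  c(0, 60, 100, 200))
})

test_that("multifocal cases have disjoint instances matching placed count", {
  spec <- quiet_spec()
  set.seed(5)
  cs <- rasterize_case(spec, c(4, 2))
  expect_setequal(setdiff(unique(as.vector(cs$labels$data)), 0L), c(1L, 2L))
  cc <- extract_instances(cs$labels$data > 0, 26L)
  expect_equal(max(cc), 2L)
})

test_that("every labelled voxel lies inside the head", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing = c(2, 2, 2))
  set.seed(6)
  cs <- rasterize_case(spec, c(10, 1))
  xs <- (seq_len(48) - 24.5) * 2
  inside <- outer(outer((xs / spec$head_axes[1])^2,
                        (xs / spec$head_axes[2])^2, `+`),
                  (xs / spec$head_axes[3])^2, `+`) <= 1
  expect_true(all(inside[cs$labels$data > 0]))
})

test_that("cohort generation is reproducible and writes complete manifests", {
  spec <- quiet_spec()
  dist <- calibrate_volume_distribution()
  c1 <- generate_cohort(6, spec, dist, seed = 1, keep_cases = FALSE)
  c2 <- generate_cohort(6, spec, dist, seed = 1, keep_cases = FALSE)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 6)
  expect_true(all(c1$manifest$n_tumors >= 1))

  dir <- withr::local_tempdir()
  c3 <- generate_cohort(2, spec, dist, seed = 2, out_dir = dir,
                        keep_cases = TRUE)
  expect_true(all(file.exists(c3$manifest$image_path)))
  im <- read_volume(c3$manifest$image_path[1])
  expect_equal(dim(im$data), dim(c3$cases[[1]]$image$data))
  expect_equal(im$spacing, c3$cases[[1]]$image$spacing)
  lab <- read_volume(c3$manifest$label_path[1], is_label = TRUE)
  expect_identical(lab$data, c3$cases[[1]]$labels$data)
})

test_that("serpentine fold assignment balances volumes", {
  # ten cases with volumes 1..10 and k = 5: mirrored pairs, equal sums
  man <- data.frame(case_id = sprintf("c%02d", 1:10),
                    total_volume_ml = 1:10)
  f <- assign_folds(man, k = 5)
  split_vols <- split(f$total_volume_ml, f$fold)
  expect_equal(unname(lapply(split_vols, sort)),
               list(c(1, 10), c(2, 9), c(3, 8), c(4, 7), c(5, 6)))
  expect_true(all(vapply(split_vols, sum, 0) == 11))

  # fold sizes differ by at most one and means stay within 10% of the
  # cohort mean at the study's cohort size (large folds absorb the
  # heavy right tail of the volume distribution)
  set.seed(8)
  man2 <- data.frame(case_id = sprintf("c%03d", 1:600),
                     total_volume_ml = sample_tumor_volume(
                       calibrate_volume_distribution(), 600))
  f2 <- assign_folds(man2, k = 5)
  sizes <- table(f2$fold)
  expect_lte(diff(range(sizes)), 1)
  means <- tapply(f2$total_volume_ml, f2$fold, mean)
  expect_true(all(abs(means - mean(man2$total_volume_ml)) <
                    0.10 * mean(man2$total_volume_ml)))

  # identical volumes: any balanced split passes
  man3 <- data.frame(case_id = sprintf("c%02d", 1:10),
                     total_volume_ml = rep(2, 10))
  f3 <- assign_folds(man3, k = 5)
  expect_lte(diff(range(table(f3$fold))), 1)
  expect_error(assign_folds(man3, k = 1), "at least 2")
})
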