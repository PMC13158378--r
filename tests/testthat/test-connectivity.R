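test_that("seed series extraction averages exactly the seed voxels", {
  set.seed(50)
  m <- matrix(rnorm(60 * 6), 60, 6)
  run <- matrix_run(m)
  seed1 <- array(FALSE, c(6, 1, 1)); seed1[3, 1, 1] <- TRUE
  expect_equal(extract_seed_series(run, seed1), m[, 3])
  seed3 <- array(FALSE, c(6, 1, 1)); seed3[c(1, 4, 5), 1, 1] <- TRUE
  expect_equal(extract_seed_series(run, seed3), rowMeans(m[, c(1, 4, 5)]))
  expect_error(extract_seed_series(run, array(FALSE, c(6, 1, 1))), "empty")
})

test_that("Fisher z maps transform correlations with clamping and odd symmetry", {
  set.seed(51)
  n <- 2000
  s <- rnorm(n)
  # build a voxel with r ~ 0.5 against the seed, one identical, one independent
  v_half <- 0.5 * s + sqrt(1 - 0.25) * rnorm(n)
  m <- cbind(v_half, s, rnorm(n), -v_half)
  run <- matrix_run(m)
  z <- seed_correlation_map(run, s)
  r_emp <- cor(v_half, s)
  expect_equal(z$values[1, 1, 1], atanh(r_emp), tolerance = 1e-10)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_gt(z$values[2, 1, 1], atanh(1 - 1e-7) - 1e-6)   # clamped, not Inf
  expect_equal(z$flags$clamped, 1L)
  expect_lt(abs(z$values[3, 1, 1]), 0.08)
  expect_equal(z$values[4, 1, 1], -z$values[1, 1, 1], tolerance = 1e-10)
  expect_error(seed_correlation_map(run, rep(1, n)), "constant")
})

test_that("smoothing has the requested width, preserves the mean, is identity at 0", {
  dm <- c(31, 31, 31)
  arr <- array(0, dm); arr[16, 16, 16] <- 1
  mask <- array(TRUE, dm)
  expect_identical(smooth_map(arr, 0, 2, mask), arr)
  sm <- smooth_map(arr, fwhm_mm = 6, voxel_size_mm = 2, mask = mask)
  prof <- sm[, 16, 16]
  half <- max(prof) / 2
  f <- approxfun(1:31, prof - half)
  lo <- uniroot(f, c(12, 15))$root
  hi <- uniroot(f, c(17, 20))$root
  expect_equal((hi - lo) * 2, 6, tolerance = 1)          # within half a voxel
  expect_equal(mean(sm[mask]), mean(arr[mask]), tolerance = 1e-6)
  # mask-aware: conservation holds even with an irregular mask
  set.seed(52)
  mask2 <- array(runif(prod(dm)) > 0.4, dm)
  vals <- array(rnorm(prod(dm), 5), dm)
  sm2 <- smooth_map(vals, 6, 2, mask2)
  expect_equal(mean(sm2[mask2]), mean(vals[mask2]), tolerance = 1e-6)
  expect_true(all(is.na(sm2[!mask2])))
})

test_that("smoothing approximately commutes with averaging over large regions", {
  set.seed(53)
  dm <- c(24, 24, 24)
  mask <- array(TRUE, dm)
  vals <- array(rnorm(prod(dm), mean = 2), dm)
  roi <- array(FALSE, dm); roi[4:20, 4:20, 4:12] <- TRUE   # region >> kernel
  sm <- smooth_map(vals, 6, 2, mask)
  expect_equal(mean(sm[roi]), mean(vals[roi]), tolerance = 0.05)
})

test_that("regional FC averages exclude the seed region", {
  labs <- array(0L, c(6, 6, 1))
  labs[1:2, , 1] <- 1L; labs[3:4, , 1] <- 2L; labs[5:6, , 1] <- 3L
  at <- label_atlas(labs)
  vals <- array(0.5, c(6, 6, 1))
  vals[3:4, , 1] <- 0.2
  z <- structure(list(values = vals, flags = list(clamped = 0L)), class = "z_map")
  fc <- roi_fc(z, at, exclude_label = 1L)
  expect_equal(names(fc), c("2", "3"))
  expect_equal(unname(fc), c(0.2, 0.5))
  u <- roi_fc(structure(list(values = array(0.7, c(6, 6, 1)),
                             flags = list(clamped = 0L)), class = "z_map"), at)
  expect_equal(unname(u), rep(0.7, 3))
})

test_that("the mixed model recovers a planted group effect on one table", {
  tab <- simulate_fc_table(30, n_rois = 1, effect_z = 0.4, subject_sd = 0.2,
                           resid_sd = 0.1, seed = 60)
  fit <- fit_fc_mixed_model(tab)
  ge <- fit$effects[grepl("^group", fit$effects$term), ]
  expect_lt(abs(ge$beta - 0.4), 0.15)
  expect_lt(ge$p, 1e-6)
  expect_gt(fit$var_subject, 0.01)   # random intercept detected
  # balanced duplication leaves the fixed effects unchanged
  fit2 <- fit_fc_mixed_model(rbind(tab, tab))
  expect_equal(fit2$effects$beta, fit$effects$beta, tolerance = 1e-6)
})

test_that("fixed-effect tests are calibrated under the null", {
  set.seed(61)
  rej <- vapply(1:200, function(s) {
    tab <- simulate_fc_table(15, n_rois = 1, effect_z = 0, subject_sd = 0.15,
                             resid_sd = 0.1, seed = 7000 + s)
    fit <- fit_fc_mixed_model(tab)
    fit$effects$p[grepl("^group", fit$effects$term)] < 0.05
  }, TRUE)
  # binomial 95% band around 0.05 at 200 replicates
  expect_gte(sum(rej), qbinom(0.025, 200, 0.05))
  expect_lte(sum(rej), qbinom(0.975, 200, 0.05))
})

test_that("FDR adjustment follows step-up arithmetic and BY dominates BH", {
  expect_equal(fdr_adjust(0.03, "BH"), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(62)
  p <- runif(50)^2
  expect_true(all(fdr_adjust(p, "BY") >= fdr_adjust(p, "BH") - 1e-15))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significant-region reports contain exactly the planted region, sorted", {
  # all-null tables produce an empty report
  fits0 <- lapply(1:6, function(r) {
    fit_fc_mixed_model(simulate_fc_table(15, n_rois = 1, effect_z = 0,
                                         seed = 800 + r))
  })
  names(fits0) <- paste0("roi", 1:6)
  expect_equal(nrow(report_significant_rois(fits0, q = 0.001)), 0L)
  # one planted region is reported at q = 0.001
  tab <- simulate_fc_table(30, n_rois = 8, effect_rois = 3, effect_z = 0.4,
                           subject_sd = 0.2, resid_sd = 0.1, seed = 63)
  fits <- lapply(split(tab, tab$roi), fit_fc_mixed_model)
  rep_ <- report_significant_rois(fits, q = 0.001)
  expect_equal(unique(rep_$roi), "3")
  expect_false(is.unsorted(rep_$p_fdr[!is.na(rep_$p_fdr)]))
})

test_that("group-coupled regions show positive group betas, uncoupled none", {
  # latent-coupling difference between groups propagates to the FC group effect
  spec <- cohort_spec(n_per_group = 8, n_sessions = 2, n_frames = 200,
                      grid_shape = c(10L, 10L, 10L), atlas_rois = 4L,
                      fc_coupling = rbind(c(3, 1, 0, 0), c(3, 2.5, 0, 0)),
                      motion_spike_prob = 0, rng_seed = 19)
  co <- simulate_cohort(spec)
  rows <- list()
  for (sid in names(co$runs)) for (s in 1:2) {
    r <- co$runs[[sid]][[s]]
    z <- seed_correlation_map(r$run, extract_seed_series(r$run, co$atlas$labels == 1))
    fc <- roi_fc(z, co$atlas, exclude_label = 1L)
    rows[[paste(sid, s)]] <- data.frame(
      subject = sid, session = s,
      group = co$subjects$group[co$subjects$subject == sid],
      roi = names(fc), fc = unname(fc))
  }
  tab <- do.call(rbind, rows)
  mean_fc <- function(roi, grp) mean(tab$fc[tab$roi == roi & tab$group == grp])
  expect_gt(mean_fc("2", 2) - mean_fc("2", 1), 0.05)   # coupled region
  expect_lt(abs(mean_fc("4", 2) - mean_fc("4", 1)), 0.05)  # uncoupled region
})
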