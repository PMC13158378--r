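test_that("generated atlas partitions the brain mask into compact nonempty regions", {
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(12L, 12L, 12L),
                      atlas_rois = 4L, rng_seed = 3L)
  at <- generate_atlas(spec)
  at2 <- generate_atlas(spec)
  expect_identical(at$labels, at2$labels)   # deterministic given (spec, seed)
  counts <- table(at$labels[at$labels > 0])
  expect_equal(sort(as.integer(names(counts))), 1:4)
  expect_true(all(counts > 0))
  # labels exactly tile the mask (union = mask, pairwise disjoint by construction)
  mask_vox <- sum(at$labels > 0)
  expect_equal(mask_vox, sum(counts))
  expect_error(generate_atlas(cohort_spec(atlas_rois = 10000L,
                                          grid_shape = c(6L, 6L, 6L))),
               "voxels")
})

test_that("motion traces are quiet without spikes and always displaced with them", {
  mt0 <- generate_motion_trace(200, spike_prob = 0, seed = 11)
  d <- abs(diff(mt0$trace[, 1:3]))
  expect_lt(max(d), 0.1)
  expect_length(mt0$spike_frames, 0)
  # spike_prob = 1: every interior frame's FD >= the 1 mm spike magnitude
  # (jitter-free trace so the bound is exact at the first spike entry)
  mt1 <- generate_motion_trace(80, spike_prob = 1, spike_mag_mm = 1.0, seed = 12,
                               jitter_sd_mm = 0)
  fd <- fd_oracle(mt1$trace)
  expect_true(all(fd[-1] >= 1.0))
})

test_that("motion traces rewrite byte-identically", {
  dir <- withr::local_tempdir()
  mt <- generate_motion_trace(50, spike_prob = 0.1, seed = 13)
  f1 <- file.path(dir, "a.tsv"); f2 <- file.path(dir, "b.tsv")
  write_motion(mt$trace, f1)
  write_motion(generate_motion_trace(50, spike_prob = 0.1, seed = 13)$trace, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_motion(f1)
  expect_equal(unclass(back), unclass(mt$trace), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("group-2 band amplitude scaling yields the squared power ratio", {
  # effect_band_amp = 1.2 -> band power ratio 1.44, checked on seed-region
  # voxels with all other signal sources switched off
  spec <- cohort_spec(n_per_group = 1, n_sessions = 1, n_frames = 480,
                      grid_shape = c(12L, 12L, 12L), atlas_rois = 4L,
                      fc_coupling = matrix(0, 2, 4),
                      physio = list(resp_hz = 0.3, cardiac_hz = 1.1,
                                    resp_amp = 0, cardiac_amp = 0),
                      global_coupling_sd = 0, sigma_global = 0,
                      sigma_white = 0.01, drift = list(on = FALSE, amp = 0,
                                                       freq_hz = 0.003),
                      subject_amp_sd = 0, subject_noise_sd = 0,
                      session_scale_sd = 0, motion_spike_prob = 0, rng_seed = 5)
  at <- generate_atlas(spec)
  band_power <- function(r, vox) {
    y <- matrix(r$run$data, ncol = dim(r$run$data)[4])[vox, , drop = FALSE]
    mean(apply(y, 1, function(x) band_rms_oracle(x, r$run$tr)^2))
  }
  vox <- which(at$labels == spec$seed_roi_id)
  vox <- vox[seq_len(min(60, length(vox)))]
  r1 <- generate_subject_run(spec, 1, 1, at, seed = 21)
  r2 <- generate_subject_run(spec, 2, 1, at, seed = 22)
  ratio <- band_power(r2, vox) / band_power(r1, vox)
  expect_equal(ratio, 1.44, tolerance = 0.08)   # Monte-Carlo error over ~60 voxels
  # and the band power itself is calibrated to sigma_neural^2 within 5%
  expect_equal(band_power(r1, vox), spec$sigma_neural^2, tolerance = 0.05)
})

test_that("zero coupling gives near-zero seed-region correlations", {
  # shared physio/global/drift components off, so voxels are independent
  spec <- cohort_spec(n_per_group = 1, n_sessions = 1, n_frames = 300,
                      grid_shape = c(10L, 10L, 10L), atlas_rois = 4L,
                      fc_coupling = matrix(0, 2, 4), motion_spike_prob = 0,
                      physio = list(resp_hz = 0.3, cardiac_hz = 1.1,
                                    resp_amp = 0, cardiac_amp = 0),
                      sigma_global = 0, global_coupling_sd = 0,
                      drift = list(on = FALSE, amp = 0, freq_hz = 0.003),
                      rng_seed = 9)
  at <- generate_atlas(spec)
  r <- generate_subject_run(spec, 1, 1, at, seed = 30)
  zs <- seed_correlation_map(r$run, extract_seed_series(r$run, at$labels == 2))
  other <- abs(zs$values[at$labels == 3])
  expect_lt(mean(other), 0.12)
})

test_that("identical spec and seed reproduce a run exactly; session index is checked", {
  spec <- tiny_spec()
  at <- generate_atlas(spec)
  a <- generate_subject_run(spec, 1, 1, at, seed = 40)
  b <- generate_subject_run(spec, 1, 1, at, seed = 40)
  expect_identical(a$run$data, b$run$data)
  expect_identical(a$motion, b$motion)
  expect_error(generate_subject_run(spec, 1, 3, at, seed = 40), "out of range")
  expect_error(generate_subject_run(spec, 5, 1, at, seed = 40), "group")
})

test_that("cohorts have the right run count, balanced sexes, and safe output", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 3, n_sessions = 2, n_frames = 40,
                      grid_shape = c(8L, 8L, 8L), atlas_rois = 3L, rng_seed = 2)
  out <- file.path(dir, "cohort")
  generate_cohort(spec, out)
  expect_length(list.files(out, pattern = "_bold\\.nii\\.gz$"), 12L)  # 3 x 2 x 2
  part <- read.delim(file.path(out, "participants.tsv"))
  expect_equal(nrow(part), 12L)
  bysex <- table(part$group, part$sex) / spec$n_sessions
  expect_true(all(bysex >= 1))   # both sexes present within each group
  expect_equal(bysex["1", "F"], bysex["1", "M"] + spec$n_per_group %% 2)
  # ground truth round-trips through JSON
  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed_roi_id, spec$seed_roi_id)
  expect_equal(unname(as.matrix(gt$band_amp_by_group)),
               matrix(c(1, 1.2, rep(1, 4)), 2, 3)[, c(1, 2, 3)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # no silent overwrite
  expect_error(generate_cohort(spec, out), "overwrite")
  # spec YAML round-trip reproduces the cohort spec
  spec2 <- read_cohort_spec(file.path(out, "cohort_spec.yaml"))
  expect_equal(spec2$fc_coupling, spec$fc_coupling)
  expect_equal(spec2$tr_by_group, spec$tr_by_group)
})

test_that("subject factors persist across sessions but differ across subjects", {
  spec <- tiny_spec(subject_amp_sd = 0.3)
  co <- simulate_cohort(spec)
  f11 <- co$runs[["sub-001"]][[1]]$subject_factors
  f12 <- co$runs[["sub-001"]][[2]]$subject_factors
  f21 <- co$runs[["sub-002"]][[1]]$subject_factors
  expect_identical(f11, f12)
  expect_false(isTRUE(all.equal(f11$amp, f21$amp)))
})
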