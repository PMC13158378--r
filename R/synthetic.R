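#' Specification of a synthetic two-group, two-session BOLD cohort
#'
#' Defines the study conditions the generator emulates: two groups scanned in
#' two sessions on separate days (70 subjects per group, sex-balanced), TR
#' 0.72 s for group 1 and 0.8 s for group 2, ~6.5-minute runs (541 frames),
#' a low-frequency (0.008-0.1 Hz) neural band whose amplitude is scaled by
#' `effect_band_amp` for group 2 inside the designated regions, aliased
#' cardiac (1.1 Hz) and respiratory (0.3 Hz) components, a global signal
#' with voxelwise coupling betas, slow drift (the analysis never detrends,
#' so the fractional metric must tolerate it), motion spike frames, and a
#' shared latent signal coupling the seed region to target regions with a
#' group-dependent strength.
#'
#' @param n_per_group subjects per group (default 70)
#' @param n_sessions sessions per subject (default 2)
#' @param tr_by_group repetition times in seconds, one per group (defaults 0.72, 0.8)
#' @param n_frames frames per run after any truncation (default 541)
#' @param grid_shape voxel grid (default 16 x 16 x 16)
#' @param voxel_size voxel edge, mm (default 2)
#' @param atlas_rois number of atlas regions (default 6)
#' @param seed_roi_id label of the seed region (default 1)
#' @param effect_rois labels whose band amplitude carries the group effect
#'   (default: the seed region)
#' @param effect_band_amp multiplicative low-frequency amplitude factor for
#'   group 2 in `effect_rois` (default 1.2)
#' @param effect_highfreq_amp multiplicative factor on group 2's white
#'   (high-frequency) noise (default 1; < 1 raises the fractional metric)
#' @param fc_coupling 2 x `atlas_rois` matrix of latent-signal coupling
#'   strengths (rows = groups, au); default: seed region 3 in both groups,
#'   regions 2-3 coupled at 1.0 (group 1) vs 1.5 (group 2), others 0
#' @param physio list: `resp_hz`, `cardiac_hz`, `resp_amp`, `cardiac_amp`
#' @param global_coupling_sd SD of voxelwise global-signal betas around 1
#' @param sigma_neural SD of the band-limited neural component (au)
#' @param sigma_white SD of the white noise floor (au)
#' @param sigma_global SD of the global (slow, shared) component (au)
#' @param drift list: `on`, `amp`, `freq_hz` -- slow (< 0.008 Hz) drift
#' @param baseline mean signal level (au)
#' @param subject_amp_sd log-scale SD of the per-subject neural amplitude factor
#' @param subject_noise_sd log-scale SD of the per-subject noise factor
#' @param session_scale_sd log-scale SD of the per-session global gain factor
#'   (a scanner-gain effect that cancels in fractional amplitude)
#' @param motion_spike_prob per-frame probability of a motion spike
#' @param spike_mag_mm translation magnitude of a spike (default 2 mm)
#' @param spike_artifact_amp BOLD artifact amplitude at spike frames (au)
#' @param band low-frequency band, a [band_spec()]
#' @param rng_seed master integer seed; the whole cohort is a deterministic
#'   function of (spec, rng_seed)
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = 70L, n_sessions = 2L,
                        tr_by_group = c(0.72, 0.8), n_frames = 541L,
                        grid_shape = c(16L, 16L, 16L), voxel_size = 2,
                        atlas_rois = 6L, seed_roi_id = 1L,
                        effect_rois = seed_roi_id,
                        effect_band_amp = 1.2, effect_highfreq_amp = 1.0,
                        fc_coupling = NULL,
                        physio = list(resp_hz = 0.3, cardiac_hz = 1.1,
                                      resp_amp = 2.0, cardiac_amp = 1.5),
                        global_coupling_sd = 0.3,
                        sigma_neural = 10, sigma_white = 5, sigma_global = 2,
                        drift = list(on = TRUE, amp = 3, freq_hz = 0.003),
                        baseline = 1000,
                        subject_amp_sd = 0.1, subject_noise_sd = 0.1,
                        session_scale_sd = 0.05,
                        motion_spike_prob = 0.01, spike_mag_mm = 2.0,
                        spike_artifact_amp = 15,
                        band = band_spec(), rng_seed = 1L) {
  if (n_per_group < 1L || n_sessions < 1L || n_frames < 2L || atlas_rois < 1L)
    stop_lfamp("counts must be >= 1 (and n_frames >= 2)")
  if (any(tr_by_group <= 0) || length(tr_by_group) != 2L)
    stop_lfamp("tr_by_group must be two positive repetition times")
  if (effect_band_amp <= 0 || effect_highfreq_amp <= 0)
    stop_lfamp("effect factors must be > 0")
  if (any(unlist(physio[c("resp_hz", "cardiac_hz")]) <= 0))
    stop_lfamp("physiological frequencies must be > 0")
  if (motion_spike_prob < 0 || motion_spike_prob > 1)
    stop_lfamp("motion_spike_prob must lie in [0, 1]")
  if (is.null(fc_coupling)) {
    fc_coupling <- matrix(0, 2, atlas_rois)
    fc_coupling[, seed_roi_id] <- 3
    targets <- setdiff(seq_len(atlas_rois), seed_roi_id)
    targets <- head(targets, 2)
    fc_coupling[1, targets] <- 1.0
    fc_coupling[2, targets] <- 1.5
  }
  if (!identical(dim(fc_coupling), c(2L, as.integer(atlas_rois))) &&
      !identical(dim(fc_coupling), c(2L, length(seq_len(atlas_rois)))))
    stop_lfamp("fc_coupling must be a 2 x atlas_rois matrix")
  if (!seed_roi_id %in% seq_len(atlas_rois))
    stop_lfamp("seed_roi_id %d outside 1..%d", seed_roi_id, atlas_rois)
  structure(list(
    n_per_group = as.integer(n_per_group), n_sessions = as.integer(n_sessions),
    tr_by_group = tr_by_group, n_frames = as.integer(n_frames),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    atlas_rois = as.integer(atlas_rois), seed_roi_id = as.integer(seed_roi_id),
    effect_rois = as.integer(effect_rois),
    effect_band_amp = effect_band_amp, effect_highfreq_amp = effect_highfreq_amp,
    fc_coupling = fc_coupling, physio = physio,
    global_coupling_sd = global_coupling_sd,
    sigma_neural = sigma_neural, sigma_white = sigma_white,
    sigma_global = sigma_global, drift = drift, baseline = baseline,
    subject_amp_sd = subject_amp_sd, subject_noise_sd = subject_noise_sd,
    session_scale_sd = session_scale_sd,
    motion_spike_prob = motion_spike_prob, spike_mag_mm = spike_mag_mm,
    spike_artifact_amp = spike_artifact_amp,
    band = band, rng_seed = as.integer(rng_seed)), class = "cohort_spec")
}

#' Null variant of a cohort specification
#'
#' The global-null condition for error-rate calibration: no amplitude or
#' noise effect, equal coupling in both groups, and a common TR, so the two
#' groups are exchangeable (a TR difference alone changes the white-noise
#' band fraction and is a real, detectable acquisition effect, not a null).
#'
#' @param spec a [cohort_spec()]
#' @return the spec with all group effects removed
#' @export
null_cohort_spec <- function(spec = cohort_spec()) {
  spec$effect_band_amp <- 1.0
  spec$effect_highfreq_amp <- 1.0
  spec$fc_coupling[2, ] <- spec$fc_coupling[1, ]
  spec$tr_by_group <- rep(mean(spec$tr_by_group), 2)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d/group x %d sessions, %d frames, TR %.2f/%.2f s,\n",
                     "  grid %s, %d regions (seed %d), band effect x%.2f, seed %d\n"),
              x$n_per_group, x$n_sessions, x$n_frames, x$tr_by_group[1],
              x$tr_by_group[2], paste(x$grid_shape, collapse = "x"),
              x$atlas_rois, x$seed_roi_id, x$effect_band_amp, x$rng_seed))
  invisible(x)
}

# ellipsoidal brain mask inscribed in the grid
cohort_mask <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  ax <- pmax(grid_shape / 2 - 1, 1)
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  r2 <- ((g$x - c0[1]) / ax[1])^2 + ((g$y - c0[2]) / ax[2])^2 +
    ((g$z - c0[3]) / ax[3])^2
  array(r2 <= 1, grid_shape)
}

cohort_affine <- function(spec) {
  a <- diag(c(rep(spec$voxel_size, 3), 1))
  a[1:3, 4] <- -spec$voxel_size * (spec$grid_shape - 1) / 2
  a
}

#' Generate a compact label atlas on the cohort grid
#'
#' Partitions the ellipsoidal brain mask into `atlas_rois` spatially compact,
#' non-overlapping regions (k-means on voxel coordinates; Voronoi cells are
#' convex, hence connected). Label 0 is background; labels 1..K exactly tile
#' the mask. Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()]
#' @return a [label_atlas()]
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mask <- cohort_mask(spec$grid_shape)
  nvox <- sum(mask)
  if (spec$atlas_rois > nvox)
    stop_lfamp("requested %d regions but the mask has only %d voxels",
               spec$atlas_rois, nvox)
  coords <- arrayInd(which(mask), spec$grid_shape)
  km <- with_seed(derive_seed(spec$rng_seed, 101L), {
    stats::kmeans(coords, centers = spec$atlas_rois, nstart = 5, iter.max = 100)
  })
  # stable label order: sort centers lexicographically so ids do not depend
  # on kmeans' internal initialization order
  ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
  relabel <- match(seq_len(spec$atlas_rois), ord)
  labs <- array(0L, spec$grid_shape)
  labs[which(mask)] <- relabel[km$cluster]
  ids <- seq_len(spec$atlas_rois)
  label_atlas(labs, names = setNames(paste0("region_", ids), ids))
}

#' Generate a rigid-body motion trace with optional spike frames
#'
#' Baseline motion is small independent jitter (translations SD 0.01 mm,
#' rotations SD 1e-4 rad per frame). Spike frames (drawn with probability
#' `spike_prob` among frames 1..n-1, 0-based) receive a one-frame
#' translation impulse of `spike_mag_mm` along a random axis; consecutive
#' spikes never repeat the previous (axis, sign) so adjacent spike frames
#' always displace relative to one another.
#'
#' @param n_frames number of frames (>= 2)
#' @param spike_prob per-frame spike probability
#' @param spike_mag_mm spike translation magnitude, mm
#' @param seed integer seed
#' @param jitter_sd_mm baseline translation jitter SD (default 0.01 mm)
#' @return list: `trace` (frames x 6 matrix), `spike_frames` (0-based indices)
#' @export
generate_motion_trace <- function(n_frames, spike_prob, spike_mag_mm = 2.0,
                                  seed = 1L, jitter_sd_mm = 0.01) {
  if (n_frames < 2L) stop_lfamp("need at least 2 frames; got %d", n_frames)
  if (spike_prob < 0 || spike_prob > 1) stop_lfamp("spike_prob must be in [0, 1]")
  with_seed(seed, {
    trace <- cbind(matrix(rnorm(n_frames * 3, sd = jitter_sd_mm), n_frames),
                   matrix(rnorm(n_frames * 3, sd = jitter_sd_mm * 1e-2), n_frames))
    colnames(trace) <- MOTION_COLUMNS
    spikes <- which(rbinom(n_frames, 1, spike_prob) == 1)
    spikes <- spikes[spikes >= 2]           # frame 0 has no predecessor
    prev <- c(NA_integer_, NA_integer_)     # (axis, sign) of previous spike
    prev_frame <- -10L
    for (f in spikes) {
      repeat {
        axis <- sample.int(3, 1)
        sgn <- sample(c(-1, 1), 1)
        if (!(f == prev_frame + 1L && !is.na(prev[1]) &&
              axis == prev[1] && sgn == prev[2])) break
      }
      trace[f, axis] <- trace[f, axis] + sgn * spike_mag_mm
      prev <- c(axis, sgn)
      prev_frame <- f
    }
    list(trace = trace, spike_frames = as.integer(spikes - 1L))
  })
}

# t x V matrix of independent band-limited unit-variance Gaussian noise
band_noise <- function(n_frames, n_series, tr, band) {
  x <- matrix(rnorm(n_frames * n_series), n_frames, n_series)
  f <- mvfft(x)
  bins <- freq_bins(n_frames, tr)
  idx <- band_bin_index(bins, band, tr)
  keep <- logical(n_frames)
  keep[bins$k[idx] + 1L] <- TRUE                       # positive bins
  keep[n_frames - bins$k[idx] + 1L] <- TRUE            # conjugate mirrors
  f[!keep, ] <- 0
  y <- Re(mvfft(f, inverse = TRUE)) / n_frames
  y / sqrt(sum(bins$weight[idx] * n_frames))           # unit expected variance
}

# slow sinusoidal series sampled at the frame times
sinusoid <- function(n_frames, tr, freq_hz, amp, phase) {
  amp * sin(2 * pi * freq_hz * (seq_len(n_frames) - 1) * tr + phase)
}

#' Generate one subject-session BOLD run with known ground truth
#'
#' Each in-mask voxel series is baseline + band-limited neural component
#' (amplitude scaled by group/region per the spec) + shared latent seed
#' signal (coupling per region and group) + sinusoidal respiratory and
#' cardiac components (the cardiac term aliases at these TRs) + slow drift +
#' global component x voxelwise beta + white noise (group-2 noise scaled by
#' `effect_highfreq_amp`) + motion-spike artifacts, all multiplied (except
#' the white noise is included) by a per-session gain factor. The confound
#' table carries CSF-like and WM-like nuisance series.
#'
#' @param spec a [cohort_spec()]
#' @param group 1 or 2
#' @param session session index in 1..n_sessions
#' @param atlas the cohort's [label_atlas()] from [generate_atlas()]
#' @param seed integer seed for this run (derive from the cohort seed)
#' @param subject_seed integer seed for the subject-level factors, shared by
#'   all of a subject's sessions so amplitude/noise factors are stable across
#'   sessions; defaults to `seed` (single-run use)
#' @return list: `run` ([bold_run()]), `confounds` (data.frame `csf`, `wm`),
#'   `motion` (frames x 6), `spike_frames` (0-based), `session_scale`,
#'   `subject_factors`
#' @export
generate_subject_run <- function(spec, group, session, atlas, seed,
                                 subject_seed = seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "label_atlas"))
  if (!group %in% 1:2) stop_lfamp("group must be 1 or 2; got %s", group)
  if (!(session >= 1 && session <= spec$n_sessions))
    stop_lfamp("session %d out of range 1..%d", session, spec$n_sessions)
  tr <- spec$tr_by_group[group]
  nt <- spec$n_frames
  mask <- cohort_mask(spec$grid_shape)
  vox <- which(mask)
  nv <- length(vox)
  roi_of_vox <- atlas$labels[vox]

  # cohort-level anatomy: global-coupling betas and baseline profile
  anat <- with_seed(derive_seed(spec$rng_seed, 102L), {
    list(global_beta = rnorm(nv, mean = 1, sd = spec$global_coupling_sd),
         baseline = spec$baseline * (0.9 + 0.2 * runif(nv)))
  })
  # subject-level factors: drawn from the subject seed so they are identical
  # across the subject's sessions
  subj_fac <- with_seed(derive_seed(subject_seed, 1L), {
    list(amp = exp(rnorm(1, sd = spec$subject_amp_sd)),
         noise = exp(rnorm(1, sd = spec$subject_noise_sd)))
  })

  mt <- generate_motion_trace(nt, spec$motion_spike_prob, spec$spike_mag_mm,
                              seed = derive_seed(seed, 2L))

  with_seed(derive_seed(seed, 3L), {
    scale_ses <- exp(rnorm(1, sd = spec$session_scale_sd))
    latent <- as.numeric(band_noise(nt, 1L, tr, spec$band))
    gbold <- spec$sigma_global * as.numeric(band_noise(nt, 1L, tr, spec$band))
    ph <- runif(3, 0, 2 * pi)
    resp <- sinusoid(nt, tr, spec$physio$resp_hz, spec$physio$resp_amp, ph[1])
    card <- sinusoid(nt, tr, spec$physio$cardiac_hz, spec$physio$cardiac_amp, ph[2])
    drift <- if (isTRUE(spec$drift$on))
      sinusoid(nt, tr, spec$drift$freq_hz, spec$drift$amp, ph[3]) else 0

    amp_roi <- rep(1, spec$atlas_rois)
    if (group == 2) amp_roi[spec$effect_rois] <- spec$effect_band_amp
    amp_vox <- ifelse(roi_of_vox > 0, amp_roi[pmax(roi_of_vox, 1L)], 1)
    neural <- band_noise(nt, nv, tr, spec$band)
    neural <- sweep(neural, 2, spec$sigma_neural * subj_fac$amp * amp_vox, "*")

    coupling <- ifelse(roi_of_vox > 0,
                       spec$fc_coupling[group, ][pmax(roi_of_vox, 1L)], 0)
    noise_sd <- spec$sigma_white * subj_fac$noise *
      if (group == 2) spec$effect_highfreq_amp else 1
    y <- neural +
      outer(latent, coupling) +
      outer(gbold, anat$global_beta) +
      (resp + card + drift) +
      matrix(rnorm(nt * nv, sd = noise_sd), nt, nv)
    if (length(mt$spike_frames)) {
      art <- spec$spike_artifact_amp * (0.8 + 0.4 * runif(nv))
      y[mt$spike_frames + 1L, ] <- y[mt$spike_frames + 1L, ] +
        matrix(art, length(mt$spike_frames), nv, byrow = TRUE)
    }
    y <- scale_ses * y
    y <- sweep(y, 2, anat$baseline, "+")

    csf <- 0.8 * (resp + card) + gbold + rnorm(nt, sd = 0.5)
    wm <- 0.5 * gbold + 0.3 * (resp + card) + rnorm(nt, sd = 0.5)

    dat <- array(0, c(spec$grid_shape, nt))
    m <- matrix(dat, nrow = prod(spec$grid_shape), ncol = nt)
    m[vox, ] <- t(y)
    dat <- array(m, c(spec$grid_shape, nt))
    list(run = bold_run(dat, tr = tr, affine = cohort_affine(spec), mask = mask),
         confounds = data.frame(csf = csf, wm = wm),
         motion = mt$trace, spike_frames = mt$spike_frames,
         session_scale = scale_ses, subject_factors = subj_fac)
  })
}

#' Subject table for a cohort
#'
#' @param spec a [cohort_spec()]
#' @return data.frame: `subject`, `group` (1/2), `sex` ("F"/"M", balanced
#'   within group)
#' @export
subject_plan <- function(spec) {
  n <- spec$n_per_group
  data.frame(
    subject = sprintf("sub-%03d", seq_len(2 * n)),
    group = rep(1:2, each = n),
    sex = rep(rep(c("F", "M"), length.out = n), 2),
    stringsAsFactors = FALSE)
}

#' Generate a whole synthetic cohort in memory
#'
#' Convenience driver over [generate_subject_run()]: all subjects x sessions,
#' with per-run seeds derived deterministically from the cohort seed. Ground
#' truth (true per-region band amplitude and coupling by group, injected
#' spike frames per run, global-coupling betas) is returned alongside.
#'
#' @param spec a [cohort_spec()]
#' @return list: `atlas`, `mask`, `subjects` (data.frame), `runs` (list
#'   indexed `[[subject]][[session]]`), `ground_truth`
#' @export
simulate_cohort <- function(spec) {
  atlas <- generate_atlas(spec)
  subjects <- subject_plan(spec)
  runs <- list()
  spikes <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    runs[[sid]] <- list()
    for (s in seq_len(spec$n_sessions)) {
      r <- generate_subject_run(spec, subjects$group[i], s, atlas,
                                seed = derive_seed(spec$rng_seed, i, s),
                                subject_seed = derive_seed(spec$rng_seed, i))
      r$run$id <- sprintf("%s_ses-%d", sid, s)
      runs[[sid]][[s]] <- r
      spikes[[sprintf("%s_ses-%d", sid, s)]] <- r$spike_frames
    }
  }
  list(atlas = atlas, mask = cohort_mask(spec$grid_shape), subjects = subjects,
       runs = runs, ground_truth = cohort_ground_truth(spec, spikes))
}

cohort_ground_truth <- function(spec, spikes = list()) {
  amp <- matrix(1, 2, spec$atlas_rois)
  amp[2, spec$effect_rois] <- spec$effect_band_amp
  nv <- sum(cohort_mask(spec$grid_shape))
  beta <- with_seed(derive_seed(spec$rng_seed, 102L),
                    rnorm(nv, mean = 1, sd = spec$global_coupling_sd))
  list(band_amp_by_group = amp, fc_coupling = spec$fc_coupling,
       global_beta = beta, spike_frames = spikes,
       seed_roi_id = spec$seed_roi_id, effect_rois = spec$effect_rois,
       rng_seed = spec$rng_seed)
}

#' Write a synthetic cohort to disk
#'
#' Writes each run as 4D NIfTI with motion and confound TSVs, the atlas and
#' brain mask, a participants table (subject, group, sex, session rows), the
#' spec as YAML and the ground truth as JSON. Never overwrites: an existing
#' target file is an error.
#'
#' @param spec a [cohort_spec()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, the list of files written
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) {
    if (file.exists(path))
      stop_lfamp("refusing to overwrite existing file: %s", path)
    written <<- c(written, path)
    path
  }
  atlas <- generate_atlas(spec)
  mask <- cohort_mask(spec$grid_shape)
  aff <- cohort_affine(spec)
  write_volume(atlas$labels, emit(file.path(out_dir, "atlas.nii.gz")), aff)
  write_volume(mask, emit(file.path(out_dir, "brain_mask.nii.gz")), aff)
  subjects <- subject_plan(spec)
  part <- do.call(rbind, lapply(seq_len(spec$n_sessions), function(s) {
    cbind(subjects, session = s)
  }))
  part <- part[order(part$subject, part$session), ]
  spikes <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    for (s in seq_len(spec$n_sessions)) {
      r <- generate_subject_run(spec, subjects$group[i], s, atlas,
                                seed = derive_seed(spec$rng_seed, i, s),
                                subject_seed = derive_seed(spec$rng_seed, i))
      stem <- sprintf("%s_ses-%d", sid, s)
      r$run$id <- stem
      write_run(r$run, emit(file.path(out_dir, paste0(stem, "_bold.nii.gz"))))
      write_motion(r$motion, emit(file.path(out_dir, paste0(stem, "_motion.tsv"))))
      write_tsv(r$confounds, emit(file.path(out_dir, paste0(stem, "_confounds.tsv"))))
      spikes[[stem]] <- r$spike_frames
    }
  }
  write_tsv(part, emit(file.path(out_dir, "participants.tsv")))
  gt <- cohort_ground_truth(spec, spikes)
  jsonlite::write_json(gt, emit(file.path(out_dir, "ground_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(spec_to_list(spec), emit(file.path(out_dir, "cohort_spec.yaml")))
  invisible(written)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$band <- list(low = spec$band$low, high = spec$band$high)
  out$fc_coupling <- lapply(seq_len(nrow(spec$fc_coupling)),
                            function(i) spec$fc_coupling[i, ])
  out
}

#' Read a cohort specification from YAML
#'
#' @param path YAML file written by [generate_cohort()] or hand-authored
#' @return a [cohort_spec()]
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$band <- band_spec(x$band$low, x$band$high)
  if (!is.null(x$fc_coupling))
    x$fc_coupling <- do.call(rbind, x$fc_coupling)
  do.call(cohort_spec, x)
}

#' Simulate a seed-connectivity table with known effects
#'
#' Draws the long table the per-region mixed model consumes: per subject a
#' random intercept (SD `subject_sd`) shared by both sessions, a group
#' effect of `effect_z` added to group 2 in the designated regions, balanced
#' sex with no effect, a small positive mean framewise displacement
#' covariate with no effect, and i.i.d. residual noise.
#'
#' @param n_per_group subjects per group
#' @param n_rois number of regions
#' @param effect_rois regions carrying the group effect (default: region 1)
#' @param effect_z group-2 minus group-1 connectivity difference, Fisher z
#' @param subject_sd SD of the subject random intercept
#' @param resid_sd residual SD
#' @param n_sessions sessions per subject (default 2)
#' @param base_fc baseline connectivity level (default 0.3 z)
#' @param seed integer seed
#' @return data.frame: `fc`, `group`, `sex`, `mfd`, `session`, `subject`, `roi`
#' @export
simulate_fc_table <- function(n_per_group, n_rois = 1L, effect_rois = 1L,
                              effect_z = 0.4, subject_sd = 0.2, resid_sd = 0.1,
                              n_sessions = 2L, base_fc = 0.3, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    subj <- sprintf("sub-%03d", seq_len(n))
    group <- rep(1:2, each = n_per_group)
    sex <- rep(rep(c("F", "M"), length.out = n_per_group), 2)
    mfd <- exp(rnorm(n, mean = log(0.1), sd = 0.3))
    u <- matrix(rnorm(n * n_rois, sd = subject_sd), n, n_rois)
    rows <- expand.grid(subject = seq_len(n), session = seq_len(n_sessions),
                        roi = seq_len(n_rois))
    eff <- (group[rows$subject] == 2) * (rows$roi %in% effect_rois) * effect_z
    fc <- base_fc + u[cbind(rows$subject, rows$roi)] + eff +
      rnorm(nrow(rows), sd = resid_sd)
    data.frame(fc = fc, group = group[rows$subject], sex = sex[rows$subject],
               mfd = mfd[rows$subject], session = rows$session,
               subject = subj[rows$subject], roi = rows$roi,
               stringsAsFactors = FALSE)
  })
}
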