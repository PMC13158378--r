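#' Pipeline configuration
#'
#' Aggregates the analysis constants of every stage: band edges, QC
#' thresholds (FD 0.5 mm, global-signal z 3.0, 10% exclusion), confound
#' component count (6), whole-brain normalization, inference settings
#' (alpha 0.05, permutations, 10-voxel extent, connectivity), repeatability
#' options and FC settings (6 mm FWHM, q 0.001, BY). The config is
#' serialized alongside every output.
#'
#' @param data_dir cohort directory (as written by [generate_cohort()])
#' @param out_dir output directory
#' @param simulate optional [cohort_spec()]: simulate the cohort into
#'   `data_dir` first
#' @param n_discard_initial leading frames to drop (default 5)
#' @param n_keep frames to keep after discarding (default: all remaining)
#' @param band a [band_spec()]
#' @param qc list: `fd_thresh_mm`, `z_thresh`, `max_fraction`
#' @param n_confound_components confound PCs (default 6)
#' @param normalize divide maps by their whole-brain mean (default TRUE)
#' @param inference list: `alpha`, `n_perm`, `min_extent`, `connectivity`,
#'   `direction`, `use_gbold_covariate`
#' @param repeatability list: `exclude_rois`, `icc_cutoff`
#' @param fc list: `fwhm_mm`, `q`, `fdr_method`
#' @param rng_seed master seed; per-stage seeds are derived deterministically
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(data_dir, out_dir, simulate = NULL,
                            n_discard_initial = 5L, n_keep = NULL,
                            band = band_spec(),
                            qc = list(fd_thresh_mm = 0.5, z_thresh = 3.0,
                                      max_fraction = 0.10),
                            n_confound_components = 6L,
                            normalize = TRUE,
                            inference = list(alpha = 0.05, n_perm = 500L,
                                             min_extent = 10L, connectivity = 26L,
                                             direction = "g2>g1",
                                             use_gbold_covariate = TRUE),
                            repeatability = list(exclude_rois = integer(0),
                                                 icc_cutoff = 0.8),
                            fc = list(fwhm_mm = 6.0, q = 0.001,
                                      fdr_method = "BY"),
                            rng_seed = 1L) {
  stopifnot(qc$fd_thresh_mm > 0, qc$z_thresh > 0,
            qc$max_fraction >= 0, qc$max_fraction <= 1,
            inference$alpha > 0, inference$alpha < 1,
            inference$min_extent >= 1, fc$fwhm_mm >= 0,
            fc$q > 0, fc$q <= 1)
  structure(list(data_dir = data_dir, out_dir = out_dir, simulate = simulate,
                 n_discard_initial = as.integer(n_discard_initial),
                 n_keep = n_keep, band = band, qc = qc,
                 n_confound_components = as.integer(n_confound_components),
                 normalize = normalize, inference = inference,
                 repeatability = repeatability, fc = fc,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

pipeline_paths <- function(cfg) {
  list(qc = file.path(cfg$out_dir, "qc"),
       metrics = file.path(cfg$out_dir, "metrics"),
       repeatability = file.path(cfg$out_dir, "repeatability"),
       group = file.path(cfg$out_dir, "group"),
       connectivity = file.path(cfg$out_dir, "connectivity"))
}

read_participants <- function(cfg) {
  part <- read_tsv(file.path(cfg$data_dir, "participants.tsv"))
  req <- c("subject", "group", "sex", "session")
  if (!all(req %in% names(part)))
    stop_lfamp("participants.tsv lacks column(s): %s",
               paste(setdiff(req, names(part)), collapse = ", "))
  part
}

run_stem <- function(subject, session) sprintf("%s_ses-%s", subject, session)

# load, truncate and QC one run; returns NULL pieces lazily
load_prepared_run <- function(cfg, subject, session) {
  stem <- run_stem(subject, session)
  run <- load_run(file.path(cfg$data_dir, paste0(stem, "_bold.nii.gz")),
                  file.path(cfg$data_dir, "brain_mask.nii.gz"), id = stem)
  motion <- read_motion(file.path(cfg$data_dir, paste0(stem, "_motion.tsv")))
  conf <- read_tsv(file.path(cfg$data_dir, paste0(stem, "_confounds.tsv")))
  nt <- dim(run$data)[4]
  keep <- cfg$n_keep %||% (nt - cfg$n_discard_initial)
  keep <- min(keep, nt - cfg$n_discard_initial)
  idx <- seq.int(cfg$n_discard_initial + 1L, cfg$n_discard_initial + keep)
  run <- truncate_run(run, keep, cfg$n_discard_initial)
  motion <- motion[idx, , drop = FALSE]
  conf <- conf[idx, , drop = FALSE]
  list(run = run, motion = motion, confounds = conf, stem = stem)
}

denoise_run <- function(cfg, prep) {
  cm <- build_confound_matrix(prep$motion, prep$confounds$csf, prep$confounds$wm,
                              n_components = cfg$n_confound_components)
  regress_confounds(prep$run, cm)
}

stage_simulate <- function(cfg) {
  if (is.null(cfg$simulate)) return(invisible(NULL))
  generate_cohort(cfg$simulate, cfg$data_dir)
}

stage_qc <- function(cfg) {
  p <- pipeline_paths(cfg)
  dir.create(p$qc, recursive = TRUE, showWarnings = FALSE)
  part <- read_participants(cfg)
  mask_centroid <- local({
    m <- RNifti::readNifti(file.path(cfg$data_dir, "brain_mask.nii.gz"))
    aff <- structure(RNifti::xform(m), class = NULL)
    ijk <- colMeans(arrayInd(which(as.array(m) > 0), dim(m))) - 1
    as.numeric(aff %*% c(ijk, 1))[1:3]
  })
  rows <- lapply(seq_len(nrow(part)), function(i) {
    prep <- load_prepared_run(cfg, part$subject[i], part$session[i])
    gs <- global_signal(prep$run)
    q <- qc_run(prep$motion, gs, cfg$qc$fd_thresh_mm, cfg$qc$z_thresh,
                cfg$qc$max_fraction, box_center_mm = mask_centroid)
    fd <- q$fd
    write_tsv(data.frame(frame = seq_along(fd) - 1L, fd_mm = fd,
                         outlier = q$outlier_mask),
              file.path(p$qc, paste0(prep$stem, "_qc.tsv")))
    data.frame(subject = part$subject[i], session = part$session[i],
               group = part$group[i], sex = part$sex[i],
               mean_fd = q$mean_fd, outlier_fraction = q$outlier_fraction,
               excluded = q$excluded)
  })
  qc <- do.call(rbind, rows)
  write_tsv(qc, file.path(p$qc, "qc_summary.tsv"))
  qc
}

# subjects retained after QC: a subject is dropped if ANY session is excluded
retained_subjects <- function(cfg) {
  p <- pipeline_paths(cfg)
  qc <- read_tsv(file.path(p$qc, "qc_summary.tsv"))
  bad <- unique(qc$subject[qc$excluded])
  qc[!qc$subject %in% bad, , drop = FALSE]
}

stage_metrics <- function(cfg) {
  p <- pipeline_paths(cfg)
  dir.create(p$metrics, recursive = TRUE, showWarnings = FALSE)
  qc <- retained_subjects(cfg)
  mask <- as.array(RNifti::readNifti(file.path(cfg$data_dir, "brain_mask.nii.gz"))) > 0
  for (i in seq_len(nrow(qc))) {
    prep <- load_prepared_run(cfg, qc$subject[i], qc$session[i])
    den <- denoise_run(cfg, prep)
    maps <- list(alff = alff_map(den, cfg$band),
                 falff = falff_map(den, cfg$band),
                 tsnr = tsnr_map(den),
                 gbold = gbold_beta_map(den))
    if (cfg$normalize) {
      maps$alff <- normalize_map(maps$alff, mask)
      maps$falff <- normalize_map(maps$falff, mask)
    }
    for (nm in names(maps)) {
      m <- maps[[nm]]
      m$values[!is.finite(m$values)] <- NA_real_  # tSNR sentinels masked out
      save_map(m, file.path(p$metrics, sprintf("%s_%s.nii.gz", prep$stem, nm)),
               affine = prep$run$affine)
    }
  }
  jsonlite::write_json(list(band = unclass(cfg$band),
                            n_components = cfg$n_confound_components,
                            normalized = cfg$normalize,
                            power_scale = "amplitude"),
                       file.path(p$metrics, "metrics_manifest.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}

load_metric_map <- function(cfg, stem, metric) {
  p <- pipeline_paths(cfg)
  img <- RNifti::readNifti(file.path(p$metrics, sprintf("%s_%s.nii.gz", stem, metric)))
  amplitude_map(array(as.numeric(img), dim(img)),
                switch(metric, alff = "ALFF", falff = "fALFF", tsnr = "tSNR",
                       gbold = "gbold_beta"),
                normalized = cfg$normalize && metric %in% c("alff", "falff"),
                run_id = stem)
}

stage_repeatability <- function(cfg) {
  p <- pipeline_paths(cfg)
  dir.create(p$repeatability, recursive = TRUE, showWarnings = FALSE)
  qc <- retained_subjects(cfg)
  atlas <- label_atlas(as.array(RNifti::readNifti(file.path(cfg$data_dir, "atlas.nii.gz"))))
  sessions <- sort(unique(qc$session))
  out <- list()
  for (metric in c("alff", "falff")) {
    maps <- list()
    for (i in seq_len(nrow(qc))) {
      s <- as.character(qc$subject[i])
      maps[[s]][[as.character(qc$session[i])]] <-
        load_metric_map(cfg, run_stem(qc$subject[i], qc$session[i]), metric)
    }
    rt <- roi_table(maps, atlas, exclude = cfg$repeatability$exclude_rois)
    meta <- qc[match(paste(rt$subject, rt$session),
                     paste(qc$subject, qc$session)), c("group", "sex")]
    rt <- cbind(rt[1:2], meta, rt[-(1:2)])
    write_tsv(rt, file.path(p$repeatability, paste0("roi_table_", metric, ".tsv")))
    roi_cols <- setdiff(names(rt), c("subject", "session", "group", "sex"))
    if (length(sessions) >= 2) {
      s1 <- rt[rt$session == sessions[1], , drop = FALSE]
      s2 <- rt[rt$session == sessions[2], , drop = FALSE]
      s2 <- s2[match(s1$subject, s2$subject), , drop = FALSE]
      icc_roi <- vapply(roi_cols, function(rc) {
        icc(cbind(s1[[rc]], s2[[rc]]))$icc
      }, 1.0)
      icc_subj <- vapply(seq_len(nrow(s1)), function(i) {
        icc(cbind(as.numeric(s1[i, roi_cols]), as.numeric(s2[i, roi_cols])),
            mode = "per_subject_across_rois")$icc
      }, 1.0)
      ba <- bland_altman(rowMeans(s1[roi_cols]), rowMeans(s2[roi_cols]))
      write_tsv(data.frame(roi = roi_cols, icc = icc_roi),
                file.path(p$repeatability, paste0("icc_per_roi_", metric, ".tsv")))
      write_tsv(data.frame(subject = s1$subject, group = s1$group, icc = icc_subj),
                file.path(p$repeatability, paste0("icc_per_subject_", metric, ".tsv")))
      out[[metric]] <- list(
        icc_fraction_above = fraction_above(icc_subj, cfg$repeatability$icc_cutoff),
        bland_altman = list(bias = ba$bias, loa = c(ba$loa_lower, ba$loa_upper)))
    }
  }
  jsonlite::write_json(out, file.path(p$repeatability, "repeatability_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# session-averaged normalized maps + covariates, one entry per subject
group_inputs <- function(cfg, metric) {
  qc <- retained_subjects(cfg)
  subjects <- unique(qc$subject)
  maps <- list(); gbold <- list()
  for (s in subjects) {
    rows <- qc[qc$subject == s, ]
    ml <- lapply(seq_len(nrow(rows)),
                 function(i) load_metric_map(cfg, run_stem(s, rows$session[i]), metric))
    gl <- lapply(seq_len(nrow(rows)),
                 function(i) load_metric_map(cfg, run_stem(s, rows$session[i]), "gbold"))
    avg <- ml[[1]]
    avg$values <- Reduce(`+`, lapply(ml, `[[`, "values")) / length(ml)
    gavg <- gl[[1]]
    gavg$values <- Reduce(`+`, lapply(gl, `[[`, "values")) / length(gl)
    maps[[s]] <- avg
    gbold[[s]] <- gavg
  }
  first <- qc[match(subjects, qc$subject), ]
  mfd <- vapply(subjects, function(s) mean(qc$mean_fd[qc$subject == s]), 1.0)
  list(maps = maps, gbold = gbold, group = first$group, sex = first$sex,
       mfd = mfd, subjects = subjects)
}

stage_group <- function(cfg) {
  p <- pipeline_paths(cfg)
  dir.create(p$group, recursive = TRUE, showWarnings = FALSE)
  aff <- local({
    img <- RNifti::readNifti(file.path(cfg$data_dir, "brain_mask.nii.gz"))
    structure(RNifti::xform(img), class = NULL)
  })
  out <- list()
  for (metric in c("alff", "falff")) {
    gi <- group_inputs(cfg, metric)
    vc <- if (isTRUE(cfg$inference$use_gbold_covariate)) list(gbold = gi$gbold) else NULL
    des <- group_design(unname(gi$maps), gi$group,
                        covariates = data.frame(mfd = gi$mfd),
                        voxel_covariates = vc)
    stat <- voxelwise_group_ttest(des, cfg$inference$direction)
    fwe <- fwe_threshold(des, cfg$inference$alpha, cfg$inference$n_perm,
                         seed = derive_seed(cfg$rng_seed, 301L))
    cl <- extract_clusters(stat, fwe$threshold, cfg$inference$min_extent,
                           cfg$inference$connectivity)
    tm <- stat$values; tm[!is.finite(tm)] <- NA_real_
    save_map(amplitude_map(tm, "gbold_beta", run_id = paste0(metric, "_t")),
             file.path(p$group, paste0(metric, "_tmap.nii.gz")), affine = aff)
    write_volume(cl$labels, file.path(p$group, paste0(metric, "_clusters.nii.gz")), aff)
    write_tsv(cl$clusters, file.path(p$group, paste0(metric, "_clusters.tsv")))
    out[[metric]] <- list(threshold = fwe$threshold, df = stat$df,
                          n_clusters = nrow(cl$clusters),
                          largest = if (nrow(cl$clusters)) cl$clusters$size[1] else 0L)
  }
  jsonlite::write_json(out, file.path(p$group, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

stage_connectivity <- function(cfg) {
  p <- pipeline_paths(cfg)
  dir.create(p$connectivity, recursive = TRUE, showWarnings = FALSE)
  qc <- retained_subjects(cfg)
  atlas <- label_atlas(as.array(RNifti::readNifti(file.path(cfg$data_dir, "atlas.nii.gz"))))
  voxmm <- abs(diag(as.matrix(local({
    img <- RNifti::readNifti(file.path(cfg$data_dir, "brain_mask.nii.gz"))
    structure(RNifti::xform(img), class = NULL)
  })))[1:3])
  cl_img <- file.path(p$group, "falff_clusters.nii.gz")
  seed_mask <- NULL
  if (file.exists(cl_img)) {
    labs <- as.array(RNifti::readNifti(cl_img))
    if (any(labs == 1)) seed_mask <- labs == 1
  }
  if (is.null(seed_mask)) {
    warn_lfamp("no surviving group-difference cluster; falling back to the atlas seed region")
    seed_mask <- atlas$labels == min(atlas$label_ids)
  }
  # target exclusion: the region(s) the seed overlaps most
  ov <- table(atlas$labels[seed_mask & atlas$labels > 0])
  seed_label <- if (length(ov)) as.integer(names(ov)[which.max(ov)]) else integer(0)
  rows <- list()
  for (i in seq_len(nrow(qc))) {
    prep <- load_prepared_run(cfg, qc$subject[i], qc$session[i])
    den <- denoise_run(cfg, prep)
    zs <- seed_correlation_map(den, extract_seed_series(den, seed_mask))
    zs <- smooth_map(zs, cfg$fc$fwhm_mm, voxmm, mask = den$mask)
    fc <- roi_fc(zs, atlas, exclude_label = seed_label)
    rows[[i]] <- data.frame(subject = qc$subject[i], session = qc$session[i],
                            group = qc$group[i], sex = qc$sex[i],
                            mfd = qc$mean_fd[i], roi = names(fc), fc = unname(fc))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[is.finite(tab$fc), , drop = FALSE]
  # per-subject mFD (covariate averaged over sessions, one value per subject)
  mfd_subj <- aggregate(mfd ~ subject, tab, mean)
  tab$mfd <- mfd_subj$mfd[match(tab$subject, mfd_subj$subject)]
  write_tsv(tab, file.path(p$connectivity, "fc_table.tsv"))
  fits <- lapply(split(tab, tab$roi), fit_fc_mixed_model)
  report <- report_significant_rois(fits, cfg$fc$q, cfg$fc$fdr_method)
  all_terms <- do.call(rbind, lapply(names(fits), function(r) {
    cbind(roi = r, fits[[r]]$effects)
  }))
  write_tsv(all_terms, file.path(p$connectivity, "mixed_model_fits.tsv"))
  write_tsv(report, file.path(p$connectivity, "significant_rois.tsv"))
  invisible(list(fits = fits, report = report, seed_label = seed_label))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate if requested, QC, metrics,
#' repeatability, group inference, seed connectivity with the mixed model),
#' writing each stage's outputs under `out_dir` and a run manifest tying
#' every output to the configuration, input hashes and seed. Subjects failing
#' motion QC are excluded from every downstream stage. Any stage failure
#' halts with the stage name.
#'
#' @param config a [pipeline_config()]
#' @param stages character vector of stages to run (default: all)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "metrics", "repeatability",
                                    "group", "connectivity")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runner <- list(simulate = stage_simulate, qc = stage_qc,
                 metrics = stage_metrics, repeatability = stage_repeatability,
                 group = stage_group, connectivity = stage_connectivity)
  for (st in stages) {
    res <- tryCatch(runner[[st]](config), error = function(e) {
      stop_lfamp("pipeline stage '%s' failed: %s", st, conditionMessage(e))
    })
  }
  cfg_list <- unclass(config)
  cfg_list$band <- unclass(config$band)
  cfg_list$simulate <- if (is.null(config$simulate)) NULL else
    spec_to_list(config$simulate)
  inputs <- list.files(config$data_dir, full.names = TRUE, recursive = TRUE)
  outputs <- setdiff(list.files(config$out_dir, full.names = TRUE, recursive = TRUE),
                     file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lfamp")),
    seed = config$rng_seed,
    stages = stages,
    config = cfg_list,
    input_md5 = as.list(tools::md5sum(sort(inputs))),
    output_md5 = as.list(tools::md5sum(sort(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
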