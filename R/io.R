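#' BOLD run container
#'
#' A 4D voxel time-series with its repetition time, voxel-to-mm affine and
#' brain mask. Data are held as double precision in memory regardless of the
#' on-disk datatype (NIfTI files are written as float32).
#'
#' @param data 4D numeric array (x, y, z, t)
#' @param tr repetition time in seconds (> 0)
#' @param affine 4x4 voxel-to-mm transform; default: identity scaled by 1 mm
#' @param mask 3D logical array matching the spatial dimensions; default all-TRUE
#' @param id optional run identifier carried into derived maps
#' @return an object of class `bold_run`
#' @export
bold_run <- function(data, tr, affine = NULL, mask = NULL, id = NULL) {
  dm <- dim(data)
  if (length(dm) != 4L)
    stop_lfamp("BOLD data must be 4D (x,y,z,t); got %d dimensions", length(dm))
  if (dm[4] < 2L) stop_lfamp("BOLD run needs at least 2 frames; got %d", dm[4])
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_lfamp("TR must be a single positive number; got %s", format(tr))
  if (is.null(affine)) affine <- diag(4)
  if (!identical(dim(affine), c(4L, 4L)))
    stop_lfamp("affine must be a 4x4 matrix")
  if (is.null(mask)) mask <- array(TRUE, dim = dm[1:3])
  if (!identical(dim(mask), dm[1:3]))
    stop_lfamp("mask shape (%s) does not match run spatial shape (%s)",
               paste(dim(mask), collapse = "x"), paste(dm[1:3], collapse = "x"))
  structure(list(data = data, tr = tr, affine = affine,
                 mask = array(as.logical(mask), dm[1:3]), id = id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<bold_run%s> %dx%dx%d voxels, %d frames, TR %.3f s, %d in mask\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              dm[1], dm[2], dm[3], dm[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Integer label atlas
#'
#' @param labels 3D integer array; 0 is background
#' @param names optional character vector naming labels, with names equal to
#'   the label integers (e.g. `c("1" = "seed", "2" = "target")`)
#' @return an object of class `label_atlas`
#' @export
label_atlas <- function(labels, names = NULL) {
  if (length(dim(labels)) != 3L) stop_lfamp("atlas labels must be 3D")
  labs <- sort(unique(as.integer(labels[labels > 0])))
  if (!is.null(names)) {
    missing <- setdiff(as.integer(base::names(names)), labs)
    if (length(missing))
      stop_lfamp("named labels absent from image: %s", paste(missing, collapse = ", "))
  }
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 names = names, label_ids = labs),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s grid, %d labels (%d foreground voxels)\n",
              paste(dim(x$labels), collapse = "x"), length(x$label_ids),
              sum(x$labels > 0)))
  invisible(x)
}

AMPLITUDE_METRICS <- c("ALFF", "fALFF", "tSNR", "gbold_beta", "gm_prob")

#' Voxelwise amplitude/metric map
#'
#' @param values 3D numeric array
#' @param metric one of `"ALFF"`, `"fALFF"`, `"tSNR"`, `"gbold_beta"`, `"gm_prob"`
#' @param normalized has the map been divided by its whole-brain mean?
#' @param run_id provenance: id of the source run
#' @param flags optional list of per-map computation flags (e.g. degenerate voxels)
#' @return an object of class `amplitude_map`
#' @export
amplitude_map <- function(values, metric, normalized = FALSE, run_id = NULL,
                          flags = list()) {
  metric <- match.arg(metric, AMPLITUDE_METRICS)
  if (length(dim(values)) != 3L) stop_lfamp("map values must be 3D")
  structure(list(values = values, metric = metric, normalized = normalized,
                 run_id = run_id, flags = flags),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("<amplitude_map> %s%s, %s grid, range [%.4g, %.4g]\n",
              x$metric, if (x$normalized) " (normalized)" else "",
              paste(dim(x$values), collapse = "x"),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values[is.finite(x$values)], na.rm = TRUE))))
  invisible(x)
}

#' Load a 4D BOLD run and its brain mask from NIfTI-1 files
#'
#' TR is taken from the NIfTI header (`pixdim[4]`) unless `tr_override` is
#' given, in which case the override wins and a warning records the
#' discrepancy. Shapes are validated strictly; nothing is resampled.
#'
#' @param path_bold path to a 4D NIfTI file
#' @param path_mask optional path to a 3D mask NIfTI aligned to the run
#' @param tr_override optional TR in seconds taking precedence over the header
#' @param id run identifier stored in the result
#' @return a [bold_run()]
#' @export
load_run <- function(path_bold, path_mask = NULL, tr_override = NULL, id = NULL) {
  if (!file.exists(path_bold)) stop_lfamp("BOLD file not found: %s", path_bold)
  img <- RNifti::readNifti(path_bold)
  dm <- dim(img)
  if (length(dm) != 4L)
    stop_lfamp("expected a 4D BOLD file, got %dD: %s", length(dm), path_bold)
  hdr_tr <- RNifti::pixdim(img)[4]
  tr <- if (!is.null(tr_override)) {
    if (is.finite(hdr_tr) && hdr_tr > 0 && abs(hdr_tr - tr_override) > 1e-9)
      warn_lfamp("TR override %.4g s replaces header TR %.4g s for %s",
                 tr_override, hdr_tr, path_bold)
    tr_override
  } else hdr_tr
  if (!is.finite(tr) || tr <= 0)
    stop_lfamp("nonpositive TR (%s) in header of %s and no tr_override given",
               format(hdr_tr), path_bold)
  mask <- NULL
  if (!is.null(path_mask)) {
    if (!file.exists(path_mask)) stop_lfamp("mask file not found: %s", path_mask)
    mimg <- RNifti::readNifti(path_mask)
    if (!identical(dim(mimg)[1:3], dm[1:3]) || length(dim(mimg)) != 3L)
      stop_lfamp("mask shape (%s) does not match run spatial shape (%s)",
                 paste(dim(mimg), collapse = "x"), paste(dm[1:3], collapse = "x"))
    mask <- array(as.array(mimg) > 0, dm[1:3])
  }
  affine <- structure(RNifti::xform(img), class = NULL)
  bold_run(array(as.numeric(img), dm), tr = tr, affine = affine, mask = mask,
           id = id %||% sub("\\.nii(\\.gz)?$", "", basename(path_bold)))
}

#' Write an amplitude map as NIfTI-1
#'
#' Values inside `mask` must be finite (non-finite sentinels such as infinite
#' tSNR must be masked out by the caller first); values outside the mask may be
#' NA and are written as NaN. The metric name is stored in the NIfTI
#' description field. Data are written as float32.
#'
#' @param map an [amplitude_map()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @param affine 4x4 voxel-to-mm transform
#' @param mask optional 3D logical array: where the map must be finite
#' @return the path, invisibly
#' @export
save_map <- function(map, path, affine = diag(4), mask = NULL) {
  stopifnot(inherits(map, "amplitude_map"))
  vals <- map$values
  if (!is.null(mask)) {
    bad <- !is.finite(vals[mask])
    if (any(bad))
      stop_lfamp("%d non-finite value(s) inside the mask; mask them out before saving",
                 sum(bad))
  }
  img <- nifti_image(vals, affine, datatype = "float")
  img$descrip <- paste0("lfamp:", map$metric, if (map$normalized) ":normalized" else "")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# build a niftiImage with sform set (code 2) and optional TR in pixdim[4]
nifti_image <- function(arr, affine, tr = NULL, datatype = "float") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  if (!is.null(tr)) {
    pd <- img$pixdim
    pd[5] <- tr
    img$pixdim <- pd
  }
  img
}

#' Write a BOLD run as a 4D NIfTI-1 file
#'
#' TR is stored in `pixdim[4]`; data are written as float32.
#'
#' @param run a [bold_run()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- nifti_image(run$data, run$affine, tr = run$tr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D mask or label image as NIfTI-1
#'
#' @param arr 3D logical or integer array
#' @param path output path
#' @param affine 4x4 voxel-to-mm transform
#' @return the path, invisibly
#' @export
write_volume <- function(arr, path, affine = diag(4)) {
  img <- nifti_image(array(as.integer(arr), dim(arr)), affine, datatype = "int")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Drop initial frames and truncate a run to a fixed length
#'
#' Retains frames `[n_discard_initial, n_discard_initial + n_keep)` (0-based,
#' half-open). Motion and confound tables must be truncated identically by the
#' caller.
#'
#' @param run a [bold_run()]
#' @param n_keep number of frames to retain
#' @param n_discard_initial number of leading frames to drop (default 0)
#' @return a [bold_run()] with `n_keep` frames
#' @export
truncate_run <- function(run, n_keep, n_discard_initial = 0L) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (n_discard_initial + 2 > nt)
    stop_lfamp("cannot discard %d of %d frames and keep a usable run",
               n_discard_initial, nt)
  if (n_keep > nt - n_discard_initial)
    stop_lfamp("requested %d frames but only %d remain after discarding %d of %d",
               n_keep, nt - n_discard_initial, n_discard_initial, nt)
  idx <- seq.int(n_discard_initial + 1L, n_discard_initial + n_keep)
  bold_run(run$data[, , , idx, drop = FALSE], tr = run$tr, affine = run$affine,
           mask = run$mask, id = run$id)
}

# ---- plain-text table helpers (TSV with header row) ----

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_lfamp("file not found: %s", path)
  read.delim(path, sep = "\t", check.names = FALSE)
}

MOTION_COLUMNS <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                    "rot_x_rad", "rot_y_rad", "rot_z_rad")

#' Read a 6-column rigid-body motion trace from TSV
#'
#' Columns: `trans_x_mm, trans_y_mm, trans_z_mm, rot_x_rad, rot_y_rad, rot_z_rad`.
#'
#' @param path TSV path with header row
#' @return numeric matrix (frames x 6) of class `motion_trace`
#' @export
read_motion <- function(path) {
  df <- read_tsv(path)
  if (!all(MOTION_COLUMNS %in% names(df)))
    stop_lfamp("motion TSV %s lacks required columns: %s", path,
               paste(setdiff(MOTION_COLUMNS, names(df)), collapse = ", "))
  m <- as.matrix(df[MOTION_COLUMNS])
  class(m) <- c("motion_trace", class(m))
  m
}

#' Write a motion trace as TSV
#'
#' Values are formatted with fixed precision so identical traces produce
#' byte-identical files.
#'
#' @param trace frames x 6 matrix (see [read_motion()] for column order)
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_motion <- function(trace, path) {
  df <- as.data.frame(unclass(trace))
  names(df) <- MOTION_COLUMNS
  df[] <- lapply(df, function(x) sprintf("%.6f", x))
  write_tsv(df, path)
}
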