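#' Framewise displacement from rigid-body parameters
#'
#' Composite framewise displacement via the bounding-box control-point method:
#' six control points are placed at the face centers of a 140 x 180 x 115 mm
#' box around the brain; each frame's rigid transform (intrinsic rotations
#' about x, y, z applied in that order, about the box center, plus the
#' translation) is applied to the points, and FD(t) is the largest Euclidean
#' displacement of any control point between frames t-1 and t. FD(0) = 0.
#'
#' Only frame-to-frame differences matter, so FD is invariant to a constant
#' offset in the parameters; under translation-only motion FD equals the
#' translation step norm exactly, for any box geometry.
#'
#' @param trace frames x 6 numeric matrix: 3 translations (mm), 3 rotations (rad)
#' @param box_dims_mm bounding-box edge lengths (x, y, z) in mm
#' @param box_center_mm box center in mm; defaults to the origin (use the
#'   brain-mask centroid in mm space when available)
#' @return numeric vector of per-frame FD in mm, first element 0
#' @export
framewise_displacement <- function(trace, box_dims_mm = c(140, 180, 115),
                                   box_center_mm = c(0, 0, 0)) {
  trace <- unclass(trace)
  if (is.data.frame(trace)) trace <- as.matrix(trace)
  if (ncol(trace) != 6L) stop_lfamp("motion trace must have 6 columns; got %d", ncol(trace))
  nt <- nrow(trace)
  if (nt < 2L) stop_lfamp("need at least 2 frames to compute FD; got %d", nt)
  bad <- which(!apply(is.finite(trace), 1, all))
  if (length(bad))
    stop_lfamp("non-finite motion parameters at frame(s): %s",
               paste(bad[seq_len(min(5, length(bad)))] - 1L, collapse = ", "))
  half <- box_dims_mm / 2
  ctr <- box_center_mm
  pts <- rbind(ctr + c(half[1], 0, 0), ctr - c(half[1], 0, 0),
               ctr + c(0, half[2], 0), ctr - c(0, half[2], 0),
               ctr + c(0, 0, half[3]), ctr - c(0, 0, half[3]))
  pos <- vapply(seq_len(nt), function(t) {
    R <- rotation_matrix_xyz(trace[t, 4], trace[t, 5], trace[t, 6])
    t(R %*% (t(pts) - ctr) + ctr + trace[t, 1:3])
  }, matrix(0, 6, 3))
  fd <- numeric(nt)
  for (t in 2:nt) {
    d <- pos[, , t] - pos[, , t - 1]
    fd[t] <- sqrt(max(rowSums(d^2)))
  }
  fd
}

# intrinsic rotations about x, then y, then z: R = Rx %*% Ry %*% Rz
rotation_matrix_xyz <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Flag outlier frames by motion and global-signal change
#'
#' A frame is flagged if its FD exceeds `fd_thresh_mm` OR the absolute
#' frame-to-frame change in the global signal, z-scored over the run, exceeds
#' `z_thresh` (union of the two criteria). A constant global signal yields
#' z-scores of 0 and contributes no flags.
#'
#' @param fd per-frame FD series (mm)
#' @param global_signal per-frame global (whole-brain mean) BOLD series; may be
#'   NULL to apply the FD criterion alone
#' @param fd_thresh_mm FD threshold in mm (default 0.5)
#' @param z_thresh global-signal-change z threshold (default 3.0)
#' @return logical vector, TRUE at outlier frames
#' @export
flag_outlier_frames <- function(fd, global_signal = NULL, fd_thresh_mm = 0.5,
                                z_thresh = 3.0) {
  flags <- fd > fd_thresh_mm
  if (!is.null(global_signal)) {
    if (length(global_signal) != length(fd))
      stop_lfamp("global signal length (%d) differs from FD length (%d)",
                 length(global_signal), length(fd))
    dg <- c(0, diff(global_signal))
    s <- sd(dg)
    z <- if (!is.finite(s) || s == 0) rep(0, length(dg)) else (dg - mean(dg)) / s
    flags <- flags | abs(z) > z_thresh
  }
  flags
}

#' Subject-level exclusion by outlier-frame fraction
#'
#' @param outlier_mask per-frame logical vector
#' @param max_fraction exclusion threshold (strict inequality; default 0.10)
#' @return TRUE if the session should be excluded
#' @export
subject_exclusion <- function(outlier_mask, max_fraction = 0.10) {
  if (!length(outlier_mask)) stop_lfamp("empty outlier mask")
  mean(outlier_mask) > max_fraction
}

#' Motion quality control for one run
#'
#' Combines [framewise_displacement()], [flag_outlier_frames()] and
#' [subject_exclusion()] into a per-session QC record.
#'
#' @param trace frames x 6 motion matrix
#' @param global_signal optional per-frame global BOLD series
#' @param fd_thresh_mm,z_thresh,max_fraction see the component functions
#' @param box_dims_mm,box_center_mm see [framewise_displacement()]
#' @return an object of class `qc_result` with fields `fd`, `outlier_mask`,
#'   `outlier_fraction`, `excluded`, `mean_fd`
#' @export
qc_run <- function(trace, global_signal = NULL, fd_thresh_mm = 0.5,
                   z_thresh = 3.0, max_fraction = 0.10,
                   box_dims_mm = c(140, 180, 115), box_center_mm = c(0, 0, 0)) {
  fd <- framewise_displacement(trace, box_dims_mm, box_center_mm)
  flags <- flag_outlier_frames(fd, global_signal, fd_thresh_mm, z_thresh)
  structure(list(fd = fd, outlier_mask = flags,
                 outlier_fraction = mean(flags),
                 excluded = subject_exclusion(flags, max_fraction),
                 mean_fd = mean(fd)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> mean FD %.3f mm, %.1f%% outlier frames, %s\n",
              x$mean_fd, 100 * x$outlier_fraction,
              if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}
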