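# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a single-voxel run holding the given series
series_run <- function(x, tr = 0.8) {
  bold_run(array(x, c(1, 1, 1, length(x))), tr = tr)
}

# a multi-voxel run: columns of `m` (t x V) laid out along x
matrix_run <- function(m, tr = 0.8) {
  bold_run(array(t(m), c(ncol(m), 1, 1, nrow(m))), tr = tr)
}

# small fast cohort spec for structural tests
tiny_spec <- function(...) {
  cohort_spec(n_per_group = 2L, n_sessions = 2L, n_frames = 60L,
              grid_shape = c(10L, 10L, 10L), atlas_rois = 4L,
              rng_seed = 7L, ...)
}

# independent FD oracle: exact rigid transforms of the six face-center
# control points, rotations composed explicitly per frame
fd_oracle <- function(trace, box_dims = c(140, 180, 115), center = c(0, 0, 0)) {
  rot <- function(ax, ay, az) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
    Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
    Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  half <- box_dims / 2
  pts <- rbind(center + c(half[1], 0, 0), center - c(half[1], 0, 0),
               center + c(0, half[2], 0), center - c(0, half[2], 0),
               center + c(0, 0, half[3]), center - c(0, 0, half[3]))
  pos <- lapply(seq_len(nrow(trace)), function(t) {
    R <- rot(trace[t, 4], trace[t, 5], trace[t, 6])
    t(R %*% (t(pts) - center) + center + trace[t, 1:3])
  })
  c(0, vapply(2:nrow(trace), function(t) {
    sqrt(max(rowSums((pos[[t]] - pos[[t - 1]])^2)))
  }, 1.0))
}

# independent spectral oracle: zero all out-of-band DFT bins (keeping the
# conjugate mirrors), invert, and take the time-domain RMS
band_rms_oracle <- function(x, tr, low = 0.008, high = 0.1) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1) / (n * tr)
  f_mirror <- pmin(f, 1 / tr - f)
  keep <- f_mirror >= low - 1e-12 & f_mirror <= high + 1e-12 & seq_len(n) != 1L
  xf <- Re(stats::fft(replace(X, !keep, 0 + 0i), inverse = TRUE)) / n
  sqrt(mean(xf^2))
}
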