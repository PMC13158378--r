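#' Low-frequency band specification
#'
#' @param low lower band edge, Hz (default 0.008)
#' @param high upper band edge, Hz (default 0.1)
#' @return an object of class `band_spec`
#' @export
band_spec <- function(low = 0.008, high = 0.1) {
  if (!(low > 0 && high > low)) stop_lfamp("need 0 < low < high; got [%g, %g]", low, high)
  structure(list(low = low, high = high), class = "band_spec")
}

# indices into the positive-frequency bins falling inside [low, high],
# inclusive on both edges (deterministic tie-break at band edges)
band_bin_index <- function(bins, band, tr) {
  nyq <- 1 / (2 * tr)
  if (band$high > nyq + 1e-12)
    stop_lfamp("band high edge %g Hz exceeds Nyquist %g Hz at TR %g s",
               band$high, nyq, tr)
  eps <- 1e-12
  which(bins$freq_hz >= band$low - eps & bins$freq_hz <= band$high + eps)
}

# per-voxel band and total mean-square power from a t x V matrix of demeaned
# series; the Parseval weights make colSums equal the time-domain mean square
spectral_power <- function(y, tr, band) {
  nt <- nrow(y)
  bins <- freq_bins(nt, tr)
  idx <- band_bin_index(bins, band, tr)
  if (!length(idx))
    stop_lfamp("band [%g, %g] Hz contains 0 of %d frequency bins at TR %g s",
               band$low, band$high, length(bins$k), tr)
  f <- mvfft(y)
  p <- Mod(f[bins$k + 1L, , drop = FALSE])^2 * bins$weight
  list(band = colSums(p[idx, , drop = FALSE]),
       total = colSums(p),
       n_band_bins = length(idx))
}

#' ALFF map: RMS amplitude in the low-frequency band
#'
#' Per voxel, the discrete Fourier transform of the demeaned series is taken
#' (plain periodogram, no taper) and ALFF is the square root of the summed
#' power over bins with `low <= f <= high` -- i.e. the RMS amplitude of the
#' ideally band-limited signal (a pure in-band sinusoid of amplitude A gives
#' A/sqrt(2)). The DC bin is excluded. With `power_scale = "power"` the
#' squared (mean-power) scale is returned instead; the choice is monotone and
#' does not affect normalized group contrasts, but must be fixed and stated.
#'
#' @param run a denoised [bold_run()]
#' @param band a [band_spec()]
#' @param power_scale `"amplitude"` (RMS, default) or `"power"`
#' @return an [amplitude_map()] with metric `"ALFF"` (NA outside the mask)
#' @export
alff_map <- function(run, band = band_spec(), power_scale = c("amplitude", "power")) {
  power_scale <- match.arg(power_scale)
  stopifnot(inherits(run, "bold_run"))
  rm_ <- run_matrix(run)
  y <- sweep(rm_$y, 2, colMeans(rm_$y))
  sp <- spectral_power(y, run$tr, band)
  vals <- if (power_scale == "amplitude") sqrt(sp$band) else sp$band
  amplitude_map(unmask(vals, rm_$vox, rm_$spatial_dim), "ALFF",
                run_id = run$id,
                flags = list(power_scale = power_scale, n_band_bins = sp$n_band_bins))
}

#' fALFF map: fractional band amplitude
#'
#' Per voxel, `sqrt(band power / total power)` where the denominator sums all
#' positive-frequency bins up to Nyquist (DC excluded). Bounded in `[0, 1]`
#' before normalization. Zero-variance voxels get 0 and are recorded in the
#' map flags.
#'
#' @inheritParams alff_map
#' @return an [amplitude_map()] with metric `"fALFF"`
#' @export
falff_map <- function(run, band = band_spec(), power_scale = c("amplitude", "power")) {
  power_scale <- match.arg(power_scale)
  stopifnot(inherits(run, "bold_run"))
  rm_ <- run_matrix(run)
  y <- sweep(rm_$y, 2, colMeans(rm_$y))
  sp <- spectral_power(y, run$tr, band)
  ratio <- ifelse(sp$total > 0, sp$band / sp$total, 0)
  ratio <- pmin(pmax(ratio, 0), 1)
  vals <- if (power_scale == "amplitude") sqrt(ratio) else ratio
  amplitude_map(unmask(vals, rm_$vox, rm_$spatial_dim), "fALFF",
                run_id = run$id,
                flags = list(power_scale = power_scale,
                             zero_variance_voxels = sum(sp$total == 0)))
}

#' Temporal signal-to-noise ratio map
#'
#' Per voxel, temporal mean divided by temporal standard deviation (computed
#' with n-1 in the denominator) after preprocessing. Zero-variance voxels get
#' an infinite sentinel and must be masked out of downstream group maps.
#'
#' @param run a preprocessed [bold_run()]
#' @return an [amplitude_map()] with metric `"tSNR"`
#' @export
tsnr_map <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  rm_ <- run_matrix(run)
  mu <- colMeans(rm_$y)
  s <- apply(rm_$y, 2, sd)
  vals <- ifelse(s > 0, mu / s, Inf)
  amplitude_map(unmask(vals, rm_$vox, rm_$spatial_dim), "tSNR",
                run_id = run$id,
                flags = list(zero_variance_voxels = sum(s == 0)))
}

#' Normalize a map to its whole-brain mean
#'
#' Divides by the mean over the brain mask, so the normalized map has mean 1
#' over the mask (making maps comparable across participants). Idempotent.
#'
#' @param map an [amplitude_map()]
#' @param global_mask 3D logical brain mask
#' @return the normalized [amplitude_map()]
#' @export
normalize_map <- function(map, global_mask) {
  stopifnot(inherits(map, "amplitude_map"))
  v <- map$values[global_mask]
  v <- v[is.finite(v)]
  m <- mean(v)
  if (!is.finite(m) || m <= 0)
    stop_lfamp("whole-brain mean is nonpositive (%.4g); cannot normalize", m)
  out <- map
  out$values <- map$values / m
  out$normalized <- TRUE
  out
}

#' Global-BOLD coupling (beta) map
#'
#' The global BOLD series is the per-frame mean over the brain mask; for each
#' voxel in `region_mask` the OLS slope of the voxel series on the demeaned
#' global series is returned (a physiology-proxy map used as a covariate in
#' group comparisons, not regressed out).
#'
#' @param run a [bold_run()]
#' @param region_mask 3D logical mask of voxels to map (default: brain mask)
#' @return an [amplitude_map()] with metric `"gbold_beta"`
#' @export
gbold_beta_map <- function(run, region_mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  rm_ <- run_matrix(run)
  g <- rowMeans(rm_$y)
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss == 0) stop_lfamp("global BOLD series is constant; beta undefined")
  if (is.null(region_mask)) region_mask <- run$mask
  vox <- which(region_mask & run$mask)
  sel <- match(vox, rm_$vox)
  yc <- sweep(rm_$y[, sel, drop = FALSE], 2, colMeans(rm_$y[, sel, drop = FALSE]))
  beta <- as.numeric(crossprod(yc, gc)) / ss
  amplitude_map(unmask(beta, vox, rm_$spatial_dim), "gbold_beta", run_id = run$id)
}

#' Global (whole-brain mean) BOLD series
#'
#' @param run a [bold_run()]
#' @return per-frame numeric vector
#' @export
global_signal <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  rowMeans(run_matrix(run)$y)
}
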