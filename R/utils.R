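#' @importFrom stats coef fft lm lm.fit mvfft p.adjust pnorm pt qnorm qt quantile
#'   rbinom rnorm runif sd var prcomp setNames aggregate
#' @importFrom utils head read.delim write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific RNG seed from a master seed
#'
#' Stages and subjects draw from independent, reproducible streams by hashing
#' the master seed with a small integer offset. Results stay below 2^31.
#'
#' @param seed master integer seed
#' @param ... integer offsets identifying the stream (stage, subject, session ...)
#' @return an integer usable with [set.seed()]
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in offs) {
    x <- (x * 48271 + as.double(o) * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_lfamp <- function(...) stop(sprintf(...), call. = FALSE)

warn_lfamp <- function(...) warning(sprintf(...), call. = FALSE)

#' Positive-frequency bin layout of a length-n real series
#'
#' Returns the DFT bin indices (1-based k, frequency k/(n*tr) Hz) for
#' 0 < f <= Nyquist, together with the Parseval weight of each bin: the
#' contribution of bin k to the time-domain mean square of the (demeaned)
#' series is w_k * |X_k|^2 with w_k = 2/n^2, halved at the Nyquist bin when
#' n is even because that bin has no conjugate mirror.
#'
#' @param n_frames series length
#' @param tr sampling interval, seconds
#' @return list with `k`, `freq_hz`, `weight`
#' @keywords internal
freq_bins <- function(n_frames, tr) {
  kmax <- floor(n_frames / 2)
  k <- seq_len(kmax)
  w <- rep(2 / n_frames^2, kmax)
  if (n_frames %% 2 == 0) w[kmax] <- 1 / n_frames^2
  list(k = k, freq_hz = k / (n_frames * tr), weight = w)
}

# matrix of in-mask voxel time-series, t x V, plus index bookkeeping
run_matrix <- function(run) {
  dm <- dim(run$data)
  v <- which(run$mask)
  nt <- dm[4]
  m <- matrix(run$data, nrow = prod(dm[1:3]), ncol = nt)[v, , drop = FALSE]
  list(y = t(m), vox = v, spatial_dim = dm[1:3])
}

# scatter a per-voxel vector back into a 3D array (NA outside mask)
unmask <- function(values, vox, spatial_dim, fill = NA_real_) {
  out <- array(fill, dim = spatial_dim)
  out[vox] <- values
  out
}
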