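#' Build a principal-component confound matrix
#'
#' The candidate nuisance regressors (six rigid-body motion parameters plus
#' mean CSF and white-matter series) are mean-centered, scaled to unit
#' variance, and jointly decomposed by principal components; the first
#' `n_components` component score series are returned. If the candidate
#' matrix has lower rank, only `rank` components are kept with a warning.
#' Columns of the result are mean-centered and mutually orthogonal.
#'
#' @param motion frames x 6 motion matrix (may be NULL to use tissue series only)
#' @param csf per-frame mean CSF series (may be NULL)
#' @param wm per-frame mean white-matter series (may be NULL)
#' @param n_components number of components to retain (default 6)
#' @param joint_pca if TRUE (default) all candidate columns enter one PCA;
#'   if FALSE, motion columns are passed through raw and only the tissue
#'   series are decomposed (alternative reading of the confound recipe)
#' @return an object of class `confound_matrix`: list with `components`
#'   (frames x k matrix), `explained_variance`, `n_requested`
#' @export
build_confound_matrix <- function(motion = NULL, csf = NULL, wm = NULL,
                                  n_components = 6L, joint_pca = TRUE) {
  cols <- list()
  if (!is.null(motion)) {
    motion <- unclass(motion)
    if (ncol(motion) != 6L) stop_lfamp("motion must have 6 columns")
    cols$motion <- motion
  }
  if (!is.null(csf)) cols$csf <- matrix(csf, ncol = 1)
  if (!is.null(wm)) cols$wm <- matrix(wm, ncol = 1)
  if (!length(cols)) stop_lfamp("no candidate confound series given")
  nf <- unique(vapply(cols, nrow, 1L))
  if (length(nf) != 1L)
    stop_lfamp("candidate confound series have unequal lengths: %s",
               paste(nf, collapse = ", "))
  if (n_components == 0L) {
    return(structure(list(components = matrix(0, nf, 0),
                          explained_variance = numeric(0),
                          n_requested = 0L),
                     class = "confound_matrix"))
  }
  scale_cols <- function(m) {
    m <- scale(m, center = TRUE, scale = FALSE)
    s <- apply(m, 2, sd)
    keep <- s > 0
    sweep(m[, keep, drop = FALSE], 2, s[keep], "/")
  }
  if (joint_pca) {
    x <- scale_cols(do.call(cbind, cols))
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    tol <- max(pc$sdev) * 1e-8
    rank <- sum(pc$sdev > tol)
    keep <- min(n_components, rank)
    if (keep < n_components)
      warn_lfamp("confound candidates have rank %d < %d requested components",
                 rank, n_components)
    comp <- pc$x[, seq_len(keep), drop = FALSE]
    ev <- pc$sdev[seq_len(keep)]^2
  } else {
    mot <- if (is.null(cols$motion)) NULL else scale_cols(cols$motion)
    tis <- do.call(cbind, cols[setdiff(names(cols), "motion")])
    tis_pc <- if (!is.null(tis) && ncol(tis)) {
      x <- scale_cols(tis)
      prcomp(x, center = FALSE)$x
    } else NULL
    comp <- cbind(mot, tis_pc)
    keep <- min(n_components, ncol(comp))
    comp <- comp[, seq_len(keep), drop = FALSE]
    ev <- apply(comp, 2, var)
  }
  structure(list(components = comp, explained_variance = ev,
                 n_requested = as.integer(n_components)),
            class = "confound_matrix")
}

#' @export
print.confound_matrix <- function(x, ...) {
  cat(sprintf("<confound_matrix> %d frames x %d components\n",
              nrow(x$components), ncol(x$components)))
  invisible(x)
}

#' Regress confounds out of a BOLD run (no detrending)
#'
#' Per voxel, the ordinary least-squares residual after projecting out the
#' confound components plus an intercept. No polynomial detrending beyond the
#' intercept is applied (detrending biases amplitude metrics and lowers their
#' repeatability). The voxel mean is re-added to the residual so tSNR remains
#' defined after denoising. An empty confound matrix yields the identity
#' transform.
#'
#' @param run a [bold_run()]
#' @param confounds a [build_confound_matrix()] result
#' @return a denoised [bold_run()]
#' @export
regress_confounds <- function(run, confounds) {
  stopifnot(inherits(run, "bold_run"), inherits(confounds, "confound_matrix"))
  C <- confounds$components
  nt <- dim(run$data)[4]
  if (ncol(C) == 0L) return(run)
  if (nrow(C) != nt)
    stop_lfamp("confound frames (%d) do not match run frames (%d)", nrow(C), nt)
  rm_ <- run_matrix(run)
  y <- rm_$y
  mu <- colMeans(y)
  X <- cbind(1, C)
  qr_x <- qr(X)
  resid <- qr.resid(qr_x, y)
  resid <- sweep(resid, 2, mu, "+")
  out <- run
  m <- matrix(aperm(run$data, c(4, 1, 2, 3)), nrow = nt)
  m[, rm_$vox] <- resid
  out$data <- aperm(array(m, c(nt, rm_$spatial_dim)), c(2, 3, 4, 1))
  out
}
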