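#' Mean map value per atlas region
#'
#' Averages a map over the in-region, in-mask, finite voxels of every atlas
#' label. Non-finite sentinel voxels (e.g. infinite tSNR) are excluded. An
#' empty region yields NA with a warning.
#'
#' @param map an [amplitude_map()]
#' @param atlas a [label_atlas()] aligned to the map
#' @param mask optional 3D logical mask further restricting the average
#' @param exclude integer labels to skip (e.g. regions unresolvable at the
#'   acquisition resolution); they are reported as NA
#' @return named numeric vector, one mean per label
#' @export
roi_summarize <- function(map, atlas, mask = NULL, exclude = integer(0)) {
  stopifnot(inherits(map, "amplitude_map"), inherits(atlas, "label_atlas"))
  if (!identical(dim(map$values), dim(atlas$labels)))
    stop_lfamp("map shape (%s) does not match atlas shape (%s)",
               paste(dim(map$values), collapse = "x"),
               paste(dim(atlas$labels), collapse = "x"))
  use <- atlas$labels > 0
  if (!is.null(mask)) use <- use & mask
  if (!any(use)) stop_lfamp("no overlap between atlas labels and mask")
  out <- setNames(rep(NA_real_, length(atlas$label_ids)),
                  as.character(atlas$label_ids))
  for (lab in setdiff(atlas$label_ids, exclude)) {
    v <- map$values[use & atlas$labels == lab]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warn_lfamp("region %d has no finite in-mask voxels; mean set to NA", lab)
    } else {
      out[as.character(lab)] <- mean(v)
    }
  }
  out
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1) in the Shrout-Fleiss taxonomy, from the two-way ANOVA mean
#' squares of an n units x k sessions table:
#' `(MS_rows - MS_err) / (MS_rows + (k-1) MS_err + k (MS_cols - MS_err)/n)`.
#' Used either per region across subjects (`mode = "per_roi_across_subjects"`)
#' or per subject across regions (`mode = "per_subject_across_rois"`); the
#' mode is recorded but does not change the arithmetic, only what a row is.
#'
#' ICC is invariant to adding a constant to all values and to positive
#' rescaling. A table with zero total variance has no defined ICC: NA is
#' returned with `defined = FALSE`.
#'
#' @param paired_values n x k numeric matrix (k = 2 sessions typical)
#' @param mode which unit the rows represent (bookkeeping only)
#' @return object of class `icc_result`: `icc`, variance components
#'   (`ms_rows`, `ms_cols`, `ms_error`), `mode`, `defined`
#' @export
icc <- function(paired_values,
                mode = c("per_roi_across_subjects", "per_subject_across_rois")) {
  mode <- match.arg(mode)
  x <- as.matrix(paired_values)
  x <- x[apply(is.finite(x), 1, all), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop_lfamp("ICC needs at least 3 complete units; got %d", n)
  if (k < 2L) stop_lfamp("ICC needs at least 2 sessions; got %d", k)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n
  defined <- ss_tot > 0 && is.finite(denom) && denom != 0
  val <- if (defined) (ms_rows - ms_err) / denom else NA_real_
  structure(list(icc = val, ms_rows = ms_rows, ms_cols = ms_cols,
                 ms_error = ms_err, n_units = n, n_sessions = k,
                 mode = mode, defined = defined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %s over %d units x %d sessions (%s)\n",
              if (x$defined) sprintf("%.4f", x$icc) else "undefined",
              x$n_units, x$n_sessions, x$mode))
  invisible(x)
}

#' Bland-Altman agreement between two sessions
#'
#' Differences are session2 - session1 (so negative bias means a decline at
#' the second session); bias is their mean, limits of agreement bias +/-
#' 1.96 SD (n-1 denominator). Per-observation (mean, difference) pairs are
#' returned for plotting.
#'
#' @param s1,s2 paired numeric vectors (session 1, session 2)
#' @return object of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, and a data.frame `points` with columns `mean`, `diff`
#' @export
bland_altman <- function(s1, s2) {
  if (length(s1) != length(s2)) stop_lfamp("sessions must be paired")
  if (length(s1) < 2L) stop_lfamp("need at least 2 pairs")
  d <- s2 - s1
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 points = data.frame(mean = (s1 + s2) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, limits [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, nrow(x$points)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$points$mean, x$points$diff, xlab = "Session mean",
       ylab = "Session 2 - session 1", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Proportion of ICC values at or above a cutoff
#'
#' @param icc_values numeric vector (or list of `icc_result`s); undefined
#'   values are dropped first
#' @param cutoff inclusive threshold (default 0.8)
#' @return proportion in `[0, 1]`
#' @export
fraction_above <- function(icc_values, cutoff = 0.8) {
  if (is.list(icc_values))
    icc_values <- vapply(icc_values, function(r) {
      if (inherits(r, "icc_result")) r$icc else as.numeric(r)
    }, 1.0)
  icc_values <- icc_values[is.finite(icc_values)]
  if (!length(icc_values)) stop_lfamp("no defined ICC values to summarize")
  mean(icc_values >= cutoff)
}

#' Per-subject-session ROI table from a set of maps
#'
#' Builds the long table of region means used by the repeatability stage:
#' one row per subject x session, one column per region label.
#'
#' @param maps named list: `maps[[subject]][[session]]` is an [amplitude_map()]
#' @param atlas a [label_atlas()]
#' @param mask optional 3D logical mask
#' @param exclude labels to exclude (see [roi_summarize()])
#' @return data.frame with columns `subject`, `session`, then one per label
#' @export
roi_table <- function(maps, atlas, mask = NULL, exclude = integer(0)) {
  rows <- list()
  for (subj in names(maps)) {
    for (ses in names(maps[[subj]])) {
      m <- roi_summarize(maps[[subj]][[ses]], atlas, mask, exclude)
      rows[[length(rows) + 1L]] <- data.frame(subject = subj, session = ses,
                                              t(m), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
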