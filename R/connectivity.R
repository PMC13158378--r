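#' Mean time-series over a seed mask
#'
#' @param run a denoised [bold_run()]
#' @param seed 3D logical seed mask (must intersect the brain mask)
#' @return per-frame numeric vector
#' @export
extract_seed_series <- function(run, seed) {
  stopifnot(inherits(run, "bold_run"))
  vox <- which(seed & run$mask)
  if (!length(vox)) stop_lfamp("seed mask is empty within the brain mask")
  rm_ <- run_matrix(run)
  sel <- match(vox, rm_$vox)
  rowMeans(rm_$y[, sel, drop = FALSE])
}

#' Voxelwise Fisher-z seed correlation map
#'
#' Per voxel, the Pearson correlation with the seed series, transformed to
#' Fisher z = atanh(r). Correlations with |r| >= 1 - 1e-7 (the seed's own
#' voxels, or degenerate series) are clamped before the transform and the
#' count recorded in the map flags. Constant voxels get z = 0.
#'
#' @param run a denoised [bold_run()]
#' @param seed_series per-frame numeric vector (nonconstant)
#' @return an [amplitude_map()]-like object of class `z_map`: 3D `values`,
#'   `flags$clamped` count
#' @export
seed_correlation_map <- function(run, seed_series) {
  stopifnot(inherits(run, "bold_run"))
  if (length(seed_series) != dim(run$data)[4])
    stop_lfamp("seed series length (%d) does not match run frames (%d)",
               length(seed_series), dim(run$data)[4])
  if (sd(seed_series) == 0) stop_lfamp("seed series is constant")
  rm_ <- run_matrix(run)
  sc <- seed_series - mean(seed_series)
  yc <- sweep(rm_$y, 2, colMeans(rm_$y))
  ssy <- colSums(yc^2)
  r <- as.numeric(crossprod(yc, sc)) / sqrt(pmax(ssy, .Machine$double.xmin) * sum(sc^2))
  r[ssy == 0] <- 0
  lim <- 1 - 1e-7
  clamped <- sum(abs(r) > lim)
  r <- pmin(pmax(r, -lim), lim)
  structure(list(values = unmask(atanh(r), rm_$vox, rm_$spatial_dim),
                 run_id = run$id, flags = list(clamped = clamped)),
            class = "z_map")
}

#' @export
print.z_map <- function(x, ...) {
  cat(sprintf("<z_map> %s grid, range [%.3f, %.3f]%s\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              if (x$flags$clamped) sprintf(", %d clamped", x$flags$clamped) else ""))
  invisible(x)
}

# separable 1D Gaussian convolution of a 3D array along one axis
conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  dm <- dim(arr)
  out <- array(0, dm)
  for (j in seq_along(kernel)) {
    shift <- j - 1L - r
    src <- seq_len(dm[axis]) + shift
    ok <- src >= 1 & src <= dm[axis]
    if (!any(ok)) next
    dst <- which(ok)
    if (axis == 1) out[dst, , ] <- out[dst, , ] + kernel[j] * arr[src[dst], , ]
    else if (axis == 2) out[, dst, ] <- out[, dst, ] + kernel[j] * arr[, src[dst], ]
    else out[, , dst] <- out[, , dst] + kernel[j] * arr[, , src[dst]]
  }
  out
}

#' Mask-aware Gaussian smoothing
#'
#' Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxels. Voxels outside the brain mask are excluded from the
#' kernel normalization (the kernel is renormalized over in-mask neighbors),
#' and a final global rescale restores the in-mask mean exactly, so smoothing
#' neither bleeds values across the brain boundary nor changes the map's
#' in-mask mean. `fwhm_mm = 0` is the identity.
#'
#' @param map a `z_map`, [amplitude_map()], or plain 3D array
#' @param fwhm_mm full width at half maximum, mm (default 6)
#' @param voxel_size_mm voxel edge length(s), mm (scalar or length 3)
#' @param mask 3D logical mask (default: finite voxels of the map)
#' @return object of the same kind with smoothed values
#' @export
smooth_map <- function(map, fwhm_mm = 6.0, voxel_size_mm = 2.0, mask = NULL) {
  vals <- if (is.list(map)) map$values else map
  if (fwhm_mm < 0) stop_lfamp("fwhm must be nonnegative")
  if (is.null(mask)) mask <- is.finite(vals)
  if (fwhm_mm == 0) return(map)
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  num <- vals
  num[!mask] <- 0
  den <- array(as.numeric(mask), dim(vals))
  for (ax in 1:3) {
    r <- max(1L, ceiling(3 * sig_vox[ax]))
    k <- exp(-0.5 * ((-r:r) / sig_vox[ax])^2)
    k <- k / sum(k)
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  sm <- array(NA_real_, dim(vals))
  sm[mask] <- num[mask] / den[mask]
  mean_in <- mean(vals[mask])
  mean_out <- mean(sm[mask])
  if (is.finite(mean_out) && mean_out != 0 && is.finite(mean_in) && mean_in != 0)
    sm[mask] <- sm[mask] * (mean_in / mean_out)
  if (is.list(map)) {
    map$values <- sm
    map
  } else sm
}

#' Mean seed connectivity per atlas region
#'
#' Averages a Fisher-z map within each atlas label; the seed's own region is
#' excluded from the target set. Empty regions yield NA with a warning.
#'
#' @param zmap a `z_map` from [seed_correlation_map()] (possibly smoothed)
#' @param atlas a [label_atlas()]
#' @param exclude_label label(s) to drop from the target set (the seed region)
#' @return named numeric vector of per-region mean z
#' @export
roi_fc <- function(zmap, atlas, exclude_label = integer(0)) {
  stopifnot(inherits(atlas, "label_atlas"))
  vals <- zmap$values
  if (!identical(dim(vals), dim(atlas$labels)))
    stop_lfamp("z map shape does not match atlas shape")
  labs <- setdiff(atlas$label_ids, exclude_label)
  out <- setNames(rep(NA_real_, length(labs)), as.character(labs))
  for (lab in labs) {
    v <- vals[atlas$labels == lab]
    v <- v[is.finite(v)]
    if (!length(v)) warn_lfamp("region %d empty in z map; NA", lab)
    else out[as.character(lab)] <- mean(v)
  }
  out
}

#' Fit the per-region mixed-effects group model of seed connectivity
#'
#' For one region, fits `fc ~ group + sex + mfd + session + (1 | subject)` by
#' restricted maximum likelihood, with the first group level and male-coded
#' sex as reference levels and session a categorical effect (session 1
#' reference). Wald t statistics use a residual-df approximation
#' (observations minus fixed-effect columns). A singular random-effect fit
#' falls back to ordinary least squares with `fallback_ols = TRUE`.
#'
#' @param table data.frame with columns `fc`, `group`, `sex`, `mfd`,
#'   `session`, `subject`, `roi`
#' @param roi region id to fit (matched against `table$roi`); NULL fits the
#'   table as given
#' @return object of class `fc_mixed_fit`: data.frame `effects` (term, beta,
#'   se, t, p), `roi`, `fallback_ols`, variance components
#' @export
fit_fc_mixed_model <- function(table, roi = NULL) {
  if (!is.null(roi)) table <- table[table$roi == roi, , drop = FALSE]
  req <- c("fc", "group", "sex", "mfd", "session", "subject")
  if (!all(req %in% names(table)))
    stop_lfamp("FC table lacks column(s): %s", paste(setdiff(req, names(table)), collapse = ", "))
  if (any(!is.finite(table$fc))) stop_lfamp("non-finite FC values in table")
  if (length(unique(table$subject)) < 10L)
    stop_lfamp("need at least 10 subjects; got %d", length(unique(table$subject)))
  table$group <- as.factor(table$group)
  table$sex <- as.factor(table$sex)
  table$session <- as.factor(table$session)
  table$subject <- as.factor(table$subject)
  fallback <- FALSE
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fc ~ group + sex + mfd + session + (1 | subject),
               data = table, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    fallback <- TRUE
    ols <- lm(fc ~ group + sex + mfd + session, data = table)
    beta <- coef(ols)
    se <- sqrt(diag(stats::vcov(ols)))
    df <- nrow(table) - length(beta)
    var_subj <- 0
    var_resid <- sum(ols$residuals^2) / df
  } else {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    df <- nrow(table) - length(beta)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_subj <- vc$vcov[vc$grp == "subject"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
  }
  tval <- beta / se
  p <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  structure(list(effects = data.frame(term = names(beta), beta = unname(beta),
                                      se = unname(se), t = unname(tval),
                                      p = unname(pmax(p, .Machine$double.xmin)),
                                      row.names = NULL),
                 roi = roi, fallback_ols = fallback, df = df,
                 var_subject = var_subj, var_residual = var_resid),
            class = "fc_mixed_fit")
}

#' @export
print.fc_mixed_fit <- function(x, ...) {
  cat(sprintf("<fc_mixed_fit>%s%s df = %d, subject var %.4g, residual var %.4g\n",
              if (is.null(x$roi)) "" else sprintf(" roi %s,", x$roi),
              if (x$fallback_ols) " (OLS fallback)" else "", x$df,
              x$var_subject, x$var_residual))
  print(x$effects, digits = 4)
  invisible(x)
}

#' Step-up false-discovery-rate adjustment
#'
#' Benjamini-Hochberg or Benjamini-Yekutieli adjusted p-values (the latter
#' multiplies by the harmonic sum c(m) and remains valid under arbitrary
#' dependence). Thin, validated front end to [stats::p.adjust()].
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @param method `"BY"` (default) or `"BH"`
#' @return adjusted p-values, same order as input
#' @export
fdr_adjust <- function(pvalues, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_lfamp("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = method)
}

#' Report regions with FDR-significant group effects
#'
#' Collects the group-effect p-value from each per-region fit, adjusts across
#' regions, and returns the rows passing `q`, sorted by adjusted p ascending,
#' with the full fixed-effect table (beta, SE, T, p, p-FDR) per region.
#'
#' @param fits named list of [fit_fc_mixed_model()] results (names = region ids)
#' @param q adjusted-p threshold (default 0.001)
#' @param method FDR method (see [fdr_adjust()])
#' @return data.frame: one row per fixed effect of each significant region
#' @export
report_significant_rois <- function(fits, q = 0.001, method = c("BY", "BH")) {
  method <- match.arg(method)
  terms <- lapply(fits, function(f) f$effects)
  group_p <- vapply(terms, function(e) e$p[grepl("^group", e$term)][1], 1.0)
  adj <- fdr_adjust(group_p, method)
  keep <- which(!is.na(adj) & adj < q)
  keep <- keep[order(adj[keep])]
  if (!length(keep))
    return(data.frame(roi = character(0), term = character(0), beta = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      p_fdr = numeric(0)))
  do.call(rbind, lapply(keep, function(i) {
    e <- terms[[i]]
    data.frame(roi = names(fits)[i] %||% as.character(i), term = e$term,
               beta = e$beta, se = e$se, t = e$t, p = e$p,
               p_fdr = ifelse(grepl("^group", e$term), adj[i], NA_real_),
               row.names = NULL)
  }))
}
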