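#' Two-group voxelwise design
#'
#' Bundles per-subject maps with the group factor and covariates for
#' voxelwise inference. Scalar covariates (e.g. mean FD) enter per subject;
#' voxelwise covariates (e.g. gray-matter probability, global-BOLD beta maps)
#' are sampled at each voxel.
#'
#' @param maps list of [amplitude_map()] objects (or a subjects x voxels
#'   matrix together with `mask`), one entry per subject
#' @param group length-n vector/factor with exactly two levels; the first
#'   level is the reference (coded 0)
#' @param covariates optional data.frame of scalar covariates (n rows)
#' @param voxel_covariates optional named list of per-subject map lists,
#'   each aligned to `maps`
#' @param mask 3D logical analysis mask (required when `maps` is a matrix;
#'   otherwise defaults to voxels finite in every subject's map)
#' @return object of class `group_design`
#' @export
group_design <- function(maps, group, covariates = NULL,
                         voxel_covariates = NULL, mask = NULL) {
  if (is.matrix(maps)) {
    if (is.null(mask)) stop_lfamp("mask is required with matrix input")
    y <- maps
    vox <- which(mask)
    spatial_dim <- dim(mask)
    if (ncol(y) != length(vox))
      stop_lfamp("matrix has %d columns but mask has %d voxels", ncol(y), length(vox))
  } else {
    stopifnot(all(vapply(maps, inherits, TRUE, "amplitude_map")))
    spatial_dim <- dim(maps[[1]]$values)
    finite <- Reduce(`&`, lapply(maps, function(m) is.finite(m$values)))
    if (is.null(mask)) mask <- finite else mask <- mask & finite
    vox <- which(mask)
    if (!length(vox)) stop_lfamp("analysis mask is empty")
    y <- do.call(rbind, lapply(maps, function(m) m$values[vox]))
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop_lfamp("group must have exactly 2 levels; got %d", nlevels(group))
  if (length(group) != nrow(y))
    stop_lfamp("group length (%d) does not match number of subjects (%d)",
               length(group), nrow(y))
  if (min(table(group)) < 2L) stop_lfamp("need at least 2 subjects per group")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(y))
      stop_lfamp("covariate rows (%d) do not match subjects (%d)",
                 nrow(covariates), nrow(y))
    if (any(!is.finite(as.matrix(covariates))))
      stop_lfamp("covariates contain non-finite values")
  }
  vc <- NULL
  if (!is.null(voxel_covariates)) {
    vc <- lapply(voxel_covariates, function(ml) {
      if (is.matrix(ml)) {
        if (!identical(dim(ml), dim(y)))
          stop_lfamp("voxelwise covariate matrix (%dx%d) must match data (%dx%d)",
                     nrow(ml), ncol(ml), nrow(y), ncol(y))
        ml
      } else {
        do.call(rbind, lapply(ml, function(m) {
          v <- if (inherits(m, "amplitude_map")) m$values else m
          v[vox]
        }))
      }
    })
  }
  structure(list(y = y, group = group, covariates = covariates,
                 voxel_covariates = vc, mask = mask, vox = vox,
                 spatial_dim = spatial_dim),
            class = "group_design")
}

# n x p fixed design matrix (no voxelwise columns); group indicator in col 2
design_matrix <- function(design, group = design$group) {
  X <- cbind(`(Intercept)` = 1, group = as.numeric(group == levels(group)[2]))
  if (!is.null(design$covariates)) X <- cbind(X, as.matrix(design$covariates))
  X
}

# voxelwise t-statistics for the group column of X; y is subjects x V
fit_group_t <- function(X, y, voxel_covariates = NULL) {
  n <- nrow(X)
  if (is.null(voxel_covariates) || !length(voxel_covariates)) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      drop <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
      stop_lfamp("rank-deficient design: collinear column(s) %s",
                 paste(drop, collapse = ", "))
    }
    xtxinv <- chol2inv(qr.R(qx))
    B <- xtxinv %*% crossprod(X, y)
    resid <- y - X %*% B
    df <- n - ncol(X)
    s2 <- colSums(resid^2) / df
    tval <- B[2, ] / sqrt(pmax(s2, .Machine$double.xmin) * xtxinv[2, 2])
    list(t = tval, df = df)
  } else {
    V <- ncol(y)
    pex <- length(voxel_covariates)
    tval <- numeric(V)
    df <- n - ncol(X) - pex
    for (v in seq_len(V)) {
      Xv <- cbind(X, vapply(voxel_covariates, function(m) m[, v], numeric(n)))
      qx <- qr(Xv)
      if (qx$rank < ncol(Xv)) {
        drop <- c(colnames(X), names(voxel_covariates))[
          qx$pivot[seq.int(qx$rank + 1L, ncol(Xv))]]
        stop_lfamp("rank-deficient design at voxel %d: collinear column(s) %s",
                   v, paste(drop, collapse = ", "))
      }
      xtxinv <- chol2inv(qr.R(qx))
      b <- xtxinv %*% crossprod(Xv, y[, v])
      r <- y[, v] - Xv %*% b
      s2 <- sum(r^2) / df
      tval[v] <- b[2] / sqrt(pmax(s2, .Machine$double.xmin) * xtxinv[2, 2])
    }
    list(t = tval, df = df)
  }
}

#' Voxelwise two-group t-test with covariates
#'
#' Per voxel, the OLS fit `value ~ intercept + group + covariates` (voxelwise
#' covariates sampled at that voxel) and the t-statistic for the group
#' coefficient in the requested direction. `"g2>g1"` leaves the coefficient
#' sign as fitted (positive t where the second group level is higher);
#' `"g1>g2"` negates it. The two one-sided maps are therefore mutually
#' exclusive at any voxel after thresholding.
#'
#' @param design a [group_design()]
#' @param direction `"g2>g1"` (default) or `"g1>g2"`
#' @return object of class `stat_map`: 3D `values` (NA outside mask), `df`,
#'   `direction`, `mask`
#' @export
voxelwise_group_ttest <- function(design, direction = c("g2>g1", "g1>g2")) {
  direction <- match.arg(direction)
  stopifnot(inherits(design, "group_design"))
  X <- design_matrix(design)
  ft <- fit_group_t(X, design$y, design$voxel_covariates)
  tval <- if (direction == "g1>g2") -ft$t else ft$t
  structure(list(values = unmask(tval, design$vox, design$spatial_dim),
                 df = ft$df, direction = direction, mask = design$mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> t (%s), df = %d, max = %.3f\n", x$direction, x$df,
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Permutation maxT family-wise-error height threshold
#'
#' Group labels are permuted `n_perm` times (covariates travel with their
#' subjects); for each permutation the maximum |t| over the mask is recorded,
#' and the threshold is the (1 - alpha) empirical quantile of that max-t null
#' distribution. Voxels with |t| above it are FWE-significant at level alpha.
#' When the groups admit fewer distinct label assignments than `n_perm`, the
#' permutation space is enumerated exhaustively instead (with a warning).
#'
#' @param design a [group_design()]
#' @param alpha family-wise error level (default 0.05)
#' @param n_perm number of permutations (>= 100)
#' @param seed integer RNG seed for the permutation draw
#' @return list of class `fwe_result`: `threshold`, `max_t` (null draws),
#'   `alpha`, `n_perm`, `exhaustive`
#' @export
fwe_threshold <- function(design, alpha = 0.05, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(design, "group_design"))
  if (n_perm < 100L) stop_lfamp("n_perm must be at least 100; got %d", n_perm)
  g <- design$group
  n <- length(g)
  n2 <- sum(g == levels(g)[2])
  n_distinct <- choose(n, n2)
  exhaustive <- n_distinct <= n_perm
  if (exhaustive) {
    warn_lfamp("only %d distinct group assignments; enumerating exhaustively",
               n_distinct)
    combos <- combn(n, n2)
    perms <- lapply(seq_len(ncol(combos)), function(j) {
      gi <- rep(levels(g)[1], n)
      gi[combos[, j]] <- levels(g)[2]
      factor(gi, levels = levels(g))
    })
  } else {
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(i) sample(g)))
  }
  simple <- is.null(design$covariates) && is.null(design$voxel_covariates)
  if (simple) {
    y <- design$y
    n1 <- n - n2
    tot <- colSums(y)
    sstot <- colSums(y^2) - tot^2 / n
    P <- do.call(rbind, lapply(perms, function(p) as.numeric(p == levels(g)[2])))
    S2 <- P %*% y
    m2 <- S2 / n2
    m1 <- sweep(-S2, 2, tot, "+") / n1
    d <- m2 - m1
    ssw <- sweep(-(n1 * n2 / n) * d^2, 2, sstot, "+")
    tmat <- d / sqrt(pmax(ssw, 0) / (n - 2) * (1 / n1 + 1 / n2))
    max_t <- apply(abs(tmat), 1, max)
  } else {
    max_t <- vapply(perms, function(p) {
      Xp <- design_matrix(design, p)
      max(abs(fit_group_t(Xp, design$y, design$voxel_covariates)$t))
    }, 1.0)
  }
  m <- sort(max_t)
  thr <- m[ceiling((1 - alpha) * length(m))]
  structure(list(threshold = thr, max_t = max_t, alpha = alpha,
                 n_perm = length(perms), exhaustive = exhaustive),
            class = "fwe_result")
}

#' @export
print.fwe_result <- function(x, ...) {
  cat(sprintf("<fwe_result> maxT height threshold %.3f at alpha %.3g (%d %s permutations)\n",
              x$threshold, x$alpha, x$n_perm,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

# neighbor offsets for 6/18/26 connectivity
neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop_lfamp("connectivity must be 6, 18 or 26; got %s", connectivity)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  as.matrix(g[keep, ])
}

#' Connected suprathreshold clusters of a statistic map
#'
#' Labels connected components of voxels strictly exceeding `height` (in the
#' map's direction) under the chosen neighborhood, discards components
#' smaller than `min_extent`, and reports per-cluster size, peak statistic
#' and peak voxel coordinate (0-based). The largest surviving cluster feeds
#' seed selection for connectivity analysis.
#'
#' @param stat a `stat_map` from [voxelwise_group_ttest()]
#' @param height height threshold (finite)
#' @param min_extent minimum cluster size in voxels (default 10)
#' @param connectivity 6, 18 or 26 (default 26)
#' @return object of class `cluster_set`: `labels` (3D integer array, 0 =
#'   background), and a data.frame `clusters` (label, size, peak_t,
#'   peak_x/y/z) sorted by size descending
#' @export
extract_clusters <- function(stat, height, min_extent = 10L, connectivity = 26L) {
  stopifnot(inherits(stat, "stat_map"))
  if (!is.finite(height)) stop_lfamp("height threshold must be finite")
  dm <- dim(stat$values)
  supra <- !is.na(stat$values) & stat$values > height
  labels <- array(0L, dm)
  offs <- neighbor_offsets(connectivity)
  idx <- which(supra)
  comp <- 0L
  info <- list()
  coords <- arrayInd(idx, dm)
  lookup <- array(0L, dm)
  lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  for (start in seq_along(idx)) {
    if (visited[start]) next
    comp <- comp + 1L
    queue <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      cc <- coords[cur, ]
      nb <- sweep(offs, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- lookup[nb]
      ni <- ni[ni > 0]
      ni <- ni[!visited[ni]]
      if (length(ni)) {
        visited[ni] <- TRUE
        queue <- c(queue, ni)
      }
    }
    if (length(members) >= min_extent) {
      vi <- idx[members]
      peak <- vi[which.max(stat$values[vi])]
      pc <- arrayInd(peak, dm)
      info[[length(info) + 1L]] <- data.frame(
        label = NA_integer_, size = length(members),
        peak_t = stat$values[peak],
        peak_x = pc[1] - 1L, peak_y = pc[2] - 1L, peak_z = pc[3] - 1L)
      labels[vi] <- length(info)
    }
  }
  clusters <- if (length(info)) do.call(rbind, info) else
    data.frame(label = integer(0), size = integer(0), peak_t = numeric(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0))
  if (nrow(clusters)) {
    ord <- order(-clusters$size)
    relab <- array(0L, dim(labels))
    for (j in seq_along(ord)) relab[labels == ord[j]] <- j
    labels <- relab
    clusters <- clusters[ord, , drop = FALSE]
    clusters$label <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  structure(list(labels = labels, clusters = clusters,
                 height = height, min_extent = min_extent,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) above %.3f (min extent %d, %d-connectivity)\n",
              nrow(x$clusters), x$height, x$min_extent, x$connectivity))
  if (nrow(x$clusters)) print(head(x$clusters, 5))
  invisible(x)
}

#' Cohen's d from group summary statistics
#'
#' `d = (mean1 - mean2) / s_pooled` with the pooled standard deviation
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return Cohen's d (signed)
#' @export
cohens_d_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Normal-quantile confidence interval from summary statistics
#'
#' `mean +/- z * sd / sqrt(n)` with z the two-sided standard-normal quantile
#' (1.959964 at level 0.95). The normal (not t) quantile is the convention
#' used for the reported cluster summaries.
#'
#' @param mean,sd,n group summary (sd >= 0, n >= 2)
#' @param level confidence level (default 0.95)
#' @return numeric vector `c(lower, upper)`
#' @export
summary_ci <- function(mean, sd, n, level = 0.95) {
  stopifnot(n >= 2, sd >= 0)
  z <- qnorm(1 - (1 - level) / 2)
  mean + c(-1, 1) * z * sd / sqrt(n)
}

#' Binarize a statistic map at an uncorrected p threshold
#'
#' Voxels with one-sided p strictly below `p_uncorrected` (in the map's
#' direction) are set TRUE.
#'
#' @param stat a `stat_map`
#' @param p_uncorrected threshold (default 0.05)
#' @return 3D logical array
#' @export
binarize_map <- function(stat, p_uncorrected = 0.05) {
  stopifnot(inherits(stat, "stat_map"))
  p <- pt(stat$values, df = stat$df, lower.tail = FALSE)
  out <- !is.na(p) & p < p_uncorrected
  array(out, dim(stat$values))
}

#' Dice coefficient of two binary masks
#'
#' `2 |a & b| / (|a| + |b|)`; two empty masks give 0 with a warning.
#'
#' @param a,b logical arrays of identical shape
#' @return dice coefficient in `[0, 1]`
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_lfamp("mask shapes differ: %s vs %s", paste(dim(a), collapse = "x"),
               paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warn_lfamp("both masks empty; dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / (na + nb)
}

# exact two-sample t-test power at equal group size n, via the noncentral t
two_sample_t_power <- function(n, d, alpha = 0.05, tails = 2) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- qt(1 - alpha / tails, df)
  pow <- pt(tc, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pow <- pow + pt(-tc, df, ncp = ncp)
  pow
}

#' Required per-group sample size for a two-sample t-test
#'
#' Starts from the normal approximation
#' `n = 2 (z_{1-alpha/tails} + z_{power})^2 / d^2` and refines by searching
#' for the smallest integer n whose exact (noncentral-t) power reaches the
#' target.
#'
#' @param d standardized effect size (> 0)
#' @param power target power (default 0.8)
#' @param alpha significance level (default 0.05)
#' @param tails 2 (default) or 1
#' @return smallest integer n per group with power >= target
#' @export
required_sample_size <- function(d, power = 0.8, alpha = 0.05, tails = 2) {
  stopifnot(d > 0, power > 0, power < 1)
  n0 <- ceiling(2 * (qnorm(1 - alpha / tails) + qnorm(power))^2 / d^2)
  n <- max(2L, n0 - 5L)
  while (two_sample_t_power(n, d, alpha, tails) < power) n <- n + 1L
  n
}
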