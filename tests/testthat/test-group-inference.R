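test_that("the null t-map is Student-t calibrated and planted effects localize", {
  set.seed(40)
  n <- 24
  mask <- array(TRUE, c(25, 20, 20))          # 10^4 voxels
  y <- matrix(rnorm(n * 1e4), n, 1e4)
  g <- rep(1:2, each = n / 2)
  des <- group_design(y, g, mask = mask)
  st <- voxelwise_group_ttest(des)
  crit <- qt(0.975, st$df)
  expect_equal(mean(abs(st$values) > crit), 0.05, tolerance = 0.01)
  expect_equal(st$df, n - 2)
  # shift a voxel block for group 2: the peak lands inside the block
  y2 <- y
  block <- 1:50
  y2[g == 2, block] <- y2[g == 2, block] + 2
  st2 <- voxelwise_group_ttest(group_design(y2, g, mask = mask))
  expect_true(which.max(st2$values) %in% which(mask)[block])
  # one-sided maps are mutually exclusive after thresholding
  stf <- voxelwise_group_ttest(group_design(y2, g, mask = mask), "g1>g2")
  expect_false(any(st2$values > 2 & stf$values > 2, na.rm = TRUE))
})

test_that("a covariate equal to the group indicator triggers a rank error", {
  set.seed(41)
  mask <- array(TRUE, c(5, 5, 4))
  y <- matrix(rnorm(10 * 100), 10, 100)
  g <- rep(1:2, each = 5)
  des <- group_design(y, g, covariates = data.frame(dup = as.numeric(g == 2)),
                      mask = mask)
  expect_error(voxelwise_group_ttest(des), "collinear")
})

test_that("a voxelwise covariate that explains a planted confound removes the cluster", {
  set.seed(42)
  n <- 30; v <- 500
  mask <- array(TRUE, c(25, 20, 1))
  conf <- matrix(rnorm(n * v), n, v)           # per-subject confound maps
  strength <- c(rep(0, v / 2), rep(1.5, v / 2))
  y <- matrix(rnorm(n * v, sd = 0.5), n, v) + sweep(conf, 2, strength, "*")
  g <- rep(1:2, each = n / 2)
  conf <- conf + outer(as.numeric(g == 2), rep(0.8, v))  # confound tracks group
  y <- y + sweep(outer(as.numeric(g == 2), rep(0.8, v)), 2, strength, "*")
  raw <- voxelwise_group_ttest(group_design(y, g, mask = mask))
  adj <- voxelwise_group_ttest(group_design(y, g, mask = mask,
                                            voxel_covariates = list(conf = conf)))
  expect_gt(max(raw$values, na.rm = TRUE), 4)
  expect_lt(max(adj$values, na.rm = TRUE), 4)
})

test_that("permutation maxT thresholds are alpha-monotone and match enumeration", {
  set.seed(43)
  mask <- array(TRUE, c(10, 10, 1))
  y <- matrix(rnorm(8 * 100), 8, 100)
  g <- rep(1:2, each = 4)
  des <- group_design(y, g, mask = mask)
  expect_warning(fw <- fwe_threshold(des, alpha = 0.05, n_perm = 100, seed = 1),
                 "exhaustively")
  expect_true(fw$exhaustive)
  expect_equal(fw$n_perm, choose(8, 4))
  # independent enumeration oracle over all 70 assignments
  combos <- combn(8, 4)
  maxt <- apply(combos, 2, function(ix) {
    gi <- rep(1, 8); gi[ix] <- 2
    tv <- vapply(seq_len(100), function(j) {
      unname(t.test(y[gi == 2, j], y[gi == 1, j], var.equal = TRUE)$statistic)
    }, 1.0)
    max(abs(tv))
  })
  thr_oracle <- sort(maxt)[ceiling(0.95 * length(maxt))]
  expect_equal(fw$threshold, thr_oracle, tolerance = 1e-8)
  # monotone decreasing in alpha
  expect_warning(fw10 <- fwe_threshold(des, alpha = 0.10, n_perm = 100, seed = 1))
  expect_lte(fw10$threshold, fw$threshold)
})

test_that("cluster extraction respects extent and connectivity semantics", {
  dm <- c(12, 12, 6)
  vals <- array(0, dm)
  vals[2:5, 2:4, 2] <- 5          # 12-voxel slab (4 x 3)
  vals[9:10, 9:10, 4] <- 5        # 4-voxel blob
  st <- structure(list(values = vals, df = 20, direction = "g2>g1",
                       mask = array(TRUE, dm)), class = "stat_map")
  cl <- extract_clusters(st, height = 2, min_extent = 10)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$size, 12L)
  # diagonal-touching voxels: one cluster at 26-connectivity, two at 6
  vals2 <- array(0, dm)
  vals2[3, 3, 3] <- 4; vals2[4, 4, 4] <- 4
  st2 <- structure(list(values = vals2, df = 20, direction = "g2>g1",
                        mask = array(TRUE, dm)), class = "stat_map")
  expect_equal(nrow(extract_clusters(st2, 2, min_extent = 1,
                                     connectivity = 26)$clusters), 1L)
  expect_equal(nrow(extract_clusters(st2, 2, min_extent = 1,
                                     connectivity = 6)$clusters), 2L)
  # empty suprathreshold set is fine
  empty <- extract_clusters(st, height = 10)
  expect_equal(nrow(empty$clusters), 0L)
})

test_that("Cohen's d reproduces the reported cluster effect size", {
  expect_equal(round(cohens_d_from_summary(1.920, 0.829, 61, 1.527, 0.613, 59), 2),
               0.54)
  expect_equal(cohens_d_from_summary(1, 1, 10, 1, 1, 10), 0)
  expect_equal(cohens_d_from_summary(1, 1, 20, 0, 1, 20), 1)
})

test_that("normal-quantile CIs reproduce the reported cluster intervals", {
  expect_equal(round(summary_ci(1.920, 0.829, 61), 3), c(1.712, 2.128))
  expect_equal(round(summary_ci(1.527, 0.613, 59), 3), c(1.371, 1.683))
  expect_equal(round(summary_ci(1.675, 0.888, 59), 3), c(1.448, 1.902))
  expect_equal(round(summary_ci(1.543, 0.816, 61), 3), c(1.338, 1.748))
  expect_equal(summary_ci(5, 0, 10), c(5, 5))
  expect_equal(summary_ci(0, 1, 4), c(-0.980, 0.980), tolerance = 1e-3)
})

test_that("map binarization is strict and monotone in the threshold", {
  dm <- c(4, 4, 2)
  vals <- array(qt(0.95, df = 30), dm)      # exactly at the critical value
  st <- structure(list(values = vals, df = 30, direction = "g2>g1",
                       mask = array(TRUE, dm)), class = "stat_map")
  expect_false(any(binarize_map(st, 0.05)))
  st$values <- array(0, dm)
  expect_false(any(binarize_map(st, 0.05)))
  set.seed(44)
  st$values <- array(rnorm(32, 1), dm)
  m1 <- binarize_map(st, 0.05)
  m2 <- binarize_map(st, 0.01)
  expect_true(all(m1[m2]))                  # smaller p keeps a subset
})

test_that("dice counts overlap as expected", {
  a <- array(FALSE, c(5, 5, 2)); b <- a
  a[1:10] <- TRUE; b[7:16] <- TRUE          # |a| = |b| = 10, overlap 4
  expect_equal(dice(a, b), 0.4)
  expect_equal(dice(a, a), 1)
  b2 <- array(FALSE, c(5, 5, 2)); b2[20:25] <- TRUE
  expect_equal(dice(a, b2), 0)
  expect_warning(z <- dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
                 "empty")
  expect_equal(z, 0)
  expect_error(dice(a, array(FALSE, c(5, 5, 3))), "differ")
})

test_that("required sample sizes match the exact-t power search", {
  expect_equal(required_sample_size(0.5), 64)
  expect_equal(required_sample_size(1.0), 17)
  # independent cross-check against the stock power routine
  for (d in c(0.3, 0.5, 0.8, 1.2)) {
    expect_equal(required_sample_size(d),
                 ceiling(stats::power.t.test(delta = d, power = 0.8)$n))
  }
  # non-increasing in effect size
  ns <- vapply(seq(0.2, 1.5, by = 0.1), required_sample_size, 1.0)
  expect_true(all(diff(ns) <= 0))
})
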