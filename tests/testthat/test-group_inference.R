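stat_fixture <- function(tvals, dims, df = 35, affine = fixture_affine()) {
  arr <- array(0, dims)
  arr[seq_along(tvals)] <- tvals
  structure(list(map = voxel_map(arr, affine, "t", array(TRUE, dims)),
                 df = df, contrast = "group"),
            class = "stat_map")
}

test_that("the design matrix encodes group and centred covariates", {
  ph <- make_phenotypes(4, 4)
  x <- make_design(ph)
  expect_equal(colnames(x), c("intercept", "group", "age", "sex",
                              "education"))
  expect_equal(unname(x[, "group"]), c(rep(1, 4), rep(0, 4)))
  expect_equal(mean(x[, "age"]), 0, tolerance = 1e-12)
  ph$group <- rep("AD", 8)
  expect_error(make_design(ph), "constant")
})

test_that("voxelwise GLM reduces to the pooled two-sample t without covariates", {
  set.seed(1)
  n <- 14
  grp <- c(rep(1, 7), rep(0, 7))
  y <- matrix(rnorm(n * 20), n, 20)
  y[, 1:5] <- y[, 1:5] + 1.5 * grp
  design <- cbind(intercept = 1, group = grp)
  mask <- array(TRUE, c(20, 1, 1))
  stat <- voxelwise_glm_ttest(y, design, mask)
  expect_equal(stat$df, 12)
  classical <- apply(y, 2, function(col)
    unname(t.test(col[grp == 1], col[grp == 0], var.equal = TRUE)$statistic))
  expect_equal(stat$map$values[mask], classical, tolerance = 1e-8)
})

test_that("GLM coefficients match the explicit normal-equations oracle", {
  set.seed(2)
  ph <- make_phenotypes(4, 4)
  x <- make_design(ph)
  y <- matrix(rnorm(8 * 6), 8, 6)
  mask <- array(TRUE, c(6, 1, 1))
  stat <- voxelwise_glm_ttest(y, x, mask)

  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)
  res <- y - x %*% beta
  sigma2 <- colSums(res ^ 2) / (8 - ncol(x))
  oracle_t <- beta["group", ] / sqrt(sigma2 * xtx_inv["group", "group"])
  expect_equal(stat$map$values[mask], unname(oracle_t), tolerance = 1e-10)

  # paired construction: identical covariates and values across the two
  # groups force the group coefficient to exactly zero
  ph2 <- make_phenotypes(6, 6)
  for (cv in c("age", "sex", "education"))
    ph2[[cv]][7:12] <- ph2[[cv]][1:6]
  x2 <- make_design(ph2)
  y0 <- matrix(rnorm(6 * 6), 6, 6)[rep(1:6, 2), ]
  stat0 <- voxelwise_glm_ttest(y0, x2, mask)
  expect_lt(max(abs(stat0$map$values)), 1e-8)

  bad <- cbind(x, dup = x[, "age"])
  expect_error(voxelwise_glm_ttest(y, bad, mask), "collinear|rank")
})

test_that("cluster extraction respects connectivity and reports mm peaks", {
  dims <- c(8, 8, 8)
  aff <- fixture_affine()
  tv <- array(0, dims)
  tv[4, 4, 4] <- 5
  st <- stat_fixture(as.numeric(tv), dims)
  cl <- cluster_extract(st)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent, 1)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z),
               as.numeric(voxel_to_mm(c(3, 3, 3), aff)))
  expect_equal(cl$peak_t, 5)

  # face-sharing pair: one cluster at every connectivity
  tv2 <- array(0, dims); tv2[4, 4, 4] <- 5; tv2[5, 4, 4] <- 4.5
  st2 <- stat_fixture(as.numeric(tv2), dims)
  for (conn in c(6, 18, 26))
    expect_equal(nrow(cluster_extract(st2, connectivity = conn)), 1)

  # corner-sharing pair: separate at 18, merged at 26
  tv3 <- array(0, dims); tv3[4, 4, 4] <- 5; tv3[5, 5, 5] <- 4.5
  st3 <- stat_fixture(as.numeric(tv3), dims)
  expect_equal(nrow(cluster_extract(st3, connectivity = 18)), 2)
  expect_equal(nrow(cluster_extract(st3, connectivity = 26)), 1)

  # edge-sharing pair: separate at 6, merged at 18
  tv4 <- array(0, dims); tv4[4, 4, 4] <- 5; tv4[5, 5, 4] <- 4.5
  st4 <- stat_fixture(as.numeric(tv4), dims)
  expect_equal(nrow(cluster_extract(st4, connectivity = 6)), 2)
  expect_equal(nrow(cluster_extract(st4, connectivity = 18)), 1)

  # opposite tails never merge, and an empty table is allowed
  tv5 <- array(0, dims); tv5[4, 4, 4] <- 5; tv5[5, 4, 4] <- -5
  st5 <- stat_fixture(as.numeric(tv5), dims)
  cl5 <- cluster_extract(st5)
  expect_equal(sort(cl5$sign), c(-1, 1))
  st6 <- stat_fixture(rep(0, 8), dims)
  expect_equal(nrow(cluster_extract(st6)), 0)
})

test_that("cluster tables shift with the affine but keep their extents", {
  dims <- c(6, 6, 6)
  tv <- array(0, dims); tv[2:3, 2, 2] <- 6
  a1 <- fixture_affine(3, 0)
  a2 <- fixture_affine(3, 0); a2[1:3, 4] <- c(30, -12, 9)
  c1 <- cluster_extract(stat_fixture(as.numeric(tv), dims, affine = a1))
  c2 <- cluster_extract(stat_fixture(as.numeric(tv), dims, affine = a2))
  expect_equal(c1$extent, c2$extent)
  expect_equal(c(c2$peak_x - c1$peak_x, c2$peak_y - c1$peak_y,
                 c2$peak_z - c1$peak_z), c(30, -12, 9))
})

test_that("permutation correction is reproducible and uses the +1 estimator", {
  set.seed(3)
  n <- 16
  grp <- rep(c(1, 0), each = 8)
  dims <- c(6, 6, 6)
  v <- prod(dims)
  y <- matrix(rnorm(n * v), n, v)
  block <- as.vector(array(seq_len(v), dims)[2:4, 2:4, 2:4])
  y[, block] <- y[, block] + 4 * grp
  design <- cbind(intercept = 1, group = grp)
  mask <- array(TRUE, dims)

  res <- permutation_cluster_correction(y, design, mask, n_perm = 100,
                                        seed = 11)
  cl <- res$clusters
  expect_gt(nrow(cl), 0)
  top <- which.max(cl$extent)
  # the +1 Monte-Carlo estimator, recomputed from the returned null
  expect_equal(cl$p_corrected[top],
               (1 + sum(res$null_max_extent >= cl$extent[top])) / 101)
  if (all(res$null_max_extent < cl$extent[top]))
    expect_equal(cl$p_corrected[top], 1 / 101)
  expect_true(cl$significant[top])

  res2 <- permutation_cluster_correction(y, design, mask, n_perm = 100,
                                         seed = 11)
  expect_identical(res$null_max_extent, res2$null_max_extent)
  expect_identical(res$clusters$p_corrected, res2$clusters$p_corrected)

  expect_error(permutation_cluster_correction(y, design, mask, n_perm = 50),
               ">= 100")
  expect_warning(permutation_cluster_correction(y, design, mask,
                                                n_perm = 100,
                                                cluster_p = 0.005,
                                                seed = 1),
                 "resolve")
})

test_that("summary-statistic t-tests reproduce tabled p-values", {
  edu <- summary_ttest(10.84, 3.11, 36, 11.62, 3.32, 42)
  expect_equal(round(edu$p, 2), 0.29)
  expect_equal(edu$df, 76)

  eq <- summary_ttest(5, 1, 10, 5, 1, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  mmse <- summary_ttest(21.3, 3.36, 36, 28.24, 1.43, 42)
  # pooled-variance oracle recomputed longhand
  sp2 <- (35 * 3.36 ^ 2 + 41 * 1.43 ^ 2) / 76
  oracle_t <- (21.3 - 28.24) / sqrt(sp2 * (1 / 36 + 1 / 42))
  expect_equal(mmse$t, oracle_t, tolerance = 1e-12)
  expect_equal(round(mmse$t, 1), -12.2)
  expect_lt(mmse$p, 1e-15)
})

test_that("2x2 chi-square matches the expected-count formula", {
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  obs <- c(21, 15, 16, 26)
  res <- chi_square_2x2(21, 15, 16, 26)
  o <- matrix(obs, 2, 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(res$chi2, sum((o - e) ^ 2 / e), tolerance = 1e-12)
  expect_equal(res$df, 1)

  dbl <- chi_square_2x2(42, 30, 32, 52)
  expect_equal(dbl$chi2, 2 * res$chi2, tolerance = 1e-12)

  yates <- chi_square_2x2(21, 15, 16, 26, yates = TRUE)
  expect_lt(yates$chi2, res$chi2)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})
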