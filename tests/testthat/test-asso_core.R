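test_that("the association index follows C(N,2) - K", {
  expect_equal(asso_index(0, 0), 0)
  expect_equal(asso_index(4, 6), 0)      # 4-clique neighborhood
  expect_equal(asso_index(5, 2), 8)      # (20 - 4) / 2
  expect_equal(asso_index(c(3, 10), c(0, 45)), c(3, 0))
  expect_error(asso_index(3, 4), "exceeds")
})

test_that("identical-signal cliques give zero association everywhere", {
  set.seed(1)
  s <- rnorm(100)
  b <- series_bold(matrix(s, 100, 5))
  mask <- first_voxels_mask(5)
  res <- compute_asso_map(b, mask)
  expect_equal(res$counts$n, rep(4, 5))
  expect_equal(res$counts$k, rep(6, 5))
  expect_true(all(res$map$values[mask] == 0))
  fcs <- compute_fcs_map(b, mask)
  expect_true(all(fcs$values[mask] == 4))
})

test_that("a star hub mediates all its leaf pairs", {
  set.seed(42)
  s <- rnorm(400)
  leaves <- sapply(1:4, function(i) s + 2.2 * rnorm(400))
  series <- cbind(s, leaves)
  # verify the construction actually realises leaf-leaf r < 0.25 < hub-leaf r
  r <- cor(series)
  expect_true(all(r[1, -1] > 0.25))
  off <- r[-1, -1][lower.tri(diag(4))]
  expect_true(all(off < 0.25))

  res <- compute_asso_map(series_bold(series), first_voxels_mask(5))
  expect_equal(res$counts$asso[1], 6)           # hub: C(4,2) open pairs
  expect_equal(res$counts$asso[-1], rep(0, 4))  # leaves: single neighbor
})

test_that("graph counts match the brute-force pair counter exactly", {
  set.seed(3)
  for (rep in 1:5) {
    v <- sample(20:60, 1)
    series <- matrix(rnorm(100 * v), 100, v)
    # add some planted structure so the graph is non-trivial
    comm <- rnorm(100)
    pick <- sample(v, ceiling(v / 3))
    series[, pick] <- series[, pick] + comm
    res <- compute_asso_map(series_bold(series), first_voxels_mask(v))
    oracle <- brute_force_asso(series_adjacency(series))
    expect_identical(res$counts$n, oracle$n)
    expect_identical(res$counts$k + 0, oracle$k + 0)
    expect_identical(res$counts$asso, oracle$asso)
  }
})

test_that("association never exceeds the degree-pair bound and respects edges", {
  set.seed(4)
  series <- matrix(rnorm(100 * 40), 100, 40) + rnorm(100) * 0.6
  b <- series_bold(series)
  mask <- first_voxels_mask(40)
  g <- voxel_graph(b, mask)
  res <- compute_asso_map(b, mask, graph = g)
  fcs <- compute_fcs_map(b, mask, graph = g)
  n <- fcs$values[mask]
  expect_true(all(res$map$values[mask] <= n * (n - 1) / 2))

  # adding one edge between two unconnected neighbors of i lowers asso_i by 1
  adj <- g$adjacency
  found <- FALSE
  for (i in seq_len(nrow(adj))) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) next
    pairs <- which(!adj[nb, nb] & upper.tri(diag(length(nb))), arr.ind = TRUE)
    if (!nrow(pairs)) next
    j <- nb[pairs[1, 1]]; k <- nb[pairs[1, 2]]
    adj2 <- adj; adj2[j, k] <- adj2[k, j] <- TRUE
    before <- asso_counts_from_adjacency(adj)
    after <- asso_counts_from_adjacency(adj2)
    expect_equal(after$asso[i], before$asso[i] - 1)
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("association counts are invariant under voxel relabeling", {
  set.seed(5)
  series <- matrix(rnorm(80 * 30), 80, 30) + rnorm(80) * 0.5
  adj <- series_adjacency(series)
  perm <- sample(30)
  a <- asso_counts_from_adjacency(adj)
  b <- asso_counts_from_adjacency(adj[perm, perm])
  expect_equal(b$asso, a$asso[perm])
  expect_true(all(adj == t(adj)))
})

test_that("a graph with no suprathreshold pair yields all-zero maps", {
  set.seed(6)
  series <- matrix(rnorm(200 * 10), 200, 10)
  b <- series_bold(series)
  mask <- first_voxels_mask(10)
  res <- compute_asso_map(b, mask, r_threshold = 0.9999)
  fcs <- compute_fcs_map(b, mask, r_threshold = 0.9999)
  expect_true(all(res$map$values == 0))
  expect_true(all(fcs$values == 0))
})

test_that("constant series are treated as never connected", {
  set.seed(7)
  series <- cbind(matrix(rnorm(300), 100, 3), 5)
  b <- series_bold(series)
  expect_message(res <- compute_asso_map(b, first_voxels_mask(4)),
                 "constant")
  expect_equal(res$counts$n[4], 0)
  expect_equal(res$counts$asso[4], 0)
})

test_that("z-scoring standardizes in-mask values and is affine-equivariant", {
  set.seed(8)
  aff <- fixture_affine()
  mask <- array(TRUE, c(5, 5, 5)); mask[1, 1, 1] <- FALSE
  vals <- array(rexp(125), c(5, 5, 5))
  m <- voxel_map(vals, aff, "asso", mask)
  z <- zscore_map(m)
  expect_equal(mean(z$values[mask]), 0, tolerance = 1e-12)
  expect_equal(sd(z$values[mask]), 1, tolerance = 1e-12)
  expect_equal(z$kind, "asso_z")

  m2 <- voxel_map(3 * vals + 7, aff, "asso", mask)
  expect_equal(zscore_map(m2)$values, z$values, tolerance = 1e-12)
  m3 <- voxel_map(-2 * vals + 1, aff, "asso", mask)
  expect_equal(zscore_map(m3)$values[mask], -z$values[mask],
               tolerance = 1e-12)
  flat <- voxel_map(array(1, c(5, 5, 5)), aff, "asso", mask)
  expect_error(zscore_map(flat), "variance")
})

test_that("Gaussian smoothing preserves mass, peaks correctly, and keeps constants", {
  aff <- fixture_affine()
  dims <- c(15, 15, 15)
  imp <- array(0, dims); imp[8, 8, 8] <- 1
  m <- voxel_map(imp, aff, "asso_z")
  expect_identical(smooth_map(m, 0)$values, m$values)
  expect_error(smooth_map(m, -1), "fwhm")

  sm <- smooth_map(m, 6, boundary = "zero")
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  # peak of the separable kernel: product of per-axis discrete maxima,
  # close to the continuous normalisation (2*pi*sigma^2)^(-3/2) * vol
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sm$values[8, 8, 8], (2 * pi * sigma ^ 2) ^ (-3 / 2),
               tolerance = 0.05)
  expect_lt(sm$values[8, 8, 8], max(m$values))

  const <- voxel_map(array(4, dims), aff, "asso_z")
  expect_equal(smooth_map(const, 6, boundary = "nearest")$values,
               const$values, tolerance = 1e-12)
})
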