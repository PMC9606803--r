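test_that("initial volumes are dropped together with their motion rows", {
  b <- bold_dataset(array(seq_len(2 * 2 * 2 * 240), c(2, 2, 2, 240)), 2,
                    fixture_affine())
  motion <- matrix(seq_len(240 * 6), 240, 6)
  out <- drop_initial_volumes(b, 10, motion)
  expect_equal(dim(out$bold$data)[4], 230)
  expect_equal(nrow(out$motion), 230)
  expect_equal(out$motion[1, 1], motion[11, 1])
  expect_identical(drop_initial_volumes(b, 0)$data, b$data)
  b10 <- bold_dataset(array(1, c(2, 2, 2, 10)), 2, fixture_affine())
  expect_error(drop_initial_volumes(b10, 10), "cannot drop")
})

test_that("framewise displacement follows the 50 mm sphere convention", {
  zero <- matrix(0, 10, 6)
  expect_equal(compute_fd(zero), rep(0, 10))

  m <- zero; m[5:10, 1] <- 0.5  # one 0.5 mm translation step
  fd <- compute_fd(m)
  expect_equal(fd[5], 0.5)
  expect_equal(fd[-5], rep(0, 9))

  m <- zero; m[5:10, 4] <- 0.01  # one 0.01 rad rotation step
  expect_equal(compute_fd(m)[5], 0.5)
  expect_equal(compute_fd(m, rotation_radius_mm = 100)[5], 1.0)
})

test_that("Friston-24 expansion has the documented lag and square structure", {
  zero <- matrix(0, 8, 6)
  expect_equal(friston24_expand(zero), matrix(0, 8, 24),
               ignore_attr = TRUE)

  const <- matrix(2, 8, 6)
  f <- friston24_expand(const)
  expect_equal(unname(f[1, 7:12]), rep(0, 6))     # lag backfilled with 0
  expect_equal(unname(f[2, 7:12]), rep(2, 6))
  expect_equal(unname(f[, 13:18]), matrix(4, 8, 6))

  set.seed(2)
  m <- matrix(rnorm(120 * 6), 120, 6)
  f <- friston24_expand(m)
  expect_equal(unname(f[2:120, 7:12]), unname(m[1:119, ]))  # exact 1-frame lag
  expect_equal(unname(f[, 19:24]), unname(rbind(0, m[-120, ]) ^ 2))
})

test_that("nuisance matrix holds Friston-24 plus three tissue means", {
  g <- c(4, 4, 4)
  brain <- array(TRUE, g)
  wm <- array(FALSE, g); wm[1, 1, 1:2] <- TRUE
  csf <- array(FALSE, g); csf[4, 4, 3] <- TRUE
  masks <- tissue_masks(brain, wm, csf)
  set.seed(3)
  b <- bold_dataset(array(rnorm(prod(g) * 30), c(g, 30)), 2,
                    fixture_affine())
  motion <- matrix(rnorm(180, sd = 0.01), 30, 6)

  nm <- build_nuisance_matrix(b, masks, motion)
  expect_equal(ncol(nm), 27)
  flat <- matrix(b$data, prod(g), 30)
  expect_equal(unname(nm[, "global_mean"]), unname(colMeans(flat)))
  expect_equal(unname(nm[, "wm_mean"]),
               unname(colMeans(flat[which(wm), ])))

  ones <- bold_dataset(array(1, c(g, 30)), 2, fixture_affine())
  nm1 <- build_nuisance_matrix(ones, masks, motion)
  expect_equal(unname(nm1[, "wm_mean"]), rep(1, 30))
  expect_equal(ncol(build_nuisance_matrix(b, masks, motion,
                                          global_signal = FALSE)), 26)
  empty <- masks; empty$csf[] <- FALSE
  expect_error(build_nuisance_matrix(b, empty, motion), "empty csf")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  tt <- seq_len(200)
  tr <- 2
  amp_after <- function(freq, type) {
    x <- sin(2 * pi * freq * tr * tt)
    b <- series_bold(matrix(c(x, rnorm(200)), 200, 2))
    out <- detrend_filter_regress(b, NULL, tr = tr, filter_type = type)
    y <- matrix(out$data, 2, 200)[1, ]
    # amplitude recovered by regressing the output on the known sinusoid
    unname(coef(lm(y ~ sin(2 * pi * freq * tr * tt)))[2])
  }
  for (type in c("butterworth", "fft")) {
    expect_gt(amp_after(0.05, type), 0.9)
    expect_lt(abs(amp_after(0.2, type)), 0.1)
  }
  const <- series_bold(matrix(5, 100, 1))
  out <- detrend_filter_regress(const, NULL, tr = tr)
  expect_lt(max(abs(out$data)), 1e-8)
  expect_error(detrend_filter_regress(const, NULL, tr = 2,
                                      band = c(0.01, 0.3)), "Nyquist")
})

test_that("ideal-filter band-pass is idempotent and the IIR path matches the reference filter", {
  set.seed(4)
  y <- matrix(rnorm(300), 100, 3)
  once <- assomap:::bandpass_matrix(y, 2, c(0.01, 0.1), "fft")
  twice <- assomap:::bandpass_matrix(once, 2, c(0.01, 0.1), "fft")
  expect_equal(twice, once, tolerance = 1e-6)

  # the vectorized IIR recursion agrees with signal::filter on one series
  bf <- signal::butter(2, c(0.01, 0.1) / 0.25, type = "pass")
  x <- rnorm(150)
  mine <- assomap:::iir_filter_matrix(bf$b, bf$a, matrix(x, ncol = 1))
  ref <- as.numeric(signal::filter(bf, x))
  expect_equal(as.numeric(mine), ref, tolerance = 1e-10)
})

test_that("regression residuals are orthogonal to retained nuisance columns", {
  set.seed(5)
  tlen <- 120
  y <- matrix(rnorm(tlen * 5), tlen, 5)
  nuis <- matrix(rnorm(tlen * 4), tlen, 4)
  colnames(nuis) <- paste0("n", 1:4)
  b <- series_bold(y)
  # band = NULL isolates detrending + regression from the band-pass
  out <- detrend_filter_regress(b, nuis, tr = 2, band = NULL)
  res <- t(matrix(out$data, 5, tlen))
  ip <- crossprod(stats::lm.fit(cbind(1, seq_len(tlen)),
                                nuis)$residuals, res)
  expect_lt(max(abs(ip)) / tlen, 1e-6)
})

test_that("collinear nuisance columns are dropped with a warning", {
  set.seed(6)
  y <- matrix(rnorm(200), 100, 2)
  nuis <- cbind(a = rnorm(100), b = rnorm(100))
  nuis <- cbind(nuis, c = nuis[, 1] + nuis[, 2])
  colnames(nuis) <- c("a", "b", "c")
  b <- series_bold(y)
  expect_warning(detrend_filter_regress(b, nuis, tr = 2),
                 "collinear")
})

test_that("scrub flagging expands the window and interpolates linearly", {
  fd <- c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  plan <- scrub_plan(fd, 0.5, 2, 1)
  expect_identical(which(plan$flagged), 1:4)  # frames 0-3 in 0-based terms

  set.seed(7)
  y <- matrix(rnorm(8 * 3), 8, 3)
  b <- series_bold(y)

  clean_plan <- scrub_plan(rep(0.1, 8), 0.5, 2, 1)
  expect_identical(scrub_interpolate(b, clean_plan)$data, b$data)

  # interior single flagged frame -> midpoint of its neighbours
  mid_plan <- scrub_plan(c(0, 0, 0, 0, 0, 0, 0, 0), 0.5, 0, 0)
  mid_plan$flagged[5] <- TRUE
  out <- scrub_interpolate(b, mid_plan)
  got <- t(matrix(out$data, 3, 8))
  expect_equal(got[5, ], (y[4, ] + y[6, ]) / 2)
  expect_equal(got[-5, ], y[-5, ])

  # leading flagged run takes the nearest unflagged value
  lead <- scrub_plan(c(0.9, 0, 0, 0, 0, 0, 0, 0), 0.5, 2, 1)
  out2 <- scrub_interpolate(b, lead)
  got2 <- t(matrix(out2$data, 3, 8))
  expect_equal(got2[1, ], y[3, ])
  expect_equal(got2[2, ], y[3, ])

  # idempotence under the same plan
  expect_identical(scrub_interpolate(out, mid_plan)$data, out$data)

  all_bad <- scrub_plan(rep(1, 8), 0.5, 2, 1)
  expect_error(scrub_interpolate(b, all_bad), "unflagged")
})

test_that("excessive-motion exclusion triggers above one voxel of travel", {
  m <- matrix(0, 10, 6)
  expect_false(excessive_motion(m, c(3, 3, 3)))
  m[5, 2] <- 3.5
  expect_true(excessive_motion(m, c(3, 3, 3)))
  m2 <- matrix(0, 10, 6); m2[5, 5] <- 0.08  # 0.08 rad * 50 mm = 4 mm
  expect_true(excessive_motion(m2, c(3, 3, 3)))
})
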