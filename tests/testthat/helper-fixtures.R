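# Shared fixture builders and independent oracles.

fixture_affine <- function(vox = 3, origin = -16.5) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

# bold dataset whose in-mask voxels carry the given T x V series matrix;
# everything else is zero
series_bold <- function(series, dims = NULL, tr = 2, affine = NULL) {
  v <- ncol(series)
  if (is.null(dims)) dims <- c(v, 1, 1)
  if (is.null(affine)) affine <- fixture_affine()
  arr <- array(0, c(dims, nrow(series)))
  flat <- matrix(arr, prod(dims), nrow(series))
  flat[seq_len(v), ] <- t(series)
  arr[] <- flat
  bold_dataset(arr, tr, affine, "fixture")
}

first_voxels_mask <- function(v, dims = c(v, 1, 1)) {
  m <- array(FALSE, dims)
  m[seq_len(v)] <- TRUE
  m
}

# brute-force association counts: explicit loop over neighbor pairs
brute_force_asso <- function(adjacency) {
  a <- adjacency != 0
  diag(a) <- FALSE
  v <- nrow(a)
  out <- data.frame(n = numeric(v), k = numeric(v), asso = numeric(v))
  for (i in seq_len(v)) {
    nb <- which(a[i, ])
    k <- 0L
    if (length(nb) >= 2L)
      for (p in seq_len(length(nb) - 1L))
        for (q in (p + 1L):length(nb))
          if (a[nb[p], nb[q]]) k <- k + 1L
    out$n[i] <- length(nb)
    out$k[i] <- k
    out$asso[i] <- length(nb) * (length(nb) - 1) / 2 - k
  }
  out
}

# thresholded adjacency straight from a series matrix (T x V)
series_adjacency <- function(series, r_threshold = 0.25) {
  r <- stats::cor(series)
  adj <- r > r_threshold
  diag(adj) <- FALSE
  adj
}

# small phenotype table with valid structure
make_phenotypes <- function(n_ad = 5, n_hc = 5, seed = 1) {
  set.seed(seed)
  n <- n_ad + n_hc
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = c(rep("AD", n_ad), rep("HC", n_hc)),
    age = round(rnorm(n, 67, 7), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = round(rnorm(n, 11, 3), 1),
    mmse = as.integer(round(c(rnorm(n_ad, 21, 3), rnorm(n_hc, 28, 1.4)))),
    moca = as.integer(round(c(rnorm(n_ad, 17, 3), rnorm(n_hc, 27, 2)))),
    stringsAsFactors = FALSE)
}
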