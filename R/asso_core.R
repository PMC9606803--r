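#' Association index from neighbor counts
#'
#' For a voxel with `N` supra-threshold neighbors of which `K` pairs are
#' directly interconnected, the association index is
#' \deqn{Asso = (N(N-1) - 2K)/2 = C(N,2) - K,}
#' the number of neighbor pairs *not* directly connected — pairs for which
#' the voxel is a potential mediator. A hub whose neighbors only communicate
#' through it has `K = 0` and maximal Asso; a clique member has
#' `K = C(N,2)` and Asso 0.
#'
#' @param n_neighbors Integer vector `N` >= 0.
#' @param k_edges Integer vector `K`, with `0 <= K <= C(N,2)`.
#' @return Numeric vector of association indices (integer-valued).
#' @export
asso_index <- function(n_neighbors, k_edges) {
  n <- as.numeric(n_neighbors); k <- as.numeric(k_edges)
  if (any(n < 0) || any(k < 0)) stop("counts must be >= 0", call. = FALSE)
  cmax <- n * (n - 1) / 2
  if (any(k > cmax))
    stop("K exceeds C(N,2): K = ", k[which(k > cmax)[1]], ", N = ",
         n[which(k > cmax)[1]], call. = FALSE)
  cmax - k
}

#' Neighbor and interconnection counts from an adjacency matrix
#'
#' @param adjacency Symmetric logical (or 0/1) matrix; the diagonal is
#'   ignored (self-connections never count).
#' @param block_size Number of columns per block in the triangle-counting
#'   matrix product, bounding memory on large graphs.
#' @return data.frame with columns `n` (degree), `k` (edges among the
#'   voxel's neighbors) and `asso`.
#' @export
asso_counts_from_adjacency <- function(adjacency, block_size = 1024L) {
  a <- matrix(as.numeric(adjacency != 0), nrow(adjacency))
  if (any(a != t(a)))
    stop("adjacency must be symmetric", call. = FALSE)
  diag(a) <- 0
  v <- nrow(a)
  n <- .rowSums(a, v, v)
  if (block_size >= v) {
    k2 <- .rowSums(crossprod(a) * a, v, v)
  } else {
    k2 <- numeric(v)  # twice K: ordered supra-threshold neighbor pairs
    for (start in seq(1L, v, by = block_size)) {
      j <- start:min(v, start + block_size - 1L)
      m <- a %*% a[, j, drop = FALSE]
      k2 <- k2 + .rowSums(m * a[, j, drop = FALSE], v, length(j))
    }
  }
  k <- k2 / 2
  data.frame(n = n, k = k, asso = asso_index(n, k))
}

#' Thresholded whole-brain voxel graph
#'
#' Builds the undirected graph over in-mask voxels with an edge wherever the
#' Pearson correlation of the two series exceeds the threshold. The test is
#' on the *signed* correlation by default (`r > threshold`); set
#' `use_absolute = TRUE` to threshold `|r|`. Constant (zero-variance) series
#' have undefined correlation and are treated as never connected; their
#' count is reported via a message.
#'
#' @param bold A [bold_dataset()] of preprocessed series.
#' @param mask Logical 3-D analysis mask (>= 3 voxels).
#' @param r_threshold Correlation threshold (default 0.25).
#' @param use_absolute Threshold on `|r|` instead of signed `r`.
#' @return List of class `voxel_graph`: `adjacency` (logical V x V),
#'   `voxels` (linear indices of in-mask voxels), `dims`, `affine`, `mask`.
#' @export
voxel_graph <- function(bold, mask, r_threshold = 0.25,
                        use_absolute = FALSE) {
  stopifnot(inherits(bold, "bold_dataset"))
  d <- dim(bold$data)
  mask <- array(as.logical(mask), d[1:3])
  vox <- which(as.vector(mask))
  if (length(vox) < 3L) stop("need >= 3 in-mask voxels", call. = FALSE)
  y <- t(matrix(bold$data, prod(d[1:3]), d[4L])[vox, , drop = FALSE])
  sds <- apply(y, 2L, stats::sd)
  n_const <- sum(sds < 1e-12)
  if (n_const > 0)
    message(n_const,
            " constant in-mask series treated as never connected")
  z <- sweep(y, 2L, colMeans(y))
  z <- sweep(z, 2L, ifelse(sds < 1e-12, 1, sds), "/")
  z[, sds < 1e-12] <- 0
  r <- crossprod(z) / (nrow(y) - 1)
  adj <- if (use_absolute) abs(r) > r_threshold else r > r_threshold
  diag(adj) <- FALSE
  structure(list(adjacency = adj, voxels = vox, dims = d[1:3],
                 affine = bold$affine, mask = mask),
            class = "voxel_graph")
}

#' Per-voxel association index map
#'
#' Computes the thresholded voxel graph (unless one is supplied) and, for
#' each in-mask voxel, its degree `N`, the number `K` of edges among its
#' neighbors, and the association index `C(N,2) - K`.
#'
#' @inheritParams voxel_graph
#' @param graph Optional precomputed [voxel_graph()] (saves recomputation
#'   when both Asso and degree maps are needed).
#' @param block_size Passed to [asso_counts_from_adjacency()].
#' @return List with `map` (a [voxel_map()] of kind `"asso"`) and `counts`
#'   (the per-voxel data.frame with linear voxel indices attached).
#' @export
compute_asso_map <- function(bold, mask, r_threshold = 0.25,
                             use_absolute = FALSE, graph = NULL,
                             block_size = 1024L) {
  if (is.null(graph)) graph <- voxel_graph(bold, mask, r_threshold,
                                           use_absolute)
  counts <- asso_counts_from_adjacency(graph$adjacency, block_size)
  counts$voxel <- graph$voxels
  vals <- array(0, graph$dims)
  vals[graph$voxels] <- counts$asso
  list(map = voxel_map(vals, graph$affine, "asso", graph$mask),
       counts = counts)
}

#' Per-voxel degree-centrality (functional connectivity strength) map
#'
#' Degree centrality counts only a voxel's supra-threshold connections and
#' ignores whether those neighbors are themselves interconnected — the
#' quantity the association index refines.
#'
#' @inheritParams compute_asso_map
#' @return A [voxel_map()] of kind `"fcs"` holding `N` per voxel.
#' @export
compute_fcs_map <- function(bold, mask, r_threshold = 0.25,
                            use_absolute = FALSE, graph = NULL) {
  if (is.null(graph)) graph <- voxel_graph(bold, mask, r_threshold,
                                           use_absolute)
  n <- .rowSums(graph$adjacency, nrow(graph$adjacency),
                ncol(graph$adjacency))
  vals <- array(0, graph$dims)
  vals[graph$voxels] <- n
  voxel_map(vals, graph$affine, "fcs", graph$mask)
}

#' Z-score a map within its mask
#'
#' Subtracts the in-mask mean and divides by the in-mask SD, improving
#' normality for group statistics. Out-of-mask voxels are untouched.
#'
#' @param map A [voxel_map()].
#' @param mask Logical mask (defaults to the map's own).
#' @return A [voxel_map()]; kind `"asso"` becomes `"asso_z"`, `"fcs"`
#'   becomes `"fc_z"`.
#' @export
zscore_map <- function(map, mask = NULL) {
  stopifnot(inherits(map, "voxel_map"))
  if (is.null(mask)) mask <- map$mask
  v <- map$values[mask]
  if (length(v) < 2L) stop("need >= 2 in-mask voxels", call. = FALSE)
  s <- stats::sd(v)
  if (s < 1e-300) stop("zero variance inside mask", call. = FALSE)
  out <- map$values
  out[mask] <- (v - mean(v)) / s
  kind <- switch(map$kind, asso = "asso_z", fcs = "fc_z", map$kind)
  voxel_map(out, map$affine, kind, mask)
}

# per-axis discrete Gaussian smoothing matrix (n x n)
smoothing_matrix <- function(n, sigma_vox, boundary) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma_vox))
  kern <- exp(-((-r):r) ^ 2 / (2 * sigma_vox ^ 2))
  kern <- kern / sum(kern)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- (i - r):(i + r)
    if (boundary == "nearest") {
      tgt <- pmin(pmax(src, 1L), n)
      for (s in seq_along(src)) w[i, tgt[s]] <- w[i, tgt[s]] + kern[s]
    } else {
      keep <- src >= 1L & src <= n
      w[i, src[keep]] <- kern[keep]
    }
  }
  w
}

smooth_array3d <- function(x, sigma_vox, boundary) {
  d <- dim(x)
  for (ax in 1:3) {
    w <- smoothing_matrix(d[ax], sigma_vox[ax], boundary)
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    xp <- array(w %*% matrix(xp, d[ax]), dim(xp))
    x <- aperm(xp, order(perm))
  }
  x
}

#' Gaussian smoothing of a scalar map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, in voxel units derived from the affine. The whole array (including
#' out-of-mask zeros) is smoothed and then re-masked.
#'
#' @param map A [voxel_map()].
#' @param fwhm_mm Full width at half maximum in mm (default 6; 0 = identity).
#' @param boundary `"nearest"` (edge value extension; preserves constants,
#'   default) or `"zero"` (zero padding; preserves total mass).
#' @return The smoothed [voxel_map()].
#' @export
smooth_map <- function(map, fwhm_mm = 6, boundary = c("nearest", "zero")) {
  stopifnot(inherits(map, "voxel_map"))
  boundary <- match.arg(boundary)
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(map)
  vsize <- sqrt(colSums(map$affine[1:3, 1:3] ^ 2))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vsize
  out <- smooth_array3d(map$values, sigma, boundary)
  voxel_map(out, map$affine, map$kind, map$mask)
}

#' Gaussian smoothing of every volume of a BOLD series
#'
#' @param bold A [bold_dataset()].
#' @param fwhm_mm FWHM in mm.
#' @param boundary As in [smooth_map()].
#' @return The smoothed [bold_dataset()].
#' @export
smooth_bold <- function(bold, fwhm_mm = 6, boundary = "nearest") {
  stopifnot(inherits(bold, "bold_dataset"))
  if (fwhm_mm == 0) return(bold)
  d <- dim(bold$data)
  vsize <- sqrt(colSums(bold$affine[1:3, 1:3] ^ 2))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vsize
  w <- lapply(1:3, function(ax) smoothing_matrix(d[ax], sigma[ax], boundary))
  out <- bold$data
  for (t in seq_len(d[4L])) {
    x <- out[, , , t]
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      xp <- aperm(x, perm)
      xp <- array(w[[ax]] %*% matrix(xp, d[ax]), dim(xp))
      x <- aperm(xp, order(perm))
    }
    out[, , , t] <- x
  }
  res <- bold
  res$data <- out
  res
}
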