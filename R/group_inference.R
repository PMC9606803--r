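#' Design matrix for covariate-adjusted group comparison
#'
#' Intercept, group indicator (AD = 1, HC = 0), and mean-centered age, sex
#' (M = 1, F = 0) and education. Centering the covariates affects only the
#' intercept, not the group t.
#'
#' @param phenotypes Phenotype data.frame (see [load_phenotypes()]).
#' @param covariates Character vector of covariate columns to adjust for.
#' @return n x p numeric design matrix with labelled columns.
#' @export
make_design <- function(phenotypes,
                        covariates = c("age", "sex", "education")) {
  x <- cbind(intercept = rep(1, nrow(phenotypes)),
             group = as.numeric(phenotypes$group == "AD"))
  if (stats::var(x[, "group"]) == 0)
    stop("group column is constant", call. = FALSE)
  for (cv in covariates) {
    col <- if (cv == "sex") as.numeric(phenotypes$sex == "M") else
      phenotypes[[cv]]
    x <- cbind(x, scale(col, scale = FALSE))
    colnames(x)[ncol(x)] <- cv
  }
  if (qr(x)$rank < ncol(x)) {
    qrx <- qr(x)
    bad <- colnames(x)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

# core vectorized GLM group-t over columns of y (n x V); returns t vector
glm_group_t <- function(y, design, group_col = "group") {
  n <- nrow(design); p <- ncol(design)
  g <- match(group_col, colnames(design))
  xtx_inv <- chol2inv(chol(crossprod(design)))
  beta <- xtx_inv %*% crossprod(design, y)
  resid <- y - design %*% beta
  sigma2 <- .colSums(resid ^ 2, n, ncol(y)) / (n - p)
  beta[g, ] / sqrt(sigma2 * xtx_inv[g, g])
}

#' Voxelwise two-sample t-test with covariates (GLM)
#'
#' Fits, per voxel, an ordinary-least-squares model of the subject maps on
#' the design matrix and returns the t statistic for the group coefficient
#' (positive t = AD > HC under the default coding). Reduces to the classical
#' pooled two-sample t when the design holds only intercept and group.
#'
#' @param maps List of per-subject [voxel_map()]s (one per design row), or
#'   an n x V matrix of in-mask values.
#' @param design Design matrix from [make_design()].
#' @param mask Logical 3-D mask (required with a matrix input only to shape
#'   the output; defaults to the first map's mask).
#' @return List of class `stat_map`: `map` (a [voxel_map()] of kind `"t"`),
#'   `df` (n - p), `contrast`.
#' @export
voxelwise_glm_ttest <- function(maps, design, mask = NULL) {
  if (is.list(maps)) {
    if (is.null(mask)) mask <- maps[[1]]$mask
    affine <- maps[[1]]$affine
    y <- t(vapply(maps, function(m) m$values[mask],
                  numeric(sum(mask))))
  } else {
    if (is.null(mask)) stop("mask required with matrix input", call. = FALSE)
    affine <- attr(maps, "affine")
    if (is.null(affine)) affine <- diag(4)
    y <- maps
  }
  if (nrow(y) != nrow(design))
    stop("one map per design row required: ", nrow(y), " maps vs ",
         nrow(design), " rows", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(design)[qrd$pivot[-seq_len(qrd$rank)]],
               collapse = ", "), call. = FALSE)
  tvals <- glm_group_t(y, design)
  vals <- array(0, dim(mask))
  vals[mask] <- tvals
  structure(list(map = voxel_map(vals, affine, "t", mask),
                 df = nrow(y) - ncol(design),
                 contrast = "group: AD - HC"),
            class = "stat_map")
}

# 3-D connected-component labelling; connectivity 6, 18 or 26
label_components <- function(mask3d, connectivity = 18) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask3d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(offs))
  offs <- offs[dist > 0 & dist <= switch(as.character(connectivity),
                                         "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, d)
  vox <- which(mask3d)
  nextlab <- 0L
  for (v in vox) {
    if (labels[v] != 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    labels[v] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      nb <- sweep(offs, 2L, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[mask3d[lin] & labels[lin] == 0L]
      labels[new] <- nextlab
      queue <- c(queue, new)
    }
  }
  labels
}

#' Extract suprathreshold clusters from a t map
#'
#' Thresholds `|t|` at the two-sided voxel-level p quantile, labels connected
#' components (positive and negative tails separately), and records extent,
#' peak t and peak mm coordinates via the affine.
#'
#' @param stat A `stat_map` from [voxelwise_glm_ttest()].
#' @param voxel_p Cluster-forming voxel-level p (default 0.001, two-sided).
#' @param two_sided Threshold `|t|` (default) or the positive tail only.
#' @param connectivity 6, 18 (default) or 26.
#' @return data.frame (possibly empty) with columns `cluster_id`, `sign`,
#'   `extent`, `peak_x`, `peak_y`, `peak_z` (mm), `peak_t`, plus the cluster
#'   label array as attribute `"labels"` (positive clusters coded by id,
#'   negative by -id).
#' @export
cluster_extract <- function(stat, voxel_p = 0.001, two_sided = TRUE,
                            connectivity = 18) {
  stopifnot(inherits(stat, "stat_map"))
  tcrit <- stats::qt(1 - (if (two_sided) voxel_p / 2 else voxel_p), stat$df)
  tvals <- stat$map$values
  mask <- stat$map$mask
  rows <- list()
  labarr <- array(0L, dim(tvals))
  id <- 0L
  signs <- if (two_sided) c(1, -1) else 1
  for (sgn in signs) {
    supra <- mask & (sgn * tvals > tcrit)
    if (!any(supra)) next
    labs <- label_components(supra, connectivity)
    for (l in seq_len(max(labs))) {
      vox <- which(labs == l)
      id <- id + 1L
      labarr[vox] <- sgn * id
      pk <- vox[which.max(sgn * tvals[vox])]
      mm <- voxel_to_mm(arrayInd(pk, dim(tvals)) - 1L, stat$map$affine)
      rows[[id]] <- data.frame(cluster_id = id, sign = sgn,
                               extent = length(vox),
                               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
                               peak_t = tvals[pk])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), sign = numeric(), extent = integer(),
               peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
               peak_t = numeric())
  attr(out, "labels") <- labarr
  attr(out, "t_critical") <- tcrit
  out
}

#' Permutation-based cluster-level correction
#'
#' Group labels are permuted (covariates stay with their subjects), the
#' voxelwise GLM t map and its suprathreshold clusters are rebuilt for each
#' permutation, and the maximum cluster extent over both tails forms the
#' null. Corrected p for an observed cluster is
#' `(1 + #\{perm max extent >= observed extent\}) / (n_perm + 1)`.
#'
#' @param maps List of per-subject [voxel_map()]s or an n x V matrix.
#' @param design Design matrix from [make_design()].
#' @param mask Logical 3-D mask (see [voxelwise_glm_ttest()]).
#' @param n_perm Number of Monte-Carlo permutations (>= 100).
#' @param voxel_p Cluster-forming voxel-level p (two-sided).
#' @param cluster_p Corrected significance level (default 0.05).
#' @param connectivity Cluster connectivity (default 18).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `cluster_correction`: `clusters` (the
#'   [cluster_extract()] table plus `p_corrected` and `significant`),
#'   `null_max_extent`, `stat` (the observed `stat_map`), `n_perm`.
#' @export
permutation_cluster_correction <- function(maps, design, mask = NULL,
                                           n_perm = 1000, voxel_p = 0.001,
                                           cluster_p = 0.05,
                                           connectivity = 18, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (1 / (n_perm + 1) >= cluster_p)
    warning("n_perm too small to resolve cluster_p = ", cluster_p,
            call. = FALSE)
  stat <- voxelwise_glm_ttest(maps, design, mask)
  obs <- cluster_extract(stat, voxel_p, TRUE, connectivity)

  if (is.list(maps)) {
    msk <- stat$map$mask
    y <- t(vapply(maps, function(m) m$values[msk], numeric(sum(msk))))
  } else {
    msk <- mask
    y <- maps
  }
  tcrit <- attr(obs, "t_critical")
  gcol <- match("group", colnames(design))
  set.seed(seed)
  null_max <- numeric(n_perm)
  dims <- dim(msk)
  for (b in seq_len(n_perm)) {
    xp <- design
    xp[, gcol] <- design[sample(nrow(design)), gcol]
    tv <- glm_group_t(y, xp)
    mx <- 0L
    for (sgn in c(1, -1)) {
      hit <- sgn * tv > tcrit
      if (!any(hit)) next
      supra <- array(FALSE, dims)
      supra[which(msk)[hit]] <- TRUE
      labs <- label_components(supra, connectivity)
      mx <- max(mx, tabulate(labs[labs > 0L]))
    }
    null_max[b] <- mx
  }
  if (nrow(obs)) {
    obs$p_corrected <- vapply(obs$extent, function(e)
      (1 + sum(null_max >= e)) / (n_perm + 1), numeric(1))
    obs$significant <- obs$p_corrected < cluster_p
  } else {
    obs$p_corrected <- numeric(0)
    obs$significant <- logical(0)
  }
  structure(list(clusters = obs, null_max_extent = null_max, stat = stat,
                 n_perm = n_perm),
            class = "cluster_correction")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' For demographic tables that report only means and SDs.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2, sd > 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df` (n1 + n2 - 2) and two-sided `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1 ^ 2 + (n2 - 1) * sd2 ^ 2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b First row counts (e.g. males/females in group 1).
#' @param c,d Second row counts.
#' @param yates Apply the Yates continuity correction (default FALSE).
#' @return List with `chi2`, `df` (1) and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table", call. = FALSE)
  res <- stats::chisq.test(tab, correct = yates)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
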