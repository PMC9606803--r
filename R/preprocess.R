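#' Discard initial volumes for magnetization equilibrium
#'
#' @param bold A [bold_dataset()].
#' @param n_drop Number of leading volumes to drop (default 10).
#' @param motion Optional T x 6 motion table, cropped identically.
#' @return The cropped [bold_dataset()]; if `motion` is supplied, a list
#'   with elements `bold` and `motion`.
#' @export
drop_initial_volumes <- function(bold, n_drop = 10, motion = NULL) {
  stopifnot(inherits(bold, "bold_dataset"))
  tlen <- dim(bold$data)[4L]
  if (n_drop < 0) stop("n_drop must be >= 0", call. = FALSE)
  if (tlen <= n_drop)
    stop("cannot drop ", n_drop, " volumes from a series of length ", tlen,
         call. = FALSE)
  out <- bold
  if (n_drop > 0) out$data <- bold$data[, , , -(seq_len(n_drop)),
                                        drop = FALSE]
  if (is.null(motion)) return(out)
  if (nrow(motion) != tlen)
    stop("length mismatch: motion table has ", nrow(motion),
         " rows but BOLD has ", tlen, " volumes", call. = FALSE)
  list(bold = out,
       motion = motion[if (n_drop > 0) -(seq_len(n_drop)) else TRUE, ,
                       drop = FALSE])
}

#' Framewise displacement (Power convention)
#'
#' FD for frame t is the sum of absolute frame-to-frame translation changes
#' plus the absolute rotation changes converted to arc length on a sphere.
#' The first frame has FD 0.
#'
#' @param motion T x 6 matrix: translations in mm, rotations in radians.
#' @param rotation_radius_mm Sphere radius converting radians to mm
#'   (default 50).
#' @return Numeric vector of length T, in mm.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("need at least 2 frames", call. = FALSE)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Friston-24 motion regressor expansion
#'
#' The six rigid-body parameters, their one-frame lags (first row backfilled
#' with 0), and the squares of both.
#'
#' @param motion T x 6 matrix.
#' @return T x 24 matrix with labelled columns.
#' @export
friston24_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns", call. = FALSE)
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion ^ 2, lagged ^ 2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Build the nuisance regressor matrix
#'
#' Columns are the Friston-24 motion expansion plus frame-wise mean signals
#' over the white-matter, CSF and whole-brain (global) masks: 27 columns.
#'
#' @param bold A [bold_dataset()].
#' @param masks A [tissue_masks()] on the same grid.
#' @param motion T x 6 motion table matching the BOLD t-dimension.
#' @param global_signal Include the global-mean column (default TRUE).
#' @return T x R labelled matrix (R = 27, or 26 without the global column).
#' @export
build_nuisance_matrix <- function(bold, masks, motion,
                                  global_signal = TRUE) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(masks, "tissue_masks"))
  d <- dim(bold$data)
  if (!all(d[1:3] == dim(masks$brain)))
    stop("mask grid does not match BOLD grid", call. = FALSE)
  if (nrow(motion) != d[4L])
    stop("motion rows do not match BOLD frames", call. = FALSE)
  flat <- matrix(bold$data, prod(d[1:3]), d[4L])
  mean_over <- function(mask, label) {
    if (!any(mask)) stop("empty ", label, " mask", call. = FALSE)
    colMeans(flat[as.vector(mask), , drop = FALSE])
  }
  tissue <- cbind(wm_mean = mean_over(masks$wm, "wm"),
                  csf_mean = mean_over(masks$csf, "csf"))
  if (global_signal)
    tissue <- cbind(tissue, global_mean = mean_over(masks$brain, "brain"))
  cbind(friston24_expand(motion), tissue)
}

# IIR filter (direct form II transposed), applied to every column of x at
# once; equivalent to signal::filter(b, a, x[, j]) per column.
iir_filter_matrix <- function(b, a, x) {
  ns <- max(length(b), length(a)) - 1L
  b <- c(b, rep(0, ns + 1L - length(b)))
  a <- c(a, rep(0, ns + 1L - length(a)))
  v <- ncol(x)
  z <- matrix(0, ns, v)
  y <- x
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (ns > 1L)
      for (k in seq_len(ns - 1L))
        z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
    z[ns, ] <- b[ns + 1L] * xt - a[ns + 1L] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase band-pass of the columns of y (T x V)
bandpass_matrix <- function(y, tr, band, filter_type = "butterworth") {
  tlen <- nrow(y)
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must lie within (0, Nyquist = ", signif(nyq, 4), " Hz)",
         call. = FALSE)
  if (filter_type == "fft") {
    freq <- (seq_len(tlen) - 1) / (tlen * tr)
    freq <- pmin(freq, 1 / tr - freq)  # two-sided spectrum
    keep <- freq >= band[1] & freq <= band[2]
    ft <- stats::mvfft(y)
    ft[!keep, ] <- 0
    return(Re(stats::mvfft(ft, inverse = TRUE)) / tlen)
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  # odd-reflection padding tames forward-backward edge transients on short
  # series, then filter forward and backward for zero phase
  pad <- min(tlen - 1L, 30L)
  yp <- rbind(2 * matrix(y[1, ], pad, ncol(y), byrow = TRUE) -
                y[(pad + 1):2, , drop = FALSE],
              y,
              2 * matrix(y[tlen, ], pad, ncol(y), byrow = TRUE) -
                y[(tlen - 1):(tlen - pad), , drop = FALSE])
  yf <- iir_filter_matrix(bf$b, bf$a, yp)
  yf <- iir_filter_matrix(bf$b, bf$a, yf[nrow(yf):1, , drop = FALSE])
  yf <- yf[nrow(yf):1, , drop = FALSE]
  yf[(pad + 1):(pad + tlen), , drop = FALSE]
}

#' Detrend, regress nuisance signals, and band-pass filter
#'
#' Per voxel: remove the linear trend, take the ordinary-least-squares
#' residual against the (detrended) nuisance columns, then apply a zero-phase
#' band-pass. The output is mean-zero per voxel. Collinear nuisance columns
#' are dropped with a warning.
#'
#' @param bold A [bold_dataset()].
#' @param nuisance T x R nuisance matrix (may be `NULL` to skip regression).
#' @param tr Repetition time in seconds (defaults to the dataset's).
#' @param band Pass band in Hz, default `c(0.01, 0.1)`; `NULL` skips the
#'   band-pass (detrend and regression only).
#' @param mask Optional logical 3-D array restricting computation; voxels
#'   outside are zeroed.
#' @param filter_type `"butterworth"` (order-2, forward-backward; default) or
#'   `"fft"` (ideal brick-wall filter).
#' @return A [bold_dataset()] of cleaned series.
#' @export
detrend_filter_regress <- function(bold, nuisance = NULL,
                                   tr = bold$tr_seconds,
                                   band = c(0.01, 0.1), mask = NULL,
                                   filter_type = c("butterworth", "fft")) {
  stopifnot(inherits(bold, "bold_dataset"))
  filter_type <- match.arg(filter_type)
  d <- dim(bold$data)
  flat <- matrix(bold$data, prod(d[1:3]), d[4L])
  vox <- if (is.null(mask)) seq_len(nrow(flat)) else which(as.vector(mask))
  y <- t(flat[vox, , drop = FALSE])  # T x V

  trend <- cbind(1, seq_len(d[4L]))
  y <- matrix(stats::lm.fit(trend, y)$residuals, d[4L])

  if (!is.null(nuisance)) {
    x <- matrix(stats::lm.fit(trend, as.matrix(nuisance))$residuals, d[4L])
    colnames(x) <- colnames(nuisance)
    keep <- apply(x, 2L, function(col) stats::sd(col) > 1e-12)
    x <- x[, keep, drop = FALSE]
    qrx <- qr(x)
    if (qrx$rank < ncol(x)) {
      drop_idx <- qrx$pivot[-seq_len(qrx$rank)]
      warning("dropping ", length(drop_idx), " collinear nuisance column(s): ",
              paste(colnames(x)[drop_idx], collapse = ", "), call. = FALSE)
      x <- x[, -drop_idx, drop = FALSE]
      qrx <- qr(x)
    }
    if (ncol(x) > 0) y <- matrix(qr.resid(qrx, y), d[4L])
  }

  if (!is.null(band)) y <- bandpass_matrix(y, tr, band, filter_type)
  y <- sweep(y, 2L, colMeans(y))

  out <- matrix(0, nrow(flat), d[4L])
  out[vox, ] <- t(y)
  res <- bold
  res$data <- array(out, d)
  res
}

#' Plan motion scrubbing from framewise displacement
#'
#' Frames with FD at or above the threshold are flagged, then the flagged set
#' is expanded by `n_before` frames before and `n_after` after each bad frame.
#'
#' @param fd Per-frame FD vector (mm), e.g. from [compute_fd()].
#' @param threshold FD threshold in mm (default 0.5; frames are kept only
#'   while FD stays below it).
#' @param n_before,n_after Expansion window around each bad frame
#'   (defaults 2 and 1).
#' @return List of class `scrub_plan` with `fd`, `flagged` (logical),
#'   `threshold`, `n_before`, `n_after`.
#' @export
scrub_plan <- function(fd, threshold = 0.5, n_before = 2, n_after = 1) {
  tlen <- length(fd)
  bad <- which(fd >= threshold)
  flagged <- rep(FALSE, tlen)
  for (b in bad)
    flagged[max(1L, b - n_before):min(tlen, b + n_after)] <- TRUE
  structure(list(fd = fd, flagged = flagged, threshold = threshold,
                 n_before = n_before, n_after = n_after),
            class = "scrub_plan")
}

#' Replace flagged frames by linear interpolation
#'
#' Flagged frames are replaced, per voxel, by linear interpolation between
#' the nearest unflagged neighbours; flagged runs at the start or end of the
#' series take the nearest unflagged value. The frame count is unchanged, so
#' downstream frequency-domain operations see an uninterrupted series.
#'
#' @param bold A [bold_dataset()].
#' @param plan A [scrub_plan()] whose length matches the t-dimension.
#' @return The scrubbed [bold_dataset()].
#' @export
scrub_interpolate <- function(bold, plan) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(plan, "scrub_plan"))
  d <- dim(bold$data)
  if (length(plan$flagged) != d[4L])
    stop("scrub plan length ", length(plan$flagged),
         " does not match BOLD frames ", d[4L], call. = FALSE)
  if (!any(plan$flagged)) return(bold)
  good <- which(!plan$flagged)
  if (length(good) < 2L) stop("fewer than 2 unflagged frames", call. = FALSE)
  flat <- matrix(bold$data, prod(d[1:3]), d[4L])
  for (f in which(plan$flagged)) {
    left <- good[good < f]
    right <- good[good > f]
    if (!length(left)) {
      flat[, f] <- flat[, right[1]]
    } else if (!length(right)) {
      flat[, f] <- flat[, left[length(left)]]
    } else {
      a <- left[length(left)]; b <- right[1]
      wgt <- (f - a) / (b - a)
      flat[, f] <- (1 - wgt) * flat[, a] + wgt * flat[, b]
    }
  }
  out <- bold
  out$data <- array(flat, d)
  out
}

#' Check the subject-level excessive-motion exclusion rule
#'
#' A subject moves "above one voxel" if any absolute translation exceeds the
#' smallest voxel size, or any absolute rotation converted to mm on the
#' 50 mm sphere does.
#'
#' @param motion T x 6 motion table.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param rotation_radius_mm Sphere radius for the rotation conversion.
#' @return `TRUE` if the subject should be excluded.
#' @export
excessive_motion <- function(motion, voxel_size_mm,
                             rotation_radius_mm = 50) {
  lim <- min(voxel_size_mm)
  max(abs(motion[, 1:3])) > lim ||
    max(abs(motion[, 4:6])) * rotation_radius_mm > lim
}

#' Full temporal preprocessing for one subject
#'
#' Pipeline order: drop initial volumes, build the scrub plan from FD on the
#' cropped motion, detrend + nuisance regression + band-pass, then replace
#' flagged frames by interpolation. Set `scrub_before_filter = TRUE` to
#' interpolate the raw series before filtering instead (sensitivity
#' analysis).
#'
#' @param bold A [bold_dataset()].
#' @param motion T x 6 motion table aligned with the raw series.
#' @param masks A [tissue_masks()].
#' @param n_drop Initial volumes to discard (default 10).
#' @param band Pass band in Hz.
#' @param fd_threshold FD flagging threshold in mm.
#' @param scrub_window `c(n_before, n_after)` expansion (default `c(2, 1)`).
#' @param global_signal Regress the global mean (default TRUE).
#' @param smooth_fwhm_mm If positive, smooth each volume with this Gaussian
#'   FWHM *before* the temporal steps (the seed-FC branch); 0 (default)
#'   leaves the series unsmoothed (the association-mapping branch).
#' @param scrub_before_filter Interpolate before detrend/filter instead of
#'   after.
#' @param filter_type Passed to [detrend_filter_regress()].
#' @return List with `bold` (cleaned series), `plan` (the [scrub_plan()]),
#'   `motion` (cropped), `excluded` (excessive-motion flag) and `n_flagged`.
#' @export
preprocess_subject <- function(bold, motion, masks, n_drop = 10,
                               band = c(0.01, 0.1), fd_threshold = 0.5,
                               scrub_window = c(2, 1), global_signal = TRUE,
                               smooth_fwhm_mm = 0,
                               scrub_before_filter = FALSE,
                               filter_type = "butterworth") {
  cropped <- drop_initial_volumes(bold, n_drop, motion)
  bold <- cropped$bold; motion <- cropped$motion
  fd <- compute_fd(motion)
  plan <- scrub_plan(fd, fd_threshold, scrub_window[1], scrub_window[2])
  excluded <- excessive_motion(motion,
                               sqrt(colSums(bold$affine[1:3, 1:3] ^ 2)))
  if (smooth_fwhm_mm > 0) bold <- smooth_bold(bold, smooth_fwhm_mm)
  if (scrub_before_filter) bold <- scrub_interpolate(bold, plan)
  nuis <- build_nuisance_matrix(bold, masks, motion, global_signal)
  clean <- detrend_filter_regress(bold, nuis, band = band,
                                  mask = masks$brain,
                                  filter_type = filter_type)
  if (!scrub_before_filter) clean <- scrub_interpolate(clean, plan)
  list(bold = clean, plan = plan, motion = motion, excluded = excluded,
       n_flagged = sum(plan$flagged))
}
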