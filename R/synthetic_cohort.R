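#' Configuration for the synthetic two-group cohort
#'
#' The generator emulates a resting-state study of two groups (patients,
#' labelled AD, and healthy controls, HC) whose BOLD series carry
#' community-structured correlations plus two planted group effects:
#'
#' * an *association* effect at a hub region, planted through two
#'   complementary mechanisms: in patients the hub-to-region coupling drops
#'   (`hub_coupling_ad < hub_coupling`), shrinking the hub's neighborhood,
#'   and the non-hub regions are additionally coupled to each other
#'   (`neighbor_coupling_ad > neighbor_coupling_hc`), directly
#'   interconnecting the hub's remaining neighbors — both lower the hub's
#'   association index;
#' * a *seed-FC* effect: patients share an extra latent signal between the hub
#'   and two default-mode-like regions (`seed_fc_gain_ad`), raising their
#'   hub-seeded functional connectivity there.
#'
#' Cognitive scores (MMSE/MoCA) are linear functions of each subject's
#' realized hub coupling — the parameter that drives that subject's hub
#' association index — plus noise, with group offsets matched to the
#' demographic targets, so brain-behavior correlations have a recoverable
#' within-sample signal.
#'
#' @param n_ad,n_hc Subjects per group (>= 2 each).
#' @param grid Grid dimensions, default `c(12, 12, 12)` at 3 mm isotropic.
#' @param t_frames Frames per run (default 120, TR 2 s).
#' @param tr_seconds Repetition time in seconds.
#' @param n_regions Number of 3x3x3 cuboid regions placed at the brain-mask
#'   corners (at most 8 on the default grid).
#' @param hub_region Index of the hub (pseudo-insula) region.
#' @param dmn_regions Two indices of the pseudo-PCC / pseudo-MPFC regions.
#' @param base_r Within-region voxel-voxel correlation level (at
#'   `noise_sd = 1`), before the global component.
#' @param hub_coupling Latent variance share tying every non-hub region
#'   signal to the hub signal, in the HC group.
#' @param hub_coupling_ad The same share in the AD group (lower by default:
#'   the disconnection effect).
#' @param global_amp Variance share of the brain-wide global signal added to
#'   every in-brain voxel (what global-signal regression removes).
#' @param neighbor_coupling_ad,neighbor_coupling_hc Shared-signal weight among
#'   non-hub regions per group; interconnects the hub's neighbors.
#' @param coupling_sd Between-subject SD of the realized hub coupling — the
#'   subject-level parameter that drives both the hub association index and
#'   the cognitive scores.
#' @param seed_fc_gain_ad Extra shared-signal weight between hub and the DMN
#'   regions in the AD group (0 in HC).
#' @param noise_sd Scale of the voxelwise temporal noise relative to the
#'   region signal.
#' @param ar1_phi AR(1) coefficient of all latent and noise series.
#' @param motion_spike_rate Per-frame probability of a head-motion spike.
#' @param spike_magnitude_mm Translation step at a spike (> 0.5 mm so the
#'   framewise displacement criterion is exercised).
#' @param cognitive_noise_sd SD of the residual noise on MMSE/MoCA.
#' @param demographics Named list of group means/SDs used for age, education
#'   and the cognitive score targets.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_ad = 20, n_hc = 20,
                          grid = c(12, 12, 12),
                          t_frames = 120, tr_seconds = 2,
                          n_regions = 8, hub_region = 1,
                          dmn_regions = c(2, 3),
                          base_r = 0.9,
                          hub_coupling = 0.25,
                          hub_coupling_ad = 0.02,
                          neighbor_coupling_ad = 0.15,
                          neighbor_coupling_hc = 0.02,
                          coupling_sd = 0.02,
                          seed_fc_gain_ad = 0.5,
                          global_amp = 0.3,
                          noise_sd = 1,
                          ar1_phi = 0.3,
                          motion_spike_rate = 0.05,
                          spike_magnitude_mm = 1,
                          cognitive_noise_sd = 1.5,
                          demographics = list(
                            age = list(ad = c(68.84, 7.84),
                                       hc = c(66.07, 6.79)),
                            education = list(ad = c(10.84, 3.11),
                                             hc = c(11.62, 3.32)),
                            mmse = list(ad = 21.3, hc = 28.24),
                            moca = list(ad = 16.92, hc = 26.95)),
                          seed = 1L) {
  cfg <- as.list(environment())
  cors <- c(base_r, hub_coupling, hub_coupling_ad, neighbor_coupling_ad,
            neighbor_coupling_hc, seed_fc_gain_ad, global_amp)
  if (any(cors < 0) || any(cors >= 1))
    stop("correlation levels must lie in [0, 1)", call. = FALSE)
  if (n_ad < 2 || n_hc < 2) stop("need >= 2 subjects per group",
                                 call. = FALSE)
  if (hub_region %in% dmn_regions)
    stop("hub_region must not be a DMN region", call. = FALSE)
  if (length(dmn_regions) != 2L)
    stop("dmn_regions must have length 2", call. = FALSE)
  if (max(hub_region, dmn_regions) > n_regions)
    stop("region index exceeds n_regions", call. = FALSE)
  if (n_regions < 3 || n_regions > 8)
    stop("n_regions must be 3..8: regions overflow grid corners",
         call. = FALSE)
  wmax <- max(hub_coupling, hub_coupling_ad) +
    max(neighbor_coupling_ad, neighbor_coupling_hc) +
    2 * coupling_sd + seed_fc_gain_ad
  if (wmax >= 1)
    stop("coupling weights sum to >= 1; reduce the coupling levels",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Region layout: brain mask is the interior cuboid (one-voxel shell removed),
# regions are disjoint 3x3x3 cuboids at the corners of the brain mask.
# Returns list(brain, labels, wm, csf); labels is 0 outside regions.
cohort_geometry <- function(cfg) {
  g <- cfg$grid
  if (any(g < 8)) stop("grid too small: regions overflow grid", call. = FALSE)
  brain <- array(FALSE, g)
  brain[2:(g[1] - 1), 2:(g[2] - 1), 2:(g[3] - 1)] <- TRUE
  starts <- expand.grid(x = c(2, g[1] - 3), y = c(2, g[2] - 3),
                        z = c(2, g[3] - 3))
  if (cfg$n_regions > nrow(starts))
    stop("regions overflow grid: at most ", nrow(starts),
         " corner regions available", call. = FALSE)
  labels <- array(0L, g)
  for (r in seq_len(cfg$n_regions)) {
    s <- as.integer(starts[r, ])
    labels[s[1]:(s[1] + 2), s[2]:(s[2] + 2), s[3]:(s[3] + 2)] <- r
  }
  # small WM/CSF blocks in the region-free central band
  mid <- pmax(floor(g / 2), 3L)
  wm <- array(FALSE, g)
  wm[(mid[1] - 1):mid[1], (mid[2] - 1):mid[2], (mid[3] - 1):mid[3]] <- TRUE
  csf <- array(FALSE, g)
  csf[mid[1] + 1, (mid[2] - 1):mid[2], (mid[3] - 1):mid[3]] <- TRUE
  wm <- wm & brain & labels == 0L
  csf <- csf & brain & labels == 0L
  list(brain = brain, labels = labels, wm = wm, csf = csf)
}

# Standardized stationary AR(1) series; x can be a T x n matrix of series.
ar1_series <- function(t_frames, phi, n = 1L) {
  innov <- matrix(stats::rnorm(t_frames * n, sd = sqrt(1 - phi ^ 2)),
                  t_frames, n)
  x <- stats::filter(innov, phi, method = "recursive")
  matrix(as.numeric(x), t_frames, n)
}

# Linear map from realized coupling to a cognitive score; degenerate
# (equal group couplings) falls back to the pooled target mean.
score_line <- function(c_hc, c_ad, target_hc, target_ad) {
  if (abs(c_ad - c_hc) < 1e-12)
    return(c(intercept = mean(c(target_hc, target_ad)), slope = 0))
  slope <- (target_ad - target_hc) / (c_ad - c_hc)
  c(intercept = target_hc - slope * c_hc, slope = slope)
}

#' Simulate rigid-body motion parameters with optional spikes
#'
#' Smooth low-amplitude sinusoidal drift plus small white jitter, with
#' Bernoulli displacement steps on a random translation axis that exceed the
#' 0.5 mm framewise-displacement criterion.
#'
#' @param t_frames Number of frames.
#' @param spike_rate Per-frame spike probability in `[0, 1)`.
#' @param spike_magnitude_mm Step size of a spike (must exceed 0.5 mm to be
#'   flagged by the scrubbing criterion).
#' @param seed Optional integer seed.
#' @return T x 6 matrix (tx, ty, tz in mm; rx, ry, rz in radians) with an
#'   attribute `spike_frames` listing the planted spike frames.
#' @export
simulate_motion <- function(t_frames, spike_rate = 0.05,
                            spike_magnitude_mm = 1, seed = NULL) {
  if (spike_rate < 0 || spike_rate >= 1)
    stop("spike_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq_len(t_frames)
  m <- matrix(0, t_frames, 6)
  for (j in 1:6) {
    amp <- stats::runif(1, 0.02, 0.08)
    freq <- stats::runif(1, 0.002, 0.01)
    drift <- amp * sin(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi))
    jitter <- stats::rnorm(t_frames, sd = 0.004)
    scale <- if (j > 3) 1 / 50 else 1  # rotations kept small in radians
    m[, j] <- (drift + jitter) * scale
  }
  spikes <- which(stats::rbinom(t_frames, 1, spike_rate) == 1L)
  spikes <- spikes[spikes > 1L]
  for (s in spikes) {
    axis <- sample(1:3, 1)
    m[s:t_frames, axis] <- m[s:t_frames, axis] +
      sample(c(-1, 1), 1) * spike_magnitude_mm
  }
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  attr(m, "spike_frames") <- spikes
  m
}

#' Simulate a two-group synthetic cohort
#'
#' See [cohort_config()] for the generative model. All randomness derives
#' from `cfg$seed`; the same configuration reproduces the cohort bit for bit.
#'
#' @param cfg A [cohort_config()].
#' @param null_cohort If `TRUE`, all group-difference parameters are forced
#'   to zero and group labels are assigned by random permutation (type-I
#'   error harness); see [simulate_null_cohort()].
#' @return Object of class `synthetic_cohort`: a list with `subjects` (each a
#'   list of `bold`, `motion`, `phenotype`), `region_labels` (integer 3-D
#'   array), `masks` (a [tissue_masks()]), `phenotypes` (data.frame),
#'   `affine`, `truth` (planted-effect descriptors) and `config`.
#' @export
simulate_cohort <- function(cfg, null_cohort = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  geo <- cohort_geometry(cfg)
  g <- cfg$grid
  affine <- diag(c(3, 3, 3, 1))
  affine[1:3, 4] <- -3 * (g - 1) / 2  # grid centred on the origin, mm
  n <- cfg$n_ad + cfg$n_hc
  groups <- c(rep("AD", cfg$n_ad), rep("HC", cfg$n_hc))
  if (null_cohort) groups <- sample(groups)

  c_ad <- if (null_cohort) cfg$neighbor_coupling_hc else
    cfg$neighbor_coupling_ad
  c_hc <- cfg$neighbor_coupling_hc
  g_ad <- if (null_cohort) 0 else cfg$seed_fc_gain_ad
  a_hc <- cfg$hub_coupling
  a_ad <- if (null_cohort) a_hc else cfg$hub_coupling_ad
  w <- cfg$base_r

  mmse_line <- score_line(a_hc, a_ad, cfg$demographics$mmse$hc,
                          cfg$demographics$mmse$ad)
  moca_line <- score_line(a_hc, a_ad, cfg$demographics$moca$hc,
                          cfg$demographics$moca$ad)

  nonhub <- setdiff(seq_len(cfg$n_regions), cfg$hub_region)
  region_voxels <- lapply(seq_len(cfg$n_regions),
                          function(r) which(geo$labels == r))
  background <- which(geo$brain & geo$labels == 0L)

  subjects <- vector("list", n)
  pheno <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- groups[i]
    c_grp <- if (grp == "AD") c_ad else c_hc
    gain <- if (grp == "AD") g_ad else 0
    a_grp <- if (grp == "AD") a_ad else a_hc
    # realized hub coupling: the subject-level association driver
    a_i <- max(0, min(a_grp + stats::rnorm(1, sd = cfg$coupling_sd),
                      0.95 - c_grp - gain))

    lat <- ar1_series(cfg$t_frames, cfg$ar1_phi, 4L + cfg$n_regions)
    H <- lat[, 1]; S <- lat[, 2]; D <- lat[, 3]; P <- lat[, 4]
    G <- lat[, -(1:4), drop = FALSE]
    h <- cfg$global_amp

    L <- matrix(0, cfg$t_frames, cfg$n_regions)
    L[, cfg$hub_region] <- sqrt(1 - gain) * H + sqrt(gain) * D
    for (r in nonhub) {
      extra <- if (r %in% cfg$dmn_regions) gain else 0
      L[, r] <- sqrt(a_i) * H + sqrt(c_grp) * S + sqrt(extra) * D +
        sqrt(1 - a_i - c_grp - extra) * G[, r]
    }

    vol <- array(0, c(g, cfg$t_frames))
    flat <- matrix(0, prod(g), cfg$t_frames)
    n_noise <- length(background) + sum(lengths(region_voxels))
    noise <- ar1_series(cfg$t_frames, cfg$ar1_phi, n_noise) * cfg$noise_sd
    k <- 0L
    glob <- matrix(sqrt(h) * P, 1, cfg$t_frames)
    for (r in seq_len(cfg$n_regions)) {
      vx <- region_voxels[[r]]
      idx <- k + seq_along(vx); k <- k + length(vx)
      flat[vx, ] <- 100 + glob[rep(1, length(vx)), ] +
        sqrt(1 - h) * (sqrt(w) * matrix(L[, r], length(vx), cfg$t_frames,
                                        byrow = TRUE) +
                         sqrt(1 - w) * t(noise[, idx, drop = FALSE]))
    }
    idx <- k + seq_along(background)
    flat[background, ] <- 100 + glob[rep(1, length(background)), ] +
      sqrt(1 - h) * t(noise[, idx, drop = FALSE])
    vol[] <- flat

    sid <- sprintf("S%03d", i)
    motion <- simulate_motion(cfg$t_frames, cfg$motion_spike_rate,
                              cfg$spike_magnitude_mm)
    demo <- cfg$demographics
    key <- tolower(grp)
    mmse <- round(min(30, max(0, mmse_line["intercept"] +
                                mmse_line["slope"] * a_i +
                                stats::rnorm(1, sd = cfg$cognitive_noise_sd))))
    moca <- round(min(30, max(0, moca_line["intercept"] +
                                moca_line["slope"] * a_i +
                                stats::rnorm(1, sd = cfg$cognitive_noise_sd))))
    pheno[[i]] <- data.frame(
      subject_id = sid, group = grp,
      age = round(stats::rnorm(1, demo$age[[key]][1], demo$age[[key]][2]), 1),
      sex = sample(c("M", "F"), 1),
      education = round(max(0, stats::rnorm(1, demo$education[[key]][1],
                                            demo$education[[key]][2])), 1),
      mmse = as.integer(mmse), moca = as.integer(moca),
      coupling = a_i, stringsAsFactors = FALSE)
    subjects[[i]] <- list(
      bold = bold_dataset(vol, cfg$tr_seconds, affine, sid),
      motion = motion)
  }
  phenotypes <- do.call(rbind, pheno)

  truth <- list(
    planted = !null_cohort && (c_ad != c_hc || a_ad != a_hc || g_ad > 0),
    hub_region = cfg$hub_region,
    dmn_regions = cfg$dmn_regions,
    asso_direction = if (!null_cohort && (c_ad > c_hc || a_ad < a_hc))
      "AD<HC" else "none",
    fc_direction = if (!null_cohort && g_ad > 0) "AD>HC" else "none",
    hub_coupling = c(ad = a_ad, hc = a_hc),
    neighbor_coupling = c(ad = c_ad, hc = c_hc),
    seed_fc_gain = c(ad = g_ad, hc = 0))

  structure(list(subjects = subjects,
                 region_labels = geo$labels,
                 masks = tissue_masks(geo$brain, geo$wm, geo$csf),
                 phenotypes = phenotypes,
                 affine = affine,
                 truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Simulate a cohort with no planted group effect
#'
#' All group-difference parameters are forced to zero (both groups use the
#' HC neighbor coupling, no seed-FC gain) and group labels are assigned at
#' random, so any detected group difference is a false positive.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_cohort` whose `truth$planted` is `FALSE`.
#' @export
simulate_null_cohort <- function(cfg) {
  simulate_cohort(cfg, null_cohort = TRUE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$phenotypes$group)
  cat("<synthetic_cohort>", length(x$subjects), "subjects (",
      paste(names(tab), tab, collapse = ", "), "),",
      max(x$region_labels), "regions, planted =", x$truth$planted, "\n")
  invisible(x)
}

#' Logical mask of one generated region
#'
#' @param cohort A `synthetic_cohort`.
#' @param region Region index.
#' @return Logical 3-D array.
#' @export
region_mask <- function(cohort, region) {
  cohort$region_labels == region
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject `<id>_bold.nii.gz` and `<id>_motion.tsv`, the three
#' tissue masks, `phenotypes.tsv`, the region label image and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sid <- s$bold$subject_id
    write_nifti_volume(s$bold, file.path(dir, paste0(sid, "_bold.nii.gz")))
    write_motion_params(s$motion, file.path(dir, paste0(sid, "_motion.tsv")))
  }
  for (m in c("brain", "wm", "csf"))
    write_nifti_volume(array(as.numeric(cohort$masks[[m]]),
                             dim(cohort$masks[[m]])),
                       file.path(dir, paste0(m, ".nii.gz")),
                       affine = cohort$affine)
  write_nifti_volume(array(as.numeric(cohort$region_labels),
                           dim(cohort$region_labels)),
                     file.path(dir, "region_labels.nii.gz"),
                     affine = cohort$affine)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
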