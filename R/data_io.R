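#' @title Containers for BOLD data and brain maps
#' @name assomap-containers
#'
#' @description
#' `bold_dataset` holds one subject's 4-D BOLD series on a common grid:
#' the data array indexed `(x, y, z, t)`, the repetition time in seconds and
#' the 4x4 affine mapping 0-based voxel indices to mm coordinates.
#' `voxel_map` holds any scalar brain map (asso, asso_z, fcs, fc_z, t) with
#' its affine and analysis mask. Both are plain lists with a class attribute,
#' constructed by the functions below so invariants are checked in one place.
NULL

#' Construct a BOLD dataset
#'
#' @param data 4-D numeric array indexed (x, y, z, t), arbitrary BOLD units.
#' @param tr_seconds Repetition time in seconds (positive).
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to mm.
#' @param subject_id Subject identifier.
#' @return An object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, tr_seconds, affine = diag(4),
                         subject_id = "subject") {
  if (length(dim(data)) != 4L)
    stop("BOLD data must be a 4-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  for (t in seq_len(dim(data)[4L]))
    if (all(is.na(data[, , , t])))
      stop("volume ", t, " is all-NaN", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 data = data,
                 tr_seconds = tr_seconds,
                 affine = affine),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_dataset> subject", x$subject_id, ":",
      paste(d[1:3], collapse = "x"), "grid,", d[4], "frames, TR",
      x$tr_seconds, "s\n")
  invisible(x)
}

#' Construct a scalar brain map
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel convention).
#' @param kind One of `"asso"`, `"asso_z"`, `"fcs"`, `"fc_z"`, `"t"`.
#' @param mask Logical 3-D array marking analysed voxels; values outside the
#'   mask are set to `outside` (0 by default, so viewers render cleanly).
#' @param outside Fill value outside the mask, `0` or `NaN`.
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(values, affine, kind = c("asso", "asso_z", "fcs",
                                               "fc_z", "t"),
                      mask = NULL, outside = 0) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- array(as.logical(mask), dim(mask))
  if (!all(dim(mask) == dim(values)))
    stop("mask and values dimensions differ", call. = FALSE)
  if (any(!is.finite(values[mask])))
    stop("non-finite values inside the mask", call. = FALSE)
  values[!mask] <- outside
  structure(list(values = values, affine = as.matrix(affine), kind = kind,
                 mask = mask),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat("<voxel_map>", x$kind, ":", paste(dim(x$values), collapse = "x"),
      "grid,", sum(x$mask), "in-mask voxels\n")
  invisible(x)
}

# 4x4 numeric matrix from an RNifti xform (attributes stripped)
strip_affine <- function(x) {
  matrix(as.numeric(x), 4L, 4L)
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param ijk Matrix (n x 3) or vector of 0-based voxel indices.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Read a 4-D BOLD NIfTI volume together with its motion parameters
#'
#' The affine is taken from the NIfTI header (RNifti's 0-based `xform`).
#' The motion file is a TSV with six numeric columns (3 translations in mm,
#' 3 rotations in radians), one row per retained frame; a header row is
#' auto-detected.
#'
#' @param path_bold Path to a 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param path_motion Path to the 6-column motion TSV.
#' @param tr Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header's time pixdim.
#' @param subject_id Subject identifier (defaults to the file stem).
#' @return List with elements `bold` (a [bold_dataset]) and `motion`
#'   (a T x 6 matrix).
#' @export
load_bold_dataset <- function(path_bold, path_motion, tr = NULL,
                              subject_id = NULL) {
  img <- RNifti::readNifti(path_bold)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4-D NIfTI image, got ", length(d), " dimensions",
         call. = FALSE)
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4L]
    if (!is.finite(tr) || tr <= 0)
      stop("no usable TR in header; pass tr explicitly", call. = FALSE)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path_bold))
  motion <- read_motion_params(path_motion)
  if (nrow(motion) != d[4L])
    stop("length mismatch: motion table has ", nrow(motion),
         " rows but BOLD has ", d[4L], " volumes", call. = FALSE)
  aff <- strip_affine(RNifti::xform(img))
  list(bold = bold_dataset(array(as.numeric(img), dim = d), tr, aff,
                           subject_id),
       motion = motion)
}

#' Read a 6-column rigid-body motion table
#'
#' @param path TSV path; header auto-detected (default none).
#' @return T x 6 numeric matrix with columns tx, ty, tz (mm), rx, ry, rz
#'   (radians).
#' @export
read_motion_params <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[\t ]+")[[1]]))))
  tab <- utils::read.table(path, header = has_header, sep = "\t")
  if (ncol(tab) == 1L)  # space-separated fallback
    tab <- utils::read.table(path, header = has_header)
  if (ncol(tab) != 6L)
    stop("motion table must have 6 columns, got ", ncol(tab), call. = FALSE)
  m <- as.matrix(tab)
  if (!all(is.finite(m))) stop("non-finite motion parameters", call. = FALSE)
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' Write a motion table as headerless TSV
#'
#' @param motion T x 6 matrix.
#' @param path Output path.
#' @export
write_motion_params <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a BOLD dataset or voxel map as NIfTI-1
#'
#' The affine is stored in both sform and qform; data are written as
#' 64-bit float so maps round-trip at full numeric precision.
#'
#' @param x A [bold_dataset], [voxel_map], or plain 3-D/4-D array.
#' @param path Output path (.nii or .nii.gz).
#' @param affine Required when `x` is a plain array.
#' @param tr Frame duration stored in the header for 4-D data.
#' @export
write_nifti_volume <- function(x, path, affine = NULL, tr = NULL) {
  if (inherits(x, "bold_dataset")) {
    arr <- x$data; affine <- x$affine; tr <- x$tr_seconds
  } else if (inherits(x, "voxel_map")) {
    arr <- x$values; affine <- x$affine
  } else {
    arr <- x
    if (is.null(affine)) stop("affine required for plain arrays",
                              call. = FALSE)
  }
  pd <- sqrt(colSums(affine[1:3, 1:3] ^ 2))
  if (length(dim(arr)) == 4L) pd <- c(pd, if (is.null(tr)) 1 else tr)
  attr(arr, "pixdim") <- pd
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar map written by [write_nifti_volume()]
#'
#' @param path NIfTI path.
#' @param kind Map kind to tag the result with.
#' @param mask Optional logical mask; default marks finite nonzero support
#'   as analysed, which matches the 0-outside writing convention.
#' @return A [voxel_map].
#' @export
read_voxel_map <- function(path, kind = "asso", mask = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D map", call. = FALSE)
  aff <- strip_affine(RNifti::xform(img))
  if (is.null(mask)) mask <- array(TRUE, dim(vals))
  vals[!is.finite(vals)] <- 0
  voxel_map(vals, aff, kind, mask)
}

#' Read tissue masks (brain, white matter, CSF) from NIfTI files
#'
#' Any nonzero voxel is treated as inside the mask.
#'
#' @param path_brain,path_wm,path_csf NIfTI paths on one grid.
#' @return List of logical 3-D arrays with class `tissue_masks`.
#' @export
load_tissue_masks <- function(path_brain, path_wm, path_csf) {
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img) != 0, dim = dim(img))
  }
  tissue_masks(rd(path_brain), rd(path_wm), rd(path_csf))
}

#' Construct tissue masks
#'
#' @param brain,wm,csf Logical 3-D arrays on one grid; `wm` and `csf` must be
#'   subsets of `brain`, and `brain` must be non-empty.
#' @return List with class `tissue_masks`.
#' @export
tissue_masks <- function(brain, wm, csf) {
  brain <- array(as.logical(brain), dim(brain))
  wm <- array(as.logical(wm), dim(wm))
  csf <- array(as.logical(csf), dim(csf))
  if (!all(dim(wm) == dim(brain)) || !all(dim(csf) == dim(brain)))
    stop("mask grids differ", call. = FALSE)
  if (!any(brain)) stop("brain mask is empty", call. = FALSE)
  if (any(wm & !brain)) stop("wm mask extends outside brain", call. = FALSE)
  if (any(csf & !brain)) stop("csf mask extends outside brain", call. = FALSE)
  structure(list(brain = brain, wm = wm, csf = csf), class = "tissue_masks")
}

#' Load the per-subject phenotype table
#'
#' Expects a TSV with header and columns `subject_id`, `group` (AD/HC),
#' `age`, `sex` (M/F), `education`, `mmse`, `moca`.
#'
#' @param path TSV path.
#' @return A data.frame, one validated record per subject.
#' @export
load_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

#' Validate a phenotype table
#'
#' @param tab Data frame with the columns listed under [load_phenotypes()].
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_phenotypes <- function(tab) {
  req <- c("subject_id", "group", "age", "sex", "education", "mmse", "moca")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("phenotype table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) stop("no records in phenotype table", call. = FALSE)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$group), c("AD", "HC"))
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(tab$sex %in% c("M", "F")))
    stop("sex must be M or F", call. = FALSE)
  for (col in c("age", "education", "mmse", "moca")) {
    ok <- is.finite(tab[[col]])
    if (!all(ok))
      stop("missing/non-finite ", col, " for subject ",
           paste(tab$subject_id[!ok], collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a phenotype table as TSV
#'
#' @param tab Phenotype data.frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
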