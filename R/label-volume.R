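#' Labelled volumetric image
#'
#' A `label_volume` is the package's container for voxelised anatomy: a 3-D
#' integer (or logical) grid together with a 4x4 voxel-to-world affine in
#' millimetres.  World coordinates follow the RAS+ convention (X = lateral,
#' positive right; Y = anterior; Z = superior).  Voxel indices are 1-based in
#' R; the affine maps the 0-based index, as in the NIfTI standard, so voxel
#' `(1,1,1)` sits at `affine %*% c(0,0,0,1)`.
#'
#' @param data 3-D array of integer label codes (0 = background).
#' @param affine 4x4 voxel-to-world matrix; last row must be `(0,0,0,1)`.
#' @param labels optional named list mapping region names to integer code
#'   vectors, so that composite regions (e.g. a nucleus made of a motor part
#'   and a non-motor shell) can be addressed by name.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine = diag(4), labels = NULL) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array, got ", length(dim(data)), " dimensions")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last row of 'affine' must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("'affine' has a singular linear part")
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  structure(list(data = data, affine = affine, labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  if (!is.null(x$labels))
    cat("  regions:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname label_volume
#' @param x a `label_volume`.
#' @export
is_label_volume <- function(x) inherits(x, "label_volume")

#' Voxel dimensions in millimetres
#'
#' @param vol a `label_volume`.
#' @return length-3 numeric vector of voxel edge lengths (mm).
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Volume of one voxel in cubic millimetres
#' @param vol a `label_volume`.
#' @export
voxel_volume_mm3 <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

#' Map voxel indices to world coordinates
#'
#' @param vol a `label_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 1-based) voxel indices
#'
#' @param vol a `label_volume`.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE] + 1
}

resolve_label <- function(vol, label) {
  if (is.character(label)) {
    if (is.null(vol$labels) || is.null(vol$labels[[label]]))
      stop("unknown region name '", label, "'")
    vol$labels[[label]]
  } else {
    as.integer(label)
  }
}

#' Logical mask of a labelled region
#'
#' @param vol a `label_volume`.
#' @param label region name (looked up in `vol$labels`) or integer code(s).
#' @return logical array matching `dim(vol$data)`.
#' @export
label_mask <- function(vol, label) {
  codes <- resolve_label(vol, label)
  array(vol$data %in% codes, dim = dim(vol$data))
}

#' Region volume in cubic millimetres
#' @inheritParams label_mask
#' @export
label_volume_mm3 <- function(vol, label) {
  sum(label_mask(vol, label)) * voxel_volume_mm3(vol)
}

#' Centre of gravity of a labelled region, in world mm
#'
#' The centroid is the unweighted mean of the world coordinates of all
#' voxel centres carrying the label.
#'
#' @inheritParams label_mask
#' @return length-3 numeric world coordinate (mm).
#' @export
label_centroid <- function(vol, label) {
  m <- label_mask(vol, label)
  if (!any(m))
    stop("region '", paste(label, collapse = ","), "' is empty")
  ijk <- which(m, arr.ind = TRUE)
  colMeans(voxel_to_world(vol, ijk))
}

#' Check that two volumes share dimensions and affine
#'
#' @param a,b `label_volume` objects.
#' @param tol absolute tolerance on affine entries.
#' @return `TRUE` invisibly; errors with a grid-mismatch message otherwise.
#' @export
assert_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: dimensions ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grid mismatch: affines differ by more than ", tol, " mm")
  invisible(TRUE)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [label_volume].  Only 3-D images are accepted.
#'
#' @param path file path.
#' @param labels optional region-name table attached to the result.
#' @return a [label_volume].
#' @export
read_nifti <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions in ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  label_volume(array(as.vector(img), dim = d), aff, labels = labels)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [label_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(is_label_volume(vol))
  img <- RNifti::asNifti(vol$data)
  # sform carries a general affine exactly; the quaternion qform cannot
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
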