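# Containers for labelled parcellation volumes and binary region masks.

#' Labelled 3D parcellation volume
#'
#' Wraps a 3D array of non-negative integer region labels (0 = background)
#' together with the physical voxel spacing, e.g. an AAL-90-style atlas
#' already warped to a subject's native space.
#'
#' @param data 3D array of non-negative integer labels.
#' @param spacing numeric length-3 voxel size in mm per axis, all > 0.
#' @param region_names optional named character vector mapping label
#'   (as character) to region name.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), region_names = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  }
  if (any(data < 0) || any(data != round(data))) {
    stop("labels must be non-negative integers (0 = background)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes (mm)")
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = spacing, region_names = region_names),
    class = "label_volume"
  )
}

#' Binary 3D mask of a single region or synthetic shape
#'
#' @param data 3D logical array.
#' @param spacing voxel size in mm per axis.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be logical or 0/1")
    data <- array(as.logical(data), dim = dim(data))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes (mm)")
  }
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat("<label_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing), collapse = "x"),
      " mm, ", length(labs), " regions\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' Spacing is taken from the header `pixdim`; orientation is not
#' reinterpreted, labels are assumed voxel-aligned.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param region_names optional label-to-name mapping.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, region_names = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.integer(round(arr)), dim(arr))  # drop NIfTI attributes
  label_volume(arr, spacing = spacing, region_names = region_names)
}

#' Write a label volume to NIfTI
#'
#' @param volume a [label_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$data, internal = FALSE)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Bounding box of the foreground as ranges per axis; NULL when empty.
mask_bbox <- function(arr) {
  idx <- which(arr, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  apply(idx, 2L, range)
}

# Crop a logical array to its foreground bounding box.
crop_to_bbox <- function(arr) {
  bb <- mask_bbox(arr)
  if (is.null(bb)) stop("mask is empty: no foreground voxels to crop")
  arr[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3], drop = FALSE]
}

# 6-connectivity boundary: foreground voxels with at least one face
# neighbour outside the mask (array borders count as outside).
boundary_voxels <- function(arr) {
  d <- dim(arr)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
  core <- function(dx, dy, dz) {
    padded[(2:(d[1] + 1L)) + dx, (2:(d[2] + 1L)) + dy, (2:(d[3] + 1L)) + dz]
  }
  interior <- arr & core(1, 0, 0) & core(-1, 0, 0) &
    core(0, 1, 0) & core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  arr & !interior
}
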