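#' 3D image volume with physical voxel spacing
#'
#' A `volume` is the unit every stage of the pipeline consumes: a 3D scalar
#' array together with its voxel spacing in millimetres. The axis order is
#' fixed as (x = left-right, y = anterior-posterior, z = inferior-superior),
#' with "left" at low x indices. World coordinates are `(index - 1) * spacing`
#' (no rotation component in phantom affines).
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing numeric length-3, strictly positive, millimetres per voxel
#'   along each axis. The default matches a typical neuromelanin-sensitive
#'   GRE acquisition, 0.67 x 1.0 x 1.34 mm.
#' @return An object of class `volume`: a list with elements `data` and
#'   `spacing`.
#' @export
volume <- function(data, spacing = c(0.67, 1.0, 1.34)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got dimensionality ",
         length(dim(data)), call. = FALSE)
  }
  if (!all(is.finite(data))) stop("volume data must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "volume")
}

#' Binary label mask on a volume grid
#'
#' A `label_mask` shares the grid and spacing of its paired [volume] and is
#' restricted to values {0, 1}. Masks carry substantia nigra labels (left and
#' right), the crus cerebri reference region, predictions and rater labels.
#'
#' @param data 3D array coercible to {0, 1}.
#' @inheritParams volume
#' @return An object of class `label_mask` (also a list with `data`,
#'   `spacing`).
#' @export
label_mask <- function(data, spacing = c(0.67, 1.0, 1.34)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("mask data must be a 3D array", call. = FALSE)
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stop("mask values must be 0 or 1; found other values", call. = FALSE)
  }
  v <- volume(array(as.numeric(data), dim(data)), spacing)
  class(v) <- c("label_mask", "volume")
  v
}

is_volume <- function(x) inherits(x, "volume")
is_mask <- function(x) inherits(x, "label_mask")

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

# Volume of one voxel in mm^3.
voxel_volume <- function(x) prod(x$spacing)

#' Number of foreground voxels in a mask
#' @param mask a [label_mask].
#' @return Integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$data)

#' Physical volume of a mask in cubic millimetres
#' @param mask a [label_mask].
#' @return Scalar, `voxel count * voxel volume`.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$data) * voxel_volume(mask)

check_same_grid <- function(x, y) {
  if (!identical(dim(x$data), dim(y$data))) {
    stop("grids differ: ", paste(dim(x$data), collapse = "x"), " vs ",
         paste(dim(y$data), collapse = "x"), call. = FALSE)
  }
  if (max(abs(x$spacing - y$spacing)) > 1e-6) {
    stop("voxel spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a NIfTI-1 file into a [volume], taking the voxel spacing from the
#' image's pixdim. Only 3D images are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; if `TRUE` the image is validated and returned as a
#'   [label_mask].
#' @return A [volume] or [label_mask].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions: ", path,
         call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path, call. = FALSE)
  arr <- array(as.numeric(img), d)
  if (mask) label_mask(arr, sp) else volume(arr, sp)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are written as float32 and masks as unsigned 8-bit; the affine is
#' diagonal, encoding the spacing only.
#'
#' @param vol a [volume] or [label_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  dtype <- if (is_mask(vol)) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
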