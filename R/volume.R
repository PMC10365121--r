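# VolumeGrid: a 3D scalar array with voxel spacing metadata, plus NIfTI IO.

#' Create a volume grid
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm per axis (length 3, strictly positive).
#' @param is_label logical; label grids hold non-negative integers and are
#'   always interpolated nearest-neighbour.
#' @return a `volume_grid` object.
#' @export
volume_grid <- function(data, spacing, is_label = FALSE) {
  stopifnot(length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (mm)")
  }
  if (is_label) {
    v <- as.vector(data)
    if (any(v < 0) || any(v != round(v))) {
      stop("label grids must contain non-negative integers")
    }
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, spacing = spacing, is_label = is_label),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              if (x$is_label) " [labels]" else ""))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param is_label logical; treat contents as integer labels.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, is_label = FALSE) {
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)[1:3]
  d <- dim(im)
  arr <- array(as.numeric(im), dim = d)
  if (length(d) > 3L) arr <- arr[, , , 1]
  if (is_label) arr <- round(arr)
  volume_grid(arr, sp, is_label)
}

#' Write a volume grid as NIfTI
#'
#' @param vol a [volume_grid()].
#' @param path output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Tumor volume in ml of one voxel count
#' @param n_voxels number of voxels.
#' @param spacing voxel spacing (mm).
#' @return volume in ml.
#' @export
voxels_to_ml <- function(n_voxels, spacing) {
  n_voxels * prod(spacing) / 1000
}
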