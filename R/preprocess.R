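# Preprocessing chain: (i) resample to isotropic 1 mm spacing (order-1 for
# images, nearest for labels), (ii) clip tightly around the head,
# (iii) resize to the network input shape, (iv) min-max intensity
# normalisation -- together with the exact geometric inverse that restores a
# probability map to the native volume's reference frame.

# global Otsu threshold on a numeric vector (256-bin between-class variance)
.otsu <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) stop("cannot threshold a constant volume")
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(r[1], r[2], length.out = nbins + 1L), all.inside = TRUE), 1L),
    nbins), nbins)
  p <- h / sum(h)
  mids <- seq(r[1], r[2], length.out = nbins + 1L)[-1] -
    (r[2] - r[1]) / (2 * nbins)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

.scale_affine <- function(in_dim, out_dim) {
  # half-pixel-centre alignment: in = s * out + (s - 1) / 2
  s <- in_dim / out_dim
  list(A = diag(s, 3), t = (s - 1) / 2)
}

.resample_to_shape <- function(arr, out_shape, order) {
  d <- dim(arr)
  if (all(d == out_shape)) return(arr)
  aff <- .scale_affine(d, out_shape)
  cpp_affine_sample(arr, as.integer(d), aff$A, aff$t,
                    as.integer(out_shape), as.integer(order), 1L)
}

#' Resample a volume to isotropic spacing
#'
#' Order-1 (trilinear) interpolation for images, nearest neighbour for label
#' grids. The output shape is `round(native_shape * native_spacing /
#' target_spacing)`.
#'
#' @param vol a [volume_grid()].
#' @param target_spacing isotropic target spacing in mm.
#' @return a resampled [volume_grid()].
#' @export
resample_isotropic <- function(vol, target_spacing = 1.0) {
  stopifnot(inherits(vol, "volume_grid"))
  out_shape <- pmax(as.integer(round(dim(vol$data) * vol$spacing /
                                       target_spacing)), 1L)
  order <- if (vol$is_label) 0L else 1L
  out <- .resample_to_shape(vol$data + 0, out_shape, order)
  volume_grid(out, rep(target_spacing, 3), vol$is_label)
}

#' Clip a volume tightly around the head
#'
#' Foreground is found by a global Otsu threshold, reduced to its largest
#' 26-connected component and closed morphologically (3x3x3 cube); the
#' volume is cropped to the component's bounding box.
#'
#' @param vol a [volume_grid()] (image intensities).
#' @return list with `volume` (cropped) and `bbox` (inclusive 1-based
#'   voxel bounds, `c(x0, x1, y0, y1, z0, z1)`).
#' @export
clip_to_head <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  x <- vol$data
  thr <- .otsu(as.vector(x))
  fg <- array(as.integer(x >= thr), dim = dim(x))
  if (!any(fg == 1L)) stop("empty foreground after thresholding")
  lab <- cpp_cc_label(fg, dim(fg), 26L)
  sizes <- tabulate(lab[lab > 0])
  main <- array(as.integer(lab == which.max(sizes)), dim = dim(x))
  main <- cpp_binary_close3(main, dim(main))
  idx <- which(main == 1L, arr.ind = TRUE)
  bbox <- as.integer(c(min(idx[, 1]), max(idx[, 1]),
                       min(idx[, 2]), max(idx[, 2]),
                       min(idx[, 3]), max(idx[, 3])))
  cropped <- x[bbox[1]:bbox[2], bbox[3]:bbox[4], bbox[5]:bbox[6],
               drop = FALSE]
  list(volume = volume_grid(cropped, vol$spacing, vol$is_label),
       bbox = bbox)
}

#' Resize a volume to a fixed grid
#'
#' Spline interpolation of order 1 (trilinear) for images, nearest
#' neighbour for labels.
#'
#' @param vol a [volume_grid()].
#' @param target_shape output voxel grid, default the network input
#'   `c(128, 128, 144)`.
#' @return resized [volume_grid()]; spacing is scaled accordingly.
#' @export
resize_volume <- function(vol, target_shape = c(128L, 128L, 144L)) {
  stopifnot(inherits(vol, "volume_grid"))
  target_shape <- as.integer(target_shape)
  order <- if (vol$is_label) 0L else 1L
  out <- .resample_to_shape(vol$data + 0, target_shape, order)
  volume_grid(out, vol$spacing * dim(vol$data) / target_shape, vol$is_label)
}

#' Min-max intensity normalisation to [0, 1]
#'
#' @param vol an image [volume_grid()].
#' @return list with `volume`, `intensity_min`, `intensity_max`. A constant
#'   input maps to all zeros.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"), !vol$is_label)
  lo <- min(vol$data)
  hi <- max(vol$data)
  out <- if (hi > lo) (vol$data - lo) / (hi - lo) else array(0, dim(vol$data))
  list(volume = volume_grid(out, vol$spacing),
       intensity_min = lo, intensity_max = hi)
}

#' Full preprocessing chain
#'
#' Resample to isotropic spacing, clip around the head, resize to the
#' network grid and normalise intensities. The returned record contains
#' everything needed to invert the geometry exactly.
#'
#' @param vol an image [volume_grid()].
#' @param target_spacing isotropic spacing (mm).
#' @param target_shape network input shape.
#' @return list with `tensor` (3D array in `[0, 1]` of shape
#'   `target_shape`) and `record` (a `preprocess_record`).
#' @export
preprocess <- function(vol, target_spacing = 1.0,
                       target_shape = c(128L, 128L, 144L)) {
  stopifnot(inherits(vol, "volume_grid"), !vol$is_label)
  rs <- resample_isotropic(vol, target_spacing)
  cl <- clip_to_head(rs)
  rz <- resize_volume(cl$volume, target_shape)
  nm <- normalize_intensity(rz)
  record <- structure(list(
    native_shape = dim(vol$data), native_spacing = vol$spacing,
    resampled_shape = dim(rs$data), crop_bbox = cl$bbox,
    resize_source_shape = dim(cl$volume$data),
    target_spacing = target_spacing,
    target_shape = as.integer(target_shape),
    intensity_min = nm$intensity_min, intensity_max = nm$intensity_max),
    class = "preprocess_record")
  list(tensor = nm$volume$data, record = record)
}

#' Apply recorded preprocessing geometry to a label volume
#'
#' Transforms a label grid with the geometry recorded while preprocessing
#' the matching image, using nearest-neighbour interpolation throughout so
#' labels stay integral.
#'
#' @param vol a label [volume_grid()].
#' @param record a `preprocess_record`.
#' @return 3D integer array of shape `record$target_shape`.
#' @export
preprocess_label <- function(vol, record) {
  stopifnot(inherits(vol, "volume_grid"), inherits(record,
                                                   "preprocess_record"))
  rs <- .resample_to_shape(vol$data + 0, record$resampled_shape, 0L)
  b <- record$crop_bbox
  cr <- rs[b[1]:b[2], b[3]:b[4], b[5]:b[6], drop = FALSE]
  out <- .resample_to_shape(cr, record$target_shape, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Restore a probability map to the native reference frame
#'
#' Inverts the resize into the crop box, embeds it in the resampled frame
#' (probability 0 outside the head crop) and inverts the isotropic
#' resampling back to the native shape and spacing.
#'
#' @param prob_map 3D array of shape `record$target_shape`, values in
#'   `[0, 1]`.
#' @param record a `preprocess_record`.
#' @return a [volume_grid()] of the native shape and spacing.
#' @export
restore_to_native <- function(prob_map, record) {
  stopifnot(inherits(record, "preprocess_record"))
  if (!all(dim(prob_map) == record$target_shape)) {
    stop("probability map shape does not match the record's network shape")
  }
  crop <- .resample_to_shape(prob_map + 0, record$resize_source_shape, 1L)
  full <- array(0, dim = record$resampled_shape)
  b <- record$crop_bbox
  full[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- crop
  # inverse of the isotropic resampling: sample the resampled frame at
  # native voxel centres (exact inverse of the half-pixel-centre mapping)
  out <- .resample_to_shape(full, record$native_shape, 1L)
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- record$native_shape
  volume_grid(out, record$native_spacing)
}

#' Serialise a preprocess record to JSON
#' @param record a `preprocess_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a preprocess record from JSON
#' @param path JSON path written by [write_preprocess_record()].
#' @return a `preprocess_record`.
#' @export
read_preprocess_record <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$native_shape <- as.integer(r$native_shape)
  r$resampled_shape <- as.integer(r$resampled_shape)
  r$crop_bbox <- as.integer(r$crop_bbox)
  r$resize_source_shape <- as.integer(r$resize_source_shape)
  r$target_shape <- as.integer(r$target_shape)
  structure(r, class = "preprocess_record")
}
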