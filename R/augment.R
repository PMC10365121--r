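# Training-time stochastic spatial augmentation: horizontal and vertical
# in-plane flips, in-plane rotation, per-axis translation and in-plane
# (axial) zoom, each applied independently with probability 50%. Image and
# label always receive the identical geometric transform (order-1 vs
# nearest-neighbour sampling); out-of-bounds voxels are filled with 0.

#' Augmentation configuration
#'
#' @param apply_prob per-transform application probability.
#' @param rotation_range in-plane rotation range in degrees.
#' @param translation_max maximum translation as a fraction of each axis.
#' @param zoom_range zoom factor range, axial plane only; must contain 1.
#' @return an `augment_config` object.
#' @export
augment_config <- function(apply_prob = 0.5,
                           rotation_range = c(-20, 20),
                           translation_max = 0.10,
                           zoom_range = c(0.8, 1.2)) {
  stopifnot(apply_prob >= 0, apply_prob <= 1,
            zoom_range[1] <= 1, zoom_range[2] >= 1)
  structure(list(apply_prob = apply_prob, rotation_range = rotation_range,
                 translation_max = translation_max, zoom_range = zoom_range),
            class = "augment_config")
}

#' Augment an image/label pair
#'
#' Draws five independent apply-coins (horizontal flip, vertical flip,
#' rotation, translation, zoom) and applies the composed transform to both
#' volumes. Deterministic under the caller's RNG state.
#'
#' @param image 3D image array.
#' @param label 3D label array of the same shape.
#' @param config an [augment_config()].
#' @return list with transformed `image` and `label` and the drawn
#'   `transform` parameters.
#' @export
augment_pair <- function(image, label, config = augment_config()) {
  if (!all(dim(image) == dim(label))) {
    stop("image and label must share their shape")
  }
  d <- dim(image)
  coins <- stats::runif(5) < config$apply_prob
  theta <- if (coins[3]) {
    stats::runif(1, config$rotation_range[1], config$rotation_range[2])
  } else 0
  shift <- if (coins[4]) {
    stats::runif(3, -config$translation_max, config$translation_max) * d
  } else c(0, 0, 0)
  zoom <- if (coins[5]) {
    stats::runif(1, config$zoom_range[1], config$zoom_range[2])
  } else 1

  # sampling map (output voxel -> input voxel), centred on the volume middle
  th <- -theta * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  A <- rot %*% diag(c(1 / zoom, 1 / zoom, 1))
  if (coins[1]) A <- A %*% diag(c(-1, 1, 1))  # horizontal flip
  if (coins[2]) A <- A %*% diag(c(1, -1, 1))  # vertical flip
  ctr <- (d - 1) / 2
  t0 <- ctr - A %*% (ctr + shift)

  warp <- function(arr, order) {
    cpp_affine_sample(arr + 0, as.integer(d), A, as.numeric(t0),
                      as.integer(d), as.integer(order))
  }
  img <- warp(image, 1L)
  lab <- warp(label, 0L)
  storage.mode(lab) <- storage.mode(label)
  list(image = img, label = lab,
       transform = list(hflip = coins[1], vflip = coins[2], rotation = theta,
                        translation = shift, zoom = zoom))
}
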