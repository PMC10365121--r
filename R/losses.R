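# Segmentation losses: class-average Dice loss (background excluded), the
# Focal Tversky loss, and the deep-supervision total loss L_Tot. The array
# versions are exported; tape-node counterparts with analytic gradients are
# used by the training loop.

#' Loss configuration
#'
#' @param kind `"dice"` or `"focal_tversky"`.
#' @param tversky_alpha weight on false negatives (default 0.7, favouring
#'   recall).
#' @param tversky_beta weight on false positives (default 0.3);
#'   `alpha + beta = 1` in the standard setting.
#' @param focal_gamma focal exponent parameter (default 2); the loss per
#'   class is `(1 - TI)^(1/gamma)`.
#' @param smooth_eps smoothing constant in numerator and denominator.
#' @param ds_weights deep-supervision head weights; `NULL` means uniform
#'   (normalised to sum to one).
#' @return a `loss_config` object.
#' @export
loss_config <- function(kind = c("dice", "focal_tversky"),
                        tversky_alpha = 0.7, tversky_beta = 0.3,
                        focal_gamma = 2.0, smooth_eps = 1e-5,
                        ds_weights = NULL) {
  kind <- match.arg(kind)
  if (focal_gamma <= 0) stop("focal_gamma must be positive")
  structure(list(kind = kind, tversky_alpha = tversky_alpha,
                 tversky_beta = tversky_beta, focal_gamma = focal_gamma,
                 smooth_eps = smooth_eps, ds_weights = ds_weights),
            class = "loss_config")
}

.check_pred_gt <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) {
    stop("pred and gt must share dimensions (got ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"), ")")
  }
}

.class_mats <- function(pred, gt) {
  d <- dim(pred)
  nc <- d[length(d)]
  n <- prod(d) / nc
  list(p = matrix(pred, nrow = n), g = matrix(gt, nrow = n), nc = nc)
}

#' Class-average Dice loss
#'
#' `1 - mean` over non-background classes of the smoothed soft Dice
#' coefficient `(2 sum(p g) + eps) / (sum(p) + sum(g) + eps)`. Class 1
#' (first channel) is the background and is excluded.
#'
#' @param pred per-voxel class probability array `(..., C)`; rows sum to 1.
#' @param gt one-hot label array of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, gt, eps = 1e-5) {
  .check_pred_gt(pred, gt)
  m <- .class_mats(pred, gt)
  dsc <- vapply(2:m$nc, function(c) {
    (2 * sum(m$p[, c] * m$g[, c]) + eps) /
      (sum(m$p[, c]) + sum(m$g[, c]) + eps)
  }, numeric(1))
  1 - mean(dsc)
}

#' Tversky similarity index
#'
#' `TI = (TP + eps) / (TP + alpha FN + beta FP + eps)` on soft counts, per
#' foreground class. With `alpha = beta = 0.5` it equals the Dice
#' coefficient.
#'
#' @inheritParams dice_loss
#' @param alpha false-negative weight.
#' @param beta false-positive weight.
#' @return numeric vector, one index per non-background class.
#' @export
tversky_index <- function(pred, gt, alpha = 0.7, beta = 0.3, eps = 1e-5) {
  .check_pred_gt(pred, gt)
  m <- .class_mats(pred, gt)
  vapply(2:m$nc, function(c) {
    tp <- sum(m$p[, c] * m$g[, c])
    fn <- sum(m$g[, c]) - tp
    fp <- sum(m$p[, c]) - tp
    (tp + eps) / (tp + alpha * fn + beta * fp + eps)
  }, numeric(1))
}

#' Focal Tversky loss
#'
#' Sum over foreground classes of `(1 - TI)^(1/gamma)`; the exponent
#' convention follows the loss's original formulation, so `gamma = 1`
#' reduces to the plain Tversky loss and `gamma = 2` flattens the loss near
#' `TI = 1`, increasing the contribution of hard examples.
#'
#' @inheritParams dice_loss
#' @param config a [loss_config()] providing `tversky_alpha`,
#'   `tversky_beta`, `focal_gamma` and `smooth_eps`.
#' @return scalar loss.
#' @export
focal_tversky_loss <- function(pred, gt, config = loss_config("focal_tversky")) {
  ti <- tversky_index(pred, gt, config$tversky_alpha, config$tversky_beta,
                      config$smooth_eps)
  sum((1 - ti)^(1 / config$focal_gamma))
}

#' Deep-supervision total loss
#'
#' The total loss `L_Tot` is the weighted sum of the per-head losses `L_x`,
#' the ground truth being recursively down-sampled (nearest neighbour) to
#' each head's grid. Weights are uniform and normalised to sum to one, so
#' the magnitude is comparable whether deep supervision is on or off.
#'
#' @param preds list of probability arrays, finest first.
#' @param gt one-hot ground truth at full resolution.
#' @param config a [loss_config()].
#' @return list with `total` and `per_level` losses.
#' @export
deep_supervision_loss <- function(preds, gt, config = loss_config()) {
  n <- length(preds)
  w <- config$ds_weights
  if (is.null(w)) w <- rep(1 / n, n)
  stopifnot(length(w) == n, all(w >= 0))
  gts <- downsample_gt_pyramid(gt, lapply(preds, function(p) dim(p)[1:3]))
  per <- vapply(seq_len(n), function(i) {
    if (config$kind == "dice") {
      dice_loss(preds[[i]], gts[[i]], config$smooth_eps)
    } else {
      focal_tversky_loss(preds[[i]], gts[[i]], config)
    }
  }, numeric(1))
  list(total = sum(w * per), per_level = per)
}

# nearest-neighbour down-sampling of a one-hot ground truth to head shapes
downsample_gt_pyramid <- function(gt, shapes) {
  d <- dim(gt)
  lapply(shapes, function(s) {
    if (all(s == d[1:3])) return(gt)
    out <- array(0, dim = c(s, d[4]))
    for (c in seq_len(d[4])) {
      out[, , , c] <- cpp_affine_sample(
        gt[, , , c], d[1:3],
        diag(d[1:3] / s), (d[1:3] / s - 1) / 2, as.integer(s), 0L, 1L)
    }
    out
  })
}

# ---- tape-node losses with analytic gradients -----------------------------

tn_dice_loss <- function(tape, pred, gt, eps = 1e-5) {
  d <- dim(pred$value)
  nc <- d[length(d)]
  n <- prod(d) / nc
  p <- matrix(pred$value, nrow = n)
  g <- matrix(gt, nrow = n)
  A <- B <- numeric(nc)
  for (c in 2:nc) {
    A[c] <- 2 * sum(p[, c] * g[, c]) + eps
    B[c] <- sum(p[, c]) + sum(g[, c]) + eps
  }
  val <- 1 - mean(A[2:nc] / B[2:nc])
  tn_node(tape, val, list(pred), function(gr) {
    dp <- matrix(0, n, nc)
    for (c in 2:nc) {
      dp[, c] <- -(2 * g[, c] * B[c] - A[c]) / B[c]^2 / (nc - 1)
    }
    dp <- gr * dp
    dim(dp) <- d
    list(dp)
  })
}

tn_focal_tversky_loss <- function(tape, pred, gt, config) {
  a <- config$tversky_alpha
  b <- config$tversky_beta
  gam <- config$focal_gamma
  eps <- config$smooth_eps
  d <- dim(pred$value)
  nc <- d[length(d)]
  n <- prod(d) / nc
  p <- matrix(pred$value, nrow = n)
  g <- matrix(gt, nrow = n)
  num <- den <- ti <- numeric(nc)
  for (c in 2:nc) {
    tp <- sum(p[, c] * g[, c])
    fn <- sum(g[, c]) - tp
    fp <- sum(p[, c]) - tp
    num[c] <- tp + eps
    den[c] <- tp + a * fn + b * fp + eps
    ti[c] <- num[c] / den[c]
  }
  val <- sum((1 - ti[2:nc])^(1 / gam))
  tn_node(tape, val, list(pred), function(gr) {
    dp <- matrix(0, n, nc)
    for (c in 2:nc) {
      dl_dti <- -(1 / gam) * (max(1 - ti[c], 1e-12))^(1 / gam - 1)
      dnum <- g[, c]
      dden <- g[, c] - a * g[, c] + b * (1 - g[, c])
      dti <- (dnum * den[c] - num[c] * dden) / den[c]^2
      dp[, c] <- dl_dti * dti
    }
    dp <- gr * dp
    dim(dp) <- d
    list(dp)
  })
}

# total loss over the output heads of forward_model()
tn_total_loss <- function(tape, heads, gt, config) {
  gts <- downsample_gt_pyramid(gt, lapply(heads,
                                          function(h) dim(h$value)[1:3]))
  per <- lapply(seq_along(heads), function(i) {
    if (config$kind == "dice") {
      tn_dice_loss(tape, heads[[i]], gts[[i]], config$smooth_eps)
    } else {
      tn_focal_tversky_loss(tape, heads[[i]], gts[[i]], config)
    }
  })
  w <- config$ds_weights
  if (is.null(w)) w <- rep(1 / length(per), length(per))
  list(total = tn_wsum(tape, per, w),
       per_level = vapply(per, function(x) x$value, numeric(1)))
}
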