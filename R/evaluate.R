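# Patient-wise validation: probability-threshold sweep, connected-component
# instance extraction, greedy overlap pairing, Dice / Dice-TP / recall /
# precision / F1, pooled cross-validation estimates and volume-binned
# reporting.

#' Evaluation configuration
#'
#' @param thresholds probability thresholds (PT) swept over the map;
#'   strictly increasing values in (0, 1].
#' @param connectivity 6, 18 or 26 (voxel neighbourhood for instances).
#' @param n_bins number of equally populated volume bins.
#' @param clinical_cutoff volume cutoff (ml) separating small from
#'   clinically typical tumors.
#' @return an `eval_config` object.
#' @export
eval_config <- function(thresholds = seq(0.1, 1.0, by = 0.1),
                        connectivity = 26L, n_bins = 10L,
                        clinical_cutoff = 3) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds <= 1), connectivity %in% c(6L, 18L, 26L))
  structure(list(thresholds = thresholds,
                 connectivity = as.integer(connectivity),
                 n_bins = as.integer(n_bins),
                 clinical_cutoff = clinical_cutoff),
            class = "eval_config")
}

#' Binarize a probability map
#' @param prob probability array, values in `[0, 1]`.
#' @param pt threshold; a voxel is foreground iff `prob >= pt`.
#' @return integer 0/1 array.
#' @export
binarize <- function(prob, pt) {
  out <- array(as.integer(prob >= pt), dim = dim(prob))
  out
}

#' Extract connected-component instances
#' @param mask binary array.
#' @param connectivity 6, 18 or 26.
#' @return integer array labelling maximal components 1..m.
#' @export
extract_instances <- function(mask, connectivity = 26L) {
  m <- array(as.integer(mask != 0), dim = dim(mask))
  cpp_cc_label(m, dim(m), as.integer(connectivity))
}

#' Pair ground-truth and predicted instances
#'
#' Greedy one-to-one matching by descending voxel overlap; any nonzero
#' overlap qualifies as a detection. Unmatched predictions are false
#' positives, unmatched ground-truth instances false negatives.
#'
#' @param gt_inst integer instance labelling of the ground truth.
#' @param pred_inst integer instance labelling of the prediction.
#' @return list with `pairs` (data.frame `gt`, `pred`, `overlap`),
#'   `fp` (pred ids), `fn` (gt ids), `n_gt`, `n_pred`.
#' @export
pair_instances <- function(gt_inst, pred_inst) {
  if (!all(dim(gt_inst) == dim(pred_inst))) {
    stop("instance maps must share their grid")
  }
  n_gt <- max(gt_inst)
  n_pred <- max(pred_inst)
  both <- gt_inst > 0 & pred_inst > 0
  ov <- if (any(both)) {
    as.data.frame(table(gt = gt_inst[both], pred = pred_inst[both]),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(gt = integer(), pred = integer(), Freq = integer())
  }
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ov$gt <- as.integer(as.character(ov$gt))
  ov$pred <- as.integer(as.character(ov$pred))
  ov <- ov[order(-ov$Freq, ov$gt, ov$pred), , drop = FALSE]
  used_gt <- used_pred <- logical(max(1, n_gt, n_pred))
  pairs <- list()
  for (r in seq_len(nrow(ov))) {
    g <- ov$gt[r]
    p <- ov$pred[r]
    if (used_gt[g] || used_pred[p]) next
    used_gt[g] <- used_pred[p] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(gt = g, pred = p,
                                              overlap = ov$Freq[r])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(gt = integer(), pred = integer(), overlap = integer())
  }
  list(pairs = pairs,
       fp = setdiff(seq_len(n_pred), pairs$pred),
       fn = setdiff(seq_len(n_gt), pairs$gt),
       n_gt = n_gt, n_pred = n_pred)
}

.dice_pct <- function(a, b) {
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(100)
  100 * 2 * sum(a & b) / (sa + sb)
}

#' Per-patient metrics over the threshold sweep
#'
#' For every probability threshold: the global Dice between ground truth
#' and the binarized map, the true-positive Dice (against the union of
#' TP-paired predicted components only, excluding false-positive voxels),
#' and the instance counts.
#'
#' @param gt_labels ground-truth instance (or binary) label array.
#' @param prob probability map on the same grid, values in `[0, 1]`.
#' @param config an [eval_config()].
#' @param spacing voxel spacing in mm (for the ground-truth volume).
#' @return data.frame with one row per threshold: `pt`, `dice`, `dice_tp`,
#'   `tp`, `fp`, `fn`, `gt_volume_ml`.
#' @export
patient_metrics <- function(gt_labels, prob, config = eval_config(),
                            spacing = c(1, 1, 1)) {
  if (!all(dim(gt_labels) == dim(prob))) stop("grid mismatch")
  gt_inst <- extract_instances(gt_labels, config$connectivity)
  gt_bin <- gt_inst > 0
  vol_ml <- voxels_to_ml(sum(gt_bin), spacing)
  rows <- lapply(config$thresholds, function(pt) {
    mask <- binarize(prob, pt)
    pred_inst <- extract_instances(mask, config$connectivity)
    pr <- pair_instances(gt_inst, pred_inst)
    dice <- .dice_pct(gt_bin, mask == 1L)
    dice_tp <- if (nrow(pr$pairs) > 0) {
      tp_mask <- array(pred_inst %in% pr$pairs$pred, dim = dim(prob))
      .dice_pct(gt_bin, tp_mask)
    } else NA_real_
    data.frame(pt = pt, dice = dice, dice_tp = dice_tp,
               tp = nrow(pr$pairs), fp = length(pr$fp),
               fn = length(pr$fn), gt_volume_ml = vol_ml)
  })
  do.call(rbind, rows)
}

#' Fold-level cohort metrics per threshold
#'
#' Instance counts are summed over the fold's patients; recall, precision
#' and F1 are computed from the summed counts, mean Dice over all patients
#' and mean Dice-TP over patients with at least one true positive. Metrics
#' with an empty denominator are reported as missing, not zero.
#'
#' @param patient_tables list of per-patient tables from
#'   [patient_metrics()].
#' @return data.frame per threshold: `pt`, `recall`, `precision`, `f1`,
#'   `dice`, `dice_tp` (percentages), plus summed counts.
#' @export
cohort_metrics <- function(patient_tables) {
  all <- do.call(rbind, patient_tables)
  out <- lapply(split(all, all$pt), function(d) {
    tp <- sum(d$tp)
    fp <- sum(d$fp)
    fn <- sum(d$fn)
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(recall) && !is.na(precision) &&
              (recall + precision) > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(pt = d$pt[1], recall = recall, precision = precision,
               f1 = f1, dice = mean(d$dice),
               dice_tp = if (any(d$tp > 0)) {
                 mean(d$dice_tp[d$tp > 0])
               } else NA_real_,
               tp = tp, fp = fp, fn = fn, n_patients = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$pt), ]
}

#' Pooled cross-validation estimates
#'
#' Fold-size-weighted mean and standard deviation of each fold-level metric
#' at every threshold.
#'
#' @param fold_tables list of per-fold tables from [cohort_metrics()].
#' @return data.frame per threshold with `<metric>_mean` and `<metric>_sd`
#'   columns for recall, precision, f1, dice, dice_tp.
#' @export
pooled_estimates <- function(fold_tables) {
  metrics <- c("recall", "precision", "f1", "dice", "dice_tp")
  all <- do.call(rbind, lapply(seq_along(fold_tables), function(i) {
    d <- fold_tables[[i]]
    d$foldid <- i
    d
  }))
  out <- lapply(split(all, all$pt), function(d) {
    w <- d$n_patients / sum(d$n_patients)
    row <- data.frame(pt = d$pt[1])
    for (m in metrics) {
      x <- d[[m]]
      ok <- !is.na(x)
      if (!any(ok)) {
        row[[paste0(m, "_mean")]] <- NA_real_
        row[[paste0(m, "_sd")]] <- NA_real_
        next
      }
      ww <- w[ok] / sum(w[ok])
      mu <- sum(ww * x[ok])
      row[[paste0(m, "_mean")]] <- mu
      row[[paste0(m, "_sd")]] <- if (sum(ok) >= 2) {
        sqrt(sum(ww * (x[ok] - mu)^2))
      } else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$pt), ]
}

#' Volume-binned performance report
#'
#' Groups patients into `n_bins` equally populated bins by ground-truth
#' volume (bin populations differ by at most one) and summarises the Dice
#' distribution per bin; patients are also split at the clinical volume
#' cutoff.
#'
#' @param dice per-patient Dice scores (%).
#' @param volumes per-patient ground-truth volumes (ml).
#' @param n_bins number of quantile bins.
#' @param cutoff clinical cutoff in ml.
#' @param detected optional logical vector (patient has >= 1 true
#'   positive), enabling per-group recall.
#' @return list with `bins` and `cutoff_groups` data.frames.
#' @export
volume_binned_report <- function(dice, volumes, n_bins = 10L, cutoff = 3,
                                 detected = NULL) {
  n <- length(dice)
  stopifnot(length(volumes) == n)
  if (n < n_bins) stop("fewer patients than bins")
  ord <- order(volumes)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- bin == b
    q <- stats::quantile(dice[i], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bin = b, n = sum(i),
               vol_min = min(volumes[i]), vol_max = max(volumes[i]),
               dice_q1 = q[1], dice_median = q[2], dice_q3 = q[3],
               dice_mean = mean(dice[i]))
  }))
  grp <- function(i, name) {
    data.frame(group = name, n = sum(i),
               dice_mean = if (any(i)) mean(dice[i]) else NA_real_,
               recall = if (!is.null(detected) && any(i)) {
                 100 * mean(detected[i])
               } else NA_real_)
  }
  cutoff_groups <- rbind(grp(volumes < cutoff, sprintf("< %g ml", cutoff)),
                         grp(volumes >= cutoff, sprintf(">= %g ml", cutoff)))
  list(bins = bins, cutoff_groups = cutoff_groups, bin_of = bin)
}

#' Plot a volume-binned report
#'
#' Box-style summary (quartiles and mean) of Dice per volume bin; requires
#' ggplot2.
#'
#' @param report result of [volume_binned_report()].
#' @return a ggplot object.
#' @export
plot_volume_bins <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  b <- report$bins
  b$label <- sprintf("[%.1f, %.1f]", b$vol_min, b$vol_max)
  ggplot2::ggplot(b, ggplot2::aes_string(x = "factor(bin)")) +
    ggplot2::geom_errorbar(ggplot2::aes_string(ymin = "dice_q1",
                                               ymax = "dice_q3"),
                           width = 0.3) +
    ggplot2::geom_point(ggplot2::aes_string(y = "dice_median"), size = 2) +
    ggplot2::geom_point(ggplot2::aes_string(y = "dice_mean"), shape = 4) +
    ggplot2::labs(x = "tumor volume bin (equally populated)",
                  y = "Dice (%)") +
    ggplot2::theme_minimal()
}

#' Select the operating probability threshold
#'
#' The threshold maximising the instance-wise F1, ties broken toward the
#' higher mean Dice, then toward the lower threshold.
#'
#' @param cohort_table data.frame from [cohort_metrics()] (or pooled
#'   table with `f1`/`dice` columns named `f1_mean`/`dice_mean`).
#' @return the selected threshold value.
#' @export
select_operating_threshold <- function(cohort_table) {
  f1 <- if ("f1" %in% names(cohort_table)) cohort_table$f1 else
    cohort_table$f1_mean
  dice <- if ("dice" %in% names(cohort_table)) cohort_table$dice else
    cohort_table$dice_mean
  f1[is.na(f1)] <- -Inf
  dice[is.na(dice)] <- -Inf
  best <- which(f1 == max(f1))
  best <- best[dice[best] == max(dice[best])]
  cohort_table$pt[min(best)]
}
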