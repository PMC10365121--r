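# Detection and segmentation metrics.

test_that("binarization is a nested sweep", {
  set.seed(1)
  prob <- array(runif(6^3), c(6, 6, 6))
  expect_equal(sum(binarize(prob * 0.99, 1.0)), 0)      # max below PT
  expect_equal(sum(binarize(array(0.5, c(6, 6, 6)), 0.1)), 6^3)
  masks <- lapply(seq(0.1, 1, 0.1), function(pt) binarize(prob, pt))
  for (i in seq_len(9)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))      # monotone nesting
  }
})

test_that("connected components respect the chosen connectivity", {
  m <- array(0L, c(8, 8, 8))
  m[2, 2, 2] <- 1L
  m[3, 3, 3] <- 1L  # touches diagonally only
  expect_equal(max(extract_instances(m, 26)), 1)
  expect_equal(max(extract_instances(m, 6)), 2)
  m2 <- array(0L, c(8, 8, 8))
  m2[1:2, 1:2, 1:2] <- 1L
  m2[5:6, 5:6, 5:6] <- 1L  # separated by background everywhere
  expect_equal(max(extract_instances(m2, 26)), 2)
  expect_equal(max(extract_instances(array(0L, c(4, 4, 4)), 26)), 0)
})

test_that("greedy pairing follows the any-overlap rule", {
  gt <- array(0L, c(10, 10, 4))
  gt[2:4, 2:4, ] <- 1L
  gt[7:9, 7:9, ] <- 2L
  # one pred overlapping gt 1 by a single voxel
  pr <- array(0L, c(10, 10, 4))
  pr[4, 4, 1] <- 1L
  r <- pair_instances(gt, pr)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$gt, 1)
  expect_length(r$fp, 0)
  expect_equal(r$fn, 2)  # second focus undetected -> instance recall 1/2

  # two predictions on one gt: larger overlap wins, other becomes FP
  pr2 <- array(0L, c(10, 10, 4))
  pr2[2:3, 2:4, ] <- 1L   # overlap 6 per slice
  pr2[5, 4, ] <- 2L       # no overlap
  pr2[4, 2:4, ] <- 3L     # overlap 3 per slice
  inst2 <- extract_instances(pr2 > 0, 26)
  r2 <- pair_instances(gt, inst2)
  expect_equal(nrow(r2$pairs), 1)
  expect_equal(length(r2$fp), max(inst2) - 1)
  expect_error(pair_instances(gt, pr2[1:5, , ]), "grid")
})

test_that("greedy pairing matches exhaustive optimal assignment", {
  # random lesion-like configurations of up to 5 ground-truth and 5
  # predicted spherical instances; the exhaustive oracle maximises the
  # number of overlap-paired instances over all one-to-one assignments
  set.seed(7)
  place_blobs <- function(n, d = 24, rmax = 3) {
    lab <- array(0L, c(d, d, d))
    for (i in seq_len(n)) {
      ctr <- runif(3, 3, d - 3)
      r <- runif(1, 1.5, rmax)
      g <- seq_len(d)
      m <- outer(outer((g - ctr[1])^2, (g - ctr[2])^2, `+`),
                 (g - ctr[3])^2, `+`) <= r^2
      lab[m & lab == 0L] <- i
    }
    lab
  }
  for (rep in 1:15) {
    gt <- place_blobs(sample(1:5, 1))
    pr <- place_blobs(sample(1:5, 1))
    ng <- max(gt)
    np <- max(pr)
    if (ng == 0 || np == 0) next
    ov <- matrix(0L, ng, np)
    both <- gt > 0 & pr > 0
    if (any(both)) {
      tab <- table(gt[both], pr[both])
      ov[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    }
    r <- pair_instances(gt, pr)
    expect_equal(nrow(r$pairs), bruteforce_optimal_pairing(ov))
    # bookkeeping invariants: TP + FN covers every gt instance exactly once
    expect_equal(nrow(r$pairs) + length(r$fn), ng)
    expect_equal(nrow(r$pairs) + length(r$fp), np)
    expect_false(any(duplicated(r$pairs$gt)))
    expect_false(any(duplicated(r$pairs$pred)))
  }
})

test_that("patient metrics match hand-computed contingencies", {
  cfg <- eval_config()
  gt <- array(0L, c(12, 12, 6))
  gt[2:5, 2:5, 2:4] <- 1L  # 48 voxels
  # perfect prediction
  r <- patient_metrics(gt, array(as.numeric(gt > 0), dim(gt)), cfg)
  sub <- r[r$pt < 1, ]
  expect_true(all(sub$dice == 100 & sub$dice_tp == 100 &
                    sub$fp == 0 & sub$fn == 0))
  # prediction = gt plus a distant equal-sized blob: Dice 2/3, Dice-TP 100
  pr <- array(0, dim(gt))
  pr[2:5, 2:5, 2:4] <- 1
  pr[8:11, 8:11, 2:4] <- 1
  r2 <- patient_metrics(gt, pr, cfg)
  row5 <- r2[r2$pt == 0.5, ]
  expect_equal(row5$dice, 100 * 2 * 48 / (48 + 96), tolerance = 1e-9)
  expect_equal(row5$dice_tp, 100)
  expect_equal(row5$fp, 1)
  # empty prediction
  r3 <- patient_metrics(gt, array(0, dim(gt)), cfg)
  expect_true(all(r3$dice == 0 & r3$tp == 0 & r3$fn == 1))
  expect_true(all(is.na(r3$dice_tp)))
  # Dice-TP >= Dice whenever a TP exists alongside FP voxels
  expect_true(all(r2$dice_tp[r2$tp > 0] >= r2$dice[r2$tp > 0]))
})

test_that("cohort metrics aggregate instance counts per fold", {
  mk <- function(tp, fp, fn, dice) {
    data.frame(pt = 0.5, dice = dice, dice_tp = ifelse(tp > 0, dice, NA),
               tp = tp, fp = fp, fn = fn, gt_volume_ml = 5)
  }
  # fold with TP=9, FN=1, FP=0 across patients
  tabs <- list(mk(4, 0, 1, 90), mk(5, 0, 0, 95))
  cm <- cohort_metrics(tabs)
  expect_equal(cm$recall, 90)
  expect_equal(cm$precision, 100)
  expect_equal(cm$f1, 2 * 100 * 90 / 190, tolerance = 1e-9)
  # all perfect
  cm2 <- cohort_metrics(list(mk(1, 0, 0, 100), mk(2, 0, 0, 100)))
  expect_true(all(c(cm2$recall, cm2$precision, cm2$f1, cm2$dice) == 100))
  # zero predictions: precision undefined, not zero
  cm3 <- cohort_metrics(list(mk(0, 0, 2, 0)))
  expect_true(is.na(cm3$precision))
  expect_equal(cm3$recall, 0)
})

test_that("pooled estimates weight folds by size", {
  mk_fold <- function(recall, n) {
    data.frame(pt = 0.4, recall = recall, precision = 90, f1 = 90,
               dice = recall, dice_tp = recall, tp = 1, fp = 0, fn = 0,
               n_patients = n)
  }
  folds <- lapply(c(80, 82, 84, 86, 88), mk_fold, n = 10)
  pe <- pooled_estimates(folds)
  expect_equal(pe$recall_mean, 84)
  expect_equal(pe$dice_mean, 84)
  # identical folds: zero spread
  pe2 <- pooled_estimates(lapply(rep(85, 4), mk_fold, n = 10))
  expect_equal(pe2$recall_sd, 0)
  # a single fold: mean passes through, spread undefined
  pe1 <- pooled_estimates(list(mk_fold(77, 10)))
  expect_equal(pe1$recall_mean, 77)
  expect_true(is.na(pe1$recall_sd))
  # unequal folds pull the mean toward the bigger fold
  pe3 <- pooled_estimates(list(mk_fold(80, 30), mk_fold(90, 10)))
  expect_equal(pe3$recall_mean, 82.5)
})

test_that("volume bins are equally populated and split at the cutoff", {
  set.seed(2)
  vols <- rlnorm(20, 1, 1)
  dice <- runif(20, 40, 100)
  r <- volume_binned_report(dice, vols, n_bins = 10, cutoff = 3)
  expect_equal(nrow(r$bins), 10)
  expect_true(all(r$bins$n == 2))
  expect_lte(diff(range(r$bins$n)), 1)
  # bins ordered by volume
  expect_true(all(diff(r$bins$vol_min) >= 0))
  expect_equal(sum(r$cutoff_groups$n), 20)

  r2 <- volume_binned_report(runif(23, 50, 100), rlnorm(23), n_bins = 10)
  expect_lte(diff(range(r2$bins$n)), 1)

  # all volumes above the cutoff: the small group is empty and flagged
  r3 <- volume_binned_report(runif(12, 50, 100), runif(12, 5, 20),
                             n_bins = 10, cutoff = 3)
  expect_equal(r3$cutoff_groups$n[1], 0)
  expect_true(is.na(r3$cutoff_groups$dice_mean[1]))
  expect_error(volume_binned_report(runif(5), runif(5), n_bins = 10),
               "fewer")
})

test_that("operating-threshold selection maximises F1 then Dice", {
  tab <- data.frame(pt = seq(0.1, 1, 0.1),
                    f1 = c(70, 80, 85, 92, 88, 84, 80, 75, 60, 10),
                    dice = 70 + seq(0.1, 1, 0.1))
  expect_equal(select_operating_threshold(tab), 0.4)
  # flat F1: Dice breaks the tie
  tab$f1 <- 90
  tab$dice <- c(70, 72, 74, 76, 78, 77, 75, 73, 71, 69)
  expect_equal(select_operating_threshold(tab), 0.5)
  # result is always a member of the sweep
  set.seed(3)
  for (i in 1:10) {
    tab$f1 <- runif(10)
    tab$dice <- runif(10)
    expect_true(select_operating_threshold(tab) %in% tab$pt)
  }
})
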