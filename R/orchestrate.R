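# Experiment orchestration: experiment naming, YAML configuration,
# single-volume inference and the ablation-grid driver.

.BACKBONE_NAMES <- c(unet = "UNet", agunet = "AGUNet", daunet = "DAUNet",
                     dagunet = "DAGUNet")

#' Compose an experiment name
#'
#' Concatenation of component abbreviations: backbone, `MS` (multi-scale
#' input), `DS` (deep supervision), `AG` (accumulated gradients), `Top`
#' (top-level-loss model selection), `FTL` (Focal Tversky loss).
#'
#' @param arch_cfg an [arch_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()] (`AG` when `accum_steps > 1`,
#'   `Top` when selecting on the top-level loss).
#' @return experiment name string, e.g. `"AGUNet-MS-DS-AG"`.
#' @export
experiment_name <- function(arch_cfg, loss_cfg = loss_config(),
                            train_cfg = train_config(accum_steps = 1L)) {
  parts <- .BACKBONE_NAMES[[arch_cfg$backbone]]
  if (arch_cfg$multiscale) parts <- c(parts, "MS")
  if (arch_cfg$deep_supervision) parts <- c(parts, "DS")
  if (train_cfg$accum_steps > 1L || arch_cfg$accum_grad) {
    parts <- c(parts, "AG")
  }
  if (train_cfg$selection == "top_level_loss") parts <- c(parts, "Top")
  if (loss_cfg$kind == "focal_tversky") parts <- c(parts, "FTL")
  paste(parts, collapse = "-")
}

#' Parse an experiment name back to its toggles
#'
#' @param name experiment name from [experiment_name()].
#' @return list with `backbone`, `multiscale`, `deep_supervision`,
#'   `accum_grad`, `top_selection`, `focal_tversky`.
#' @export
parse_experiment_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  bk <- names(.BACKBONE_NAMES)[match(parts[1], .BACKBONE_NAMES)]
  if (is.na(bk)) stop("unknown backbone in experiment name: ", parts[1])
  rest <- parts[-1]
  bad <- setdiff(rest, c("MS", "DS", "AG", "Top", "FTL"))
  if (length(bad)) stop("unknown experiment tags: ",
                        paste(bad, collapse = ", "))
  list(backbone = bk, multiscale = "MS" %in% rest,
       deep_supervision = "DS" %in% rest, accum_grad = "AG" %in% rest,
       top_selection = "Top" %in% rest, focal_tversky = "FTL" %in% rest)
}

#' Read an experiment configuration from YAML
#'
#' The file may define `name`, `seed`, and `architecture`, `loss`,
#' `training`, `evaluation` blocks whose keys mirror the corresponding
#' configuration constructors.
#'
#' @param path YAML file.
#' @return list with `name`, `seed`, `arch_cfg`, `loss_cfg`, `train_cfg`,
#'   `eval_cfg`, `data` (paths, as given).
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  a <- y$architecture
  arch_cfg <- arch_config(
    backbone = a$backbone %||% "unet",
    levels = a$levels %||% 5L,
    filters = a$filters,
    multiscale = a$multiscale %||% FALSE,
    deep_supervision = a$deep_supervision %||% FALSE,
    input_shape = a$input_shape %||% c(128L, 128L, 144L),
    n_classes = a$n_classes %||% 2L)
  lo <- y$loss
  loss_cfg <- loss_config(
    kind = lo$kind %||% "dice",
    tversky_alpha = lo$alpha %||% 0.7,
    tversky_beta = lo$beta %||% 0.3,
    focal_gamma = lo$gamma %||% 2.0)
  tr <- y$training
  train_cfg <- train_config(
    learning_rate = tr$learning_rate %||% 1e-3,
    batch_size = tr$batch_size %||% 2L,
    accum_steps = tr$accum_steps %||% 16L,
    patience = tr$patience %||% 30L,
    max_epochs = tr$max_epochs %||% 1000L,
    selection = tr$selection %||% "total_loss",
    seed = tr$seed %||% y$seed %||% 1L)
  ev <- y$evaluation
  eval_cfg <- eval_config(
    thresholds = ev$thresholds %||% seq(0.1, 1, by = 0.1),
    connectivity = ev$connectivity %||% 26L,
    n_bins = ev$n_bins %||% 10L,
    clinical_cutoff = ev$clinical_cutoff %||% 3)
  list(name = y$name %||% experiment_name(arch_cfg, loss_cfg, train_cfg),
       seed = y$seed %||% 1L, arch_cfg = arch_cfg, loss_cfg = loss_cfg,
       train_cfg = train_cfg, eval_cfg = eval_cfg, data = y$data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a single volume
#'
#' Preprocess, forward pass, restoration to the native reference frame and
#' thresholding at the operating probability threshold.
#'
#' @param model an `attunet_model`.
#' @param weights trained weights.
#' @param image an image [volume_grid()] (or path to a NIfTI file).
#' @param pt operating probability threshold.
#' @param target_spacing,target_shape preprocessing geometry; the shape
#'   defaults to the model's configured input shape.
#' @return list with `prob` and `mask` [volume_grid()]s in the native
#'   frame, and the stage `timings` (seconds).
#' @export
predict_volume <- function(model, weights, image, pt = 0.5,
                           target_spacing = 1.0, target_shape = NULL) {
  if (is.character(image)) image <- read_volume(image)
  if (is.null(target_shape)) target_shape <- model$config$input_shape
  t0 <- proc.time()[[3]]
  pp <- preprocess(image, target_spacing, target_shape)
  t1 <- proc.time()[[3]]
  fw <- forward_model(model, weights, promote4d(pp$tensor),
                      training = FALSE)
  prob_net <- fw$output$value[, , , 2]
  t2 <- proc.time()[[3]]
  prob <- restore_to_native(prob_net, pp$record)
  mask <- volume_grid(array(as.integer(prob$data >= pt), dim(prob$data)),
                      prob$spacing, is_label = TRUE)
  t3 <- proc.time()[[3]]
  list(prob = prob, mask = mask,
       timings = c(preprocess = t1 - t0, inference = t2 - t1,
                   restore = t3 - t2))
}

#' Run an ablation grid
#'
#' Trains and evaluates each experiment with cross-validation on the same
#' cohort and fold assignment, then reports one comparison row per
#' experiment: the selected PT and pooled Dice, Dice-TP, F1, recall and
#' precision at that PT.
#'
#' @param experiments named list; each element is a list with `arch_cfg`
#'   and optionally `loss_cfg`, `train_cfg`.
#' @param cases phantom cases shared by all experiments.
#' @param manifest manifest with fold assignment, shared by all
#'   experiments.
#' @param eval_cfg an [eval_config()].
#' @param target_spacing,target_shape preprocessing geometry.
#' @return data.frame, one row per experiment.
#' @export
run_ablation <- function(experiments, cases, manifest,
                         eval_cfg = eval_config(),
                         target_spacing = 1.0,
                         target_shape = c(128L, 128L, 144L)) {
  if (is.null(manifest$fold)) stop("manifest lacks fold assignment")
  rows <- lapply(names(experiments), function(nm) {
    ex <- experiments[[nm]]
    loss_cfg <- ex$loss_cfg %||% loss_config()
    train_cfg <- ex$train_cfg %||% train_config()
    cv <- run_cross_validation(cases, manifest, ex$arch_cfg, loss_cfg,
                               train_cfg, target_spacing, target_shape)
    fold_tables <- lapply(cv, function(fold) {
      pts <- lapply(seq_along(fold$test_idx), function(j) {
        i <- fold$test_idx[j]
        patient_metrics(cases[[i]]$labels$data, fold$predictions[[j]]$data,
                        eval_cfg, cases[[i]]$labels$spacing)
      })
      cohort_metrics(pts)
    })
    pooled <- pooled_estimates(fold_tables)
    pt <- select_operating_threshold(pooled)
    at <- pooled[pooled$pt == pt, ]
    data.frame(experiment = nm, pt = pt,
               dice = at$dice_mean, dice_sd = at$dice_sd,
               dice_tp = at$dice_tp_mean, f1 = at$f1_mean,
               recall = at$recall_mean, precision = at$precision_mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
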