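# Optimisation: Adam with accumulated gradients (micro-batches evaluated at
# identical weights, gradients averaged, one update per effective batch),
# early stopping on the validation selection loss, and five-fold
# cross-validation orchestration.

#' Training configuration
#'
#' @param learning_rate Adam initial learning rate.
#' @param batch_size samples per micro-batch.
#' @param accum_steps accumulated-gradient steps `n`; the effective batch is
#'   `batch_size * accum_steps` and one optimiser update is applied per
#'   effective batch. `1` disables accumulation.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param selection checkpoint selection criterion: the total validation
#'   loss (`L_Tot` when deep supervision is on) or the loss of the
#'   top-resolution head only (the "Top" variant).
#' @param clip_norm global gradient-norm clip applied to the effective
#'   (accumulated) gradient before each update; `Inf` disables clipping.
#' @param seed RNG seed for shuffling, dropout and augmentation.
#' @param augment optional [augment_config()]; `NULL` disables
#'   augmentation. Validation is always computed without augmentation.
#' @param target_val_dice optional early-exit: stop once the validation
#'   soft Dice of the top head reaches this value.
#' @param target_train_dice optional companion early-exit on the training
#'   soft Dice of the top head; when both targets are set, training stops
#'   only once both are met.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 2L,
                         accum_steps = 16L, patience = 30L,
                         max_epochs = 1000L,
                         selection = c("total_loss", "top_level_loss"),
                         clip_norm = 1, seed = 1L, augment = NULL,
                         target_val_dice = NULL,
                         target_train_dice = NULL) {
  selection <- match.arg(selection)
  stopifnot(accum_steps >= 1, patience >= 1, batch_size >= 1, clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 accum_steps = as.integer(accum_steps),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 selection = selection, clip_norm = clip_norm,
                 seed = as.integer(seed),
                 augment = augment, target_val_dice = target_val_dice,
                 target_train_dice = target_train_dice),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(weights, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0))
}

adam_step <- function(state, weights, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    weights[[nm]] <- weights[[nm]] -
      state$lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) +
                                           state$eps)
  }
  list(state = state, weights = weights)
}

.grads_axpy <- function(acc, g, a) {
  if (is.null(acc)) return(lapply(g, function(x) a * x))
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + a * g[[nm]]
  acc
}

#' Loss and gradients of a model on one batch
#'
#' The batch loss is the mean of per-sample losses; with deep supervision
#' the per-sample loss is the uniformly weighted head sum `L_Tot`.
#'
#' @param model an `attunet_model`.
#' @param weights flat weight list.
#' @param batch list of samples, each `list(x = input array, y = one-hot
#'   ground truth at full resolution)`.
#' @param loss_cfg a [loss_config()].
#' @param training logical (enables dropout).
#' @return list with `loss`, `grads`, `per_level` (mean per-head losses,
#'   finest first).
#' @export
model_batch_gradients <- function(model, weights, batch, loss_cfg,
                                  training = TRUE) {
  n <- length(batch)
  acc <- NULL
  loss <- 0
  per <- NULL
  for (s in batch) {
    fw <- forward_model(model, weights, s$x, training = training)
    tl <- tn_total_loss(fw$tape, fw$heads, s$y, loss_cfg)
    g <- backprop(fw$tape, tl$total)
    acc <- .grads_axpy(acc, g, 1 / n)
    loss <- loss + tl$total$value / n
    per <- if (is.null(per)) tl$per_level / n else per + tl$per_level / n
  }
  list(loss = loss, grads = acc, per_level = per)
}

#' One accumulated-gradient optimisation step
#'
#' Evaluates `loss_grad_fn` on each micro-batch at identical weights,
#' averages the gradients over the `n` micro-batches and applies exactly
#' one optimiser update, so the applied gradient equals the gradient of the
#' mean loss over the effective batch.
#'
#' @param loss_grad_fn `function(weights, batch) -> list(loss, grads)`.
#' @param weights flat weight list.
#' @param micro_batches non-empty list of batches.
#' @param opt_state Adam state from `adam_new()`.
#' @param clip_norm global-norm clip on the accumulated gradient
#'   (`Inf` = none).
#' @return list with updated `weights`, `opt_state`, mean `loss`.
#' @export
accumulated_gradient_step <- function(loss_grad_fn, weights, micro_batches,
                                      opt_state, clip_norm = Inf) {
  n <- length(micro_batches)
  if (n == 0) stop("micro_batches must be non-empty")
  acc <- NULL
  loss <- 0
  for (mb in micro_batches) {
    r <- loss_grad_fn(weights, mb)
    acc <- .grads_axpy(acc, r$grads, 1 / n)
    loss <- loss + r$loss / n
  }
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(acc, function(g) sum(g^2), 0)))
    if (gn > clip_norm) acc <- lapply(acc, function(g) g * clip_norm / gn)
  }
  st <- adam_step(opt_state, weights, acc)
  list(weights = st$weights, opt_state = st$state, loss = loss)
}

# validation pass: selection losses and top-head soft Dice
.validate <- function(model, weights, val_cases, loss_cfg) {
  tot <- topl <- dsc <- 0
  for (s in val_cases) {
    fw <- forward_model(model, weights, s$x, training = FALSE)
    tl <- tn_total_loss(fw$tape, fw$heads, s$y, loss_cfg)
    tot <- tot + tl$total$value / length(val_cases)
    topl <- topl + tl$per_level[1] / length(val_cases)
    dsc <- dsc + (1 - dice_loss(fw$output$value, s$y)) / length(val_cases)
  }
  list(total = tot, top = topl, dice = dsc)
}

#' Train a model
#'
#' Adam optimisation with accumulated gradients; the checkpoint with the
#' best validation selection loss is kept and training stops after
#' `patience` epochs without improvement.
#'
#' @param model an `attunet_model` (or an [arch_config()]).
#' @param train_cases,val_cases lists of samples `list(x, y)` (input array
#'   and one-hot ground truth).
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `weights` (best checkpoint), `history` (data.frame of
#'   per-epoch train/validation losses), `best_epoch`, `epochs_run`.
#' @export
train_model <- function(model, train_cases, val_cases,
                        loss_cfg = loss_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  if (inherits(model, "arch_config")) model <- build_model(model)
  if (length(train_cases) == 0) stop("empty training set")
  set.seed(train_cfg$seed)
  weights <- init_weights(model, seed = train_cfg$seed)
  opt <- adam_new(weights, lr = train_cfg$learning_rate)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  since_best <- 0L
  hist <- list()
  bs <- train_cfg$batch_size
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(length(train_cases))
    nb <- ceiling(length(ord) / bs)
    batches <- lapply(seq_len(nb), function(i) {
      idx <- ord[((i - 1L) * bs + 1L):min(i * bs, length(ord))]
      lapply(train_cases[idx], function(s) {
        if (!is.null(train_cfg$augment)) {
          dy <- dim(s$y)
          lab <- max.col(matrix(s$y, ncol = dy[4])) - 1L
          dim(lab) <- dy[1:3]
          a <- augment_pair(drop_last_dim(s$x), lab, train_cfg$augment)
          list(x = promote4d(a$image), y = onehot(a$label, dim(s$y)[4]))
        } else s
      })
    })
    tr_loss <- 0
    top_sum <- 0
    i <- 1L
    while (i <= nb) {
      j <- min(i + train_cfg$accum_steps - 1L, nb)
      r <- accumulated_gradient_step(
        function(w, b) {
          g <- model_batch_gradients(model, w, b, loss_cfg, training = TRUE)
          top_sum <<- top_sum + g$per_level[1]
          list(loss = g$loss, grads = g$grads)
        },
        weights, batches[i:j], opt, clip_norm = train_cfg$clip_norm)
      weights <- r$weights
      opt <- r$opt_state
      tr_loss <- tr_loss + r$loss * (j - i + 1L) / nb
      i <- j + 1L
    }
    tr_top <- top_sum / nb
    val <- if (length(val_cases) > 0) {
      .validate(model, weights, val_cases, loss_cfg)
    } else list(total = NA_real_, top = NA_real_, dice = NA_real_)
    sel <- if (train_cfg$selection == "total_loss") val$total else val$top
    if (!is.finite(tr_loss)) stop("non-finite training loss at epoch ",
                                  epoch)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                train_top_loss = tr_top,
                                val_loss = val$total, val_top_loss = val$top,
                                val_dice = val$dice)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val-dice %.4f",
                      epoch, tr_loss, val$total, val$dice))
    }
    if (is.finite(sel) && sel < best$loss) {
      best <- list(loss = sel, weights = weights, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    val_ok <- is.null(train_cfg$target_val_dice) ||
      (is.finite(val$dice) && val$dice >= train_cfg$target_val_dice)
    train_ok <- is.null(train_cfg$target_train_dice) ||
      (1 - tr_top) >= train_cfg$target_train_dice
    if ((!is.null(train_cfg$target_val_dice) ||
         !is.null(train_cfg$target_train_dice)) && val_ok && train_ok) break
    if (since_best >= train_cfg$patience) break
  }
  list(weights = best$weights, history = do.call(rbind, hist),
       best_epoch = best$epoch, epochs_run = length(hist))
}

drop_last_dim <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

promote4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' One-hot encode an integer label array
#' @param label 3D array of class indices (0 = background).
#' @param n_classes number of classes.
#' @return array `(dim(label), n_classes)`.
#' @export
onehot <- function(label, n_classes = 2L) {
  d <- dim(label)
  out <- array(0, dim = c(d, n_classes))
  for (c in seq_len(n_classes)) {
    out[, , , c] <- as.numeric(label == (c - 1L))
  }
  out
}

#' Five-fold cross-validation
#'
#' At every iteration `k - 2` folds train, one validates and one tests;
#' every fold is the test fold exactly once. Test predictions are restored
#' to each case's native frame for evaluation.
#'
#' @param cases list of `phantom_case` objects (or any objects with
#'   `image` / `labels` [volume_grid()]s).
#' @param manifest manifest with a `fold` column from [assign_folds()].
#' @param arch_cfg an [arch_config()].
#' @param loss_cfg,train_cfg loss and training configurations.
#' @param target_spacing,target_shape preprocessing geometry.
#' @return list of per-fold results: `weights`, `history`, `test_ids`,
#'   `predictions` (native-space probability [volume_grid()]s).
#' @export
run_cross_validation <- function(cases, manifest, arch_cfg,
                                 loss_cfg = loss_config(),
                                 train_cfg = train_config(),
                                 target_spacing = 1.0,
                                 target_shape = c(128L, 128L, 144L)) {
  if (is.null(manifest$fold)) stop("manifest lacks fold assignment")
  k <- max(manifest$fold)
  prepped <- lapply(cases, function(cs) {
    pp <- preprocess(cs$image, target_spacing, target_shape)
    lab <- preprocess_label(cs$labels, pp$record)
    list(x = promote4d(pp$tensor),
         y = onehot(array(as.numeric(lab > 0), dim(lab)),
                    arch_cfg$n_classes),
         record = pp$record)
  })
  lapply(seq_len(k), function(fi) {
    test_idx <- which(manifest$fold == fi)
    val_fold <- fi %% k + 1L
    val_idx <- which(manifest$fold == val_fold)
    train_idx <- setdiff(seq_along(cases), c(test_idx, val_idx))
    fit <- train_model(arch_cfg, prepped[train_idx], prepped[val_idx],
                       loss_cfg, train_cfg)
    preds <- lapply(test_idx, function(i) {
      fw <- forward_model(build_model(arch_cfg), fit$weights,
                          prepped[[i]]$x, training = FALSE)
      prob <- fw$output$value[, , , 2]
      restore_to_native(prob, prepped[[i]]$record)
    })
    list(fold = fi, weights = fit$weights, history = fit$history,
         best_epoch = fit$best_epoch, test_ids = manifest$case_id[test_idx],
         test_idx = test_idx, predictions = preds)
  })
}
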