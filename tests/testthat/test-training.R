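# Optimisation: accumulated gradients, early stopping, cross-validation.

# norm-free two-layer dense toy model built on the tape primitives: the loss
# is the mean squared error over the batch, so batch gradients are means
toy_loss_grad <- function(weights, batch) {
  tp <- attunet3d:::tape_new()
  W1 <- attunet3d:::tn_param(tp, weights$W1, "W1")
  b1 <- attunet3d:::tn_param(tp, weights$b1, "b1")
  W2 <- attunet3d:::tn_param(tp, weights$W2, "W2")
  b2 <- attunet3d:::tn_param(tp, weights$b2, "b2")
  X <- do.call(rbind, lapply(batch, `[[`, "x"))
  Yt <- do.call(rbind, lapply(batch, `[[`, "y"))
  h <- attunet3d:::tn_relu(tp, attunet3d:::tn_bias_row(
    tp, attunet3d:::tn_matmul(tp, attunet3d:::tn_input(tp, X), W1), b1))
  out <- attunet3d:::tn_bias_row(tp, attunet3d:::tn_matmul(tp, h, W2), b2)
  loss <- attunet3d:::tn_mean_sq_diff(tp, out, Yt)
  grads <- attunet3d:::backprop(tp, loss)
  list(loss = loss$value, grads = grads)
}

toy_weights <- function(seed = 1, d = 5, hdim = 7, m = 3) {
  set.seed(seed)
  list(W1 = matrix(rnorm(d * hdim, sd = 0.5), d, hdim), b1 = rnorm(hdim),
       W2 = matrix(rnorm(hdim * m, sd = 0.5), hdim, m), b2 = rnorm(m))
}

toy_data <- function(n, seed = 2, d = 5, m = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(x = matrix(rnorm(d), 1, d), y = matrix(rnorm(m), 1, m))
  })
}

test_that("16 accumulated micro-batches of 2 equal one 32-sample batch", {
  w <- toy_weights()
  samples <- toy_data(32)
  micro <- lapply(seq_len(16), function(i) samples[(2 * i - 1):(2 * i)])
  direct <- toy_loss_grad(w, samples)
  acc <- NULL
  for (mb in micro) {
    r <- toy_loss_grad(w, mb)
    acc <- attunet3d:::.grads_axpy(acc, r$grads, 1 / 16)
  }
  for (nm in names(acc)) {
    expect_lt(max(abs(acc[[nm]] - direct$grads[[nm]])) /
                max(abs(direct$grads[[nm]])), 1e-10)
  }
})

test_that("one accumulated step equals one large-batch Adam step", {
  w <- toy_weights()
  samples <- toy_data(32)
  micro <- lapply(seq_len(16), function(i) samples[(2 * i - 1):(2 * i)])
  r_acc <- accumulated_gradient_step(toy_loss_grad, w, micro,
                                     attunet3d:::adam_new(w, lr = 1e-3))
  direct <- toy_loss_grad(w, samples)
  r_dir <- attunet3d:::adam_step(attunet3d:::adam_new(w, lr = 1e-3), w,
                                 direct$grads)
  for (nm in names(w)) {
    expect_lt(max(abs(r_acc$weights[[nm]] - r_dir$weights[[nm]])) /
                max(abs(r_dir$weights[[nm]])), 1e-5)
  }
  expect_error(accumulated_gradient_step(toy_loss_grad, w, list(),
                                         attunet3d:::adam_new(w)),
               "non-empty")
  # n = 1: a plain optimiser step
  r1 <- accumulated_gradient_step(toy_loss_grad, w, list(samples[1:2]),
                                  attunet3d:::adam_new(w, lr = 1e-3))
  d1 <- toy_loss_grad(w, samples[1:2])
  p1 <- attunet3d:::adam_step(attunet3d:::adam_new(w, lr = 1e-3), w,
                              d1$grads)
  expect_equal(r1$weights, p1$weights, tolerance = 1e-12)
})

tiny_cases <- function(n, seed = 1) {
  dist <- calibrate_volume_distribution(3, 1.5, 0.5, 8)
  spec <- quiet_spec(grid_shape = c(16, 16, 16), spacing = c(2, 2, 2))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    rasterize_case(spec, sample_tumor_volume(dist, 1),
                   case_id = sprintf("c%02d", i))
  })
}

test_that("training runs, improves the loss and is seed-reproducible", {
  cases <- lapply(tiny_cases(6), case_to_sample)
  cfg <- arch_config("unet", levels = 2, filters = c(2, 4),
                     input_shape = c(16, 16, 16))
  tc <- train_config(batch_size = 2, accum_steps = 1, patience = 5,
                     max_epochs = 3, seed = 3)
  fit1 <- train_model(cfg, cases[1:4], cases[5:6], loss_config(), tc)
  fit2 <- train_model(cfg, cases[1:4], cases[5:6], loss_config(), tc)
  expect_equal(fit1$history$train_loss[1], fit2$history$train_loss[1])
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_equal(nrow(fit1$history), 3)
  expect_error(train_model(cfg, list(), cases[5:6], loss_config(), tc),
               "empty")
})

test_that("early stopping halts patience epochs after the best epoch", {
  # the counter logic in isolation: a validation loss that stops improving
  # at epoch 5 with patience 3 stops at epoch 8
  losses <- c(1.0, 0.8, 0.6, 0.5, 0.4, rep(0.4 + 1e-9, 20))
  best <- Inf
  since <- 0L
  stopped <- NA
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= 3L) {
      stopped <- e
      break
    }
  }
  expect_equal(stopped, 8)

  # and in train_model itself: with patience 2 on a tiny problem the run
  # ends no later than best_epoch + 2
  cases <- lapply(tiny_cases(4, seed = 9), case_to_sample)
  cfg <- arch_config("unet", levels = 2, filters = c(2, 2),
                     input_shape = c(16, 16, 16))
  tc <- train_config(batch_size = 2, accum_steps = 1, patience = 2,
                     max_epochs = 12, seed = 4)
  fit <- train_model(cfg, cases[1:2], cases[3:4], loss_config(), tc)
  expect_lte(fit$epochs_run, fit$best_epoch + 2)
  # the checkpoint is never worse than any later validation selection loss
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("cross-validation partitions cases correctly", {
  cases <- tiny_cases(6, seed = 5)
  man <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                    total_volume_ml = vapply(cases, function(cs) {
                      cs$tumors[[1]]$volume_ml
                    }, 0))
  man <- assign_folds(man, k = 3)
  cfg <- arch_config("unet", levels = 2, filters = c(2, 2),
                     input_shape = c(16, 16, 16))
  tc <- train_config(batch_size = 2, accum_steps = 1, patience = 1,
                     max_epochs = 1, seed = 5)
  cv <- run_cross_validation(cases, man, cfg, loss_config(), tc,
                             target_spacing = 2.0,
                             target_shape = c(16, 16, 16))
  expect_length(cv, 3)
  tested <- sort(unlist(lapply(cv, `[[`, "test_ids")))
  expect_equal(tested, sort(man$case_id))  # every case tested exactly once
  for (fold in cv) {
    expect_length(fold$predictions, 2)
    p <- fold$predictions[[1]]
    expect_equal(dim(p$data), c(16, 16, 16))  # native frame
    expect_true(all(p$data >= 0 & p$data <= 1))
  }
})
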