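# Network graphs, attention mechanisms and parameter counting.

test_that("every backbone x MS x DS combination builds and runs forward", {
  set.seed(1)
  x <- array(runif(32 * 32 * 48), c(32, 32, 48, 1))
  for (bk in c("unet", "agunet", "daunet", "dagunet")) {
    for (ms in c(FALSE, TRUE)) {
      for (ds in c(FALSE, TRUE)) {
        cfg <- arch_config(bk, levels = 3, filters = c(2, 4, 8),
                           multiscale = ms, deep_supervision = ds,
                           input_shape = c(32, 32, 48))
        m <- build_model(cfg)
        w <- init_weights(m, 1)
        fw <- forward_model(m, w, x)
        expect_equal(dim(fw$output$value), c(32, 32, 48, 2))
        expect_equal(length(fw$heads), if (ds) 2L else 1L)
        # per-voxel softmax at every head
        for (h in fw$heads) {
          sums <- rowSums(matrix(h$value, ncol = 2))
          expect_lt(max(abs(sums - 1)), 1e-9)
          expect_gte(min(h$value), 0)
          expect_lte(max(h$value), 1)
        }
      }
    }
  }
})

test_that("deep-supervision heads sit at halved resolutions", {
  cfg <- arch_config("agunet", levels = 4, filters = c(2, 4, 8, 8),
                     multiscale = TRUE, deep_supervision = TRUE,
                     input_shape = c(32, 32, 32))
  m <- build_model(cfg)
  w <- init_weights(m, 2)
  fw <- forward_model(m, w, array(0.3, c(32, 32, 32, 1)))
  expect_equal(length(fw$heads), 3L)
  expect_equal(lapply(fw$heads, function(h) dim(h$value)[1:3]),
               list(c(32, 32, 32), c(16, 16, 16), c(8, 8, 8)))
})

test_that("weight initialisation is reproducible and seed-dependent", {
  m <- build_model(arch_config("agunet", levels = 3, filters = c(2, 4, 8),
                               input_shape = c(16, 16, 16)))
  expect_identical(init_weights(m, 7), init_weights(m, 7))
  expect_false(identical(init_weights(m, 7), init_weights(m, 8)))
})

test_that("full-size parameter counts reproduce the published figures", {
  tab <- list(
    list(arch_config("unet"), 5.89),
    list(arch_config("agunet"), 16.41),
    list(arch_config("agunet", deep_supervision = TRUE), 16.41),
    list(arch_config("agunet", multiscale = TRUE, deep_supervision = TRUE),
         18.66),
    list(arch_config("daunet", multiscale = TRUE, deep_supervision = TRUE),
         25.72),
    list(arch_config("dagunet", multiscale = TRUE, deep_supervision = TRUE),
         30.96))
  for (row in tab) {
    expect_equal(round(count_parameters(row[[1]]) / 1e6, 2), row[[2]])
  }
})

test_that("toggles change parameter counts in the expected direction", {
  base <- count_parameters(arch_config("agunet"))
  ms <- count_parameters(arch_config("agunet", multiscale = TRUE))
  expect_gt(ms, base)
  # the accumulated-gradients tag is a training strategy and adds nothing
  expect_equal(count_parameters(arch_config("agunet", multiscale = TRUE,
                                            deep_supervision = TRUE,
                                            accum_grad = TRUE)),
               count_parameters(arch_config("agunet", multiscale = TRUE,
                                            deep_supervision = TRUE)))
  # DAGUNet differs from DAUNet only by the propagation path
  dau <- build_model(arch_config("daunet", multiscale = TRUE,
                                 deep_supervision = TRUE))
  dag <- build_model(arch_config("dagunet", multiscale = TRUE,
                                 deep_supervision = TRUE))
  extra <- setdiff(vapply(dag$layers, `[[`, "", "name"),
                   vapply(dau$layers, `[[`, "", "name"))
  expect_true(all(grepl("^prop", extra)))
})

test_that("attention gate output is elementwise bounded by the skip", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  g <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4))
  w <- list(wx = matrix(rnorm(2 * 2), 2, 2), bx = rnorm(2),
            wg = matrix(rnorm(2 * 4), 2, 4), bg = rnorm(2),
            psi = matrix(rnorm(2), 1, 2), bpsi = rnorm(1))
  r <- attention_gate(x, g, w)
  expect_true(all(abs(r$gated) <= abs(x) + 1e-12))
  expect_true(all(r$coefficients > 0 & r$coefficients < 1))

  # saturated gate (huge psi bias) passes the skip through unchanged
  w_open <- w
  w_open$bpsi <- 50
  r_open <- attention_gate(x, g, w_open)
  expect_equal(r_open$gated, x, tolerance = 1e-9)
  # blocked gate (large negative bias) suppresses everything
  w_shut <- w
  w_shut$bpsi <- -50
  expect_lt(max(abs(attention_gate(x, g, w_shut)$gated)), 1e-9)
})

test_that("position attention equals the brute-force double loop", {
  set.seed(4)
  f <- array(rnorm(2 * 2 * 1 * 4), c(2, 2, 1, 4))
  w <- list(q = matrix(rnorm(2 * 4), 2, 4), bq = rnorm(2),
            k = matrix(rnorm(2 * 4), 2, 4), bk = rnorm(2),
            v = matrix(rnorm(4 * 4), 4, 4), bv = rnorm(4))
  got <- position_attention(f, w, scale = 0.7)
  want <- bruteforce_position_attention(f, w, scale = 0.7)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)

  f2 <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  w2 <- list(q = matrix(rnorm(1 * 4), 1, 4), bq = rnorm(1),
             k = matrix(rnorm(1 * 4), 1, 4), bk = rnorm(1),
             v = matrix(rnorm(4 * 4), 4, 4), bv = rnorm(4))
  expect_lt(max(abs(position_attention(f2, w2, 0.3) -
                      bruteforce_position_attention(f2, w2, 0.3))), 1e-8)

  # residual identity at initialisation (scale 0)
  expect_equal(position_attention(f, w, scale = 0), f)
  # single voxel: softmax over one position, still the identity at init
  f1 <- array(rnorm(4), c(1, 1, 1, 4))
  expect_equal(position_attention(f1, w, scale = 0), f1)
})

test_that("channel attention equals the brute-force double loop", {
  set.seed(5)
  f <- array(rnorm(3 * 2 * 2 * 4), c(3, 2, 2, 4))
  expect_lt(max(abs(channel_attention(f, 0.5) -
                      bruteforce_channel_attention(f, 0.5))), 1e-8)
  expect_equal(channel_attention(f, 0), f)
  f1 <- array(rnorm(8), c(2, 2, 2, 1))  # C = 1: affinity is [1]
  expect_equal(channel_attention(f1, 0.9),
               bruteforce_channel_attention(f1, 0.9))
})

test_that("position attention refuses oversized affinities", {
  f <- array(0, c(40, 40, 40, 1))
  w <- list(q = matrix(0, 1, 1), bq = 0, k = matrix(0, 1, 1), bk = 0,
            v = matrix(0, 1, 1), bv = 0)
  expect_error(position_attention(f, w), "too large")
})

test_that("the dual attention block composes its branches as documented", {
  set.seed(6)
  C <- 4
  f <- array(rnorm(2 * 2 * 2 * C), c(2, 2, 2, C))
  cfg <- arch_config("daunet", levels = 2, filters = c(2, C),
                     input_shape = c(8, 8, 8))
  w <- init_weights(build_model(cfg), 6)
  afm <- dual_attention_block(f, w, dropout_rate = 0.5, training = FALSE)
  # at init the residual scales are zero, so each branch reduces to its
  # input conv followed by the output transform
  conv <- function(x, nm) {
    attunet3d:::cpp_conv3_fwd(x, dim(x), w[[paste0(nm, ".W")]],
                              w[[paste0(nm, ".b")]], 3L)
  }
  relu <- function(x) x * (x > 0)
  want <- conv(relu(conv(f, "da_in_p")), "da_out_p") +
    conv(relu(conv(f, "da_in_c")), "da_out_c")
  expect_equal(afm, want, tolerance = 1e-10)

  # training with dropout rate 1 zeroes the attention maps entirely, so
  # only the output-transform biases remain
  afm1 <- dual_attention_block(f, w, dropout_rate = 1, training = TRUE)
  bias_only <- conv(array(0, dim(f)), "da_out_p") +
    conv(array(0, dim(f)), "da_out_c")
  expect_equal(afm1, bias_only, tolerance = 1e-12)
})

test_that("spatial dropout zeroes whole channels", {
  tp <- attunet3d:::tape_new()
  x <- attunet3d:::tn_input(tp, array(1, c(4, 4, 4, 8)))
  set.seed(8)
  y <- attunet3d:::tn_dropout_spatial(tp, x, 0.5, TRUE)$value
  per_channel <- apply(y, 4, function(ch) length(unique(as.vector(ch))))
  expect_true(all(per_channel == 1))  # each channel all-kept or all-zero
  expect_true(any(apply(y, 4, sum) == 0))
})

test_that("multi-scale pyramid halves shapes and preserves constants", {
  x <- array(2.5, c(16, 16, 24))
  pyr <- multiscale_pyramid(x, 3)
  expect_equal(dim(pyr[[1]])[1:3], c(16, 16, 24))
  expect_equal(dim(pyr[[2]])[1:3], c(8, 8, 12))
  expect_equal(dim(pyr[[3]])[1:3], c(4, 4, 6))
  for (p in pyr) expect_true(all(abs(p - 2.5) < 1e-12))
})

test_that("AFM propagation feeds every decoder level of DAGUNet", {
  dag <- build_model(arch_config("dagunet", levels = 5,
                                 input_shape = c(32, 32, 32)))
  nms <- vapply(dag$layers, `[[`, "", "name")
  expect_true(all(sprintf("prop%d", 1:4) %in% nms))
  # the decoder conv1 of dagunet widens by exactly the propagated channels
  dau <- build_model(arch_config("daunet", levels = 5,
                                 input_shape = c(32, 32, 32)))
  for (l in 1:4) {
    c_dag <- Filter(function(x) x$name == sprintf("dec%d_conv1", l),
                    dag$layers)[[1]]
    c_dau <- Filter(function(x) x$name == sprintf("dec%d_conv1", l),
                    dau$layers)[[1]]
    expect_equal(c_dag$cin - c_dau$cin, dag$config$filters[l])
  }
})

test_that("model gradients agree with finite differences", {
  set.seed(9)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8, 1))
  lab <- array(0L, c(8, 8, 8))
  lab[3:5, 3:5, 3:5] <- 1L
  y <- onehot(lab, 2)
  for (bk in c("agunet", "dagunet")) {
    cfg <- arch_config(bk, levels = 3, filters = c(2, 3, 4),
                       multiscale = TRUE, deep_supervision = TRUE,
                       input_shape = c(8, 8, 8))
    m <- build_model(cfg)
    w <- init_weights(m, 2)
    expect_lt(fd_gradient_check(m, w, x, y, loss_config()), 1e-4)
  }
})
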