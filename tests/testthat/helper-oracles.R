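# Independent oracles and small fixtures shared across the suite.

# brute-force position attention: explicit double loop over all N x N
# position pairs (no matrix algebra), residual scale included
bruteforce_position_attention <- function(f, w, scale = 0) {
  d <- dim(f)
  n <- prod(d[1:3])
  C <- d[4]
  m <- matrix(f, nrow = n)
  q <- sweep(m %*% t(w$q), 2, w$bq, `+`)
  k <- sweep(m %*% t(w$k), 2, w$bk, `+`)
  v <- sweep(m %*% t(w$v), 2, w$bv, `+`)
  out <- matrix(0, n, C)
  for (i in seq_len(n)) {
    e <- numeric(n)
    for (j in seq_len(n)) e[j] <- sum(q[i, ] * k[j, ])
    e <- exp(e - max(e))
    a <- e / sum(e)
    for (c in seq_len(C)) out[i, c] <- sum(a * v[, c])
  }
  res <- scale * out + m
  array(res, dim = d)
}

# brute-force channel attention: explicit double loop over channel pairs
bruteforce_channel_attention <- function(f, scale = 0) {
  d <- dim(f)
  n <- prod(d[1:3])
  C <- d[4]
  m <- matrix(f, nrow = n)
  out <- matrix(0, n, C)
  for (ci in seq_len(C)) {
    e <- numeric(C)
    for (cj in seq_len(C)) e[cj] <- sum(m[, ci] * m[, cj])
    e <- exp(e - max(e))
    a <- e / sum(e)
    for (p in seq_len(n)) out[p, ci] <- sum(a * m[p, ])
  }
  res <- scale * out + m
  array(res, dim = d)
}

# exhaustive optimal one-to-one instance assignment maximising total overlap
# (permutation search; instances <= 5 x 5)
bruteforce_optimal_pairing <- function(overlap) {
  ng <- nrow(overlap)
  np <- ncol(overlap)
  k <- min(ng, np)
  best <- 0
  gsets <- utils::combn(seq_len(ng), k, simplify = FALSE)
  psets <- utils::combn(seq_len(np), k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (gs in gsets) for (ps in psets) for (pp in perms(ps)) {
    tot <- sum(overlap[cbind(gs, pp)] > 0)
    if (tot > best) best <- tot
  }
  best
}

# numeric-vs-analytic gradient comparison on a random subset of weights;
# weights are jittered away from zero first so no ReLU argument sits exactly
# on its kink (finite differences are ill-defined there)
fd_gradient_check <- function(model, weights, x, y, loss_cfg, n_checks = 6,
                              h = 1e-5) {
  weights <- lapply(weights, function(w) {
    w + stats::rnorm(length(w), sd = 0.05)
  })
  lossfn <- function(w) {
    fw <- forward_model(model, w, x)
    attunet3d:::tn_total_loss(fw$tape, fw$heads, y, loss_cfg)$total$value
  }
  g <- model_batch_gradients(model, weights, list(list(x = x, y = y)),
                             loss_cfg, training = FALSE)
  worst <- 0
  for (nm in sample(names(weights), min(n_checks, length(weights)))) {
    i <- sample(length(weights[[nm]]), 1)
    wp <- weights
    wp[[nm]][i] <- wp[[nm]][i] + h
    wm <- weights
    wm[[nm]][i] <- wm[[nm]][i] - h
    num <- (lossfn(wp) - lossfn(wm)) / (2 * h)
    ana <- g$grads[[nm]][i]
    worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-6))
  }
  worst
}

# small noiseless phantom spec for geometry-sensitive tests
quiet_spec <- function(grid_shape = c(48L, 48L, 48L), spacing = c(2, 2, 2)) {
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               tissue_intensities = list(background = c(0, 0),
                                         scalp = c(60, 0),
                                         brain = c(100, 0),
                                         tumor = c(200, 0),
                                         vessel = c(200, 0)),
               n_vessels = 0L, bias_field_strength = 0, noise_sigma = 0)
}

# normalised training sample from a phantom case (no preprocessing chain)
case_to_sample <- function(cs) {
  img <- cs$image$data
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  list(x = array(img, c(dim(img), 1L)),
       y = onehot(array(as.numeric(cs$labels$data > 0), dim(img)), 2L))
}
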