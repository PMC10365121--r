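# Attention mechanisms: attention gates on skip connections, and the dual
# (position + channel) attention block computed once at the encoder
# bottleneck. The exported functions operate on plain arrays and are the same
# computations the network forward pass uses (both are built from the tape
# primitives), so oracle tests on the standalone ops cover the network path.

# ---- shared tape-level cores ----------------------------------------------

# gate coefficients: sigmoid(psi(relu(Wx x + Wg g))), all 1x1x1; the gating
# signal g comes from the coarser scale and its projection is resized
# (order 1) to the skip grid when the spatial shapes differ
.gate_core <- function(tape, skip, g, wxW, wxb, wgW, wgb, psW, psb) {
  xg <- tn_conv3(tape, skip, wxW, wxb, 1L)
  gg <- tn_conv3(tape, g, wgW, wgb, 1L)
  if (!all(dim(gg$value)[1:3] == dim(xg$value)[1:3])) {
    gg <- tn_resize(tape, gg, dim(xg$value)[1:3])
  }
  s <- tn_relu(tape, tn_add(tape, xg, gg))
  a <- tn_sigmoid(tape, tn_conv3(tape, s, psW, psb, 1L))
  list(gated = tn_gate_mul(tape, skip, a), coefficients = a)
}

# position attention with residual learnable scale (init 0)
.pam_core <- function(tape, hp, qW, qb, kW, kb, vW, vb, s) {
  d <- dim(hp$value)
  n <- prod(d[1:3])
  if (n > 32768) {
    stop("position attention: spatial extent too large for the N x N ",
         "affinity (", n, " positions); compute it at the bottleneck only")
  }
  m <- tn_reshape(tape, hp, c(n, d[4]))
  proj <- function(W, b) {
    tn_bias_row(tape, tn_matmul(tape, m, tn_transpose(tape, W)), b)
  }
  q <- proj(qW, qb)
  k <- proj(kW, kb)
  v <- proj(vW, vb)
  S <- tn_softmax_rows(tape, tn_matmul(tape, q, tn_transpose(tape, k)))
  att <- tn_reshape(tape, tn_matmul(tape, S, v), d)
  tn_add(tape, tn_scale(tape, att, s), hp)
}

# channel attention: C x C affinity from the raw features, no projections
.cam_core <- function(tape, hc, s) {
  d <- dim(hc$value)
  n <- prod(d[1:3])
  m <- tn_reshape(tape, hc, c(n, d[4]))
  S <- tn_softmax_rows(tape, tn_matmul(tape, tn_transpose(tape, m), m))
  att <- tn_reshape(tape, tn_matmul(tape, m, tn_transpose(tape, S)), d)
  tn_add(tape, tn_scale(tape, att, s), hc)
}

# attention gate on one skip connection, network naming; `coarse` is the
# decoder's pre-upsampling feature map
attention_gate_tape <- function(tape, skip, coarse, p, l) {
  .gate_core(tape, skip, coarse,
             p(sprintf("gate%d_wx.W", l)), p(sprintf("gate%d_wx.b", l)),
             p(sprintf("gate%d_wg.W", l)), p(sprintf("gate%d_wg.b", l)),
             p(sprintf("gate%d_psi.W", l)),
             p(sprintf("gate%d_psi.b", l)))$gated
}

# dual attention block at the bottleneck, network naming
dual_attention_tape <- function(tape, h, p, cfg, training) {
  branch_in <- function(name) {
    tn_relu(tape, tn_conv3(tape, h, p(paste0(name, ".W")),
                           p(paste0(name, ".b")), 3L))
  }
  pa <- .pam_core(tape, branch_in("da_in_p"),
                  p("da_q.W"), p("da_q.b"), p("da_k.W"), p("da_k.b"),
                  p("da_v.W"), p("da_v.b"), p("da_scale_p.s"))
  pa <- tn_dropout_spatial(tape, pa, cfg$dropout_rate, training)
  pa <- tn_conv3(tape, pa, p("da_out_p.W"), p("da_out_p.b"), 3L)
  ca <- .cam_core(tape, branch_in("da_in_c"), p("da_scale_c.s"))
  ca <- tn_dropout_spatial(tape, ca, cfg$dropout_rate, training)
  ca <- tn_conv3(tape, ca, p("da_out_c.W"), p("da_out_c.b"), 3L)
  tn_add(tape, pa, ca)
}

# ---- standalone array-level operations ------------------------------------

.as4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

.wrap_tape <- function(vals) {
  tape <- tape_new()
  nodes <- lapply(vals, function(v) tn_input(tape, v))
  list(tape = tape, nodes = nodes)
}

#' Attention gate
#'
#' Gates skip-connection features `x_l` by a coarser-scale gating signal `g`
#' (already upsampled to the same spatial shape): the gate coefficients are
#' `sigmoid(psi(relu(Wx x_l + Wg g)))`, computed with 1x1x1 convolutions,
#' and the gated output is the elementwise product with `x_l`, broadcast over
#' channels. Coefficients lie in (0, 1), so gated features never exceed the
#' skip features in magnitude.
#'
#' @param x_l skip feature array `(X, Y, Z, C_l)`.
#' @param g gating feature array `(X, Y, Z, C_g)`; when it sits on a
#'   coarser grid its projection is resized (order 1) to the skip grid.
#' @param weights list with matrices `wx` `(F_int, C_l)`, `wg`
#'   `(F_int, C_g)`, `psi` `(1, F_int)` and bias vectors `bx`, `bg`, `bpsi`.
#' @return list with `gated` (array like `x_l`) and `coefficients`
#'   (`(X, Y, Z, 1)` array in (0, 1)).
#' @export
attention_gate <- function(x_l, g, weights) {
  x_l <- .as4d(x_l)
  g <- .as4d(g)
  tape <- tape_new()
  r <- .gate_core(tape, tn_input(tape, x_l), tn_input(tape, g),
                  tn_input(tape, weights$wx), tn_input(tape, weights$bx),
                  tn_input(tape, weights$wg), tn_input(tape, weights$bg),
                  tn_input(tape, weights$psi), tn_input(tape, weights$bpsi))
  list(gated = r$gated$value, coefficients = r$coefficients$value)
}

#' Position (spatial) attention
#'
#' Self-attention over all spatial positions of a bottleneck feature map:
#' query/key projections at `C / reduction` channels, value at `C`, row-wise
#' softmax affinity over positions, and a residual connection through a
#' learnable scale (initialised to zero, so the op is the identity at init).
#'
#' @param f feature array `(X, Y, Z, C)`.
#' @param weights list with `q`, `k` (`(C/r, C)`), `v` (`(C, C)`) projection
#'   matrices and biases `bq`, `bk`, `bv`.
#' @param scale residual scale (default 0, the initialisation value).
#' @return array like `f`.
#' @export
position_attention <- function(f, weights, scale = 0) {
  f <- .as4d(f)
  tape <- tape_new()
  .pam_core(tape, tn_input(tape, f),
            tn_input(tape, weights$q), tn_input(tape, weights$bq),
            tn_input(tape, weights$k), tn_input(tape, weights$bk),
            tn_input(tape, weights$v), tn_input(tape, weights$bv),
            tn_input(tape, scale))$value
}

#' Channel attention
#'
#' Self-attention over feature channels: the `C x C` affinity is computed
#' from the raw features without projections, row-softmax normalised, and
#' applied with a residual learnable scale (initialised to zero).
#'
#' @param f feature array `(X, Y, Z, C)`.
#' @param scale residual scale (default 0).
#' @return array like `f`.
#' @export
channel_attention <- function(f, scale = 0) {
  f <- .as4d(f)
  tape <- tape_new()
  .cam_core(tape, tn_input(tape, f), tn_input(tape, scale))$value
}

#' Dual attention block
#'
#' The bottleneck attention block of the dual-attention backbones: each
#' branch applies a 3x3x3 input convolution, its attention module (position
#' or channel), spatial dropout on the raw attention maps, and a 3x3x3
#' output transform; the branch sum is the attention feature map (AFM).
#'
#' @param f bottleneck feature array `(X, Y, Z, C)`.
#' @param weights flat named weight list using the `da_*` layer names of
#'   [init_weights()].
#' @param dropout_rate spatial dropout rate (whole channels), default 0.5.
#' @param training logical; dropout is active only in training mode.
#' @return the AFM array `(X, Y, Z, C)`.
#' @export
dual_attention_block <- function(f, weights, dropout_rate = 0.5,
                                 training = FALSE) {
  f <- .as4d(f)
  cfg <- list(dropout_rate = dropout_rate,
              filters = dim(f)[4], levels = 1L)
  tape <- tape_new()
  cache <- new.env(parent = emptyenv())
  p <- function(name) .pn(tape, weights, name, cache)
  dual_attention_tape(tape, tn_input(tape, f), p, cfg, training)$value
}

#' Multi-scale input pyramid
#'
#' Consecutive 3x3x3 average-pooling (stride 2, edge-renormalised) of the
#' network input; level 1 is the input itself and level `k` has been pooled
#' `k - 1` times.
#'
#' @param x input array, 3D or `(X, Y, Z, C)`.
#' @param levels number of pyramid levels.
#' @return list of `levels` arrays.
#' @export
multiscale_pyramid <- function(x, levels) {
  x <- .as4d(x)
  out <- list(x)
  for (k in seq_len(levels - 1L)) {
    out[[k + 1L]] <- cpp_avgpool3s2_fwd(out[[k]], dim(out[[k]]))
  }
  out
}
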