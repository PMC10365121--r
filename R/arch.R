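# Network architectures: U-Net backbone, attention-gated U-Net (AGUNet),
# dual-attention U-Net (DAUNet) and dual-attention-guided U-Net (DAGUNet),
# with toggleable multi-scale input (MS) and deep supervision (DS).
#
# Two block families are used:
#  * backbone "unet" is the classic full-volume U-Net: channel-doubling
#    filters, two 3x3x3 conv + batch-norm + ReLU per level, max-pool
#    downsampling, trilinear upsampling + concatenation in the decoder;
#  * the attention backbones share one block design: two 3x3x3 conv + ReLU
#    (bias, no normalisation) per level, max-pool downsampling, 3x3x3
#    transpose-conv upsampling + concatenation, two decoder convs.
# Block internals were fixed by calibrating total trainable-parameter counts
# of the published full-size configurations; see the methods vignette.

#' Architecture configuration
#'
#' @param backbone one of `"unet"`, `"agunet"`, `"daunet"`, `"dagunet"`.
#' @param levels number of resolution levels (5 for the full-size models).
#' @param filters integer vector of per-level filter counts, length `levels`.
#'   Defaults to `c(16, 32, 128, 256, 256)` for the attention backbones and
#'   to the channel-doubling `16 * 2^(0:(levels-1))` scheme (capped at 256)
#'   for `"unet"`.
#' @param multiscale enable the multi-scale input pyramid (MS).
#' @param deep_supervision enable per-decoder-level output heads (DS).
#' @param input_shape spatial input shape, divisible by `2^(levels-1)`.
#' @param n_classes number of output classes (softmax per voxel).
#' @param in_channels number of input channels.
#' @param attention_reduction channel reduction ratio of the position
#'   attention projections (dual-attention backbones).
#' @param dropout_rate spatial dropout rate on the raw attention feature maps.
#' @param accum_grad training-strategy tag (accumulated gradients); carried
#'   for experiment naming only and adds no weights.
#' @return an `arch_config` object.
#' @export
arch_config <- function(backbone = c("unet", "agunet", "daunet", "dagunet"),
                        levels = 5L,
                        filters = NULL,
                        multiscale = FALSE,
                        deep_supervision = FALSE,
                        input_shape = c(128L, 128L, 144L),
                        n_classes = 2L,
                        in_channels = 1L,
                        attention_reduction = 8L,
                        dropout_rate = 0.5,
                        accum_grad = FALSE) {
  backbone <- match.arg(backbone)
  levels <- as.integer(levels)
  if (is.null(filters)) {
    filters <- if (backbone == "unet") {
      pmin(16L * 2L^(seq_len(levels) - 1L), 256L)
    } else if (levels == 5L) {
      c(16L, 32L, 128L, 256L, 256L)
    } else {
      pmin(16L * 2L^(seq_len(levels) - 1L), 256L)
    }
  }
  filters <- as.integer(filters)
  stopifnot(length(filters) == levels, all(filters > 0), n_classes >= 2,
            levels >= 2)
  if (!is.null(input_shape)) {
    input_shape <- as.integer(input_shape)
    stopifnot(length(input_shape) == 3)
    if (any(input_shape %% 2L^(levels - 1L) != 0L)) {
      stop("input_shape must be divisible by 2^(levels-1)")
    }
  }
  structure(list(backbone = backbone, levels = levels, filters = filters,
                 multiscale = isTRUE(multiscale),
                 deep_supervision = isTRUE(deep_supervision),
                 input_shape = input_shape, n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 attention_reduction = as.integer(attention_reduction),
                 dropout_rate = dropout_rate,
                 accum_grad = isTRUE(accum_grad)),
            class = "arch_config")
}

.layer <- function(name, kind, cin = 0L, cout = 0L, k = 3L) {
  list(name = name, kind = kind, cin = as.integer(cin),
       cout = as.integer(cout), k = as.integer(k))
}

# ordered inventory of parameterised layers; the single source of truth for
# parameter counting, initialisation and the forward pass
arch_layers <- function(cfg) {
  stopifnot(inherits(cfg, "arch_config"))
  L <- cfg$levels
  f <- cfg$filters
  fam <- cfg$backbone != "unet"
  bn <- !fam
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- .layer(...)
  addconv <- function(name, cin, cout, k = 3L) {
    add(name, "conv", cin, cout, k)
    if (bn) add(paste0(name, "_bn"), "bn", cout, cout)
  }
  for (l in seq_len(L)) {
    cin <- if (l == 1L) cfg$in_channels else f[l - 1L]
    addconv(sprintf("enc%d_conv1", l), cin, f[l])
    addconv(sprintf("enc%d_conv2", l), f[l], f[l])
    if (cfg$multiscale && l < L) {
      addconv(sprintf("ms_fuse%d", l), f[l], f[l])
    }
  }
  if (cfg$backbone %in% c("daunet", "dagunet")) {
    C <- f[L]
    Cr <- max(1L, C %/% cfg$attention_reduction)
    addconv("da_in_p", C, C)
    addconv("da_in_c", C, C)
    add("da_q", "conv", C, Cr, 1L)
    add("da_k", "conv", C, Cr, 1L)
    add("da_v", "conv", C, C, 1L)
    add("da_scale_p", "scalar", 1L, 1L)
    add("da_scale_c", "scalar", 1L, 1L)
    addconv("da_out_p", C, C)
    addconv("da_out_c", C, C)
  }
  for (l in seq(L - 1L, 1L)) {
    if (fam) add(sprintf("dec%d_up", l), "tconv", f[l + 1L], f[l])
    if (cfg$backbone == "agunet") {
      fint <- max(1L, f[l] %/% 2L)
      add(sprintf("gate%d_wx", l), "conv", f[l], fint, 1L)
      add(sprintf("gate%d_wg", l), "conv", f[l + 1L], fint, 1L)
      add(sprintf("gate%d_psi", l), "conv", fint, 1L, 1L)
    }
    extra <- 0L
    if (cfg$backbone == "dagunet") {
      addconv(sprintf("prop%d", l), f[L], f[l])
      extra <- f[l]
    }
    up_ch <- if (fam) f[l] else f[l + 1L]
    addconv(sprintf("dec%d_conv1", l), up_ch + f[l] + extra, f[l])
    addconv(sprintf("dec%d_conv2", l), f[l], f[l])
    if (cfg$deep_supervision && l > 1L) {
      add(sprintf("ds_head%d", l), "conv", f[l], cfg$n_classes, 1L)
    }
  }
  add("head", "conv", f[1L], cfg$n_classes, 1L)
  out
}

.layer_nparams <- function(ly) {
  switch(ly$kind,
    conv = ly$k^3 * ly$cin * ly$cout + ly$cout,
    tconv = 27L * ly$cin * ly$cout + ly$cout,
    bn = 2L * ly$cout,
    scalar = 1L,
    stop("unknown layer kind"))
}

#' Build a network graph from a configuration
#'
#' Assembles the ordered layer inventory and total trainable-parameter count
#' without allocating any tensors, so full-size graphs build in milliseconds.
#'
#' @param config an [arch_config()].
#' @return an `attunet_model` with elements `config`, `layers`, `n_params`.
#' @export
build_model <- function(config) {
  layers <- arch_layers(config)
  n <- sum(vapply(layers, .layer_nparams, numeric(1)))
  structure(list(config = config, layers = layers, n_params = n),
            class = "attunet_model")
}

#' Count trainable parameters of a model
#'
#' @param model an `attunet_model` from [build_model()], or an
#'   [arch_config()].
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "arch_config")) model <- build_model(model)
  stopifnot(inherits(model, "attunet_model"))
  model$n_params
}

#' @export
print.attunet_model <- function(x, ...) {
  cat(sprintf("<attunet_model> %s, %d levels, filters [%s]%s%s\n",
              x$config$backbone, x$config$levels,
              paste(x$config$filters, collapse = ", "),
              if (x$config$multiscale) ", MS" else "",
              if (x$config$deep_supervision) ", DS" else ""))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(x$n_params, big.mark = ","), x$n_params / 1e6))
  invisible(x)
}

#' Layer-by-layer model summary
#'
#' @param object an `attunet_model`.
#' @param ... unused.
#' @return invisibly, a data.frame with one row per parameterised layer.
#' @export
summary.attunet_model <- function(object, ...) {
  df <- do.call(rbind, lapply(object$layers, function(ly) {
    data.frame(layer = ly$name, kind = ly$kind, cin = ly$cin, cout = ly$cout,
               k = ly$k, params = .layer_nparams(ly))
  }))
  print(object)
  print(df, row.names = FALSE)
  invisible(df)
}

#' Initialise model weights
#'
#' Variance-scaling (He) normal initialisation for convolution kernels with a
#' fixed seed so repeated runs are reproducible; biases start at zero,
#' batch-norm at identity, residual attention scales at zero.
#'
#' @param model an `attunet_model`.
#' @param seed integer RNG seed.
#' @return flat named list of weight arrays (`"<layer>.W"`, `"<layer>.b"`,
#'   ...).
#' @export
init_weights <- function(model, seed = 42L) {
  stopifnot(inherits(model, "attunet_model"))
  set.seed(as.integer(seed))
  w <- list()
  for (ly in model$layers) {
    if (ly$kind %in% c("conv", "tconv")) {
      k3 <- if (ly$kind == "conv") ly$k^3 else 27L
      fan_in <- k3 * ly$cin
      W <- matrix(stats::rnorm(ly$cout * k3 * ly$cin, sd = sqrt(2 / fan_in)),
                  nrow = if (ly$kind == "conv") ly$cout else ly$cin,
                  ncol = if (ly$kind == "conv") k3 * ly$cin else 27L * ly$cout)
      # tconv weights are stored as the matrix of the dual stride-2 conv:
      # (coarse channels, 27 * fine channels)
      w[[paste0(ly$name, ".W")]] <- W
      w[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
    } else if (ly$kind == "bn") {
      w[[paste0(ly$name, ".gamma")]] <- rep(1, ly$cout)
      w[[paste0(ly$name, ".beta")]] <- numeric(ly$cout)
    } else if (ly$kind == "scalar") {
      w[[paste0(ly$name, ".s")]] <- 0
    }
  }
  w
}

# ---------------------------------------------------------------------------
# forward pass
# ---------------------------------------------------------------------------

.pn <- function(tape, weights, name, cache) {
  if (!is.null(cache[[name]])) return(cache[[name]])
  nd <- tn_param(tape, weights[[name]], name)
  cache[[name]] <- nd
  nd
}

#' Forward pass of a network
#'
#' Executes the model on one input volume, building an autodiff tape so the
#' result can be backpropagated through.
#'
#' @param model an `attunet_model`.
#' @param weights flat weight list from [init_weights()].
#' @param x input array of dim `(X, Y, Z, in_channels)` (a 3D array is
#'   promoted to one channel).
#' @param training logical; enables dropout.
#' @return list with `tape`, `output` (full-resolution class-probability
#'   node), `heads` (all output heads, finest first) and `afm` (dual
#'   attention feature map node, when present).
#' @export
forward_model <- function(model, weights, x, training = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == cfg$in_channels)
  if (any(dim(x)[1:3] %% 2L^(cfg$levels - 1L) != 0L)) {
    stop("input shape must be divisible by 2^(levels-1)")
  }
  L <- cfg$levels
  f <- cfg$filters
  fam <- cfg$backbone != "unet"
  tape <- tape_new()
  cache <- new.env(parent = emptyenv())
  p <- function(name) .pn(tape, weights, name, cache)

  conv_block <- function(h, name) {
    h <- tn_conv3(tape, h, p(paste0(name, ".W")), p(paste0(name, ".b")), 3L)
    if (!fam) {
      h <- tn_batchnorm(tape, h, p(paste0(name, "_bn.gamma")),
                        p(paste0(name, "_bn.beta")))
    }
    tn_relu(tape, h)
  }
  conv1x1 <- function(h, name) {
    tn_conv3(tape, h, p(paste0(name, ".W")), p(paste0(name, ".b")), 1L)
  }

  xin <- tn_input(tape, x)
  pooled <- list(xin)
  if (cfg$multiscale) {
    for (k in 2:L) pooled[[k]] <- tn_avgpool3s2(tape, pooled[[k - 1L]])
  }

  skips <- vector("list", L)
  h <- xin
  for (l in seq_len(L)) {
    h <- conv_block(h, sprintf("enc%d_conv1", l))
    h <- conv_block(h, sprintf("enc%d_conv2", l))
    if (l < L) {
      if (cfg$multiscale) {
        h <- tn_badd1(tape, h, pooled[[l]])
        h <- conv_block(h, sprintf("ms_fuse%d", l))
      }
      skips[[l]] <- h
      h <- tn_maxpool2(tape, h)
    }
  }

  afm <- NULL
  if (cfg$backbone %in% c("daunet", "dagunet")) {
    afm <- dual_attention_tape(tape, h, p, cfg, training)
    h <- afm
  }

  heads <- vector("list", L - 1L)
  for (l in seq(L - 1L, 1L)) {
    skip <- skips[[l]]
    sdim <- dim(skip$value)
    if (fam) {
      up <- tn_tconv3(tape, h, p(sprintf("dec%d_up.W", l)),
                      p(sprintf("dec%d_up.b", l)), f[l])
      up <- tn_relu(tape, up)
    } else {
      up <- tn_resize(tape, h, sdim[1:3])
    }
    if (cfg$backbone == "agunet") {
      skip <- attention_gate_tape(tape, skip, h, p, l)
    }
    parts <- list(up, skip)
    if (cfg$backbone == "dagunet") {
      af <- tn_resize(tape, afm, sdim[1:3])
      af <- tn_conv3(tape, af, p(sprintf("prop%d.W", l)),
                     p(sprintf("prop%d.b", l)), 3L)
      parts <- c(parts, list(tn_relu(tape, af)))
    }
    h <- tn_concat(tape, parts)
    h <- conv_block(h, sprintf("dec%d_conv1", l))
    h <- conv_block(h, sprintf("dec%d_conv2", l))
    if (cfg$deep_supervision && l > 1L) {
      heads[[l]] <- tn_softmax_c(tape, conv1x1(h, sprintf("ds_head%d", l)))
    }
  }
  out <- tn_softmax_c(tape, conv1x1(h, "head"))
  heads[[1]] <- out
  heads <- Filter(Negate(is.null), heads)
  list(tape = tape, output = out, heads = heads, afm = afm)
}

# attention_gate_tape() and dual_attention_tape() live in attention.R
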