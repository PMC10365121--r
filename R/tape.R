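# Minimal reverse-mode autodiff over dense arrays.
#
# A tape is an environment collecting nodes in creation order; each node holds
# its value, its parent nodes and a backward closure mapping the output
# gradient to one gradient per parent. backprop() walks the tape in reverse.
# Feature arrays use dim (X, Y, Z, C); dense layers use plain matrices.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tn_node <- function(tape, value, parents = list(), backward = NULL,
                    param = FALSE, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$param <- param
  nd$name <- name
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

tn_input <- function(tape, value) tn_node(tape, value)

tn_param <- function(tape, value, name) {
  tn_node(tape, value, param = TRUE, name = name)
}

.accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation from a scalar loss node
#'
#' Seeds the loss gradient with 1 and walks the tape in reverse creation
#' order, accumulating gradients into every parameter node.
#'
#' @param tape tape created with `tape_new()` on which the loss was built.
#' @param loss_node scalar output node.
#' @return named list of gradients, one per parameter node.
#' @keywords internal
backprop <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .accum_grad(nd$parents[[j]], gs[[j]])
    }
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (nd$param) grads[[nd$name]] <- if (is.null(nd$grad)) {
      array(0, dim = dim_or_len(nd$value))
    } else nd$grad
  }
  grads
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

.dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  as.integer(d)
}

# ---- convolutions ----------------------------------------------------------

tn_conv3 <- function(tape, x, W, b, k) {
  d <- .dims4(x$value)
  if (k == 1L) {
    y <- cpp_conv3_fwd(x$value, d, W$value, b$value, 1L)
    return(tn_node(tape, y, list(x, W, b), function(g) {
      r <- cpp_conv3_bwd(x$value, d, g, W$value, 1L)
      list(r$dx, r$dW, r$db)
    }))
  }
  y <- cpp_conv3d_fwd(x$value, d, W$value, b$value)
  need_dx <- x$param || !is.null(x$backward)
  tn_node(tape, y, list(x, W, b), function(g) {
    r <- cpp_conv3d_bwd(x$value, d, g, W$value, need_dx)
    list(if (need_dx) r$dx else NULL, r$dW, r$db)
  })
}

# transpose conv, kernel 3, stride 2: coarse (Cc) -> fine (Cf), fine = 2*coarse
# weight is the matrix of the dual stride-2 conv: (Cc, 27*Cf); bias over Cf
tn_tconv3 <- function(tape, x, W, b, cf) {
  dc <- .dims4(x$value)
  df <- as.integer(c(dc[1:3] * 2L, cf))
  y <- cpp_conv3s2_bwd_data(x$value, dc, W$value, df)
  nf <- prod(df[1:3])
  y <- y + rep(b$value, each = nf)
  dim(y) <- df
  tn_node(tape, y, list(x, W, b), function(g) {
    col_g <- cpp_im2col3_s2(g, df, dc)
    dx <- col_g %*% t(W$value)
    dim(dx) <- dc
    dW <- crossprod(matrix(x$value, ncol = dc[4]), col_g)
    db <- colSums(matrix(g, ncol = cf))
    list(dx, dW, db)
  })
}

# ---- pooling and resizing --------------------------------------------------

tn_maxpool2 <- function(tape, x) {
  d <- .dims4(x$value)
  stopifnot(all(d[1:3] %% 2L == 0L))
  r <- cpp_maxpool2_fwd(x$value, d)
  tn_node(tape, r$y, list(x), function(g) {
    list(cpp_maxpool2_bwd(g, r$arg, d))
  })
}

tn_avgpool3s2 <- function(tape, x) {
  d <- .dims4(x$value)
  y <- cpp_avgpool3s2_fwd(x$value, d)
  tn_node(tape, y, list(x), function(g) list(cpp_avgpool3s2_bwd(g, d)))
}

tn_resize <- function(tape, x, oshape) {
  d <- .dims4(x$value)
  od <- as.integer(c(oshape, d[4]))
  y <- cpp_resize_tril(x$value, d, od, FALSE)
  tn_node(tape, y, list(x), function(g) {
    list(cpp_resize_tril(g, d, od, TRUE))
  })
}

# ---- pointwise -------------------------------------------------------------

tn_relu <- function(tape, x) {
  m <- x$value > 0
  tn_node(tape, x$value * m, list(x), function(g) list(g * m))
}

tn_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  tn_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

tn_add <- function(tape, a, b) {
  tn_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# broadcast-add a single-channel volume over every channel of x
tn_badd1 <- function(tape, x, s) {
  d <- .dims4(x$value)
  y <- x$value + as.vector(s$value)
  dim(y) <- d
  n <- prod(d[1:3])
  tn_node(tape, y, list(x, s), function(g) {
    gs <- rowSums(matrix(g, nrow = n))
    dim(gs) <- c(d[1:3], 1L)
    list(g, gs)
  })
}

# multiply features x (C channels) by a single-channel gate, broadcast over C
tn_gate_mul <- function(tape, x, gate) {
  d <- .dims4(x$value)
  gv <- as.vector(gate$value)
  y <- x$value * gv
  dim(y) <- d
  n <- prod(d[1:3])
  tn_node(tape, y, list(x, gate), function(g) {
    dgate <- rowSums(matrix(g * x$value, nrow = n))
    dim(dgate) <- c(d[1:3], 1L)
    list(g * gv, dgate)
  })
}

tn_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) .dims4(x$value))
  cs <- vapply(ds, function(d) d[4], integer(1))
  d0 <- ds[[1]]
  y <- array(0, dim = c(d0[1:3], sum(cs)))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , , at + seq_len(cs[i])] <- xs[[i]]$value
    at <- at + cs[i]
  }
  tn_node(tape, y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- g[, , , at + seq_len(cs[i]), drop = FALSE]
      dim(gi) <- c(d0[1:3], cs[i])
      out[[i]] <- gi
      at <- at + cs[i]
    }
    out
  })
}

# softmax over the channel axis of an (X,Y,Z,C) array
tn_softmax_c <- function(tape, x) {
  d <- .dims4(x$value)
  n <- prod(d[1:3])
  m <- matrix(x$value, nrow = n)
  m <- m - m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  y <- array(p, dim = d)
  tn_node(tape, y, list(x), function(g) {
    gm <- matrix(g, nrow = n)
    dot <- rowSums(gm * p)
    dx <- p * (gm - dot)
    dim(dx) <- d
    list(dx)
  })
}

# multiply by a learnable scalar (residual attention scale, init 0)
tn_scale <- function(tape, x, s) {
  tn_node(tape, x$value * s$value[1], list(x, s), function(g) {
    list(g * s$value[1], sum(g * x$value))
  })
}

# spatial (channel-wise) dropout: whole channels are zeroed
tn_dropout_spatial <- function(tape, x, rate, training) {
  d <- .dims4(x$value)
  if (!training || rate <= 0) {
    return(tn_node(tape, x$value, list(x), function(g) list(g)))
  }
  keep <- stats::runif(d[4]) >= rate
  scale <- if (rate < 1) 1 / (1 - rate) else 0
  mask <- rep(keep * scale, each = prod(d[1:3]))
  y <- x$value * mask
  dim(y) <- d
  tn_node(tape, y, list(x), function(g) list(g * mask))
}

# batch normalisation over spatial positions, per channel (gamma, beta)
tn_batchnorm <- function(tape, x, gamma, beta, eps = 1e-3) {
  d <- .dims4(x$value)
  n <- prod(d[1:3])
  m <- matrix(x$value, nrow = n)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, istd, `*`)
  y <- sweep(xn, 2, gamma$value, `*`)
  y <- sweep(y, 2, beta$value, `+`)
  dim(y) <- d
  tn_node(tape, y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n)
    dgamma <- colSums(gm * xn)
    dbeta <- colSums(gm)
    gxn <- sweep(gm, 2, gamma$value, `*`)
    # standard batch-norm backward
    t1 <- gxn
    t2 <- matrix(rep(colMeans(gxn), each = n), nrow = n)
    t3 <- xn * matrix(rep(colMeans(gxn * xn), each = n), nrow = n)
    dx <- sweep(t1 - t2 - t3, 2, istd, `*`)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# ---- dense / matrix ops (toy networks, attention affinities) ---------------

tn_matmul <- function(tape, a, b) {
  tn_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

tn_transpose <- function(tape, x) {
  tn_node(tape, t(x$value), list(x), function(g) list(t(g)))
}

tn_reshape <- function(tape, x, newdim) {
  olddim <- dim_or_len(x$value)
  y <- x$value
  dim(y) <- newdim
  tn_node(tape, y, list(x), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

tn_bias_row <- function(tape, x, b) {
  # add bias vector to every row of a matrix
  y <- sweep(x$value, 2, b$value, `+`)
  tn_node(tape, y, list(x, b), function(g) list(g, colSums(g)))
}

tn_softmax_rows <- function(tape, x) {
  nr <- nrow(x$value)
  m <- x$value -
    x$value[cbind(seq_len(nr), max.col(x$value, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  tn_node(tape, p, list(x), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

tn_mean_sq_diff <- function(tape, x, target) {
  # mean((x - target)^2), target constant
  df <- x$value - target
  n <- length(df)
  tn_node(tape, sum(df^2) / n, list(x), function(g) list(g * 2 * df / n))
}

# weighted sum of scalar nodes
tn_wsum <- function(tape, xs, w) {
  v <- 0
  for (i in seq_along(xs)) v <- v + w[i] * xs[[i]]$value
  tn_node(tape, v, xs, function(g) {
    lapply(seq_along(xs), function(i) g * w[i])
  })
}
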