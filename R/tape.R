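# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records each intermediate as a node (an environment holding value,
# accumulated gradient and a backward closure). Nodes are created in forward
# order; ad_backward() walks them in reverse. All values are plain numeric
# matrices; scalars are 1x1. The op set is deliberately small: just what the
# autoencoder, GCN and fusion networks need, plus fused losses so tapes stay
# short. Gradients of every op are validated against central differences in
# the test suite.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  i <- tape$n + 1L
  if (i > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[i]] <- nd
  tape$n <- i
  nd
}

# Leaf node: a parameter (gradient collected) or a constant (gradient ignored).
ad_leaf <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_node(tape, value)
}

.acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, backward = function(g) {
    .acc(a, g %*% t(b$value))
    .acc(b, t(a$value) %*% g)
  })
}

# Matrix + matrix of equal shape.
ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, backward = function(g) {
    .acc(a, g)
    .acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, backward = function(g) {
    .acc(a, g)
    .acc(b, -g)
  })
}

# Add a 1 x k bias row to every row of an n x k matrix.
ad_add_bias <- function(tape, a, bias) {
  v <- a$value + matrix(bias$value, nrow(a$value), ncol(a$value), byrow = TRUE)
  ad_node(tape, v, backward = function(g) {
    .acc(a, g)
    .acc(bias, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, backward = function(g) {
    .acc(a, g * b$value)
    .acc(b, g * a$value)
  })
}

# Multiply by a fixed scalar.
ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, backward = function(g) .acc(a, g * s))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, backward = function(g) .acc(a, g * v * (1 - v)))
}

ad_lrelu <- function(tape, a, alpha = 0.01) {
  pos <- a$value > 0
  v <- ifelse(pos, a$value, alpha * a$value)
  ad_node(tape, v, backward = function(g) .acc(a, g * ifelse(pos, 1, alpha)))
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), backward = function(g) .acc(a, t(g)))
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L),
          backward = function(g) .acc(a, matrix(g[1L], nrow(a$value), ncol(a$value))))
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1L, 1L),
          backward = function(g) .acc(a, matrix(g[1L] / n, nrow(a$value), ncol(a$value))))
}

# Select rows by index (no duplicates).
ad_select_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], backward = function(g) {
    gb <- matrix(0, nrow(a$value), ncol(a$value))
    gb[idx, ] <- g
    .acc(a, gb)
  })
}

# Column-wise max within row groups. `groups` is an integer vector (1..G) of
# length nrow(a); the result is G x ncol(a). The subgradient flows to the
# argmax row of each (group, column) cell (first index on ties).
ad_rowgroup_max <- function(tape, a, groups, n_groups = max(groups)) {
  av <- a$value
  nc <- ncol(av)
  val <- matrix(0, n_groups, nc)
  arg <- matrix(0L, n_groups, nc)
  for (gi in seq_len(n_groups)) {
    rows <- which(groups == gi)
    if (length(rows) == 0L) stop("row group with no members: ", gi)
    if (length(rows) == 1L) {
      val[gi, ] <- av[rows, ]
      arg[gi, ] <- rows
    } else {
      sub <- av[rows, , drop = FALSE]
      wm <- max.col(t(sub), ties.method = "first")
      arg[gi, ] <- rows[wm]
      val[gi, ] <- sub[cbind(wm, seq_len(nc))]
    }
  }
  ad_node(tape, val, backward = function(g) {
    gb <- matrix(0, nrow(av), nc)
    gb[cbind(as.vector(arg), rep(seq_len(nc), each = n_groups))] <- as.vector(g)
    .acc(a, gb)
  })
}

ad_colgroup_max <- function(tape, a, groups, n_groups = max(groups)) {
  ad_transpose(tape, ad_rowgroup_max(tape, ad_transpose(tape, a), groups, n_groups))
}

# Row-wise triple Kronecker product: each row of the n x T inputs becomes the
# flattened T^3 outer product with the third index varying fastest
# (entry (e1*T + e2)*T + e3, zero-based).
ad_kron3 <- function(tape, y1, y2, y3) {
  T <- ncol(y1$value)
  i1 <- rep(seq_len(T), each = T * T)
  i2 <- rep(rep(seq_len(T), each = T), times = T)
  i3 <- rep(seq_len(T), times = T * T)
  v1 <- y1$value[, i1, drop = FALSE]
  v2 <- y2$value[, i2, drop = FALSE]
  v3 <- y3$value[, i3, drop = FALSE]
  e1 <- 1 * outer(i1, seq_len(T), "==")
  e2 <- 1 * outer(i2, seq_len(T), "==")
  e3 <- 1 * outer(i3, seq_len(T), "==")
  ad_node(tape, v1 * v2 * v3, backward = function(g) {
    .acc(y1, (g * v2 * v3) %*% e1)
    .acc(y2, (g * v1 * v3) %*% e2)
    .acc(y3, (g * v1 * v2) %*% e3)
  })
}

# Fused losses -----------------------------------------------------------

# Mean squared error against a fixed target.
ad_mse <- function(tape, pred, target) {
  d <- pred$value - target
  n <- length(d)
  ad_node(tape, matrix(sum(d^2) / n, 1L, 1L),
          backward = function(g) .acc(pred, g[1L] * 2 * d / n))
}

# Mean absolute (L1) error against a fixed target.
ad_l1 <- function(tape, pred, target) {
  d <- pred$value - target
  n <- length(d)
  ad_node(tape, matrix(sum(abs(d)) / n, 1L, 1L),
          backward = function(g) .acc(pred, g[1L] * sign(d) / n))
}

# Weighted binary cross-entropy: -(1/denom) * sum(W * (y log p + (1-y) log(1-p)))
# with p clipped to [eps, 1-eps]. W is an elementwise weight matrix (zero
# entries mask cells out of the loss entirely).
ad_wbce <- function(tape, pred, y, w, denom, eps = 1e-7) {
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  v <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / denom
  ad_node(tape, matrix(v, 1L, 1L), backward = function(g) {
    .acc(pred, g[1L] * (-w) * (y / p - (1 - y) / (1 - p)) / denom)
  })
}

# -(1/n) * sum(log(clip(p))): the non-saturating adversarial generator term
# and, composed, the discriminator objective.
ad_nll <- function(tape, pred, eps = 1e-7) {
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  n <- length(p)
  ad_node(tape, matrix(-sum(log(p)) / n, 1L, 1L),
          backward = function(g) .acc(pred, -g[1L] / (p * n)))
}

# Same on 1 - p.
ad_nll_complement <- function(tape, pred, eps = 1e-7) {
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  n <- length(p)
  ad_node(tape, matrix(-sum(log(1 - p)) / n, 1L, 1L),
          backward = function(g) .acc(pred, g[1L] / ((1 - p) * n)))
}

# Optimizer ---------------------------------------------------------------

# Adam over a named list of parameter matrices.
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  class(st) <- "adam_state"
  st
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + state$eps)
  }
  list(state = state, params = params)
}

# Register a named list of parameter matrices as leaves; returns node list.
ad_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

# Collect gradients from parameter nodes (zeros where a parameter was unused).
ad_grads <- function(param_nodes) {
  lapply(param_nodes, function(nd) {
    if (is.null(nd$grad)) nd$value * 0 else nd$grad
  })
}
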