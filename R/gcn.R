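# Omics-specific graph convolutional classifiers.
#
# Each omics view X (n isoforms x d features) induces a cosine-similarity
# graph thresholded to a target mean degree; a GCN over the renormalized
# adjacency predicts per-isoform GO-term probabilities. Supervision is
# gene-level: isoform scores are max-pooled within genes (the multiple-
# instance assumption) and compared to gene labels with a class-weighted
# binary cross-entropy. Training is transductive: test isoforms sit unlabeled
# in the graph.

#' Build the thresholded cosine-similarity graph for one omics view
#'
#' Pairwise cosine similarities `s_ij` are computed between feature rows;
#' the threshold `theta` is the `(n * a)`-th largest off-diagonal similarity
#' (both ordered copies counted), so each node retains `a` edges on average.
#' Entries at or above `theta` are kept with their similarity as weight; ties
#' at the threshold are all retained and the diagonal is zero. All-zero rows
#' have similarity 0 to everything by convention.
#'
#' @param X `n x d` feature matrix.
#' @param a target mean number of retained edges per node.
#' @return A `graph_spec` list with the weighted adjacency `A`, the threshold
#'   `theta`, `a`, and the renormalized operator `A_norm`.
#' @export
build_adjacency <- function(X, a = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2L, a > 0)
  nrm <- sqrt(rowSums(X^2))
  Xn <- X / ifelse(nrm > 0, nrm, 1)
  S <- Xn %*% t(Xn)
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  S <- pmin(pmax(S, -1), 1)
  off <- S[row(S) != col(S)]
  k <- as.integer(round(n * a))
  if (k > length(off)) {
    if_log("build_adjacency", note = "n*a exceeds available pairs; using minimum similarity")
    theta <- min(off)
  } else {
    theta <- sort(off, decreasing = TRUE)[k]
  }
  A <- S * (S >= theta)
  # edge weights are nonnegative by contract; anti-correlated pairs that pass
  # a negative threshold carry no edge rather than a negative one
  A[A < 0] <- 0
  diag(A) <- 0
  gs <- list(A = A, theta = theta, a = a, A_norm = normalize_adjacency(A))
  class(gs) <- "graph_spec"
  gs
}

#' Renormalize an adjacency matrix for graph convolution
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I`; the self-loop guarantees strictly positive degrees.
#'
#' @param A symmetric nonnegative adjacency with zero diagonal.
#' @return The symmetric normalized operator.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  Ab <- A + diag(nrow(A))
  d <- rowSums(Ab)
  if (any(d <= 0)) stop("non-positive degree after adding self-loops")
  s <- 1 / sqrt(d)
  Ab * outer(s, s)
}

#' GCN training configuration
#'
#' @param hidden widths of the graph-convolution layers (one layer per entry).
#' @param dropout dropout rate applied between convolution layers in training.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs (full-batch).
#' @param patience early-stopping patience on validation loss (epochs).
#' @param a_edges target mean degree for [build_adjacency()].
#' @param activation hidden-layer nonlinearity: leaky rectifier or linear.
#' @param seed integer seed for initialization and dropout.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(hidden = c(256L, 128L, 64L), dropout = 0.5, lr = 1e-3,
                       epochs = 300L, patience = 30L, a_edges = 10,
                       activation = c("lrelu", "linear"), seed = 1L) {
  cfg <- list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
              epochs = as.integer(epochs), patience = as.integer(patience),
              a_edges = a_edges, activation = match.arg(activation),
              seed = as.integer(seed))
  stopifnot(all(cfg$hidden > 0), dropout >= 0, dropout < 1, lr > 0, epochs >= 0)
  class(cfg) <- "gcn_config"
  cfg
}

# Parameter initialization; draws from the current RNG stream.
gcn_init <- function(d, hidden, n_terms) {
  dims <- c(d, hidden)
  params <- list()
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- init_dense(dims[l], dims[l + 1L])
  }
  params$WL <- init_dense(dims[length(dims)], n_terms, scale = sqrt(1 / dims[length(dims)]))
  params$bL <- zeros_bias(n_terms)
  params
}

# Forward pass on a tape. dropout_masks: list per hidden gap or NULL.
gcn_forward_tape <- function(tape, pn, X, A_norm, activation = "lrelu",
                             dropout_masks = NULL) {
  An <- ad_leaf(tape, A_norm)
  H <- ad_leaf(tape, X)
  n_conv <- sum(grepl("^W[0-9]+$", names(pn)))
  act <- function(nd) if (activation == "linear") nd else ad_lrelu(tape, nd)
  for (l in seq_len(n_conv)) {
    H <- act(ad_matmul(tape, ad_matmul(tape, An, H), pn[[paste0("W", l)]]))
    if (!is.null(dropout_masks) && l < n_conv && !is.null(dropout_masks[[l]])) {
      H <- ad_mul(tape, H, ad_leaf(tape, dropout_masks[[l]]))
    }
  }
  Z <- ad_add_bias(tape, ad_matmul(tape, H, pn$WL), pn$bL)
  ad_sigmoid(tape, Z)
}

#' GCN forward pass (evaluation mode)
#'
#' Applies the stacked graph convolutions `H_{l+1} = sigma(A_norm H_l W_l)`,
#' the final dense layer and an element-wise sigmoid. Deterministic (no
#' dropout).
#'
#' @param params parameter list from a fit (or [gcn_init] internally).
#' @param X `n x d` feature matrix.
#' @param A_norm normalized adjacency from [build_adjacency()].
#' @param activation hidden nonlinearity (matching the training config).
#' @return `n x T` matrix of probabilities strictly inside (0, 1).
#' @export
gcn_forward <- function(params, X, A_norm, activation = "lrelu") {
  tape <- new_tape()
  pn <- ad_params(tape, params)
  out <- gcn_forward_tape(tape, pn, as.matrix(X), A_norm, activation)
  out$value
}

#' Pool isoform scores to gene scores by within-gene maximum
#'
#' Under the multiple-instance assumption, a gene carries a function if at
#' least one of its isoforms does, so the gene's score for each term is the
#' maximum over its isoforms.
#'
#' @param Yhat `n x T` isoform score matrix.
#' @param iso2gene integer gene index per isoform.
#' @param n_genes total number of genes.
#' @return `g x T` matrix of gene scores.
#' @export
gene_pool <- function(Yhat, iso2gene, n_genes = max(iso2gene)) {
  rowgroup_max(as.matrix(Yhat), iso2gene, n_genes)
}

#' Per-term class weights from training genes
#'
#' `w_pos[t]` is the inverse of the proportion of positive training genes for
#' term `t` (and `w_neg[t]` analogously for negatives); both are at least 1.
#' Terms with no positive (or no negative) training gene get `NA` and are
#' dropped from the loss by the trainer.
#'
#' @param Y `g x T` binary gene label matrix.
#' @param train_genes integer indices of training genes.
#' @return List with numeric vectors `w_pos`, `w_neg`.
#' @export
class_weights <- function(Y, train_genes) {
  Yt <- Y[train_genes, , drop = FALSE]
  n <- nrow(Yt)
  npos <- colSums(Yt)
  w_pos <- ifelse(npos > 0, n / npos, NA_real_)
  w_neg <- ifelse(n - npos > 0, n / (n - npos), NA_real_)
  list(w_pos = w_pos, w_neg = w_neg)
}

#' Gene-pooled weighted binary cross-entropy
#'
#' For each term `t` the loss is the mean over genes of
#' `-(w_pos[t] y log yhat + w_neg[t] (1 - y) log(1 - yhat))`, and the total is
#' the sum over terms. Predictions are clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param yhat_gene `g x T` pooled gene scores.
#' @param Y `g x T` binary labels.
#' @param weights list with `w_pos`, `w_neg` (see [class_weights()]).
#' @return Scalar loss.
#' @export
wbce_loss <- function(yhat_gene, Y, weights) {
  if (any(c(weights$w_pos, weights$w_neg) <= 0, na.rm = TRUE))
    stop("config error: class weights must be positive")
  p <- pmin(pmax(as.matrix(yhat_gene), 1e-7), 1 - 1e-7)
  W <- Y * rep(weights$w_pos, each = nrow(Y)) +
    (1 - Y) * rep(weights$w_neg, each = nrow(Y))
  ce <- -(Y * log(p) + (1 - Y) * log(1 - p))
  sum(colMeans(W * ce, na.rm = FALSE), na.rm = TRUE)
}

# Elementwise weight matrix for the tape loss: class weight on the given gene
# rows, zero elsewhere (masked cells contribute nothing).
wbce_weight_matrix <- function(Y, genes, weights) {
  W <- matrix(0, nrow(Y), ncol(Y))
  wp <- ifelse(is.na(weights$w_pos), 0, weights$w_pos)
  wn <- ifelse(is.na(weights$w_neg) | is.na(weights$w_pos), 0, weights$w_neg)
  W[genes, ] <- Y[genes, , drop = FALSE] * rep(wp, each = length(genes)) +
    (1 - Y[genes, , drop = FALSE]) * rep(wn, each = length(genes))
  W
}

# One full-batch Adam step on the gene-pooled WBCE; returns updated params,
# optimizer state and the loss value.
gcn_step <- function(params, opt, X, A_norm, Y, iso2gene, n_genes, Wtrain,
                     denom, activation, dropout, extra_loss = NULL) {
  tape <- new_tape()
  pn <- ad_params(tape, params)
  masks <- NULL
  n_conv <- sum(grepl("^W[0-9]+$", names(params)))
  if (dropout > 0 && n_conv > 1L) {
    masks <- lapply(seq_len(n_conv - 1L), function(l) {
      w <- ncol(params[[paste0("W", l)]])
      matrix(stats::rbinom(nrow(X) * w, 1L, 1 - dropout) / (1 - dropout), nrow(X), w)
    })
  }
  Yhat <- gcn_forward_tape(tape, pn, X, A_norm, activation, masks)
  pooled <- ad_rowgroup_max(tape, Yhat, iso2gene, n_genes)
  loss <- ad_wbce(tape, pooled, Y, Wtrain, denom)
  if (!is.null(extra_loss)) loss <- ad_add(tape, loss, extra_loss(tape, Yhat))
  ad_backward(tape, loss)
  up <- adam_step(opt, params, ad_grads(pn))
  list(params = up$params, opt = up$state, loss = loss$value[1L])
}

# Evaluation-mode gene-pooled WBCE on a gene subset.
gcn_eval_loss <- function(params, X, A_norm, Y, iso2gene, n_genes, genes,
                          weights, activation) {
  Yhat <- gcn_forward(params, X, A_norm, activation)
  pooled <- gene_pool(Yhat, iso2gene, n_genes)
  W <- wbce_weight_matrix(Y, genes, weights)
  p <- pmin(pmax(pooled, 1e-7), 1 - 1e-7)
  -sum(W * (Y * log(p) + (1 - Y) * log(1 - p))) / length(genes)
}

#' Train one omics-specific GCN
#'
#' Full-batch Adam on the gene-pooled weighted BCE over training genes, with
#' early stopping on the validation-gene loss. Transductive: the graph spans
#' all isoforms, but only training-gene labels enter the gradient. Terms with
#' no positive training gene are dropped from this view's loss with a warning.
#'
#' @param X `n x d` feature matrix for this omics view.
#' @param A_norm normalized adjacency over all isoforms.
#' @param Y `g x T` binary gene labels.
#' @param iso2gene integer gene index per isoform.
#' @param split a `split_spec` from [grouped_split()].
#' @param cfg a [gcn_config()].
#' @return A `gcn_fit` list: `params`, `pred` (`n x T` probabilities for all
#'   isoforms), `trace` (per-epoch losses), `weights`, `config`.
#' @export
train_gcn <- function(X, A_norm, Y, iso2gene, split, cfg = gcn_config()) {
  X <- as.matrix(X)
  n_genes <- nrow(Y)
  weights <- class_weights(Y, split$train_genes)
  dropped <- which(is.na(weights$w_pos) | is.na(weights$w_neg))
  if (length(dropped)) {
    warning("term(s) without positive training genes dropped from this view's loss: ",
            paste(dropped, collapse = ", "))
  }
  with_seed(cfg$seed, {
    params <- gcn_init(ncol(X), cfg$hidden, ncol(Y))
    opt <- adam_new(params, lr = cfg$lr)
    Wtrain <- wbce_weight_matrix(Y, split$train_genes, weights)
    denom <- length(split$train_genes)
    best <- list(params = params, val = Inf, epoch = 0L)
    trace <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
    bad <- 0L
    if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
      st <- gcn_step(params, opt, X, A_norm, Y, iso2gene, n_genes, Wtrain,
                     denom, cfg$activation, cfg$dropout)
      params <- st$params; opt <- st$opt
      if (!is.finite(st$loss)) stop("divergence error: non-finite GCN loss at epoch ", ep)
      val <- if (length(split$val_genes)) {
        gcn_eval_loss(params, X, A_norm, Y, iso2gene, n_genes, split$val_genes,
                      weights, cfg$activation)
      } else NA_real_
      trace <- rbind(trace, data.frame(epoch = ep, train = st$loss, val = val))
      if (length(split$val_genes)) {
        if (val < best$val - 1e-9) {
          best <- list(params = params, val = val, epoch = ep)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= cfg$patience) break
        }
      }
    }
    if (length(split$val_genes) && best$epoch > 0L) params <- best$params
  })
  fit <- list(params = params, pred = gcn_forward(params, X, A_norm, cfg$activation),
              trace = trace, weights = weights, dropped_terms = dropped,
              config = cfg)
  class(fit) <- "gcn_fit"
  fit
}
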