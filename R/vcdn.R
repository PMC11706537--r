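# Cross-omics integration: the per-view label distributions predicted by the
# three GCNs are combined, per isoform, into the outer-product tensor
# C[e1,e2,e3] = yhat1[e1] * yhat2[e2] * yhat3[e3], flattened row-major
# (third index fastest) and classified by a small fully connected network
# that learns cross-view label correlations. Training alternates between the
# omics-specific GCNs and the integration network, supervised throughout by
# the gene-pooled weighted BCE.

#' Build cross-omics discovery tensors
#'
#' @param yhat1,yhat2,yhat3 `n x T` per-view probability matrices (rows may
#'   also be single T-vectors).
#' @return `n x T^3` matrix; entry `(e1*T + e2)*T + e3` (zero-based) of row
#'   `i` is `yhat1[i,e1] * yhat2[i,e2] * yhat3[i,e3]`. Memory grows as
#'   `O(n * T^3)`; callers stream isoform blocks when `T` is large.
#' @export
build_tensor <- function(yhat1, yhat2, yhat3) {
  if (is.null(dim(yhat1))) yhat1 <- matrix(yhat1, 1L)
  if (is.null(dim(yhat2))) yhat2 <- matrix(yhat2, 1L)
  if (is.null(dim(yhat3))) yhat3 <- matrix(yhat3, 1L)
  T <- ncol(yhat1)
  if (ncol(yhat2) != T || ncol(yhat3) != T) stop("shape error: label dimensions differ")
  tape <- new_tape()
  nd <- ad_kron3(tape, ad_leaf(tape, as.matrix(yhat1)), ad_leaf(tape, as.matrix(yhat2)),
                 ad_leaf(tape, as.matrix(yhat3)))
  nd$value
}

#' Integration network configuration
#'
#' @param hidden hidden width; default half the flattened tensor length
#'   (`ceiling(T^3 / 2)`), set when the label count is known.
#' @param lr Adam learning rate.
#' @param seed integer seed for initialization.
#' @return A `vcdn_config` list.
#' @export
vcdn_config <- function(hidden = NULL, lr = 1e-3, seed = 1L) {
  cfg <- list(hidden = hidden, lr = lr, seed = as.integer(seed))
  class(cfg) <- "vcdn_config"
  cfg
}

vcdn_init <- function(n_terms, hidden = NULL) {
  d <- n_terms^3
  hidden <- hidden %||% ceiling(d / 2)
  list(Wv1 = init_dense(d, hidden), bv1 = zeros_bias(hidden),
       Wv2 = init_dense(hidden, n_terms, scale = sqrt(1 / hidden)),
       bv2 = zeros_bias(n_terms))
}

vcdn_forward_tape <- function(tape, vn, Cn) {
  H <- ad_lrelu(tape, ad_add_bias(tape, ad_matmul(tape, Cn, vn$Wv1), vn$bv1))
  ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, H, vn$Wv2), vn$bv2))
}

#' Integration network forward pass (evaluation mode)
#'
#' @param params parameter list (from [joint_train()]).
#' @param C `n x T^3` tensor matrix from [build_tensor()] (or one flattened
#'   tensor as a vector).
#' @return `n x T` matrix of probabilities strictly inside (0, 1).
#' @export
vcdn_forward <- function(params, C) {
  if (is.null(dim(C))) C <- matrix(C, 1L)
  tape <- new_tape()
  vn <- ad_params(tape, params)
  vcdn_forward_tape(tape, vn, ad_leaf(tape, as.matrix(C)))$value
}

#' Alternating training schedule
#'
#' @param pretrain_epochs epochs of standalone pretraining per GCN.
#' @param joint_epochs maximum alternating epochs.
#' @param gcn_steps,vcdn_steps update steps per alternating epoch.
#' @param patience early-stopping patience on the validation integration loss.
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(pretrain_epochs = 300L, joint_epochs = 100L,
                           gcn_steps = 1L, vcdn_steps = 1L, patience = 20L) {
  sc <- list(pretrain_epochs = as.integer(pretrain_epochs),
             joint_epochs = as.integer(joint_epochs),
             gcn_steps = as.integer(gcn_steps), vcdn_steps = as.integer(vcdn_steps),
             patience = as.integer(patience))
  stopifnot(all(unlist(sc) >= 0))
  class(sc) <- "train_schedule"
  sc
}

# One Adam step of the integration network on the gene-pooled WBCE.
vcdn_step <- function(vparams, vopt, C, Y, iso2gene, n_genes, Wtrain, denom) {
  tape <- new_tape()
  vn <- ad_params(tape, vparams)
  out <- vcdn_forward_tape(tape, vn, ad_leaf(tape, C))
  pooled <- ad_rowgroup_max(tape, out, iso2gene, n_genes)
  loss <- ad_wbce(tape, pooled, Y, Wtrain, denom)
  ad_backward(tape, loss)
  up <- adam_step(vopt, vparams, ad_grads(vn))
  list(params = up$params, opt = up$state, loss = loss$value[1L])
}

vcdn_eval_loss <- function(vparams, C, Y, iso2gene, n_genes, genes, weights) {
  pooled <- gene_pool(vcdn_forward(vparams, C), iso2gene, n_genes)
  W <- wbce_weight_matrix(Y, genes, weights)
  p <- pmin(pmax(pooled, 1e-7), 1 - 1e-7)
  -sum(W * (Y * log(p) + (1 - Y) * log(1 - p))) / length(genes)
}

#' Joint training of the omics-specific GCNs and the integration network
#'
#' Pretrains one GCN per view (expression, sequence, generated interactions),
#' then alternates: with the integration network fixed, each GCN takes
#' gradient steps on its own gene-pooled weighted BCE (optionally augmented by
#' the integration loss when `couple_vcdn = TRUE`); with the GCNs fixed, the
#' integration network takes steps on the gene-pooled weighted BCE of its
#' fused predictions. Early stopping monitors the validation-gene integration
#' loss. All views are transductive over the same isoform set.
#'
#' @param views list of three lists, each with elements `X` (feature matrix)
#'   and `A_norm` (normalized adjacency); order = expression, sequence,
#'   interactions.
#' @param Y `g x T` binary gene labels.
#' @param iso2gene integer gene index per isoform.
#' @param split a `split_spec`.
#' @param gcn_cfgs list of three [gcn_config()]s (one per view).
#' @param vcdn_cfg a [vcdn_config()].
#' @param schedule a [train_schedule()].
#' @param couple_vcdn if `TRUE`, GCN updates during the alternating phase also
#'   receive the integration loss gradient through the tensor.
#' @return A `joint_fit` list: `gcn_fits` (3), `vcdn_params`, `pred`
#'   (`n x T` final isoform scores), `pred_views` (per-view predictions),
#'   `trace`.
#' @export
joint_train <- function(views, Y, iso2gene, split, gcn_cfgs, vcdn_cfg = vcdn_config(),
                        schedule = train_schedule(), couple_vcdn = FALSE) {
  stopifnot(length(views) == 3L, length(gcn_cfgs) == 3L)
  n_genes <- nrow(Y)
  n_terms <- ncol(Y)
  weights <- class_weights(Y, split$train_genes)
  Wtrain <- wbce_weight_matrix(Y, split$train_genes, weights)
  denom <- length(split$train_genes)

  # (i) pretrain each omics-specific GCN
  fits <- vector("list", 3L)
  for (k in 1:3) {
    cfgk <- gcn_cfgs[[k]]
    cfgk$epochs <- schedule$pretrain_epochs
    fits[[k]] <- train_gcn(views[[k]]$X, views[[k]]$A_norm, Y, iso2gene, split, cfgk)
    if_log("pretrain_gcn", view = k,
           final_train = if (nrow(fits[[k]]$trace)) utils::tail(fits[[k]]$trace$train, 1) else NA)
  }
  gparams <- lapply(fits, `[[`, "params")
  gopts <- lapply(seq_len(3L), function(k) adam_new(gparams[[k]], lr = gcn_cfgs[[k]]$lr))

  vparams <- with_seed(vcdn_cfg$seed, vcdn_init(n_terms, vcdn_cfg$hidden))
  vopt <- adam_new(vparams, lr = vcdn_cfg$lr)

  view_pred <- function() lapply(1:3, function(k) {
    gcn_forward(gparams[[k]], views[[k]]$X, views[[k]]$A_norm, gcn_cfgs[[k]]$activation)
  })

  trace <- data.frame(epoch = integer(0), vcdn_train = numeric(0), vcdn_val = numeric(0))
  best <- list(gparams = gparams, vparams = vparams, val = Inf, epoch = 0L)
  bad <- 0L
  if (schedule$joint_epochs > 0) for (ep in seq_len(schedule$joint_epochs)) {
    # (ii) update GCNs with the integration network fixed
    for (k in 1:3) {
      cfgk <- gcn_cfgs[[k]]
      extra <- NULL
      if (couple_vcdn) {
        ok <- setdiff(1:3, k)
        preds_fixed <- lapply(ok, function(j) {
          gcn_forward(gparams[[j]], views[[j]]$X, views[[j]]$A_norm, gcn_cfgs[[j]]$activation)
        })
        extra <- function(tape, Yhat_k) {
          inputs <- vector("list", 3L)
          inputs[[k]] <- Yhat_k
          inputs[[ok[1L]]] <- ad_leaf(tape, preds_fixed[[1L]])
          inputs[[ok[2L]]] <- ad_leaf(tape, preds_fixed[[2L]])
          Cn <- ad_kron3(tape, inputs[[1L]], inputs[[2L]], inputs[[3L]])
          vn <- ad_params(tape, vparams)
          out <- vcdn_forward_tape(tape, vn, Cn)
          pooled <- ad_rowgroup_max(tape, out, iso2gene, n_genes)
          ad_wbce(tape, pooled, Y, Wtrain, denom)
        }
      }
      for (s in seq_len(schedule$gcn_steps)) {
        st <- with_seed(derive_seed(cfgk$seed, paste0("joint", ep, "k", k, "s", s)),
                        gcn_step(gparams[[k]], gopts[[k]], views[[k]]$X, views[[k]]$A_norm,
                                 Y, iso2gene, n_genes, Wtrain, denom, cfgk$activation,
                                 cfgk$dropout, extra_loss = extra))
        gparams[[k]] <- st$params; gopts[[k]] <- st$opt
        if (!is.finite(st$loss)) stop("divergence error (gcn stage, view ", k,
                                      ") at joint epoch ", ep)
      }
    }
    # (iii) update the integration network with the GCNs fixed
    preds <- view_pred()
    C <- build_tensor(preds[[1L]], preds[[2L]], preds[[3L]])
    vloss <- NA_real_
    for (s in seq_len(schedule$vcdn_steps)) {
      st <- vcdn_step(vparams, vopt, C, Y, iso2gene, n_genes, Wtrain, denom)
      vparams <- st$params; vopt <- st$opt; vloss <- st$loss
      if (!is.finite(vloss)) stop("divergence error (integration stage) at joint epoch ", ep)
    }
    val <- if (length(split$val_genes)) {
      vcdn_eval_loss(vparams, C, Y, iso2gene, n_genes, split$val_genes, weights)
    } else NA_real_
    trace <- rbind(trace, data.frame(epoch = ep, vcdn_train = vloss, vcdn_val = val))
    if (ep %% 20L == 0L) if_log("joint_train", epoch = ep, vcdn_train = vloss, vcdn_val = val)
    if (length(split$val_genes)) {
      if (val < best$val - 1e-9) {
        best <- list(gparams = gparams, vparams = vparams, val = val, epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= schedule$patience) break
      }
    }
  }
  if (length(split$val_genes) && best$epoch > 0L) {
    gparams <- best$gparams
    vparams <- best$vparams
  }
  for (k in 1:3) fits[[k]]$params <- gparams[[k]]
  preds <- view_pred()
  for (k in 1:3) fits[[k]]$pred <- preds[[k]]
  C <- build_tensor(preds[[1L]], preds[[2L]], preds[[3L]])
  final <- vcdn_forward(vparams, C)
  out <- list(gcn_fits = fits, vcdn_params = vparams, pred = final,
              pred_views = preds, trace = trace, weights = weights)
  class(out) <- "joint_fit"
  out
}
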