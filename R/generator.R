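# Isoform-isoform interaction (III) generation.
#
# A multi-input multi-output autoencoder reads an isoform's expression row,
# sequence-feature row and gene-level PPI row through modality-specific input
# layers, fuses them in shared layers down to a bottleneck, and decodes
# through shared layers to three outputs. The PPI output head is widened from
# g genes to n isoforms, so decoding yields a predicted interaction row
# against every isoform -- the III matrix. The interaction head is bilinear:
# isoform i's decoded hidden state is projected and scored against the
# bottleneck embedding of every candidate partner j (plus a per-partner
# bias), so which isoform of a partner gene carries an interaction is
# determined by that isoform's own features; a head with free per-partner
# columns would only ever see gene-block-level supervision and could not
# resolve partner isoforms. Training combines:
#   * a generation loss: for every gene pair, the maximum generated value over
#     its isoform-pair block is scored against the observed PPI with binary
#     cross-entropy (a PPI implies at least one interacting isoform pair);
#   * mean-squared reconstruction of expression and sequence;
#   * a cycle-consistency L1 loss (outputs fed back through the model must
#     reproduce the inputs; the III output is max-pooled back to gene columns
#     before re-entering the PPI input layer);
#   * three auxiliary objectives, each regenerating one zero-masked modality
#     from the other two, with the same loss structure;
#   * an adversarial term from a discriminator separating real PPI rows from
#     generated interaction rows pooled to gene columns.

#' Autoencoder configuration for III generation
#'
#' @param shared_widths widths of the shared encoder interlayers (the decoder
#'   mirrors them).
#' @param bottleneck bottleneck width.
#' @param lambdas length-3 weights for (generation, reconstruction, cycle).
#' @param gan_weight weight of the adversarial generator term.
#' @param disc_widths two hidden widths of the discriminator.
#' @param lr Adam learning rate (autoencoder and discriminator).
#' @param epochs training epochs.
#' @param batch_genes genes per minibatch (`Inf` = full batch; blocks are
#'   gene-complete so the pairwise generation loss stays exact).
#' @param val_frac fraction of genes whose pairwise generation loss is
#'   monitored for early stopping.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed.
#' @return An `ae_config` list.
#' @export
ae_config <- function(shared_widths = c(512L, 256L), bottleneck = 128L,
                      lambdas = c(1, 1, 1), gan_weight = 0.1, disc_widths = c(256L, 64L),
                      lr = 1e-3, epochs = 400L, batch_genes = Inf, val_frac = 0.1,
                      patience = 100L, seed = 1L) {
  cfg <- list(shared_widths = as.integer(shared_widths), bottleneck = as.integer(bottleneck),
              lambdas = as.numeric(lambdas), gan_weight = gan_weight,
              disc_widths = as.integer(disc_widths), lr = lr,
              epochs = as.integer(epochs), batch_genes = batch_genes,
              val_frac = val_frac, patience = as.integer(patience), seed = as.integer(seed))
  stopifnot(length(cfg$lambdas) == 3L, all(cfg$lambdas >= 0), cfg$gan_weight >= 0,
            all(cfg$shared_widths > 0), cfg$bottleneck > 0,
            length(cfg$disc_widths) == 2L, cfg$epochs >= 0)
  class(cfg) <- "ae_config"
  cfg
}

# Parameter initialization. dims = list(e, s, g, n).
ae_init <- function(cfg, dims) {
  h1 <- cfg$shared_widths[1L]
  p <- list(
    Win1 = init_dense(dims$e, h1),
    Win2 = init_dense(dims$s, h1),
    Win3 = init_dense(dims$g, h1),
    benc1 = zeros_bias(h1)
  )
  enc_path <- c(cfg$shared_widths, cfg$bottleneck)
  for (j in seq_len(length(enc_path) - 1L)) {
    p[[paste0("Wenc", j)]] <- init_dense(enc_path[j], enc_path[j + 1L])
    p[[paste0("benc", j + 1L)]] <- zeros_bias(enc_path[j + 1L])
  }
  dec_path <- rev(enc_path)
  for (j in seq_len(length(dec_path) - 1L)) {
    p[[paste0("Wdec", j)]] <- init_dense(dec_path[j], dec_path[j + 1L])
    p[[paste0("bdec", j)]] <- zeros_bias(dec_path[j + 1L])
  }
  p$Wout1 <- init_dense(h1, dims$e, scale = sqrt(1 / h1))
  p$bout1 <- zeros_bias(dims$e)
  p$Wout2 <- init_dense(h1, dims$s, scale = sqrt(1 / h1))
  p$bout2 <- zeros_bias(dims$s)
  # bilinear III head: project the decoder hidden state into bottleneck space
  # and score against partner embeddings; one bias per partner isoform
  p$Wout3 <- init_dense(h1, cfg$bottleneck, scale = sqrt(1 / h1))
  p$bout3 <- zeros_bias(dims$n)
  p
}

disc_init <- function(g, widths) {
  list(Wd1 = init_dense(g, widths[1L]), bd1 = zeros_bias(widths[1L]),
       Wd2 = init_dense(widths[1L], widths[2L]), bd2 = zeros_bias(widths[2L]),
       Wd3 = init_dense(widths[2L], 1L, scale = sqrt(1 / widths[2L])),
       bd3 = zeros_bias(1L))
}

disc_forward_tape <- function(tape, dn, X) {
  H <- ad_lrelu(tape, ad_add_bias(tape, ad_matmul(tape, X, dn$Wd1), dn$bd1))
  H <- ad_lrelu(tape, ad_add_bias(tape, ad_matmul(tape, H, dn$Wd2), dn$bd2))
  ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, H, dn$Wd3), dn$bd3))
}

# Tape forward pass. X nodes are constants; masked modalities contribute
# nothing to the encoder (their input is zero-filled, biases stay shared).
ae_forward_tape <- function(tape, pn, X1, X2, X3, n_enc, n_dec, mask = integer(0)) {
  terms <- list()
  if (!(1L %in% mask)) terms <- c(terms, list(ad_matmul(tape, X1, pn$Win1)))
  if (!(2L %in% mask)) terms <- c(terms, list(ad_matmul(tape, X2, pn$Win2)))
  if (!(3L %in% mask)) terms <- c(terms, list(ad_matmul(tape, X3, pn$Win3)))
  stopifnot(length(terms) >= 2L)
  pre <- terms[[1L]]
  for (tm in terms[-1L]) pre <- ad_add(tape, pre, tm)
  H <- ad_lrelu(tape, ad_add_bias(tape, pre, pn$benc1))
  for (j in seq_len(n_enc)) {
    H <- ad_lrelu(tape, ad_add_bias(tape, ad_matmul(tape, H, pn[[paste0("Wenc", j)]]),
                                    pn[[paste0("benc", j + 1L)]]))
  }
  Z <- H  # bottleneck embedding, one row per isoform
  for (j in seq_len(n_dec)) {
    H <- ad_lrelu(tape, ad_add_bias(tape, ad_matmul(tape, H, pn[[paste0("Wdec", j)]]),
                                    pn[[paste0("bdec", j)]]))
  }
  Q <- ad_matmul(tape, H, pn$Wout3)
  list(
    O1 = ad_add_bias(tape, ad_matmul(tape, H, pn$Wout1), pn$bout1),
    O2 = ad_add_bias(tape, ad_matmul(tape, H, pn$Wout2), pn$bout2),
    O3 = ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, Q, ad_transpose(tape, Z)),
                                      pn$bout3)),
    Z = Z
  )
}

n_shared_layers <- function(params) {
  c(enc = sum(grepl("^Wenc", names(params))), dec = sum(grepl("^Wdec", names(params))))
}

#' Autoencoder forward pass (evaluation mode)
#'
#' @param params autoencoder parameters (from [train_generator()]).
#' @param X1,X2,X3 input matrices (rows may be a subset of isoforms; `X3`
#'   columns are genes).
#' @param mask modalities (subset of 1:3) whose input is zero-masked; the
#'   shared layers and all output heads still run.
#' @return List of output matrices `O1` (expression), `O2` (sequence), `O3`
#'   (interaction rows against all isoforms, in `[0, 1]`), and the bottleneck
#'   embedding `Z`.
#' @export
ae_forward <- function(params, X1, X2, X3, mask = integer(0)) {
  tape <- new_tape()
  pn <- ad_params(tape, params)
  nl <- n_shared_layers(params)
  out <- ae_forward_tape(tape, pn, ad_leaf(tape, as.matrix(X1)),
                         ad_leaf(tape, as.matrix(X2)), ad_leaf(tape, as.matrix(X3)),
                         nl["enc"], nl["dec"], mask)
  lapply(out, function(nd) nd$value)
}

# Gene-pair block maximum of an (isoform x isoform) score matrix -> g x g.
block_max <- function(O3, row_genes, col_genes, n_genes) {
  rowgroup_max(t(rowgroup_max(as.matrix(O3), row_genes, n_genes)), col_genes, n_genes)
}

#' Gene-pair generation loss
#'
#' For every ordered pair of distinct genes, the maximum generated value over
#' the corresponding isoform-pair block of `O3` is scored against the binary
#' PPI status of the gene pair with binary cross-entropy; the result is the
#' mean over gene pairs. A PPI between two genes asserts that at least one of
#' their isoform pairs interacts, which is exactly what the block maximum
#' encodes.
#'
#' @param O3 `n x n` generated interaction matrix in `[0, 1]`.
#' @param X3 `n x g` binary PPI incidence (each isoform carries its gene row).
#' @param iso2gene integer gene index per isoform.
#' @return Scalar loss.
#' @export
loss_generation <- function(O3, X3, iso2gene) {
  g <- ncol(X3)
  if (!all(seq_len(g) %in% iso2gene)) stop("mapping error: gene without isoforms")
  P <- X3[match(seq_len(g), iso2gene), , drop = FALSE]
  M <- block_max(O3, iso2gene, iso2gene, g)
  off <- 1 - diag(g)
  p <- pmin(pmax(M, 1e-7), 1 - 1e-7)
  -sum(off * (P * log(p) + (1 - P) * log(1 - p))) / (g * (g - 1))
}

#' Reconstruction loss for the continuous modalities
#'
#' Sum of the mean squared errors between the expression and sequence outputs
#' and their inputs.
#'
#' @param O1,O2 generated expression / sequence matrices.
#' @param X1,X2 the corresponding inputs.
#' @return Scalar loss.
#' @export
loss_reconstruction <- function(O1, O2, X1, X2) {
  mean((O1 - X1)^2) + mean((O2 - X2)^2)
}

#' Cycle-consistency loss
#'
#' Feeds the first-pass outputs back through the autoencoder (the interaction
#' output is max-pooled over gene columns to re-enter the PPI input layer) and
#' returns the summed mean absolute error between the second-pass outputs and
#' the original inputs, over all three modalities.
#'
#' @param outputs list `O1`, `O2`, `O3` from [ae_forward()].
#' @param params autoencoder parameters.
#' @param X1,X2,X3 original inputs.
#' @param iso2gene integer gene index per isoform (pools `O3` columns).
#' @return Scalar loss.
#' @export
loss_cycle <- function(outputs, params, X1, X2, X3, iso2gene) {
  g <- ncol(X3)
  back3 <- t(rowgroup_max(t(outputs$O3), iso2gene, g))
  second <- ae_forward(params, outputs$O1, outputs$O2, back3)
  mean(abs(second$O1 - X1)) + mean(abs(second$O2 - X2)) +
    mean(abs(t(rowgroup_max(t(second$O3), iso2gene, g)) - X3))
}

#' Combine the primary-objective loss components
#'
#' @param gen,rec,cycle component losses.
#' @param lambdas length-3 nonnegative weights.
#' @return `lambdas[1]*gen + lambdas[2]*rec + lambdas[3]*cycle`.
#' @export
loss_total_primary <- function(gen, rec, cycle, lambdas = c(1, 1, 1)) {
  if (any(lambdas < 0)) stop("config error: lambdas must be nonnegative")
  sum(lambdas * c(gen, rec, cycle))
}

#' Adversarial losses at the current discriminator
#'
#' Generated interaction rows are max-pooled to gene columns and scored by the
#' discriminator against real PPI rows. Returns the minimax discriminator
#' objective `-(E[log D(real)] + E[log(1 - D(fake))])` (to be minimized by the
#' discriminator) and the non-saturating generator term `-E[log D(fake)]`.
#'
#' @param O3 `n x n` generated interaction matrix.
#' @param X3 `n x g` real PPI rows.
#' @param iso2gene integer gene index per isoform.
#' @param disc_params discriminator parameters.
#' @return List with scalars `gen` and `disc`.
#' @export
loss_adversarial <- function(O3, X3, iso2gene, disc_params) {
  g <- ncol(X3)
  fake <- t(rowgroup_max(t(as.matrix(O3)), iso2gene, g))
  tape <- new_tape()
  dn <- ad_params(tape, disc_params)
  d_real <- disc_forward_tape(tape, dn, ad_leaf(tape, as.matrix(X3)))
  d_fake <- disc_forward_tape(tape, dn, ad_leaf(tape, fake))
  if (any(d_real$value <= 0 | d_real$value >= 1 | d_fake$value <= 0 | d_fake$value >= 1))
    stop("activation error: discriminator output outside (0, 1)")
  eps <- 1e-7
  pr <- pmin(pmax(d_real$value, eps), 1 - eps)
  pf <- pmin(pmax(d_fake$value, eps), 1 - eps)
  list(gen = -mean(log(pf)), disc = -(mean(log(pr)) + mean(log(1 - pf))))
}

# Build the full training loss for one objective (0 = primary, k = auxiliary
# masking modality k) on a tape. Returns list(loss, out).
ae_objective_tape <- function(tape, pn, nl, X1n, X2n, X3n,
                              iso2gene_rows, iso2gene, P, offmask, denom_pairs,
                              lambdas, objective) {
  mask <- if (objective == 0L) integer(0) else objective
  out <- ae_forward_tape(tape, pn, X1n, X2n, X3n, nl["enc"], nl["dec"], mask)
  g <- ncol(P)
  L1 <- ad_mse(tape, out$O1, X1n$value)
  L2 <- ad_mse(tape, out$O2, X2n$value)
  M <- ad_colgroup_max(tape, ad_rowgroup_max(tape, out$O3, iso2gene_rows,
                                             max(iso2gene_rows)), iso2gene, g)
  L3 <- ad_wbce(tape, M, P, offmask, denom_pairs)
  parts <- list(`1` = L1, `2` = L2, `3` = L3)
  gen <- if (objective == 0L) L3 else parts[[as.character(objective)]]
  rec_idx <- if (objective == 0L) c(1L, 2L) else setdiff(1:3, objective)
  rec <- parts[[as.character(rec_idx[1L])]]
  for (j in rec_idx[-1L]) rec <- ad_add(tape, rec, parts[[as.character(j)]])
  # cycle: outputs back through the model, unmasked
  back3 <- ad_transpose(tape, ad_rowgroup_max(tape, ad_transpose(tape, out$O3),
                                              iso2gene, g))
  second <- ae_forward_tape(tape, pn, out$O1, out$O2, back3, nl["enc"], nl["dec"])
  cyc <- ad_add(tape, ad_l1(tape, second$O1, X1n$value), ad_l1(tape, second$O2, X2n$value))
  back3b <- ad_transpose(tape, ad_rowgroup_max(tape, ad_transpose(tape, second$O3),
                                               iso2gene, g))
  cyc <- ad_add(tape, cyc, ad_l1(tape, back3b, X3n$value))
  loss <- ad_add(tape, ad_add(tape, ad_scale(tape, gen, lambdas[1L]),
                              ad_scale(tape, rec, lambdas[2L])),
                 ad_scale(tape, cyc, lambdas[3L]))
  list(loss = loss, out = out)
}

#' Train the III generator
#'
#' Alternates one discriminator update and one autoencoder update per epoch.
#' The autoencoder step minimizes the primary objective plus the three
#' auxiliary (masked-modality) objectives plus the non-saturating adversarial
#' term; the discriminator step minimizes its minimax objective on real PPI
#' rows versus pooled generated rows. Early stopping monitors the gene-pair
#' generation loss on a held-out fraction of genes. Deterministic given
#' `cfg$seed`; with `epochs = 0` the freshly initialized parameters are
#' returned.
#'
#' @param bundle an [omics_bundle()].
#' @param cfg an [ae_config()].
#' @return An `iii_generator` fit: `params`, `disc_params`, `trace`, `config`,
#'   `val_genes`.
#' @export
train_generator <- function(bundle, cfg = ae_config()) {
  n <- length(bundle$isoform_ids)
  g <- length(bundle$gene_ids)
  dims <- list(e = ncol(bundle$X1), s = ncol(bundle$X2), g = g, n = n)
  X1 <- bundle$X1; X2 <- bundle$X2; X3 <- bundle$X3
  P <- gene_ppi_matrix(bundle)
  with_seed(cfg$seed, {
    params <- ae_init(cfg, dims)
    disc <- disc_init(g, cfg$disc_widths)
    nl <- n_shared_layers(params)
    opt_ae <- adam_new(params, lr = cfg$lr)
    opt_d <- adam_new(disc, lr = cfg$lr)
    n_val <- max(1L, round(cfg$val_frac * g))
    val_genes <- if (cfg$val_frac > 0) sort(sample.int(g, n_val)) else integer(0)
    trace <- data.frame(epoch = integer(0), total = numeric(0), gen = numeric(0),
                        disc = numeric(0), val_gen = numeric(0))
    best <- list(params = params, val = Inf, epoch = 0L)
    bad <- 0L
    val_gen_loss <- function(pp) {
      O3 <- ae_forward(pp, X1, X2, X3)$O3
      M <- block_max(O3, bundle$iso2gene, bundle$iso2gene, g)
      p <- pmin(pmax(M[val_genes, , drop = FALSE], 1e-7), 1 - 1e-7)
      Pv <- P[val_genes, , drop = FALSE]
      offv <- matrix(1, length(val_genes), g)
      offv[cbind(seq_along(val_genes), val_genes)] <- 0
      -sum(offv * (Pv * log(p) + (1 - Pv) * log(1 - p))) / sum(offv)
    }
    if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
      # a finite gene minibatch restricts which gene rows enter the pairwise
      # generation loss; the forward pass always spans all isoforms because
      # the interaction head scores against every partner embedding
      offb <- 1 - diag(g)
      if (is.finite(cfg$batch_genes) && cfg$batch_genes < g) {
        batch_g <- sort(sample.int(g, cfg$batch_genes))
        offb[setdiff(seq_len(g), batch_g), ] <- 0
      }
      denom_pairs <- sum(offb)

      # -- discriminator step on current generator output
      O3_now <- ae_forward(params, X1, X2, X3)$O3
      fake <- t(rowgroup_max(t(O3_now), bundle$iso2gene, g))
      td <- new_tape()
      dn <- ad_params(td, disc)
      d_real <- disc_forward_tape(td, dn, ad_leaf(td, X3))
      d_fake <- disc_forward_tape(td, dn, ad_leaf(td, fake))
      d_loss <- ad_add(td, ad_nll(td, d_real), ad_nll_complement(td, d_fake))
      ad_backward(td, d_loss)
      upd <- adam_step(opt_d, disc, ad_grads(dn))
      disc <- upd$params; opt_d <- upd$state

      # -- autoencoder step: primary + auxiliaries + adversarial term
      ta <- new_tape()
      pn <- ad_params(ta, params)
      X1n <- ad_leaf(ta, X1)
      X2n <- ad_leaf(ta, X2)
      X3n <- ad_leaf(ta, X3)
      total <- NULL
      primary_out <- NULL
      for (obj in 0:3) {
        ob <- ae_objective_tape(ta, pn, nl, X1n, X2n, X3n,
                                bundle$iso2gene, bundle$iso2gene, P, offb, denom_pairs,
                                cfg$lambdas, obj)
        if (obj == 0L) primary_out <- ob$out
        total <- if (is.null(total)) ob$loss else ad_add(ta, total, ob$loss)
      }
      gen_val <- NA_real_
      if (cfg$gan_weight > 0) {
        dn_fixed <- ad_params(ta, disc)
        fake_nd <- ad_transpose(ta, ad_rowgroup_max(ta, ad_transpose(ta, primary_out$O3),
                                                    bundle$iso2gene, g))
        d_on_fake <- disc_forward_tape(ta, dn_fixed, fake_nd)
        adv <- ad_nll(ta, d_on_fake)
        gen_val <- adv$value[1L]
        total <- ad_add(ta, total, ad_scale(ta, adv, cfg$gan_weight))
      }
      ad_backward(ta, total)
      upa <- adam_step(opt_ae, params, ad_grads(pn))
      params <- upa$params; opt_ae <- upa$state
      if (!is.finite(total$value[1L]))
        stop("divergence error: non-finite autoencoder loss at epoch ", ep)

      vg <- if (length(val_genes)) val_gen_loss(params) else NA_real_
      trace <- rbind(trace, data.frame(epoch = ep, total = total$value[1L],
                                       gen = gen_val, disc = d_loss$value[1L],
                                       val_gen = vg))
      if (ep %% 25L == 0L) {
        if_log("iii_generator", epoch = ep, total = total$value[1L], val_gen = vg)
      }
      if (length(val_genes)) {
        if (vg < best$val - 1e-9) {
          best <- list(params = params, val = vg, epoch = ep)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= cfg$patience) break
        }
      }
    }
    if (length(val_genes) && best$epoch > 0L) params <- best$params
  })
  fit <- list(params = params, disc_params = disc, trace = trace, config = cfg,
              dims = dims, val_genes = val_genes)
  class(fit) <- "iii_generator"
  fit
}

#' Generate the symmetric III matrix from a trained generator
#'
#' @param fit an `iii_generator` from [train_generator()].
#' @param bundle the [omics_bundle()] to score.
#' @return Symmetric `n x n` interaction weight matrix with zero diagonal.
#' @export
predict_iii <- function(fit, bundle) {
  O3 <- ae_forward(fit$params, bundle$X1, bundle$X2, bundle$X3)$O3
  symmetrize(O3)
}

#' Symmetrize a generated interaction matrix
#'
#' Elementwise maximum of the matrix and its transpose, with the diagonal
#' forced to zero; idempotent.
#'
#' @param O3 square matrix with entries in `[0, 1]`.
#' @return Symmetric matrix with zero diagonal.
#' @export
symmetrize <- function(O3) {
  O3 <- as.matrix(O3)
  stopifnot(nrow(O3) == ncol(O3))
  W <- pmax(O3, t(O3))
  diag(W) <- 0
  W
}
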