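# Shared fixtures and oracles, generated in code and cached per test run.

options(isofusion.verbose = FALSE)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Very small dataset for unit tests (fast, structurally complete).
tiny_synth <- function() {
  cached("tiny", synth_generate(synth_config(
    n_genes = 12L, n_terms = 3L, e = 6L, s = 7L, n_latent = 3L, seed = 11L)))
}

# Mid-size dataset for short training runs.
mid_synth <- function() {
  cached("mid", synth_generate(synth_config(
    n_genes = 40L, n_terms = 4L, e = 10L, s = 12L, n_latent = 4L, seed = 5L)))
}

# Down-scaled training configuration used where a test only needs the training
# machinery to run end to end, not to reach full accuracy.
small_pipeline_config <- function() {
  pipeline_config(
    ae = ae_config(shared_widths = 32L, bottleneck = 16L, epochs = 60L,
                   gan_weight = 0.1, patience = 60L),
    gcn = gcn_config(hidden = c(32L, 16L, 8L), epochs = 60L, patience = 60L),
    schedule = train_schedule(pretrain_epochs = 60L, joint_epochs = 8L, patience = 8L))
}

# Independent dense forward pass for the autoencoder, written with explicit
# loops/matrix ops against the parameter list (oracle for ae_forward).
oracle_ae_forward <- function(params, X1, X2, X3, mask = integer(0)) {
  lr <- function(x) ifelse(x > 0, x, 0.01 * x)
  sg <- function(x) 1 / (1 + exp(-x))
  addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)
  pre <- 0
  if (!(1 %in% mask)) pre <- pre + X1 %*% params$Win1
  if (!(2 %in% mask)) pre <- pre + X2 %*% params$Win2
  if (!(3 %in% mask)) pre <- pre + X3 %*% params$Win3
  H <- lr(addb(pre, params$benc1))
  n_enc <- sum(grepl("^Wenc", names(params)))
  for (j in seq_len(n_enc)) {
    H <- lr(addb(H %*% params[[paste0("Wenc", j)]], params[[paste0("benc", j + 1)]]))
  }
  Z <- H
  n_dec <- sum(grepl("^Wdec", names(params)))
  for (j in seq_len(n_dec)) {
    H <- lr(addb(H %*% params[[paste0("Wdec", j)]], params[[paste0("bdec", j)]]))
  }
  list(O1 = addb(H %*% params$Wout1, params$bout1),
       O2 = addb(H %*% params$Wout2, params$bout2),
       O3 = sg(addb((H %*% params$Wout3) %*% t(Z), params$bout3)),
       Z = Z)
}

# Brute-force gene-pair-max generation loss (triple loop over isoform pairs).
oracle_loss_generation <- function(O3, X3, iso2gene) {
  g <- ncol(X3)
  P <- X3[match(seq_len(g), iso2gene), , drop = FALSE]
  total <- 0
  count <- 0
  for (a in seq_len(g)) for (b in seq_len(g)) {
    if (a == b) next
    best <- -Inf
    for (i in which(iso2gene == a)) for (j in which(iso2gene == b)) {
      if (O3[i, j] > best) best <- O3[i, j]
    }
    p <- min(max(best, 1e-7), 1 - 1e-7)
    total <- total - (P[a, b] * log(p) + (1 - P[a, b]) * log(1 - p))
    count <- count + 1
  }
  total / count
}

# Brute-force pairwise-concordance AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# Central-difference gradient of f at params[[name]][idx].
fd_grad <- function(f, params, name, idx, h = 1e-5) {
  up <- params; up[[name]][idx] <- up[[name]][idx] + h
  dn <- params; dn[[name]][idx] <- dn[[name]][idx] - h
  (f(up) - f(dn)) / (2 * h)
}
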