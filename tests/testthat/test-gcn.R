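# Graph construction, renormalization, the GCN forward pass, gene pooling and
# the class-weighted loss, each pinned to hand calculations or brute-force
# oracles.

test_that("the thresholded cosine graph matches a sort-based oracle", {
  # hand example: two identical rows and one orthogonal row, one edge per node
  X <- rbind(c(1, 0), c(1, 0), c(0, 1))
  gs <- build_adjacency(X, a = 1)
  expect_equal(gs$theta, 0)  # 3rd largest of {1,1,0,0,0,0}
  expect_equal(unname(gs$A), rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  # randomized oracle
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1); d <- sample(2:6, 1); a <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n)
    gs <- build_adjacency(X, a)
    S <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      S[i, j] <- sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
    }
    off <- sort(S[row(S) != col(S)], decreasing = TRUE)
    theta <- off[round(n * a)]
    A <- ifelse(S >= theta, pmax(S, 0), 0); diag(A) <- 0
    expect_equal(unname(gs$A), A, tolerance = 1e-6)
  }
})

test_that("identical rows keep all ties and the diagonal stays zero", {
  X <- matrix(1, 5, 3)
  gs <- build_adjacency(X, a = 1)
  expect_equal(unname(gs$A), 1 - diag(5))
  expect_true(all(diag(gs$A) == 0))
})

test_that("adjacency renormalization matches closed forms", {
  # 2-node path: degrees 2 after self-loops -> all entries 1/2
  expect_equal(normalize_adjacency(rbind(c(0, 1), c(1, 0))),
               matrix(0.5, 2, 2))
  # single node
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # 4-cycle (2-regular): every nonzero entry 1/3
  A <- matrix(0, 4, 4)
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1
  A <- pmax(A, t(A))
  An <- normalize_adjacency(A)
  expect_equal(sort(unique(round(An[An > 0], 10))), 1 / 3)
})

test_that("normalized operators have spectral radius at most one", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    ev <- eigen(normalize_adjacency(A), symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("a degenerate identity network reduces to sigmoid(X)", {
  d <- 3
  X <- matrix(rnorm(12), 4)
  params <- list(W1 = diag(d), WL = diag(d), bL = matrix(0, 1, d))
  out <- gcn_forward(params, X, diag(4), activation = "linear")
  expect_equal(out, 1 / (1 + exp(-X)), tolerance = 1e-12)
})

test_that("the GCN forward pass matches an explicit-loop oracle and stays in (0,1)", {
  set.seed(23)
  n <- 6; d <- 4; T <- 3
  X <- matrix(rnorm(n * d), n)
  A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
  An <- normalize_adjacency(A)
  params <- isofusion:::gcn_init(d, c(5, 4, 3), T)
  got <- gcn_forward(params, X, An)
  lr <- function(M) ifelse(M > 0, M, 0.01 * M)
  H <- X
  for (l in 1:3) {
    conv <- matrix(0, n, ncol(params[[paste0("W", l)]]))
    AH <- matrix(0, n, ncol(H))
    for (i in 1:n) for (j in 1:n) AH[i, ] <- AH[i, ] + An[i, j] * H[j, ]
    for (i in 1:n) conv[i, ] <- AH[i, ] %*% params[[paste0("W", l)]]
    H <- lr(conv)
  }
  Z <- H %*% params$WL + matrix(params$bL, n, T, byrow = TRUE)
  expect_equal(got, 1 / (1 + exp(-Z)), tolerance = 1e-6)
  expect_true(all(got > 0 & got < 1))
})

test_that("gene pooling takes the within-gene maximum and ignores isoform order", {
  Yhat <- rbind(c(0.2), c(0.9), c(0.4), c(0.7))
  expect_equal(gene_pool(Yhat, c(1, 1, 1, 2), 2), rbind(0.9, 0.7))
  perm <- c(3, 1, 2, 4)
  expect_equal(gene_pool(Yhat[perm, , drop = FALSE], c(1, 1, 1, 2)[perm], 2),
               rbind(0.9, 0.7))
  # pooled scores dominate every member isoform
  syn <- tiny_synth()
  set.seed(2)
  P <- matrix(runif(length(syn$bundle$isoform_ids) * 3), ncol = 3)
  pooled <- gene_pool(P, syn$bundle$iso2gene, length(syn$bundle$gene_ids))
  for (i in seq_len(nrow(P))) {
    expect_true(all(pooled[syn$bundle$iso2gene[i], ] >= P[i, ]))
  }
})

test_that("the weighted BCE obeys its closed forms", {
  # balanced labels force w_pos = w_neg = 2 and loss = 2 x plain BCE
  Y <- matrix(c(1, 1, 0, 0), 4)
  w <- class_weights(Y, 1:4)
  expect_equal(w$w_pos, 2); expect_equal(w$w_neg, 2)
  set.seed(5)
  p <- matrix(runif(4, 0.2, 0.8), 4)
  plain <- -mean(Y * log(p) + (1 - Y) * log(1 - p))
  expect_equal(wbce_loss(p, Y, w), 2 * plain, tolerance = 1e-12)
  # single positive gene, score 1/2, weight 4 -> 4 ln 2
  expect_equal(wbce_loss(matrix(0.5), matrix(1), list(w_pos = 4, w_neg = 1)),
               4 * log(2), tolerance = 1e-12)
  # perfect predictions vanish (up to clipping)
  expect_lt(wbce_loss(Y, Y, w), 1e-5)
  expect_error(wbce_loss(p, Y, list(w_pos = -1, w_neg = 1)), "config error")
})

test_that("gene-max gradient reaches only the argmax isoform per (gene, term)", {
  syn <- tiny_synth()
  b <- syn$bundle
  g <- length(b$gene_ids)
  set.seed(9)
  params <- list(S = matrix(rnorm(length(b$isoform_ids) * 2), ncol = 2))
  Y <- syn$ann$Y[, 1:2]
  W <- matrix(1, g, 2)
  build <- function(p) {
    tp <- isofusion:::new_tape()
    pn <- isofusion:::ad_params(tp, p)
    sig <- isofusion:::ad_sigmoid(tp, pn$S)
    pooled <- isofusion:::ad_rowgroup_max(tp, sig, b$iso2gene, g)
    list(tape = tp, pn = pn, loss = isofusion:::ad_wbce(tp, pooled, Y, W, g))
  }
  r <- build(params)
  isofusion:::ad_backward(r$tape, r$loss)
  grads <- isofusion:::ad_grads(r$pn)$S
  sig <- 1 / (1 + exp(-params$S))
  for (gi in seq_len(g)) {
    rows <- which(b$iso2gene == gi)
    if (length(rows) < 2) next
    for (t in 1:2) {
      loser <- rows[-which.max(sig[rows, t])]
      expect_true(all(grads[loser, t] == 0))
    }
  }
  # and the argmax gradient matches finite differences
  i <- which(b$iso2gene == b$iso2gene[1])[1]
  fd <- fd_grad(function(p) build(p)$loss$value[1], params, "S",
                which.max(abs(grads)))
  expect_lt(abs(fd - grads[which.max(abs(grads))]) / max(abs(fd), 1e-8), 1e-4)
})

test_that("GCN training descends and never reads test labels", {
  syn <- mid_synth()
  b <- syn$bundle
  sp <- grouped_split(b, syn$homolog_groups, seed = 3)
  gs <- build_adjacency(b$X1, 6)
  cfg <- gcn_config(hidden = c(16L, 8L, 8L), epochs = 40L, patience = 40L, seed = 2L)
  fit0 <- train_gcn(b$X1, gs$A_norm, syn$ann$Y, b$iso2gene, sp,
                    gcn_config(hidden = c(16L, 8L, 8L), epochs = 0L, seed = 2L))
  expect_equal(dim(fit0$pred), c(length(b$isoform_ids), 4L))  # init-only predictions
  fit <- train_gcn(b$X1, gs$A_norm, syn$ann$Y, b$iso2gene, sp, cfg)
  expect_lt(utils::tail(fit$trace$train, 1), fit$trace$train[1])
  # shuffle test-gene labels: training trace and predictions must be identical
  Y2 <- syn$ann$Y
  set.seed(1)
  Y2[sp$test_genes, ] <- Y2[sample(sp$test_genes), ]
  fit2 <- train_gcn(b$X1, gs$A_norm, Y2, b$iso2gene, sp, cfg)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$pred, fit2$pred)
})
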