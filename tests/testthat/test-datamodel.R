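# File I/O, PPI expansion, GO-term filtering, grouped splits and the
# tissue-enhanced subnetwork rule.

write_toy_inputs <- function(dir, ppi_rows = "gA\tgB",
                             map_rows = c("i1\tgA", "i2\tgA", "i3\tgB")) {
  writeLines(c("isoform\tS1\tS2", "i1\t1\t0", "i2\t2\t1", "i3\t0\t3"),
             file.path(dir, "expr.tsv"))
  writeLines(c("isoform\tF1", "i1\t0.5", "i2\t-0.5", "i3\t1.5"),
             file.path(dir, "seq.tsv"))
  writeLines(c("gene_a\tgene_b", ppi_rows), file.path(dir, "ppi.tsv"))
  writeLines(c("isoform\tgene", map_rows), file.path(dir, "map.tsv"))
  dir
}

test_that("PPI edges expand to isoform rows inherited from genes", {
  dir <- write_toy_inputs(withr::local_tempdir())
  b <- load_bundle(file.path(dir, "expr.tsv"), file.path(dir, "seq.tsv"),
                   file.path(dir, "ppi.tsv"), file.path(dir, "map.tsv"))
  # genes sorted: gA, gB; isoforms sorted: i1, i2, i3
  expect_equal(b$gene_ids, c("gA", "gB"))
  expect_equal(unname(b$X3), rbind(c(0, 1), c(0, 1), c(1, 0)))
})

test_that("an empty PPI edge list yields an all-zero incidence matrix", {
  dir <- write_toy_inputs(withr::local_tempdir(), ppi_rows = character(0))
  b <- load_bundle(file.path(dir, "expr.tsv"), file.path(dir, "seq.tsv"),
                   file.path(dir, "ppi.tsv"), file.path(dir, "map.tsv"))
  expect_true(all(b$X3 == 0))
})

test_that("an isoform absent from the map is a mapping error", {
  dir <- write_toy_inputs(withr::local_tempdir(), map_rows = c("i1\tgA", "i2\tgA"))
  expect_error(
    load_bundle(file.path(dir, "expr.tsv"), file.path(dir, "seq.tsv"),
                file.path(dir, "ppi.tsv"), file.path(dir, "map.tsv")),
    "mapping error")
})

test_that("a bundle round-trips through write_bundle / load_bundle", {
  syn <- tiny_synth()
  dir <- withr::local_tempdir()
  write_bundle(syn$bundle, dir)
  b2 <- load_bundle(file.path(dir, "expr.tsv"), file.path(dir, "seq.tsv"),
                    file.path(dir, "ppi.tsv"), file.path(dir, "map.tsv"))
  expect_equal(b2$isoform_ids, syn$bundle$isoform_ids)
  expect_equal(b2$iso2gene, syn$bundle$iso2gene)
  expect_equal(unname(b2$X1), unname(syn$bundle$X1), tolerance = 1e-10)
  expect_equal(unname(b2$X2), unname(syn$bundle$X2), tolerance = 1e-10)
  expect_equal(unname(b2$X3), unname(syn$bundle$X3))
})

test_that("term filtering keeps exactly the in-range sizes and is idempotent", {
  Y <- matrix(0, 1001, 4)
  Y[1:3, 1] <- 1; Y[1:5, 2] <- 1; Y[1:1000, 3] <- 1; Y[1:1001, 4] <- 1
  ann <- annotation_set(c("t1", "t2", "t3", "t4"), Y)
  f <- filter_terms(ann, 5, 1000)
  expect_equal(f$term_ids, c("t2", "t3"))
  expect_equal(f$term_size, c(5L, 1000L))
  expect_equal(filter_terms(f, 5, 1000), f)           # idempotent
  expect_equal(filter_terms(ann, 1, Inf)$term_ids, ann$term_ids)  # identity
  small <- annotation_set(c("a", "b", "c"), {
    m <- matrix(0, 10, 3); m[1:4, ] <- 1; m
  })
  expect_warning(res <- filter_terms(small, 5, 1000), "empty")
  expect_length(res$term_ids, 0L)
})

test_that("grouped splits propagate gene and homolog constraints and are seeded", {
  syn <- mid_synth()
  b <- syn$bundle
  # determinism and gene-level fractions on the synthetic bundle
  s1 <- grouped_split(b, syn$homolog_groups, test_frac = 0.2, seed = 99L)
  s2 <- grouped_split(b, syn$homolog_groups, test_frac = 0.2, seed = 99L)
  expect_identical(s1, s2)
  # exhaustive scan: no gene's isoforms and no homolog group on both sides
  for (sp in list(s1)) {
    test_set <- b$iso2gene[sp$test_iso]
    train_set <- b$iso2gene[c(sp$train_iso, sp$val_iso)]
    expect_length(intersect(test_set, train_set), 0L)
    for (grp in syn$homolog_groups) {
      gi <- match(grp, b$gene_ids)
      expect_true(all(gi %in% sp$test_genes) ||
                    all(gi %in% c(sp$train_genes, sp$val_genes)))
    }
  }
  # one homolog group spanning many genes lands wholly on one side
  grp10 <- list(b$gene_ids[1:10])
  s3 <- grouped_split(b, grp10, test_frac = 0.3, seed = 4L)
  side_test <- all(1:10 %in% s3$test_genes)
  side_train <- all(1:10 %in% c(s3$train_genes, s3$val_genes))
  expect_true(side_test || side_train)
  # a group larger than either side is infeasible
  expect_error(grouped_split(b, list(b$gene_ids), test_frac = 0.2),
               "infeasible")
})

test_that("100 singleton genes split 80/20 exactly and reproducibly", {
  ids <- sprintf("g%03d", 1:100)
  b <- omics_bundle(paste0(ids, ".1"), ids, 1:100,
                    matrix(1, 100, 2), matrix(0, 100, 2), matrix(0, 100, 100))
  s1 <- grouped_split(b, NULL, test_frac = 0.2, val_frac = 0, seed = 21L)
  expect_length(s1$test_genes, 20L)
  expect_identical(s1, grouped_split(b, NULL, test_frac = 0.2, val_frac = 0, seed = 21L))
})

test_that("tissue-enhanced subnetwork keeps edges with an enhanced endpoint", {
  expr <- rbind(gA = c(8, 2, 2, 2), gB = c(1, 1, 1, 1), gC = c(2, 2, 2, 2))
  colnames(expr) <- c("tX", "t2", "t3", "t4")
  edges <- data.frame(gene_a = c("gA", "gB"), gene_b = c("gB", "gC"))
  # gA: 8 >= 4 * mean(2,2,2) -> enhanced; keeps only its edge
  out <- tissue_enhanced_subnetwork(expr, edges, "tX", fold = 4)
  expect_equal(out$gene_a, "gA")
  # nothing enhanced -> empty; everything enhanced -> full
  expr0 <- expr; expr0["gA", "tX"] <- 2
  expect_equal(nrow(tissue_enhanced_subnetwork(expr0, edges, "tX", fold = 4)), 0L)
  expect_equal(nrow(tissue_enhanced_subnetwork(expr, edges, "tX", fold = 0.1)), 2L)
  expect_error(tissue_enhanced_subnetwork(expr, edges, "nope"), "key error")
})

test_that("prediction scores round-trip at six decimals and are range-checked", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(matrix(0.5), "i1", "t1", path)
  expect_match(readLines(path)[2], "0\\.500000")
  set.seed(2)
  scores <- matrix(runif(12), 4)
  write_predictions(scores, paste0("i", 1:4), paste0("t", 1:3), path)
  back <- read_predictions(path)
  expect_equal(unname(back), unname(scores), tolerance = 1e-6)
  expect_error(write_predictions(matrix(1.2), "i1", "t1", path), "range error")
})
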