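# Data model and file I/O: aligned multi-omics matrices, GO annotations,
# grouped train/validation/test splits and tissue-enhanced PPI subnetworks.
#
# All files are plain TSV, UTF-8, unquoted, first column an identifier.
# After loading, isoform and gene identifiers are put in canonical (sorted)
# order and every downstream matrix uses that order.

#' Construct an aligned multi-omics bundle
#'
#' An `omics_bundle` holds three feature matrices over the same ordered set of
#' `n` isoforms: `X1` (`n x e` expression, nonnegative), `X2` (`n x s` sequence
#' features, real) and `X3` (`n x g` binary PPI incidence, where
#' `X3[i, m] = 1` iff the gene of isoform `i` interacts with gene `m`). PPIs
#' are recorded between genes, so every isoform of a gene carries the same
#' `X3` row.
#'
#' @param isoform_ids character vector of isoform identifiers (unique).
#' @param gene_ids character vector of gene identifiers (unique).
#' @param iso2gene integer vector mapping each isoform to its gene's index in
#'   `gene_ids`.
#' @param X1,X2,X3 feature matrices; rows follow `isoform_ids`.
#' @return An object of class `omics_bundle`.
#' @export
omics_bundle <- function(isoform_ids, gene_ids, iso2gene, X1, X2, X3) {
  b <- list(
    isoform_ids = as.character(isoform_ids),
    gene_ids = as.character(gene_ids),
    iso2gene = as.integer(iso2gene),
    X1 = as.matrix(X1), X2 = as.matrix(X2), X3 = as.matrix(X3)
  )
  class(b) <- "omics_bundle"
  validate_bundle(b)
  b
}

validate_bundle <- function(b) {
  n <- length(b$isoform_ids)
  g <- length(b$gene_ids)
  if (anyDuplicated(b$isoform_ids)) stop("duplicate isoform identifiers")
  if (anyDuplicated(b$gene_ids)) stop("duplicate gene identifiers")
  if (length(b$iso2gene) != n) stop("alignment error: iso2gene length != n")
  if (any(b$iso2gene < 1L | b$iso2gene > g)) stop("mapping error: gene index out of range")
  if (!all(seq_len(g) %in% b$iso2gene)) stop("mapping error: gene without isoforms")
  for (nm in c("X1", "X2", "X3")) {
    if (nrow(b[[nm]]) != n) stop("alignment error: ", nm, " has ", nrow(b[[nm]]),
                                 " rows, expected ", n)
  }
  if (ncol(b$X3) != g) stop("alignment error: X3 must have one column per gene")
  if (any(b$X1 < 0)) stop("format error: expression matrix must be nonnegative")
  if (!all(b$X3 %in% c(0, 1))) stop("format error: non-binary PPI entry")
  # PPIs are assigned at the gene level: isoforms of one gene share X3 rows.
  for (gi in seq_len(g)) {
    rows <- which(b$iso2gene == gi)
    if (length(rows) > 1L) {
      ref <- b$X3[rows[1L], ]
      if (any(b$X3[rows[-1L], , drop = FALSE] != rep(ref, each = length(rows) - 1L)))
        stop("format error: isoforms of gene ", b$gene_ids[gi], " have differing PPI rows")
    }
  }
  invisible(b)
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("omics_bundle: %d isoforms / %d genes; X1 %dx%d, X2 %dx%d, X3 %dx%d\n",
              length(x$isoform_ids), length(x$gene_ids),
              nrow(x$X1), ncol(x$X1), nrow(x$X2), ncol(x$X2), nrow(x$X3), ncol(x$X3)))
  invisible(x)
}

read_id_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_id_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a multi-omics bundle from TSV files
#'
#' Reads the expression matrix (isoform x sample), sequence-feature matrix
#' (isoform x feature), gene-level PPI edge list (`gene_a`, `gene_b`, optional
#' binary third column) and the isoform-to-gene map (`isoform`, `gene`), and
#' assembles a validated [omics_bundle()]. The edge list is expanded into the
#' `n x g` binary incidence matrix with each isoform inheriting its gene's
#' interaction row. Isoforms are reordered canonically (sorted identifiers);
#' genes likewise. Genes present in the map without any isoform in the feature
#' files are dropped with a warning.
#'
#' @param expr_path,seq_path,ppi_path,map_path paths to the four TSV inputs.
#' @return An [omics_bundle()].
#' @export
load_bundle <- function(expr_path, seq_path, ppi_path, map_path) {
  X1 <- read_id_matrix(expr_path)
  X2 <- read_id_matrix(seq_path)
  map <- utils::read.delim(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("format error: map file needs two columns (isoform, gene)")
  iso_ids <- sort(rownames(X1))
  if (nrow(X2) != nrow(X1)) {
    stop("alignment error: expression has ", nrow(X1), " isoforms, sequence has ",
         nrow(X2))
  }
  if (!setequal(rownames(X1), rownames(X2)))
    stop("alignment error: expression and sequence files list different isoforms")
  X1 <- X1[iso_ids, , drop = FALSE]
  X2 <- X2[iso_ids, , drop = FALSE]
  map_gene <- as.character(map[[2L]])
  names(map_gene) <- as.character(map[[1L]])
  missing <- setdiff(iso_ids, names(map_gene))
  if (length(missing))
    stop("mapping error: isoform(s) absent from map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  dropped <- setdiff(unique(map_gene), unique(map_gene[iso_ids]))
  if (length(dropped)) {
    warning(length(dropped), " gene(s) in the map have no isoform in the feature files; dropped")
  }
  gene_of_iso <- map_gene[iso_ids]
  gene_ids <- sort(unique(gene_of_iso))
  iso2gene <- match(gene_of_iso, gene_ids)

  edges <- utils::read.delim(ppi_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  P <- matrix(0, length(gene_ids), length(gene_ids),
              dimnames = list(gene_ids, gene_ids))
  if (nrow(edges)) {
    if (ncol(edges) >= 3L) {
      w <- edges[[3L]]
      if (!all(w %in% c(0, 1))) stop("format error: non-binary PPI entry")
      edges <- edges[w == 1, , drop = FALSE]
    }
    a <- as.character(edges[[1L]])
    bb <- as.character(edges[[2L]])
    known <- a %in% gene_ids & bb %in% gene_ids
    if (any(!known)) {
      warning(sum(!known), " PPI edge(s) reference genes without isoforms; dropped")
      a <- a[known]; bb <- bb[known]
    }
    if (length(a)) {
      P[cbind(a, bb)] <- 1
      P[cbind(bb, a)] <- 1
    }
  }
  X3 <- P[iso2gene, , drop = FALSE]
  rownames(X3) <- iso_ids
  omics_bundle(iso_ids, gene_ids, iso2gene, X1, X2, X3)
}

#' Write a bundle back to a directory of TSV files
#'
#' Emits `expr.tsv`, `seq.tsv`, `ppi.tsv` (edge list) and `map.tsv` so that
#' [load_bundle()] round-trips the object.
#'
#' @param bundle an [omics_bundle()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rownames(bundle$X1) <- bundle$isoform_ids
  rownames(bundle$X2) <- bundle$isoform_ids
  if (is.null(colnames(bundle$X1))) colnames(bundle$X1) <- paste0("S", seq_len(ncol(bundle$X1)))
  if (is.null(colnames(bundle$X2))) colnames(bundle$X2) <- paste0("F", seq_len(ncol(bundle$X2)))
  write_id_matrix(bundle$X1, file.path(dir, "expr.tsv"), "isoform")
  write_id_matrix(bundle$X2, file.path(dir, "seq.tsv"), "isoform")
  P <- gene_ppi_matrix(bundle)
  idx <- which(P == 1 & upper.tri(P), arr.ind = TRUE)
  utils::write.table(
    data.frame(gene_a = bundle$gene_ids[idx[, 1L]], gene_b = bundle$gene_ids[idx[, 2L]]),
    file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(isoform = bundle$isoform_ids, gene = bundle$gene_ids[bundle$iso2gene]),
    file.path(dir, "map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# g x g symmetric gene-level PPI matrix recovered from the isoform-expanded X3.
gene_ppi_matrix <- function(bundle) {
  first_iso <- match(seq_along(bundle$gene_ids), bundle$iso2gene)
  P <- bundle$X3[first_iso, , drop = FALSE]
  dimnames(P) <- list(bundle$gene_ids, bundle$gene_ids)
  P
}

# Annotations --------------------------------------------------------------

#' Construct a gene-by-term annotation set
#'
#' @param term_ids character vector of GO term identifiers.
#' @param Y binary `g x T` matrix; rows follow the bundle's gene order.
#' @return An object of class `annotation_set` with per-term sizes.
#' @export
annotation_set <- function(term_ids, Y) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("format error: annotation matrix must be binary")
  if (ncol(Y) != length(term_ids)) stop("alignment error: one column per term required")
  a <- list(term_ids = as.character(term_ids), Y = Y,
            term_size = as.integer(colSums(Y)))
  class(a) <- "annotation_set"
  a
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes x %d terms; term sizes %s\n",
              nrow(x$Y), length(x$term_ids),
              paste(range(x$term_size), collapse = "-")))
  invisible(x)
}

#' Load gene-to-GO annotations
#'
#' Reads a two-column TSV of (gene, term) pairs and builds the binary label
#' matrix over the bundle's canonical gene order. Pairs for unknown genes are
#' dropped with a warning.
#'
#' @param path annotation TSV.
#' @param gene_ids canonical gene order (e.g. `bundle$gene_ids`).
#' @return An [annotation_set()].
#' @export
load_annotations <- function(path, gene_ids) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  terms <- as.character(df[[2L]])
  keep <- genes %in% gene_ids
  if (any(!keep)) warning(sum(!keep), " annotation pair(s) for unknown genes dropped")
  genes <- genes[keep]; terms <- terms[keep]
  term_ids <- sort(unique(terms))
  Y <- matrix(0, length(gene_ids), length(term_ids),
              dimnames = list(gene_ids, term_ids))
  Y[cbind(match(genes, gene_ids), match(terms, term_ids))] <- 1
  annotation_set(term_ids, Y)
}

#' Filter GO terms by annotation size
#'
#' Keeps exactly the terms annotated to between `min_size` and `max_size`
#' genes (inclusive); overly specific and overly general categories carry
#' little transferable signal, so the defaults drop terms with fewer than 5 or
#' more than 1000 annotated genes.
#'
#' @param ann an [annotation_set()].
#' @param min_size,max_size inclusive size bounds.
#' @return A filtered [annotation_set()]; warns if no term survives.
#' @export
filter_terms <- function(ann, min_size = 5L, max_size = 1000L) {
  stopifnot(min_size > 0L, min_size <= max_size)
  keep <- ann$term_size >= min_size & ann$term_size <= max_size
  if (!any(keep)) warning("empty annotation set: all terms filtered out")
  annotation_set(ann$term_ids[keep], ann$Y[, keep, drop = FALSE])
}

# Splits -------------------------------------------------------------------

#' Load homolog groups from a two-column TSV (gene, group_id)
#'
#' @param path TSV path.
#' @return A list of character vectors of gene identifiers, one per group.
#' @export
load_homolog_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' Group-aware train/validation/test split
#'
#' Splits genes (and hence their isoforms) so that no gene's isoforms, and no
#' homologous group's genes, straddle the train/test boundary; homologous
#' genes share sequence, so splitting them would leak test information into
#' training. Gene-level and homolog-group constraints are merged via connected
#' components, whole components are then assigned to sides, and the requested
#' fractions are met at the gene level to within one component. The validation
#' set is carved from the training side the same way.
#'
#' @param bundle an [omics_bundle()].
#' @param homolog_groups list of character vectors of gene ids (or `NULL`);
#'   genes not listed form singleton groups.
#' @param test_frac fraction of genes assigned to the test side.
#' @param val_frac fraction of training genes held out for validation.
#' @param seed integer seed; the split is deterministic given it.
#' @return An object of class `split_spec` with isoform index sets
#'   `train_iso`, `val_iso`, `test_iso` and gene index sets
#'   `train_genes`, `val_genes`, `test_genes`.
#' @export
grouped_split <- function(bundle, homolog_groups = NULL, test_frac = 0.2,
                          val_frac = 0.1, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac >= 0, val_frac < 1)
  g <- length(bundle$gene_ids)
  comp <- seq_len(g)  # union-find over gene indices
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (!is.null(homolog_groups)) {
    for (grp in homolog_groups) {
      idx <- match(grp, bundle$gene_ids)
      idx <- idx[!is.na(idx)]
      if (length(idx) > 1L) for (j in idx[-1L]) comp[find(j)] <- find(idx[1L])
    }
  }
  roots <- vapply(seq_len(g), find, integer(1))
  comp_id <- match(roots, unique(roots))
  comp_sizes <- tabulate(comp_id)
  if (max(comp_sizes) > max(test_frac, 1 - test_frac) * g) {
    stop("infeasible split: one linked group covers ",
         max(comp_sizes), " of ", g, " genes")
  }
  n_comp <- max(comp_id)
  assign_side <- function(comps, sizes, frac) {
    # greedy fill after a seeded shuffle; overshoot by at most one component
    target <- frac * sum(sizes)
    ord <- sample.int(length(comps))
    side <- logical(length(comps))
    got <- 0
    for (i in ord) {
      if (got < target) { side[i] <- TRUE; got <- got + sizes[i] }
    }
    comps[side]
  }
  with_seed(seed, {
    test_comps <- assign_side(seq_len(n_comp), comp_sizes, test_frac)
    test_genes <- which(comp_id %in% test_comps)
    train_side <- setdiff(seq_len(g), test_genes)
    tr_comps <- setdiff(seq_len(n_comp), test_comps)
    val_comps <- if (val_frac > 0 && length(tr_comps))
      assign_side(tr_comps, comp_sizes[tr_comps], val_frac) else integer(0)
    val_genes <- which(comp_id %in% val_comps)
    train_genes <- setdiff(train_side, val_genes)
  })
  sp <- list(
    train_genes = train_genes, val_genes = val_genes, test_genes = test_genes,
    train_iso = which(bundle$iso2gene %in% train_genes),
    val_iso = which(bundle$iso2gene %in% val_genes),
    test_iso = which(bundle$iso2gene %in% test_genes),
    components = comp_id, seed = seed
  )
  class(sp) <- "split_spec"
  sp
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: genes train/val/test = %d/%d/%d; isoforms = %d/%d/%d\n",
              length(x$train_genes), length(x$val_genes), length(x$test_genes),
              length(x$train_iso), length(x$val_iso), length(x$test_iso)))
  invisible(x)
}

# Tissue-enhanced PPI ------------------------------------------------------

#' Extract the tissue-enhanced PPI subnetwork
#'
#' A gene is tissue-enhanced when its mean expression in the target tissue is
#' at least `fold` times its mean across the other tissues (fold 4 for major
#' tissues, 2 for brain sub-tissues). The subnetwork keeps the edges with at
#' least one tissue-enhanced endpoint.
#'
#' @param expr_by_tissue gene x tissue matrix of mean expression with row and
#'   column names.
#' @param ppi_edges data frame with gene identifier columns `gene_a`, `gene_b`.
#' @param tissue target tissue (must be a column of `expr_by_tissue`).
#' @param fold enhancement fold-change threshold (> 0).
#' @return The filtered edge data frame.
#' @export
tissue_enhanced_subnetwork <- function(expr_by_tissue, ppi_edges, tissue, fold = 4) {
  stopifnot(fold > 0)
  if (!tissue %in% colnames(expr_by_tissue))
    stop("key error: tissue '", tissue, "' not in expression matrix")
  if (ncol(expr_by_tissue) < 2L)
    stop("need at least two tissues to define enhancement")
  others <- setdiff(colnames(expr_by_tissue), tissue)
  base <- rowMeans(expr_by_tissue[, others, drop = FALSE])
  enhanced <- rownames(expr_by_tissue)[expr_by_tissue[, tissue] >= fold * base]
  keep <- ppi_edges[[1L]] %in% enhanced | ppi_edges[[2L]] %in% enhanced
  ppi_edges[keep, , drop = FALSE]
}

# Prediction I/O -----------------------------------------------------------

#' Write isoform-level prediction scores to TSV
#'
#' @param scores `n x T` matrix of scores in `[0, 1]`.
#' @param isoform_ids,term_ids identifiers for rows and columns.
#' @param path output path.
#' @return `path`, invisibly. Values are written with six decimals and
#'   round-trip through [read_predictions()] at that precision.
#' @export
write_predictions <- function(scores, isoform_ids, term_ids, path) {
  scores <- as.matrix(scores)
  if (any(scores < 0 | scores > 1)) stop("range error: scores must lie in [0, 1]")
  fm <- matrix(sprintf("%.6f", scores), nrow(scores), ncol(scores))
  df <- data.frame(isoform = as.character(isoform_ids), fm, check.names = FALSE)
  names(df)[-1L] <- as.character(term_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path TSV path.
#' @return Numeric matrix with isoform rownames and term colnames.
#' @export
read_predictions <- function(path) {
  read_id_matrix(path)
}

#' Write an isoform-isoform interaction edge list
#'
#' @param W symmetric `n x n` weight matrix in `[0, 1]` with zero diagonal.
#' @param isoform_ids row/column identifiers.
#' @param path output TSV (`iso_a`, `iso_b`, `weight`).
#' @param threshold minimum weight emitted (default 0 keeps all pairs).
#' @return `path`, invisibly.
#' @export
write_iii_edges <- function(W, isoform_ids, path, threshold = 0) {
  idx <- which(upper.tri(W) & W >= threshold, arr.ind = TRUE)
  df <- data.frame(iso_a = isoform_ids[idx[, 1L]], iso_b = isoform_ids[idx[, 2L]],
                   weight = sprintf("%.6f", W[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
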