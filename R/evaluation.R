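# Gene-level evaluation: per-GO-term AUC and AUPRC over test genes, medians
# across terms, size-bin / ontology-branch breakdowns, and a within-gene
# isoform-resolution AUC for checking that the model distinguishes isoforms
# of the same gene, not just genes.

#' Area under the ROC curve (rank estimator, midpoint ties)
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks give the midpoint tie convention
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise precision-recall summation)
#'
#' Computed as `sum over score thresholds of (delta recall) * precision`
#' without interpolation; tied scores are handled as a single threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @return AUPRC in `[0, 1]`, or `NA` if no positive is present.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  P <- sum(labels)
  if (P == 0L || P == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # threshold groups (ties merged)
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))  # last index of each group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate isoform predictions against gene-level annotations
#'
#' For each term, isoform scores are pooled to genes by the within-gene
#' maximum and AUC / AUPRC are computed over the test genes; per-term values
#' are reported together with medians across terms. Terms whose test genes are
#' single-class are excluded from the medians. SIG (single-isoform gene) and
#' MIG (multi-isoform gene) subsets are also scored per term.
#'
#' @param pred `n x T` isoform score matrix.
#' @param ann an [annotation_set()].
#' @param iso2gene integer gene index per isoform.
#' @param test_genes integer indices of test genes.
#' @return A `metrics_table` data frame (term, size, n_pos_test, auc, auprc,
#'   auc_sig, auprc_sig, auc_mig, auprc_mig) with medians in
#'   `attr(, "medians")`.
#' @export
evaluate_predictions <- function(pred, ann, iso2gene, test_genes) {
  n_genes <- nrow(ann$Y)
  pooled <- gene_pool(as.matrix(pred), iso2gene, n_genes)
  iso_count <- tabulate(iso2gene, n_genes)
  sig <- intersect(test_genes, which(iso_count == 1L))
  mig <- intersect(test_genes, which(iso_count > 1L))
  per_term <- function(t, genes) {
    if (!length(genes)) return(c(NA_real_, NA_real_))
    y <- ann$Y[genes, t]
    c(auc_score(pooled[genes, t], y), average_precision(pooled[genes, t], y))
  }
  T <- length(ann$term_ids)
  m <- data.frame(term = ann$term_ids, size = ann$term_size,
                  n_pos_test = colSums(ann$Y[test_genes, , drop = FALSE]))
  all_m <- vapply(seq_len(T), per_term, numeric(2), genes = test_genes)
  sig_m <- vapply(seq_len(T), per_term, numeric(2), genes = sig)
  mig_m <- vapply(seq_len(T), per_term, numeric(2), genes = mig)
  m$auc <- all_m[1L, ]; m$auprc <- all_m[2L, ]
  m$auc_sig <- sig_m[1L, ]; m$auprc_sig <- sig_m[2L, ]
  m$auc_mig <- mig_m[1L, ]; m$auprc_mig <- mig_m[2L, ]
  excluded <- which(is.na(m$auc))
  if (length(excluded)) {
    if_log("evaluate", note = paste("terms excluded from medians (single-class test labels):",
                                    paste(m$term[excluded], collapse = ",")))
  }
  attr(m, "medians") <- c(auc = stats::median(m$auc, na.rm = TRUE),
                          auprc = stats::median(m$auprc, na.rm = TRUE))
  class(m) <- c("metrics_table", "data.frame")
  m
}

#' Median metrics by term-size bin and ontology branch
#'
#' Aggregates a per-term [evaluate_predictions()] table into median AUC/AUPRC
#' per term-size bin (and optionally per GO branch), separately for all test
#' genes, SIGs and MIGs. Empty bins yield rows of `NA`.
#'
#' @param metrics a `metrics_table`.
#' @param size_bins list of inclusive `(lo, hi)` size ranges; the defaults are
#'   `[10,150]`, `[151,300]`, `[301,600]`, `[601,1000]`.
#' @param branch_map optional named character vector term -> branch
#'   (e.g. BP/CC/MF).
#' @return Data frame of group medians.
#' @export
size_category_report <- function(metrics,
                                 size_bins = list(c(10, 150), c(151, 300),
                                                  c(301, 600), c(601, 1000)),
                                 branch_map = NULL) {
  med <- function(rows) {
    if (!length(rows)) return(rep(NA_real_, 6L))
    apply(metrics[rows, c("auc", "auprc", "auc_sig", "auprc_sig",
                          "auc_mig", "auprc_mig")], 2L,
          stats::median, na.rm = TRUE)
  }
  rows_list <- lapply(size_bins, function(b) {
    which(metrics$size >= b[1L] & metrics$size <= b[2L])
  })
  out <- data.frame(
    group = vapply(size_bins, function(b) sprintf("size[%d,%d]", b[1L], b[2L]),
                   character(1)),
    n_terms = lengths(rows_list)
  )
  out <- cbind(out, t(vapply(rows_list, med, numeric(6))))
  if (!is.null(branch_map)) {
    br <- branch_map[metrics$term]
    for (b in sort(unique(stats::na.omit(br)))) {
      rows <- which(br == b)
      out <- rbind(out, cbind(data.frame(group = paste0("branch:", b),
                                         n_terms = length(rows)),
                              t(med(rows))))
    }
  }
  names(out)[3:8] <- c("auc", "auprc", "auc_sig", "auprc_sig", "auc_mig", "auprc_mig")
  rownames(out) <- NULL
  out
}

#' Within-gene isoform-resolution AUC
#'
#' Considers, for every (gene, term), all pairs of a positive and a negative
#' isoform of the same gene, and returns the fraction of pairs where the
#' positive isoform outscores the negative (ties count 1/2). This isolates the
#' model's ability to disambiguate isoforms of one gene: gene-level pooling is
#' blind to within-gene ordering, and randomly permuting the isoform truth
#' within genes drives this statistic to 0.5.
#'
#' @param pred `n x T` isoform score matrix.
#' @param iso_labels `n x T` binary isoform-level truth.
#' @param iso2gene integer gene index per isoform.
#' @param genes optional gene subset (default: all genes).
#' @return Scalar in `[0, 1]`, or `NA` if no informative pair exists.
#' @export
within_gene_auc <- function(pred, iso_labels, iso2gene, genes = NULL) {
  genes <- genes %||% sort(unique(iso2gene))
  conc <- 0
  total <- 0
  for (gi in genes) {
    rows <- which(iso2gene == gi)
    if (length(rows) < 2L) next
    for (t in seq_len(ncol(pred))) {
      y <- iso_labels[rows, t]
      pos <- rows[y == 1]
      neg <- rows[y == 0]
      if (!length(pos) || !length(neg)) next
      for (p in pos) {
        conc <- conc + sum(pred[p, t] > pred[neg, t]) + 0.5 * sum(pred[p, t] == pred[neg, t])
        total <- total + length(neg)
      }
    }
  }
  if (total == 0) return(NA_real_)
  conc / total
}

#' Write a metrics table to TSV
#'
#' @param metrics a `metrics_table` (or any data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "f"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
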