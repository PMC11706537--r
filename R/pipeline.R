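# End-to-end orchestration: split, III generation, per-view GCNs, integration,
# evaluation -- plus the ablation variants. One master seed fans out to
# per-stage seeds (split, autoencoder, each GCN, integration network) so any
# stage can be reproduced in isolation.

#' Pipeline configuration
#'
#' Bundles the stage configurations. Any field left `NULL` uses that stage's
#' defaults; stage seeds are always overridden by the fan-out from the master
#' seed given to [run_pipeline()].
#'
#' @param ae an [ae_config()] or `NULL`.
#' @param gcn a [gcn_config()] template applied to every view, or `NULL`.
#' @param vcdn a [vcdn_config()] or `NULL`.
#' @param schedule a [train_schedule()] or `NULL`.
#' @param test_frac,val_frac split fractions for [grouped_split()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ae = NULL, gcn = NULL, vcdn = NULL, schedule = NULL,
                            test_frac = 0.2, val_frac = 0.1) {
  cfg <- list(ae = ae %||% ae_config(), gcn = gcn %||% gcn_config(),
              vcdn = vcdn %||% vcdn_config(), schedule = schedule %||% train_schedule(),
              test_frac = test_frac, val_frac = val_frac)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_variants <- c("full", "no-vcdn-expr", "no-vcdn-seq", "no-vcdn-ppi",
                       "no-vcdn-iii", "no-iii", "per-term")

# Build the (X, A_norm) view list for a variant.
make_views <- function(bundle, iii, which_views, a_edges) {
  feats <- list(expr = bundle$X1, seq = bundle$X2, ppi = bundle$X3, iii = iii)
  lapply(which_views, function(v) {
    X <- feats[[v]]
    list(X = X, A_norm = build_adjacency(X, a_edges)$A_norm, name = v)
  })
}

#' Run the full prediction pipeline or one of its ablation variants
#'
#' Variants: `"full"` (III generation, three GCNs on expression / sequence /
#' generated interactions, tensor integration); `"no-vcdn-expr"`,
#' `"no-vcdn-seq"`, `"no-vcdn-ppi"`, `"no-vcdn-iii"` (a single omics-specific
#' GCN, no integration); `"no-iii"` (integration of expression, sequence and
#' raw PPI views, skipping interaction generation); `"per-term"` (the full
#' model run on each GO term separately, dropping multi-label learning).
#'
#' @param bundle an [omics_bundle()].
#' @param ann an [annotation_set()] over the bundle's genes.
#' @param homolog_groups optional list of homologous gene-id groups for the
#'   split.
#' @param variant one of the variants above.
#' @param seed master seed.
#' @param config a [pipeline_config()].
#' @param split optional precomputed `split_spec` (shared across variants).
#' @param iii optional precomputed symmetric interaction matrix (shared across
#'   variants so ablations differ only in the component under study).
#' @return A `pipeline_result`: `pred` (`n x T`), `metrics`, `split`, `iii`
#'   (when generated), `fit`, `variant`, `seed`.
#' @export
run_pipeline <- function(bundle, ann, homolog_groups = NULL,
                         variant = c("full", "no-vcdn-expr", "no-vcdn-seq",
                                     "no-vcdn-ppi", "no-vcdn-iii", "no-iii",
                                     "per-term"),
                         seed = 1L, config = pipeline_config(), split = NULL,
                         iii = NULL) {
  variant <- match.arg(variant)
  stopifnot(nrow(ann$Y) == length(bundle$gene_ids))
  if (is.null(split)) {
    split <- grouped_split(bundle, homolog_groups, config$test_frac, config$val_frac,
                           seed = derive_seed(seed, "split"))
  }
  needs_iii <- variant %in% c("full", "no-vcdn-iii", "per-term")
  gen_fit <- NULL
  if (needs_iii && is.null(iii)) {
    ae_cfg <- config$ae
    ae_cfg$seed <- derive_seed(seed, "ae")
    if_log("pipeline", stage = "iii_generation", variant = variant)
    gen_fit <- train_generator(bundle, ae_cfg)
    iii <- predict_iii(gen_fit, bundle)
  }
  gcn_for <- function(k) {
    cfg <- config$gcn
    cfg$seed <- derive_seed(seed, paste0("gcn", k))
    cfg
  }
  single_view <- c("no-vcdn-expr" = "expr", "no-vcdn-seq" = "seq",
                   "no-vcdn-ppi" = "ppi", "no-vcdn-iii" = "iii")
  if (variant %in% names(single_view)) {
    v <- make_views(bundle, iii, single_view[[variant]], config$gcn$a_edges)[[1L]]
    cfg <- gcn_for(1L)
    cfg$epochs <- config$schedule$pretrain_epochs
    fit <- train_gcn(v$X, v$A_norm, ann$Y, bundle$iso2gene, split, cfg)
    pred <- fit$pred
  } else if (variant == "per-term") {
    views <- make_views(bundle, iii, c("expr", "seq", "iii"), config$gcn$a_edges)
    pred <- matrix(NA_real_, length(bundle$isoform_ids), length(ann$term_ids))
    fit <- vector("list", length(ann$term_ids))
    for (t in seq_along(ann$term_ids)) {
      ann_t <- annotation_set(ann$term_ids[t], ann$Y[, t, drop = FALSE])
      vcfg <- config$vcdn
      vcfg$seed <- derive_seed(seed, paste0("vcdn_t", t))
      fit[[t]] <- joint_train(views, ann_t$Y, bundle$iso2gene, split,
                              lapply(1:3, gcn_for), vcfg, config$schedule)
      pred[, t] <- fit[[t]]$pred
    }
  } else {
    which_views <- if (variant == "no-iii") c("expr", "seq", "ppi") else c("expr", "seq", "iii")
    views <- make_views(bundle, iii, which_views, config$gcn$a_edges)
    vcfg <- config$vcdn
    vcfg$seed <- derive_seed(seed, "vcdn")
    fit <- joint_train(views, ann$Y, bundle$iso2gene, split, lapply(1:3, gcn_for),
                       vcfg, config$schedule)
    pred <- fit$pred
  }
  dimnames(pred) <- list(bundle$isoform_ids, ann$term_ids)
  metrics <- evaluate_predictions(pred, ann, bundle$iso2gene, split$test_genes)
  res <- list(pred = pred, metrics = metrics, split = split, iii = iii,
              generator = gen_fit, fit = fit, variant = variant, seed = seed)
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  med <- attr(x$metrics, "medians")
  cat(sprintf("pipeline_result [%s, seed %d]: median test AUC %.3f, AUPRC %.3f over %d terms\n",
              x$variant, x$seed, med["auc"], med["auprc"], nrow(x$metrics)))
  invisible(x)
}

#' Run every ablation variant on shared inputs
#'
#' All variants share one split and one generated interaction matrix, so the
#' comparison isolates the component each variant removes.
#'
#' @inheritParams run_pipeline
#' @param variants subset of variants to run (default: all six plus the full
#'   model).
#' @return Named list of `pipeline_result`s.
#' @export
ablation_suite <- function(bundle, ann, homolog_groups = NULL, seed = 1L,
                           config = pipeline_config(), variants = pipeline_variants) {
  split <- grouped_split(bundle, homolog_groups, config$test_frac, config$val_frac,
                         seed = derive_seed(seed, "split"))
  iii <- NULL
  if (any(variants %in% c("full", "no-vcdn-iii", "per-term"))) {
    ae_cfg <- config$ae
    ae_cfg$seed <- derive_seed(seed, "ae")
    iii <- predict_iii(train_generator(bundle, ae_cfg), bundle)
  }
  out <- lapply(variants, function(v) {
    if_log("ablation", variant = v)
    run_pipeline(bundle, ann, homolog_groups, variant = v, seed = seed,
                 config = config, split = split, iii = iii)
  })
  names(out) <- variants
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits `pred_final.tsv`, per-view predictions when available
#' (`pred_expr.tsv`, `pred_seq.tsv`, `pred_iii.tsv`), the generated
#' interaction edge list `iii.tsv`, and `metrics.tsv`.
#'
#' @param result a `pipeline_result`.
#' @param bundle the [omics_bundle()] it was computed on.
#' @param ann the [annotation_set()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(result, bundle, ann, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_predictions(result$pred, bundle$isoform_ids, ann$term_ids,
                    file.path(outdir, "pred_final.tsv"))
  if (inherits(result$fit, "joint_fit")) {
    nm <- c("pred_expr.tsv", "pred_seq.tsv", "pred_iii.tsv")
    for (k in 1:3) {
      write_predictions(result$fit$pred_views[[k]], bundle$isoform_ids, ann$term_ids,
                        file.path(outdir, nm[k]))
    }
  }
  if (!is.null(result$iii)) {
    write_iii_edges(result$iii, bundle$isoform_ids, file.path(outdir, "iii.tsv"),
                    threshold = 0.5)
  }
  write_metrics(result$metrics, file.path(outdir, "metrics.tsv"))
  writeLines(c(sprintf("variant\t%s", result$variant),
               sprintf("seed\t%d", result$seed),
               sprintf("median_auc\t%.6f", attr(result$metrics, "medians")["auc"]),
               sprintf("median_auprc\t%.6f", attr(result$metrics, "medians")["auprc"])),
             file.path(outdir, "run_summary.tsv"))
  invisible(outdir)
}
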