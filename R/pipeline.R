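#' Run the full synthetic end-to-end pipeline
#'
#' Simulates a cohort, applies the gene filters, selects the NMF rank,
#' extracts the rank-2 NMF and Welch signatures with their overlap, tests
#' imprinted-gene over-representation in the RT-up list, classifies the
#' study samples with silhouette acceptance, runs the somatic variant
#' cascade on a simulated variant table, and summarizes clinical outcomes.
#' All stage parameters and headline results are collected in a run
#' report; with `out_dir` set, stage outputs are written as TSV/CSV and
#' the report as JSON. Identical seed and parameters give identical
#' outputs.
#'
#' @param seed Master seed for every random stage.
#' @param out_dir Optional output directory (created if needed).
#' @param sim_args List of overrides for [sim_cohort()].
#' @param ranks Candidate NMF ranks for [select_rank()].
#' @param n_runs NMF runs per rank.
#' @param filter_args List of overrides for [filter_genes()].
#' @param signature_fraction Fraction for [nmf_signature()].
#' @param alpha BH significance level for [welch_de()].
#' @param threshold_quantile Silhouette acceptance quantile for
#'   [classify_cohort()].
#' @return The run report (a list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL, sim_args = list(),
                         ranks = 2:4, n_runs = 20, filter_args = list(),
                         signature_fraction = 0.2, alpha = 0.05,
                         threshold_quantile = 0) {
  sim <- do.call(sim_cohort, c(sim_args, list(seed = seed)))
  m <- expr_matrix(sim$expression)
  train_ids <- sim$truth$sample_id[sim$truth$cohort == "training"]
  study_ids <- sim$truth$sample_id[sim$truth$cohort == "study"]
  train_labels <- setNames(sim$truth$true_class[sim$truth$cohort == "training"],
                           train_ids)
  rt_train <- train_ids[train_labels == "RT"]

  filt <- do.call(filter_genes, c(list(m), filter_args))
  mf <- filt$expression

  sel <- select_rank(mf, ranks = ranks, n_runs = n_runs, seed = seed)
  cons2 <- sel$results[["2"]]

  V <- mf - min(mf)
  fit2 <- nmf_factorize(V, 2, seed = derive_seed(seed, 424242))
  sig <- nmf_signature(fit2, rt_samples = rt_train,
                       fraction = signature_fraction)
  de <- welch_de(mf, rt_samples = rt_train, alpha = alpha)
  overlap <- signature_overlap(sig, de)

  universe <- rownames(mf)
  rt_up_de <- de$gene_id[de$significant & de$direction == "RT_up"]
  enrich <- if (length(rt_up_de)) {
    overrepresentation_test(rt_up_de, sim$gene_sets$IMPRINTED, universe)
  } else NULL

  res <- classify_cohort(m[, train_ids], train_labels, m[, study_ids],
                         sig, threshold_quantile = threshold_quantile)
  truth <- setNames(sim$truth$true_class, sim$truth$sample_id)
  study_res <- res[res$cohort == "study", ]
  planted <- truth[study_res$sample_id]
  real <- planted != "OTHER"
  cluster_class <- ifelse(study_res$cluster == "RT_cluster", "RT", "SD-NRT")
  truth_class <- ifelse(planted == "RT", "RT", "SD-NRT")
  accuracy <- if (any(real)) mean(cluster_class[real] == truth_class[real]) else NA
  orthogonal_unclassified <- if (any(!real)) {
    mean(study_res$label[!real] == "unclassified")
  } else NA

  variants <- sim_variants(matched = TRUE, seed = derive_seed(seed, 515151))
  casc <- run_cascade(variants, matched = TRUE)
  kept_truth <- casc$kept$truth
  precision <- if (nrow(casc$kept)) mean(kept_truth == "somatic") else NA
  recall <- sum(kept_truth == "somatic") / sum(variants$truth == "somatic")

  outcome <- dplyr::bind_rows(
    outcome_summary(sim$clinical, "RT"),
    outcome_summary(sim$clinical, "SD-NRT")
  )

  report <- list(
    seed = seed,
    n_genes_total = nrow(m),
    n_genes_kept = nrow(mf),
    rank_selected = sel$rank,
    weak_structure = sel$weak_structure,
    rank_diagnostics = sel$diagnostics,
    cophenetic_rank2 = cons2$cophenetic,
    pac_rank2 = cons2$pac,
    n_signature_genes = nrow(sig),
    n_welch_significant = sum(de$significant),
    signature_overlap = overlap,
    enrichment = enrich,
    classification_accuracy = accuracy,
    orthogonal_unclassified_rate = orthogonal_unclassified,
    variant_precision = precision,
    variant_recall = recall,
    outcome_summary = outcome,
    parameters = list(ranks = ranks, n_runs = n_runs,
                      signature_fraction = signature_fraction, alpha = alpha,
                      threshold_quantile = threshold_quantile,
                      sim = sim$params)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
    write_clinical(sim$clinical, file.path(out_dir, "clinical.csv"))
    readr::write_tsv(filt$report, file.path(out_dir, "gene_filter_report.tsv"))
    readr::write_tsv(sel$diagnostics, file.path(out_dir, "rank_diagnostics.tsv"))
    readr::write_tsv(tibble::as_tibble(sig), file.path(out_dir, "signature.tsv"))
    readr::write_tsv(tibble::as_tibble(de), file.path(out_dir, "welch_de.tsv"))
    readr::write_tsv(tibble::as_tibble(res), file.path(out_dir, "classification.tsv"))
    readr::write_tsv(variants, file.path(out_dir, "variants.tsv"))
    readr::write_tsv(casc$attrition, file.path(out_dir, "variant_attrition.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    return(invisible(report))
  }
  report
}
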