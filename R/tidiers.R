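# broom-style tidiers for the fitted objects

#' @rdname tidy.sdt_consensus
#' @export
glance.sdt_consensus <- function(x, ...) {
  tibble::tibble(rank = x$rank, n_runs = x$n_runs,
                 cophenetic = x$cophenetic, pac = x$pac,
                 n_samples = ncol(x$consensus))
}

#' Tidy NMF consensus results
#'
#' `tidy()` returns one row per sample pair with the co-clustering
#' frequency; `glance()` returns the one-row rank diagnostics.
#'
#' @param x An `sdt_consensus` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdt_consensus <- function(x, ...) {
  co <- x$consensus
  idx <- which(upper.tri(co), arr.ind = TRUE)
  tibble::tibble(sample_1 = rownames(co)[idx[, 1]],
                 sample_2 = colnames(co)[idx[, 2]],
                 consensus = co[idx])
}

#' @rdname tidy.sdt_rank
#' @export
glance.sdt_rank <- function(x, ...) {
  tibble::tibble(rank_selected = x$rank, weak_structure = x$weak_structure,
                 pac = x$diagnostics$pac[x$diagnostics$rank == x$rank],
                 cophenetic = x$diagnostics$cophenetic[x$diagnostics$rank == x$rank])
}

#' Tidy rank-selection diagnostics
#'
#' `tidy()` returns the per-rank PAC and cophenetic table; `glance()` the
#' selected rank with its diagnostics.
#'
#' @param x An `sdt_rank` object from [select_rank()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdt_rank <- function(x, ...) x$diagnostics

#' @rdname tidy.sdt_classification
#' @export
glance.sdt_classification <- function(x, ...) {
  study <- x[x$cohort == "study", ]
  tibble::tibble(
    n_training = sum(x$cohort == "training"),
    n_study = nrow(study),
    n_study_rt = sum(study$label == "RT"),
    n_study_sdnrt = sum(study$label == "SD-NRT"),
    n_study_unclassified = sum(study$label == "unclassified"),
    rt_threshold = attr(x, "thresholds")[["RT_cluster"]],
    nrt_threshold = attr(x, "thresholds")[["NRT_cluster"]]
  )
}

#' Tidy classification results
#'
#' `tidy()` strips attributes and returns the per-sample tibble;
#' `glance()` summarizes call counts and the silhouette acceptance
#' thresholds.
#'
#' @param x An `sdt_classification` object from [classify_cohort()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdt_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sdt_classification")
  attr(out, "hclust") <- NULL
  attr(out, "thresholds") <- NULL
  attr(out, "threshold_quantile") <- NULL
  tibble::as_tibble(out)
}

#' @rdname tidy.sdt_de
#' @export
glance.sdt_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_rt_up = sum(x$significant & x$direction == "RT_up"),
    n_nrt_up = sum(x$significant & x$direction == "NRT_up"),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction")
  )
}

#' Tidy differential-expression tables
#'
#' `tidy()` returns the per-gene table sorted by p-value; `glance()` the
#' significant-gene counts by direction.
#'
#' @param x An `sdt_de` object from [welch_de()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdt_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sdt_de")
  attr(out, "alpha") <- NULL
  attr(out, "correction") <- NULL
  dplyr::arrange(tibble::as_tibble(out), .data$p_value)
}
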