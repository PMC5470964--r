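#' Relative interquartile spread (RIQR)
#'
#' The invariant-gene statistic `max(Q3 - Q2, Q2 - Q1) / Q2`, with
#' quartiles computed by linear interpolation (`stats::quantile` type 7).
#' A constant vector scores 0; genes whose expression barely moves across
#' samples score low and are dropped by [filter_genes()].
#'
#' @param values Numeric vector of positive values, length >= 4.
#' @return A non-negative scalar.
#' @export
#' @examples
#' riqr(c(1, 2, 3, 4, 5)) # 1/3
riqr <- function(values) {
  if (length(values) < 4) abort("riqr needs at least 4 values")
  if (any(!is.finite(values))) abort("riqr: values must be finite")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (q[2] == 0) abort("riqr: median is zero, statistic undefined")
  max(q[3] - q[2], q[2] - q[1]) / q[2]
}

#' Pre-clustering gene filters
#'
#' Keeps the expressed and variable genes on which all clustering is based.
#' A gene is kept iff all three rules hold:
#' \itemize{
#'   \item background: maximum log2 value across samples >=
#'     `background_threshold` (default 3.5 log2 units);
#'   \item fold change: `2^(max - min) >= fold_change_threshold`
#'     (default 1.2, linear ratio);
#'   \item variability: [riqr()] of the gene's values, by default on the
#'     anti-logged (linear) scale, >= `riqr_threshold` (default 0.9).
#' }
#' With `riqr_mode = "quantile"` the RIQR rule instead keeps the top
#' `1 - riqr_threshold` fraction of genes by RIQR.
#'
#' @param expr Expression tibble (`gene_id` + sample columns) or matrix,
#'   log2 scale.
#' @param background_threshold Log2 intensity floor.
#' @param fold_change_threshold Linear max/min ratio.
#' @param riqr_threshold RIQR cutoff (absolute mode) or quantile
#'   (quantile mode).
#' @param riqr_scale Scale on which RIQR is evaluated: `"linear"`
#'   (anti-logged, default) or `"log2"`.
#' @param riqr_mode `"absolute"` (default) or `"quantile"`.
#' @return A list with `expression` (the kept rows, same format as input)
#'   and `report`, a tibble with per-gene `kept` and `removed_by` (the
#'   first failing rule: `background`, `fold_change`, `riqr`, or `NA`).
#' @export
#' @examples
#' sim <- sim_cohort(n_genes = 300, n_signature = 40, seed = 2)
#' f <- filter_genes(sim$expression)
#' dplyr::count(f$report, removed_by)
filter_genes <- function(expr, background_threshold = 3.5,
                         fold_change_threshold = 1.2,
                         riqr_threshold = 0.9,
                         riqr_scale = c("linear", "log2"),
                         riqr_mode = c("absolute", "quantile")) {
  riqr_scale <- match.arg(riqr_scale)
  riqr_mode <- match.arg(riqr_mode)
  if (background_threshold <= 0 || fold_change_threshold <= 0 ||
      riqr_threshold <= 0) {
    abort("all thresholds must be > 0")
  }
  m <- expr_matrix(expr)
  mx <- apply(m, 1, max)
  mn <- apply(m, 1, min)
  pass_bg <- mx >= background_threshold
  pass_fc <- 2^(mx - mn) >= fold_change_threshold
  rq <- apply(if (riqr_scale == "linear") 2^m else m, 1, riqr)
  pass_rq <- if (riqr_mode == "absolute") rq >= riqr_threshold
             else rq >= quantile(rq, riqr_threshold, type = 7)
  kept <- pass_bg & pass_fc & pass_rq
  removed_by <- dplyr::case_when(
    kept ~ NA_character_,
    !pass_bg ~ "background",
    !pass_fc ~ "fold_change",
    TRUE ~ "riqr"
  )
  if (!any(kept)) abort("all genes removed: empty matrix after filtering")
  report <- tibble::tibble(gene_id = rownames(m), riqr = unname(rq),
                           max_log2 = unname(mx),
                           fold_change = unname(2^(mx - mn)),
                           kept = unname(kept),
                           removed_by = unname(removed_by))
  out_m <- m[kept, , drop = FALSE]
  out <- if (is.matrix(expr)) out_m else expr_tibble(out_m)
  list(expression = out, report = report)
}
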