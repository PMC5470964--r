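#' NMF-based signature extraction (rank 2)
#'
#' Scores each gene by the contrast of its two basis weights after scaling
#' each basis column to unit sum: `score = |w1 - w2| / (w1 + w2)` (0 when
#' both weights are 0). The top `fraction` of genes by score form the
#' signature; each selected gene is assigned to the class (RT vs SD-NRT)
#' whose metagene it loads on, where the RT metagene is the one whose `H`
#' weights dominate among the training RT samples.
#'
#' @param fit Rank-2 `sdt_nmf` object from [nmf_factorize()], fitted on a
#'   genes x samples matrix with rownames/colnames.
#' @param rt_samples Character vector of training RT sample ids (columns
#'   of the fitted matrix).
#' @param fraction Fraction of genes to keep (default 0.2, the "20% most
#'   differential" rule).
#' @param gene_ids,sample_ids Identifiers for the rows of `W` and columns
#'   of `H`; taken from the matrices' dimnames when `NULL`.
#' @return An object of class `sdt_signature`: tibble with `gene_id`,
#'   `class` (`RT_up`/`NRT_up`), `score`, sorted by descending score, with
#'   attribute `method = "nmf"`.
#' @export
nmf_signature <- function(fit, rt_samples, fraction = 0.2,
                          gene_ids = NULL, sample_ids = NULL) {
  if (!inherits(fit, "sdt_nmf")) abort("fit must come from nmf_factorize()")
  if (fit$rank != 2) abort("nmf_signature requires a rank-2 factorization")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  W <- fit$W
  H <- fit$H
  gene_ids <- gene_ids %||% rownames(W)
  sample_ids <- sample_ids %||% colnames(H)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("gene and sample identifiers are required (dimnames or arguments)")
  }
  if (!all(rt_samples %in% sample_ids)) abort("unknown rt_samples")
  Ws <- sweep(W, 2, pmax(colSums(W), .Machine$double.eps), `/`)
  tot <- Ws[, 1] + Ws[, 2]
  score <- ifelse(tot == 0, 0, abs(Ws[, 1] - Ws[, 2]) / tot)
  # RT metagene: larger mean relative H weight over training RT samples
  Hn <- sweep(H, 2, pmax(colSums(H), .Machine$double.eps), `/`)
  rt_meta <- which.max(rowMeans(Hn[, sample_ids %in% rt_samples, drop = FALSE]))
  n_keep <- ceiling(fraction * length(score))
  ord <- order(score, decreasing = TRUE)
  keep <- ord[seq_len(n_keep)]
  cls <- ifelse(Ws[keep, rt_meta] >= Ws[keep, 3 - rt_meta], "RT_up", "NRT_up")
  out <- tibble::tibble(gene_id = unname(gene_ids[keep]), class = unname(cls),
                        score = unname(score[keep]))
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  attr(out, "method") <- "nmf"
  class(out) <- c("sdt_signature", class(out))
  out
}

# vectorized per-gene Welch t-test of group a vs group b (columns)
.welch_rows <- function(m, a, b) {
  n1 <- length(a); n2 <- length(b)
  x1 <- m[, a, drop = FALSE]; x2 <- m[, b, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # constant genes in both groups: no evidence either way
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p, diff = m1 - m2)
}

#' Welch t-test differential expression, RT vs the rest
#'
#' Per-gene Welch t-statistics with Welch-Satterthwaite degrees of
#' freedom, two-sided p-values and (by default) Benjamini-Hochberg
#' q-values. "Significantly RT-up" means `q < alpha` (or `p < alpha` when
#' `correction = "none"`) with a positive mean log2 difference.
#'
#' @param expr Expression tibble or matrix, log2 scale.
#' @param rt_samples Character vector of sample ids forming the RT group;
#'   all other columns form the contrast group.
#' @param alpha Significance level.
#' @param correction `"BH"` (default) or `"none"`.
#' @return An object of class `sdt_de`: tibble with `gene_id`,
#'   `t_statistic`, `df`, `p_value`, `q_value`, `mean_diff_log2`,
#'   `direction` (`RT_up`/`NRT_up`) and `significant`.
#' @export
welch_de <- function(expr, rt_samples, alpha = 0.05,
                     correction = c("BH", "none")) {
  correction <- match.arg(correction)
  m <- expr_matrix(expr)
  a <- which(colnames(m) %in% rt_samples)
  b <- setdiff(seq_len(ncol(m)), a)
  if (length(a) < 2 || length(b) < 2) {
    abort("both groups need at least 2 samples")
  }
  w <- .welch_rows(m, a, b)
  q <- if (correction == "BH") p.adjust(w$p, method = "BH") else w$p
  out <- tibble::tibble(
    gene_id = rownames(m),
    t_statistic = unname(w$t), df = unname(w$df),
    p_value = unname(w$p), q_value = unname(q),
    mean_diff_log2 = unname(w$diff),
    direction = unname(ifelse(w$diff >= 0, "RT_up", "NRT_up")),
    significant = unname(q < alpha)
  )
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  class(out) <- c("sdt_de", class(out))
  out
}

#' Pairwise Welch comparison of RT against one subtype
#'
#' Restricts the contrast group to a single named subtype and reports the
#' full differential table plus the `top_n` genes by p-value (all genes if
#' `top_n` exceeds the gene count).
#'
#' @inheritParams welch_de
#' @param subtype_samples Sample ids of the one subtype to contrast.
#' @param top_n Number of top genes to return.
#' @return A list with `table` (an `sdt_de` tibble over
#'   `rt_samples` + `subtype_samples` only) and `top_genes`.
#' @export
pairwise_welch <- function(expr, rt_samples, subtype_samples, top_n = 20,
                           alpha = 0.05, correction = c("BH", "none")) {
  m <- expr_matrix(expr)
  keep <- colnames(m) %in% c(rt_samples, subtype_samples)
  tab <- welch_de(m[, keep, drop = FALSE], rt_samples, alpha = alpha,
                  correction = correction)
  top <- dplyr::arrange(tab, .data$p_value)
  list(table = tab, top_genes = head(top$gene_id, top_n))
}

#' Overlap between an NMF signature and a Welch differential list
#'
#' Counts how many NMF-signature genes also appear in the
#' Welch-significant list, overall and by direction.
#'
#' @param signature `sdt_signature` tibble from [nmf_signature()].
#' @param de `sdt_de` tibble from [welch_de()].
#' @return A tibble with one row per direction plus a `total` row:
#'   `n_signature`, `n_welch`, `n_shared`.
#' @export
signature_overlap <- function(signature, de) {
  sig_sets <- split(signature$gene_id, signature$class)
  de_sig <- de[de$significant, ]
  de_sets <- split(de_sig$gene_id, de_sig$direction)
  rows <- lapply(c("RT_up", "NRT_up"), function(cl) {
    a <- sig_sets[[cl]] %||% character(0)
    b <- de_sets[[cl]] %||% character(0)
    tibble::tibble(direction = cl, n_signature = length(a),
                   n_welch = length(b), n_shared = length(intersect(a, b)))
  })
  tot <- tibble::tibble(
    direction = "total",
    n_signature = nrow(signature),
    n_welch = nrow(de_sig),
    n_shared = length(intersect(signature$gene_id, de_sig$gene_id))
  )
  dplyr::bind_rows(rows, tot)
}
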