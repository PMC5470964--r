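# Internal helpers shared across modules.

# Convert an expression tibble (gene_id + one numeric column per sample) to a
# genes x samples matrix with dimnames. Validates the invariants every stage
# relies on: unique ids, all finite, no missing.
expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    m <- expr
  } else {
    stopifnot(is.data.frame(expr))
    if (!"gene_id" %in% names(expr)) {
      abort("expression table must have a `gene_id` column")
    }
    gid <- as.character(expr$gene_id)
    m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
    if (!is.numeric(m)) abort("expression values must all be numeric")
    rownames(m) <- gid
  }
  if (anyDuplicated(rownames(m))) abort("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in expression matrix")
  if (any(!is.finite(m))) abort("expression matrix contains missing or non-finite values")
  m
}

# Inverse of expr_matrix().
expr_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

# Deterministic per-task seed stream derived from a master seed; stays well
# inside 32-bit integer range for any master below ~2^20.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)
}

# 1 - Pearson correlation distance between the *columns* of m.
# Errors (naming the offender) on zero-variance columns, for which the
# correlation is undefined.
pearson_dist <- function(m) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "zero-variance sample(s): ",
      paste(colnames(m)[sds == 0], collapse = ", "),
      "; Pearson correlation distance is undefined"
    ))
  }
  d <- 1 - cor(m)
  # guard tiny negative values from floating point
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
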