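#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (genes x samples) as `W %*% H`
#' minimizing the squared Frobenius reconstruction error with the classic
#' multiplicative update rules. The objective trace is non-increasing;
#' iteration stops when the relative objective change falls below `tol` or
#' after `max_iter` iterations. Initialization is uniform-random, scaled to
#' the magnitude of `V`; a fixed seed gives identical factors.
#'
#' Log2 expression matrices may contain negative values after centering;
#' use [nmf_consensus()] / [select_rank()], which min-shift per run, or
#' shift the matrix yourself before calling this.
#'
#' @param V Non-negative numeric matrix.
#' @param rank Factorization rank `k`, `2 <= rank < min(dim(V))` (rank 1
#'   is allowed for degenerate checks).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @return An object of class `sdt_nmf`: list with `W`, `H`, `rank`,
#'   `objective_trace`, `iterations`, `converged`, `seed`.
#' @export
nmf_factorize <- function(V, rank, seed = 1, max_iter = 200, tol = 1e-5) {
  V <- as.matrix(V)
  if (any(V < 0)) abort("V must be non-negative; shift log2 data first")
  if (rank < 1 || rank >= min(dim(V))) abort("rank must be in [1, min(dim(V)))")
  eps <- .Machine$double.eps
  withr::with_seed(seed, {
    sc <- sqrt(mean(V) / rank)
    W <- matrix(runif(nrow(V) * rank), nrow(V), rank) * sc
    H <- matrix(runif(rank * ncol(V)), rank, ncol(V)) * sc
  })
  obj <- numeric(max_iter + 1)
  obj[1] <- 0.5 * sum((V - W %*% H)^2)
  it <- 0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    it <- i
    obj[i + 1] <- 0.5 * sum((V - W %*% H)^2)
    if (obj[i] - obj[i + 1] < tol * max(obj[i], eps)) {
      converged <- TRUE
      break
    }
  }
  structure(list(W = W, H = H, rank = rank,
                 objective_trace = obj[seq_len(it + 1)],
                 iterations = it, converged = converged, seed = seed),
            class = "sdt_nmf")
}

#' @export
print.sdt_nmf <- function(x, ...) {
  cat(sprintf("NMF factorization: rank %d, %d x %d, %d iterations, objective %.4g\n",
              x$rank, nrow(x$W), ncol(x$H), x$iterations,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# per-run sample memberships: argmax metagene of H
.nmf_membership <- function(H) apply(H, 2, which.max)

#' Proportion of ambiguous clustering (PAC)
#'
#' The empirical CDF of the off-diagonal upper-triangle consensus entries
#' evaluated at `upper` minus the same CDF at `lower`. Entries near 0 or 1
#' mean samples always or never co-cluster; the mass strictly between the
#' two bounds measures clustering ambiguity. Lower is cleaner.
#'
#' @param consensus Symmetric consensus matrix with entries in `[0, 1]`.
#' @param lower,upper CDF evaluation points, `0 <= lower < upper <= 1`
#'   (defaults 0.1 and 0.9, the established convention).
#' @return A scalar in `[0, 1]`.
#' @export
pac <- function(consensus, lower = 0.1, upper = 0.9) {
  if (lower >= upper || lower < 0 || upper > 1) {
    abort("need 0 <= lower < upper <= 1")
  }
  x <- consensus[upper.tri(consensus)]
  if (!length(x)) abort("consensus matrix has no off-diagonal entries")
  cdf <- ecdf(x)
  cdf(upper) - cdf(lower)
}

#' Consensus clustering over repeated NMF runs
#'
#' Runs [nmf_factorize()] `n_runs` times with different random starts, each
#' time assigning every sample to its argmax metagene, and records the
#' fraction of runs in which each pair of samples co-clusters. Reports the
#' cophenetic correlation (Pearson correlation between the consensus
#' dissimilarities `1 - consensus` and the cophenetic distances of their
#' average-linkage dendrogram) and the [pac()] score.
#'
#' Log2 input may be negative; it is shifted by its minimum so the NMF
#' input is non-negative.
#'
#' @param expr Expression tibble or matrix (genes x samples), log2 scale.
#' @param rank Number of metagenes.
#' @param n_runs Number of randomized runs (>= 2; the reference analysis
#'   used 50).
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param ... Passed to [nmf_factorize()] (`max_iter`, `tol`).
#' @return An object of class `sdt_consensus`: list with `rank`,
#'   `consensus` (samples x samples), `cophenetic`, `pac`, `n_runs`,
#'   `hclust` (the average-linkage tree of `1 - consensus`), and
#'   `membership` (cluster ids from cutting that tree at `rank`).
#' @export
nmf_consensus <- function(expr, rank, n_runs = 50, seed = 1, ...) {
  if (n_runs < 2) abort("n_runs must be >= 2")
  m <- expr_matrix(expr)
  V <- m - min(m)
  n <- ncol(V)
  co <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(V, rank, seed = derive_seed(seed, r), ...)
    memb <- .nmf_membership(fit$H)
    co <- co + outer(memb, memb, `==`)
  }
  consensus <- co / n_runs
  stopifnot(isSymmetric(unname(consensus)), all(diag(consensus) == 1))
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  coph <- if (sd(d) == 0 || sd(cd) == 0) 1 else cor(d, cd)
  structure(list(rank = rank, consensus = consensus, cophenetic = coph,
                 pac = pac(consensus), n_runs = n_runs, hclust = hc,
                 membership = setNames(cutree(hc, k = rank), colnames(V))),
            class = "sdt_consensus")
}

#' @export
print.sdt_consensus <- function(x, ...) {
  cat(sprintf("NMF consensus: rank %d, %d runs, cophenetic %.3f, PAC %.3f\n",
              x$rank, x$n_runs, x$cophenetic, x$pac))
  invisible(x)
}

#' Rank selection by PAC with cophenetic tie-breaking
#'
#' Computes [nmf_consensus()] for each candidate rank and selects the rank
#' with the lowest proportion of ambiguous clustering; ties are broken by
#' higher cophenetic correlation, then lower rank. When even the best rank
#' shows substantial ambiguity (PAC above `weak_pac`), the diagnostics are
#' flagged as weak structure.
#'
#' @param expr Expression tibble or matrix, log2 scale.
#' @param ranks Integer vector of candidate ranks.
#' @param n_runs Randomized runs per rank.
#' @param seed Master seed.
#' @param weak_pac PAC above which the chosen rank is flagged as weak.
#' @param ... Passed to [nmf_factorize()].
#' @return An object of class `sdt_rank`: list with `rank` (chosen),
#'   `diagnostics` (tibble rank/pac/cophenetic), `weak_structure` flag and
#'   `results` (the per-rank `sdt_consensus` objects).
#' @export
#' @examples
#' sim <- sim_cohort(n_genes = 300, n_signature = 40, noise_sd = 0.3,
#'                   effect_size_log2 = 3, n_unclassifiable = 0, seed = 3)
#' sel <- select_rank(filter_genes(sim$expression)$expression,
#'                    ranks = 2:3, n_runs = 5, seed = 3)
#' sel$rank
select_rank <- function(expr, ranks, n_runs = 50, seed = 1, weak_pac = 0.2, ...) {
  if (!length(ranks)) abort("ranks must be non-empty")
  m <- expr_matrix(expr)
  if (any(ranks < 2) || any(ranks >= min(dim(m)))) {
    abort("ranks must lie in [2, min(dim(V)))")
  }
  results <- lapply(ranks, function(k) {
    nmf_consensus(m, k, n_runs = n_runs, seed = derive_seed(seed, 100000 + k), ...)
  })
  diagnostics <- tibble::tibble(
    rank = ranks,
    pac = vapply(results, `[[`, 0, "pac"),
    cophenetic = vapply(results, `[[`, 0, "cophenetic")
  )
  ord <- order(diagnostics$pac, -diagnostics$cophenetic, diagnostics$rank)
  best <- ord[1]
  weak <- diagnostics$pac[best] > weak_pac
  if (weak) {
    warn(sprintf("weak cluster structure: best PAC %.3f at rank %d",
                 diagnostics$pac[best], diagnostics$rank[best]))
  }
  structure(list(rank = diagnostics$rank[best], diagnostics = diagnostics,
                 weak_structure = weak, results = setNames(results, ranks)),
            class = "sdt_rank")
}

#' @export
print.sdt_rank <- function(x, ...) {
  cat(sprintf("Selected NMF rank: %d%s\n", x$rank,
              if (x$weak_structure) " (weak structure)" else ""))
  print(x$diagnostics)
  invisible(x)
}

#' Unsupervised hierarchical clustering of samples
#'
#' Average-linkage clustering of samples under the Pearson correlation
#' distance `d(i, j) = 1 - cor(x_i, x_j)` over genes, cut into `k`
#' clusters.
#'
#' @param expr Expression tibble or matrix (genes x samples).
#' @param k Number of clusters.
#' @return A list with `clusters` (tibble `sample_id`, `cluster`) and
#'   `hclust` (the dendrogram).
#' @export
hierarchical_cluster <- function(expr, k) {
  m <- expr_matrix(expr)
  if (k < 1 || k > ncol(m)) abort("k must be in [1, n_samples]")
  d <- as.dist(pearson_dist(m))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = k)
  list(clusters = tibble::tibble(sample_id = colnames(m), cluster = unname(cl)),
       hclust = hc)
}
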