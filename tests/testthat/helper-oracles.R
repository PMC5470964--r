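# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. Deliberately naive.

# linear-interpolation quantile: h = (n-1)p, x[h+1] interpolated
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

oracle_riqr <- function(x) {
  q1 <- oracle_quantile(x, 0.25)
  q2 <- oracle_quantile(x, 0.5)
  q3 <- oracle_quantile(x, 0.75)
  max(q3 - q2, q2 - q1) / q2
}

# naive average-linkage agglomeration: returns sorted merge heights
oracle_avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

oracle_silhouette <- function(d, cl) {
  d <- as.matrix(d)
  vapply(seq_len(nrow(d)), function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(sapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(d[i, cl == k])))
    (b - a) / max(a, b)
  }, 0)
}

# upper-tail hypergeometric P(X >= k) by direct pmf summation
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

oracle_pac <- function(x, lower = 0.1, upper = 0.9) {
  mean(x <= upper) - mean(x <= lower)
}

# random expression matrix with two planted sample blocks
two_block_matrix <- function(n_genes = 60, n1 = 6, n2 = 6, effect = 3,
                             noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    base <- runif(n_genes, 4, 8)
    m <- matrix(rnorm(n_genes * (n1 + n2), 0, noise), n_genes) + base
    up1 <- seq_len(n_genes / 2)
    up2 <- setdiff(seq_len(n_genes), up1)
    m[up1, seq_len(n1)] <- m[up1, seq_len(n1)] + effect
    m[up2, n1 + seq_len(n2)] <- m[up2, n1 + seq_len(n2)] + effect
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        c(sprintf("A%02d", seq_len(n1)),
                          sprintf("B%02d", seq_len(n2))))
    m
  })
}
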