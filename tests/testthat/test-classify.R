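# training matrix + labels used across classification tests
make_training <- function(seed = 30, ...) {
  sim <- sim_cohort(n_genes = 300, n_signature = 60,
                    study_counts = c(RT = 6, ES = 3, UC = 1),
                    n_unclassifiable = 3, seed = seed, ...)
  m <- sdtclass:::expr_matrix(sim$expression)
  tr <- sim$truth$cohort == "training"
  list(sim = sim, m = m,
       train = m[, sim$truth$sample_id[tr]],
       study = m[, sim$truth$sample_id[!tr]],
       labels = setNames(sim$truth$true_class[tr], sim$truth$sample_id[tr]),
       truth = setNames(sim$truth$true_class, sim$truth$sample_id))
}

test_that("silhouette matches its definition and the cluster package", {
  # hand-computable 4-point configuration
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  cl <- setNames(c(1, 1, 2, 2), letters[1:4])
  s <- silhouette_scores(NULL, cl, dist_matrix = d)
  expect_equal(s$silhouette, rep((5 - 1) / 5, 4))

  # sample equidistant to both clusters scores 0
  d2 <- matrix(c(0, 2, 2,
                 2, 0, 2,
                 2, 2, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  s2 <- silhouette_scores(NULL, setNames(c(1, 1, 2), letters[1:3]),
                          dist_matrix = d2)
  expect_equal(s2$silhouette[1], 0)
  expect_equal(s2$silhouette[3], 0)  # singleton convention

  withr::with_seed(31, {
    for (i in 1:5) {
      n <- sample(6:15, 1)
      x <- matrix(rnorm(n * n), n)
      d <- as.matrix(dist(x)); dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
      cl <- setNames(sample(1:3, n, replace = TRUE), colnames(d))
      if (length(unique(cl)) < 2) next
      got <- silhouette_scores(NULL, cl, dist_matrix = d)$silhouette
      expect_equal(got, oracle_silhouette(d, cl[colnames(d)]))
      ref <- cluster::silhouette(as.integer(cl[colnames(d)]), dmatrix = d)
      if (!is.null(dim(ref))) {
        # cluster:: assigns singletons 0 as well
        expect_equal(got, unname(ref[, "sil_width"]), tolerance = 1e-12)
      }
    }
  })
  expect_error(silhouette_scores(NULL, setNames(c(1, 1, 1), letters[1:3]),
                                 dist_matrix = d2), "2 clusters")
})

test_that("well-separated clusters score near 1", {
  m <- two_block_matrix(effect = 4, noise = 0.1, seed = 33)
  cl <- setNames(rep(1:2, each = 6), colnames(m))
  s <- silhouette_scores(m, cl)
  expect_true(all(s$silhouette > 0.9))
})

test_that("classification engine assigns duplicates, noise and truth correctly", {
  tt <- make_training(seed = 34)
  sig <- tt$sim$signature

  res <- classify_cohort(tt$train, tt$labels, tt$study, sig)
  expect_s3_class(res, "sdt_classification")
  stu <- res[res$cohort == "study", ]
  planted <- tt$truth[stu$sample_id]

  # orthogonal samples are unclassified
  expect_true(all(stu$label[planted == "OTHER"] == "unclassified"))
  # real samples land in the correct cluster
  cc <- ifelse(stu$cluster == "RT_cluster", "RT", "SD-NRT")
  expect_equal(cc[planted != "OTHER"],
               unname(ifelse(planted[planted != "OTHER"] == "RT",
                             "RT", "SD-NRT")))

  # a study sample duplicated from a training RT profile is RT
  rt1 <- names(tt$labels)[tt$labels == "RT"][1]
  study2 <- cbind(tt$study, DUP = tt$train[, rt1])
  res2 <- classify_cohort(tt$train, tt$labels, study2, sig)
  dup <- res2[res2$sample_id == "DUP", ]
  expect_equal(dup$cluster, "RT_cluster")
  expect_equal(dup$label, "RT")
  expect_gte(dup$silhouette,
             res2$silhouette[res2$sample_id == rt1] - 1e-9)
})

test_that("acceptance threshold is monotone and ordering-invariant", {
  tt <- make_training(seed = 35)
  sig <- tt$sim$signature
  res0 <- classify_cohort(tt$train, tt$labels, tt$study, sig,
                          threshold_quantile = 0)
  res5 <- classify_cohort(tt$train, tt$labels, tt$study, sig,
                          threshold_quantile = 0.5)
  un0 <- res0$sample_id[res0$label == "unclassified"]
  un5 <- res5$sample_id[res5$label == "unclassified"]
  expect_true(all(un0 %in% un5))

  perm <- withr::with_seed(35, sample(ncol(tt$study)))
  resp <- classify_cohort(tt$train, tt$labels, tt$study[, perm], sig)
  resp <- resp[match(res0$sample_id, resp$sample_id), ]
  expect_equal(resp$silhouette, res0$silhouette)
  expect_equal(resp$label, res0$label)
})

test_that("zero study samples reduce to the training-only clustering", {
  tt <- make_training(seed = 36)
  sig <- tt$sim$signature
  res <- classify_cohort(tt$train, tt$labels, NULL, sig)
  hc <- hierarchical_cluster(tt$train[sig$gene_id, ], k = 2)
  cl <- setNames(hc$clusters$cluster, hc$clusters$sample_id)
  ref <- silhouette_scores(tt$train[sig$gene_id, ], cl)
  expect_equal(setNames(res$silhouette, res$sample_id)[ref$sample_id],
               setNames(ref$silhouette, ref$sample_id))
})

test_that("subtype centroid calls behave on exact and degenerate profiles", {
  tt <- make_training(seed = 37)
  sig_genes <- tt$sim$signature$gene_id
  train <- tt$train[sig_genes, ]
  es <- names(tt$labels)[tt$labels == "ES"]
  centroid <- rowMeans(train[, es, drop = FALSE])
  query <- cbind(ESC = centroid, FLAT = rep(3, length(centroid)))
  res <- subtype_call(query, train, tt$labels)
  expect_equal(res$subtype_call[res$sample_id == "ESC"], "ES")
  expect_equal(res$cor_ES[res$sample_id == "ESC"], 1, tolerance = 1e-12)
  expect_equal(res$subtype_call[res$sample_id == "FLAT"], "none")

  # planted UC study sample is recovered as UC when the gene space
  # includes the subtype-discriminating blocks
  disc <- c(sig_genes, unlist(tt$sim$subtype_blocks[c("ES", "RMC", "UC")]))
  uc_study <- tt$sim$truth$sample_id[tt$sim$truth$cohort == "study" &
                                       tt$sim$truth$true_class == "UC"]
  res2 <- subtype_call(tt$study[disc, uc_study, drop = FALSE],
                       tt$train[disc, ], tt$labels)
  expect_equal(res2$subtype_call, rep("UC", length(uc_study)))
})

test_that("marker z-scores match brute force and flag outliers", {
  m <- two_block_matrix(seed = 38)
  rep_ <- marker_report(m, c("g001", "g002"))
  for (g in c("g001", "g002")) {
    v <- m[g, ]
    expect_equal(rep_$z[rep_$gene_id == g], unname((v - mean(v)) / sd(v)))
  }
  flat <- m
  flat["g003", ] <- 7
  expect_true(all(marker_report(flat, "g003")$z == 0))
  shifted <- m
  shifted["g004", 1] <- mean(m["g004", ]) + 5 * sd(m["g004", ])
  expect_true(marker_report(shifted, "g004")$flagged[1])
  expect_error(marker_report(m, "absent_gene"), "absent_gene")
})

test_that("silhouette-age correlation matches closed-form Pearson", {
  mk <- function(sil, age) {
    list(
      classification = tibble::tibble(sample_id = paste0("s", seq_along(sil)),
                                      label = "RT", silhouette = sil),
      clinical = tibble::tibble(sample_id = paste0("s", seq_along(sil)),
                                age_years = age)
    )
  }
  x <- mk(c(0, 1, 2, 3), c(0, 1, 2, 4))
  out <- silhouette_age_correlation(x$classification, x$clinical)
  expect_equal(out$r, 0.9827, tolerance = 1e-4)
  prop <- mk(c(0.1, 0.2, 0.4), c(1, 2, 4))
  expect_equal(silhouette_age_correlation(prop$classification,
                                          prop$clinical)$r, 1)
  expect_error(silhouette_age_correlation(mk(1:2, 1:2)$classification,
                                          mk(1:2, 1:2)$clinical), "3 RT")

  # permuted ages show no correlation on average
  withr::with_seed(39, {
    rs <- replicate(200, {
      y <- mk(runif(8), sample(1:40, 8))
      silhouette_age_correlation(y$classification, y$clinical)$r
    })
    expect_lt(abs(mean(rs)), 0.1)
  })
})
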