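#' Silhouette scores under the Pearson correlation distance
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where
#' `a(i)` is the mean distance of sample `i` to its own cluster and `b(i)`
#' the mean distance to the nearest other cluster. Samples in singleton
#' clusters score 0 by convention. Distances are `1 - Pearson correlation`
#' between sample profiles unless a precomputed distance matrix is given.
#'
#' @param expr Expression tibble or matrix (genes x samples), or `NULL`
#'   when `dist_matrix` is supplied.
#' @param clusters Named vector (or tibble `sample_id`, `cluster`) of
#'   cluster labels covering every sample.
#' @param dist_matrix Optional precomputed symmetric distance matrix.
#' @return A tibble `sample_id`, `cluster`, `silhouette`.
#' @export
silhouette_scores <- function(expr, clusters, dist_matrix = NULL) {
  if (is.data.frame(clusters)) {
    clusters <- setNames(clusters$cluster, clusters$sample_id)
  }
  d <- if (is.null(dist_matrix)) pearson_dist(expr_matrix(expr)) else as.matrix(dist_matrix)
  ids <- colnames(d)
  if (!all(ids %in% names(clusters))) abort("clusters must cover every sample")
  cl <- clusters[ids]
  if (length(unique(cl)) < 2) abort("silhouette needs at least 2 clusters")
  sil <- vapply(seq_along(ids), function(i) {
    own <- which(cl == cl[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k) {
      mean(d[i, cl == k])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  tibble::tibble(sample_id = ids, cluster = unname(cl), silhouette = sil)
}

#' Classify a study cohort against a labelled training set
#'
#' The supervised re-classification engine: training and study samples are
#' restricted to the signature genes and jointly clustered (average
#' linkage, `1 - Pearson` distance) with the tree cut at `k = 2`. The
#' cluster holding the majority of training RT samples is the RT cluster.
#' Silhouette scores are computed on the joint two-cluster partition; a
#' study sample is given its cluster's class label only when its
#' silhouette is at least the `threshold_quantile` quantile of the
#' *training* silhouettes within that cluster (default 0, i.e. the
#' training minimum — "at least equivalent to the training scores"),
#' otherwise it is `unclassified`. Samples landing in the SD-NRT cluster
#' additionally receive a nearest-subtype-centroid call via
#' [subtype_call()].
#'
#' @param train Expression tibble or matrix of training samples.
#' @param train_labels Named vector (or tibble `sample_id`,
#'   `diagnosis_label`) with training classes among `RT`, `ES`, `RMC`,
#'   `UC`.
#' @param study Expression tibble or matrix of study samples (may have 0
#'   columns).
#' @param signature `sdt_signature` tibble, or character vector of gene
#'   ids.
#' @param threshold_quantile Quantile of within-cluster training
#'   silhouettes a study sample must reach to be labelled.
#' @return An object of class `sdt_classification`: tibble with
#'   `sample_id`, `cohort`, `cluster` (`RT_cluster`/`NRT_cluster`),
#'   `silhouette`, `label` (`RT`/`SD-NRT`/`unclassified`; training samples
#'   keep their training class), `subtype_call` and per-subtype
#'   correlation columns. The joint dendrogram and acceptance thresholds
#'   are attached as attributes.
#' @export
#' @examples
#' sim <- sim_cohort(n_genes = 300, n_signature = 60, n_unclassifiable = 2,
#'                   study_counts = c(RT = 4, ES = 2), seed = 5)
#' tr <- sim$truth$cohort == "training"
#' res <- classify_cohort(
#'   dplyr::select(sim$expression, gene_id, dplyr::all_of(sim$truth$sample_id[tr])),
#'   setNames(sim$truth$true_class[tr], sim$truth$sample_id[tr]),
#'   dplyr::select(sim$expression, gene_id, dplyr::all_of(sim$truth$sample_id[!tr])),
#'   sim$signature)
#' dplyr::count(res, label)
classify_cohort <- function(train, train_labels, study, signature,
                            threshold_quantile = 0) {
  if (is.data.frame(train_labels)) {
    train_labels <- setNames(train_labels$diagnosis_label, train_labels$sample_id)
  }
  genes <- if (is.data.frame(signature) && "gene_id" %in% names(signature)) {
    signature$gene_id
  } else {
    as.character(signature)
  }
  mt <- expr_matrix(train)
  ms <- if (is.null(study)) mt[, 0, drop = FALSE] else expr_matrix(study)
  if (!all(genes %in% rownames(mt)) || (ncol(ms) && !all(genes %in% rownames(ms)))) {
    abort("signature genes missing from training or study matrix")
  }
  if (!all(colnames(mt) %in% names(train_labels))) {
    abort("train_labels must cover every training sample")
  }
  rt_train <- colnames(mt)[train_labels[colnames(mt)] == "RT"]
  if (!length(rt_train) || length(rt_train) == ncol(mt)) {
    abort("training set must contain both RT and non-RT samples")
  }

  joint <- cbind(mt[genes, , drop = FALSE], ms[genes, , drop = FALSE])
  d <- pearson_dist(joint)
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = 2)

  n_rt_in_1 <- sum(cl[rt_train] == 1)
  if (n_rt_in_1 * 2 == length(rt_train)) {
    abort("unstable training separation: training RT split equally between clusters")
  }
  rt_cluster <- if (n_rt_in_1 * 2 > length(rt_train)) 1L else 2L
  cluster_name <- ifelse(cl == rt_cluster, "RT_cluster", "NRT_cluster")

  sil <- silhouette_scores(NULL, cl, dist_matrix = d)
  sil_v <- setNames(sil$silhouette, sil$sample_id)

  is_train <- names(cl) %in% colnames(mt)
  thr <- vapply(c("RT_cluster", "NRT_cluster"), function(cn) {
    s <- sil_v[is_train & cluster_name == cn]
    if (!length(s)) return(Inf)
    unname(quantile(s, threshold_quantile, type = 7))
  }, 0)

  cls_of_cluster <- c(RT_cluster = "RT", NRT_cluster = "SD-NRT")
  label <- character(length(cl))
  label[is_train] <- ifelse(train_labels[names(cl)[is_train]] == "RT",
                            "RT", "SD-NRT")
  for (i in which(!is_train)) {
    cn <- cluster_name[i]
    label[i] <- if (sil_v[names(cl)[i]] >= thr[[cn]]) cls_of_cluster[[cn]]
                else "unclassified"
  }

  # subtype centroid calls for every sample outside the RT cluster
  subtypes <- intersect(c("ES", "RMC", "UC"), unique(train_labels[colnames(mt)]))
  sub_res <- NULL
  if (length(subtypes)) {
    sub_res <- subtype_call(joint, mt[genes, , drop = FALSE],
                            train_labels[colnames(mt)])
  }

  out <- tibble::tibble(
    sample_id = names(cl),
    cohort = ifelse(is_train, "training", "study"),
    cluster = unname(cluster_name),
    silhouette = unname(sil_v[names(cl)]),
    label = label
  )
  if (!is.null(sub_res)) {
    sub_res$subtype_call[out$cluster == "RT_cluster"] <- "none"
    out <- dplyr::left_join(out, sub_res, by = "sample_id")
  } else {
    out$subtype_call <- "none"
  }
  attr(out, "hclust") <- hc
  attr(out, "thresholds") <- thr
  attr(out, "threshold_quantile") <- threshold_quantile
  class(out) <- c("sdt_classification", class(out))
  out
}

#' Nearest-subtype-centroid call
#'
#' Correlates each sample's signature-gene profile with the mean profile
#' (centroid) of every training subtype and reports the best-correlated
#' subtype. Ties are broken alphabetically and flagged; all-constant
#' samples (undefined correlation) get subtype `none`.
#'
#' @param query Matrix or expression tibble of samples to call (rows
#'   already restricted to the signature genes, or a superset containing
#'   the training genes).
#' @param train Matrix of training samples over the same genes.
#' @param train_labels Named vector of training classes; only `ES`, `RMC`,
#'   `UC` samples define centroids.
#' @return A tibble `sample_id`, `subtype_call`, `subtype_tie`, plus one
#'   `cor_<subtype>` column per subtype.
#' @export
subtype_call <- function(query, train, train_labels) {
  mq <- expr_matrix(query)
  mt <- expr_matrix(train)
  genes <- intersect(rownames(mq), rownames(mt))
  mq <- mq[genes, , drop = FALSE]
  mt <- mt[genes, , drop = FALSE]
  subtypes <- sort(intersect(c("ES", "RMC", "UC"), unique(train_labels)))
  if (!length(subtypes)) abort("no subtype training samples available")
  centroids <- vapply(subtypes, function(s) {
    rowMeans(mt[, names(train_labels)[train_labels == s], drop = FALSE])
  }, numeric(length(genes)))
  cors <- matrix(NA_real_, ncol(mq), length(subtypes),
                 dimnames = list(colnames(mq), subtypes))
  for (j in seq_len(ncol(mq))) {
    if (sd(mq[, j]) > 0) cors[j, ] <- cor(mq[, j], centroids)
  }
  call <- apply(cors, 1, function(r) {
    if (all(is.na(r))) return("none")
    subtypes[which.max(r)]
  })
  tie <- apply(cors, 1, function(r) {
    if (all(is.na(r))) return(FALSE)
    sum(r == max(r, na.rm = TRUE), na.rm = TRUE) > 1
  })
  out <- tibble::tibble(sample_id = colnames(mq), subtype_call = unname(call),
                        subtype_tie = unname(tie))
  colnames(cors) <- paste0("cor_", subtypes)
  dplyr::bind_cols(out, tibble::as_tibble(cors))
}

#' Marker-gene z-score report
#'
#' Per-marker, per-sample z-scores relative to the cohort mean and
#' standard deviation, flagging samples above a z cutoff — e.g. high
#' `EPCAM` (carcinoma marker) or `T`/Brachyury (chordoma marker)
#' expression among unclassified samples.
#'
#' @param expr Expression tibble or matrix.
#' @param markers Character vector of gene ids; all must be present.
#' @param z_cutoff Flagging threshold (default 2).
#' @return A tibble `gene_id`, `sample_id`, `value`, `z`, `flagged`.
#' @export
marker_report <- function(expr, markers, z_cutoff = 2) {
  m <- expr_matrix(expr)
  miss <- setdiff(markers, rownames(m))
  if (length(miss)) {
    abort(paste0("marker(s) absent from matrix: ", paste(miss, collapse = ", ")))
  }
  rows <- lapply(markers, function(g) {
    v <- m[g, ]
    s <- sd(v)
    z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    tibble::tibble(gene_id = g, sample_id = colnames(m), value = unname(v),
                   z = unname(z), flagged = unname(z >= z_cutoff))
  })
  dplyr::bind_rows(rows)
}

#' Correlation between silhouette score and age in the RT group
#'
#' Pearson correlation (with two-sided test) between the silhouette scores
#' of samples labelled RT and their age at diagnosis; samples with missing
#' age are dropped.
#'
#' @param classification `sdt_classification` tibble.
#' @param clinical Clinical tibble with `sample_id` and `age_years`.
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
silhouette_age_correlation <- function(classification, clinical) {
  df <- dplyr::inner_join(
    dplyr::filter(classification, .data$label == "RT"),
    dplyr::select(clinical, "sample_id", "age_years"),
    by = "sample_id"
  )
  df <- df[!is.na(df$age_years), ]
  if (nrow(df) < 3) abort("need at least 3 RT samples with known age")
  ct <- cor.test(df$silhouette, df$age_years, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(df))
}
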