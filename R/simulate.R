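#' Simulate a two-class SMARCB1-deficient tumor cohort
#'
#' Generates a log2 expression matrix with the structure the downstream
#' analysis assumes: a training set of rhabdoid tumors (RT) and non-rhabdoid
#' tumors (SD-NRT, with ES/RMC/UC substructure), a study set of unlabelled
#' samples drawn from the same classes, a planted differential signature
#' (half RT-up, half SD-NRT-up), disjoint subtype-specific gene blocks, a
#' block of genes forced below the background threshold, additive Gaussian
#' noise on the log2 scale, and an "imprinted" gene set enriched among the
#' RT-up signature genes. Optionally, study samples drawn from a third
#' profile orthogonal to both classes emulate tumors that belong to neither.
#'
#' Default sizes mirror the published cohort: 16 RT, 8 ES, 5 RMC and 3 UC
#' training tumors, and 37 study tumors.
#'
#' @param n_rt,n_es,n_rmc,n_uc Training-set sizes per class.
#' @param study_counts Named integer vector of true study-set class counts
#'   (names among `RT`, `ES`, `RMC`, `UC`).
#' @param n_unclassifiable Study samples drawn from a third, orthogonal
#'   profile (no signature shift, own marker block).
#' @param n_genes Total genes.
#' @param n_signature Planted signature genes (half RT-up, half SD-NRT-up).
#' @param effect_size_log2 Signature shift, log2 units.
#' @param subtype_effect_log2 Shift of the subtype-specific blocks.
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param baseline_mean_range Range of per-gene baseline means (log2).
#' @param background_fraction Fraction of genes forced below the default
#'   background threshold of 3.5 log2 units.
#' @param imprinted_overlap_fraction Fraction of RT-up signature genes
#'   included in the simulated "imprinted" gene set.
#' @param subtype_block_size Genes per subtype-specific block.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `sdt_sim`: a list with `expression` (tibble,
#'   `gene_id` + one column per sample), `clinical` (annotation tibble with
#'   study labels hidden as `unknown`), `truth` (tibble `sample_id`,
#'   `cohort`, `true_class`), `signature` (tibble `gene_id`, `class`),
#'   `gene_sets` (list with the `IMPRINTED` set), and `params`.
#' @export
#' @examples
#' sim <- sim_cohort(n_genes = 300, n_signature = 40, seed = 7)
#' dim(sim$expression)
sim_cohort <- function(n_rt = 16, n_es = 8, n_rmc = 5, n_uc = 3,
                       study_counts = c(RT = 16, ES = 6, RMC = 1, UC = 1),
                       n_unclassifiable = 13,
                       n_genes = 2000, n_signature = 200,
                       effect_size_log2 = 2, subtype_effect_log2 = 1.5,
                       noise_sd = 0.5, baseline_mean_range = c(4, 10),
                       background_fraction = 0.1,
                       imprinted_overlap_fraction = 0.3,
                       subtype_block_size = 30,
                       seed = 1) {
  counts <- c(n_rt, n_es, n_rmc, n_uc, study_counts, n_unclassifiable)
  if (any(counts < 0)) abort("all sample counts must be >= 0")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  if (effect_size_log2 < 0 || subtype_effect_log2 < 0) abort("effects must be >= 0")
  if (is.null(names(study_counts)) ||
      !all(names(study_counts) %in% c("RT", "ES", "RMC", "UC"))) {
    abort("study_counts must be named with classes RT/ES/RMC/UC")
  }
  n_background <- floor(background_fraction * n_genes)
  # signature + 3 subtype blocks + orthogonal block must fit before the
  # background block
  n_blocks <- 4 * subtype_block_size
  if (n_signature + n_blocks + n_background > n_genes) {
    abort("n_signature + subtype blocks + background exceed n_genes")
  }

  withr::with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    train_class <- rep(c("RT", "ES", "RMC", "UC"), c(n_rt, n_es, n_rmc, n_uc))
    study_class <- rep(names(study_counts), study_counts)
    study_class <- c(study_class, rep("OTHER", n_unclassifiable))
    # hidden labels appear in a fixed shuffled order so class is not
    # recoverable from sample position
    study_class <- sample(study_class)
    train_ids <- sprintf("T%02d_%s", seq_along(train_class), train_class)
    study_ids <- sprintf("S%02d", seq_along(study_class))
    sample_ids <- c(train_ids, study_ids)
    cls <- c(train_class, study_class)
    n_samples <- length(sample_ids)

    # gene layout: [signature][ES block][RMC block][UC block][OTHER block]
    # [invariant expressed genes][background]
    n_rt_up <- ceiling(n_signature / 2)
    rt_up <- gene_ids[seq_len(n_rt_up)]
    nrt_up <- gene_ids[seq(n_rt_up + 1, n_signature)]
    blk <- function(i) gene_ids[n_signature + (i - 1) * subtype_block_size +
                                  seq_len(subtype_block_size)]
    blocks <- list(ES = blk(1), RMC = blk(2), UC = blk(3), OTHER = blk(4))
    background <- if (n_background > 0) gene_ids[seq(n_genes - n_background + 1, n_genes)]
                  else character(0)

    baseline <- runif(n_genes, baseline_mean_range[1], baseline_mean_range[2])
    names(baseline) <- gene_ids
    baseline[background] <- runif(n_background, 0.5, 1.5)

    mu <- matrix(baseline, nrow = n_genes, ncol = n_samples,
                 dimnames = list(gene_ids, sample_ids))
    is_rt <- cls == "RT"
    is_nrt <- cls %in% c("ES", "RMC", "UC")
    mu[rt_up, is_rt] <- mu[rt_up, is_rt] + effect_size_log2
    mu[nrt_up, is_nrt] <- mu[nrt_up, is_nrt] + effect_size_log2
    for (sub in c("ES", "RMC", "UC")) {
      if (any(cls == sub)) {
        mu[blocks[[sub]], cls == sub] <- mu[blocks[[sub]], cls == sub] +
          subtype_effect_log2
      }
    }
    if (any(cls == "OTHER")) {
      mu[blocks$OTHER, cls == "OTHER"] <- mu[blocks$OTHER, cls == "OTHER"] +
        effect_size_log2
    }

    vals <- mu + matrix(rnorm(n_genes * n_samples, 0, noise_sd),
                        nrow = n_genes)
    # background genes stay below the 3.5 log2 background threshold
    if (n_background > 0) {
      vals[background, ] <- pmin(vals[background, ], 3.4)
    }

    n_impr_sig <- ceiling(imprinted_overlap_fraction * length(rt_up))
    other_expressed <- setdiff(gene_ids[seq_len(n_genes - n_background)],
                               c(rt_up, nrt_up, unlist(blocks)))
    imprinted <- c(sample(rt_up, n_impr_sig),
                   sample(other_expressed, n_impr_sig))

    ages <- numeric(n_samples)
    ages[is_rt & seq_len(n_samples) <= length(train_ids)] <-
      round(runif(sum(is_rt & seq_len(n_samples) <= length(train_ids)), 0.1, 4.9), 1)
    idx_rest <- which(ages == 0)
    ages[idx_rest] <- round(runif(length(idx_rest), 1, 55), 1)
    outcome <- ifelse(seq_len(n_samples) > length(train_ids),
                      sample(c("DOD", "NED", NA), n_samples, replace = TRUE,
                             prob = c(0.45, 0.35, 0.2)),
                      NA)
    followup <- ifelse(is.na(outcome), NA, round(runif(n_samples, 7, 1800)))

    clinical <- tibble::tibble(
      sample_id = sample_ids,
      cohort = rep(c("training", "study"),
                   c(length(train_ids), length(study_ids))),
      diagnosis_label = ifelse(seq_len(n_samples) <= length(train_ids),
                               cls, "unknown"),
      age_years = ages,
      location = "synthetic",
      outcome = outcome,
      followup_days = as.numeric(followup)
    )

    out <- list(
      expression = expr_tibble(vals),
      clinical = clinical,
      truth = tibble::tibble(sample_id = sample_ids,
                             cohort = clinical$cohort,
                             true_class = cls),
      signature = tibble::tibble(
        gene_id = c(rt_up, nrt_up),
        class = rep(c("RT_up", "NRT_up"), c(length(rt_up), length(nrt_up)))
      ),
      gene_sets = list(IMPRINTED = imprinted),
      subtype_blocks = blocks,
      params = list(
        n_rt = n_rt, n_es = n_es, n_rmc = n_rmc, n_uc = n_uc,
        study_counts = study_counts, n_unclassifiable = n_unclassifiable,
        n_genes = n_genes, n_signature = n_signature,
        effect_size_log2 = effect_size_log2,
        subtype_effect_log2 = subtype_effect_log2, noise_sd = noise_sd,
        baseline_mean_range = baseline_mean_range,
        background_fraction = background_fraction,
        imprinted_overlap_fraction = imprinted_overlap_fraction,
        subtype_block_size = subtype_block_size, seed = seed
      )
    )
    class(out) <- "sdt_sim"
    out
  })
}

#' @export
print.sdt_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated SMARCB1-deficient cohort: %d genes x %d samples\n",
    p$n_genes, nrow(x$truth)))
  cat(sprintf("  training: %d RT, %d ES, %d RMC, %d UC; study: %d (%d orthogonal)\n",
              p$n_rt, p$n_es, p$n_rmc, p$n_uc,
              sum(x$truth$cohort == "study"), p$n_unclassifiable))
  cat(sprintf("  signature: %d genes, effect %.2g log2, noise sd %.2g\n",
              p$n_signature, p$effect_size_log2, p$noise_sd))
  invisible(x)
}

#' Simulate a candidate-variant table with planted truth
#'
#' Generates a flat variant table in the schema consumed by the somatic
#' filter cascade, with three planted classes: true somatic variants that
#' satisfy every pass criterion, germline variants that violate the
#' population-frequency or tumor/normal allele-fraction rules, and
#' technical artifacts that violate the quality/depth/supporting-read
#' rules. The returned truth column allows precision/recall evaluation.
#'
#' @param n_true_somatic,n_germline,n_artifacts Planted class sizes.
#' @param matched If `TRUE`, records carry matched-normal fields; if
#'   `FALSE`, normal fields are missing and true somatic records carry a
#'   COSMIC id so they survive the unmatched rescue rules.
#' @param seed Integer seed.
#' @return A tibble of variant records with a `truth` column
#'   (`somatic`/`germline`/`artifact`).
#' @export
sim_variants <- function(n_true_somatic = 5, n_germline = 5, n_artifacts = 5,
                         matched = TRUE, seed = 1) {
  if (any(c(n_true_somatic, n_germline, n_artifacts) < 0)) {
    abort("counts must be >= 0")
  }
  withr::with_seed(seed, {
    n <- n_true_somatic + n_germline + n_artifacts
    truth <- rep(c("somatic", "germline", "artifact"),
                 c(n_true_somatic, n_germline, n_artifacts))
    depth_t <- sample(50:200, n, replace = TRUE)
    vaf_t <- round(runif(n, 0.25, 0.7), 3)
    rec <- tibble::tibble(
      chrom = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
      pos = sample.int(2e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      gene = sprintf("GENE%03d", sample.int(500, n)),
      quality = round(runif(n, 30, 60), 1),
      depth_tumor = depth_t,
      alt_reads_tumor = pmax(5L, as.integer(round(vaf_t * depth_t))),
      depth_normal = if (matched) sample(50:200, n, replace = TRUE) else NA_integer_,
      alt_reads_normal = if (matched) 0L else NA_integer_,
      freq_1000g = NA_real_,
      freq_esp6500 = NA_real_,
      freq_exac = NA_real_,
      synonymous = FALSE,
      cosmic_id = NA_character_,
      pp2_hdiv = "damaging", pp2_hvar = "unknown", lrt = "damaging",
      mutation_taster = "damaging", mutation_assessor = "unknown",
      truth = truth
    )
    rec$vaf_tumor <- rec$alt_reads_tumor / rec$depth_tumor
    rec$vaf_normal <- if (matched) rec$alt_reads_normal / rec$depth_normal else NA_real_

    if (!matched) {
      som <- rec$truth == "somatic"
      rec$cosmic_id[som] <- sprintf("COSM%05d", sample.int(99999, sum(som)))
    }

    germ <- which(rec$truth == "germline")
    for (j in seq_along(germ)) {
      i <- germ[j]
      if (!matched || j %% 2 == 1) {
        # common polymorphism: reported above 1% in at least one panel
        col <- c("freq_1000g", "freq_esp6500", "freq_exac")[1 + (j %% 3)]
        rec[[col]][i] <- round(runif(1, 0.02, 0.3), 3)
      } else {
        # inherited het: same allele fraction in tumor and normal
        rec$vaf_tumor[i] <- 0.5
        rec$alt_reads_tumor[i] <- as.integer(round(0.5 * rec$depth_tumor[i]))
        rec$vaf_normal[i] <- 0.5
        rec$alt_reads_normal[i] <- as.integer(round(0.5 * rec$depth_normal[i]))
      }
    }

    art <- which(rec$truth == "artifact")
    for (j in seq_along(art)) {
      i <- art[j]
      mode <- j %% 3
      if (mode == 0) {
        rec$quality[i] <- round(runif(1, 2, 19.5), 1)
      } else if (mode == 1) {
        rec$depth_tumor[i] <- sample(1:9, 1)
        rec$alt_reads_tumor[i] <- min(rec$depth_tumor[i], 5L)
        rec$vaf_tumor[i] <- rec$alt_reads_tumor[i] / rec$depth_tumor[i]
      } else {
        rec$alt_reads_tumor[i] <- sample(0:4, 1)
        rec$vaf_tumor[i] <- rec$alt_reads_tumor[i] / rec$depth_tumor[i]
      }
    }

    # ref == alt would not be a variant
    swap <- rec$ref == rec$alt
    rec$alt[swap] <- ifelse(rec$ref[swap] == "A", "G", "A")
    dplyr::relocate(rec, "vaf_tumor", .after = "alt_reads_tumor") |>
      dplyr::relocate("vaf_normal", .after = "alt_reads_normal")
  })
}
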