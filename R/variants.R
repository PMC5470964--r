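# Somatic variant filter cascade. All boundary readings are strict as
# printed: "quality under 20", "less than 5 reads", "more than 1%".

.predictor_cols <- c("pp2_hdiv", "pp2_hvar", "lrt", "mutation_taster",
                     "mutation_assessor")

#' Basic quality filter
#'
#' Keeps a variant iff quality >= 20, tumor depth >= 10 and at least 5
#' reads support the alternative allele.
#'
#' @param variants Variant tibble (columns `quality`, `depth_tumor`,
#'   `alt_reads_tumor`).
#' @return Logical vector, `TRUE` = keep.
#' @export
basic_filter <- function(variants) {
  variants$quality >= 20 & variants$depth_tumor >= 10 &
    variants$alt_reads_tumor >= 5
}

#' Polymorphism filter
#'
#' Discards variants reported in more than 1% of the population in any of
#' the 1000 Genomes, ESP6500 or ExAC panels; a missing frequency counts as
#' not reported.
#'
#' @param variants Variant tibble (columns `freq_1000g`, `freq_esp6500`,
#'   `freq_exac`).
#' @param max_freq Population-frequency cutoff (strict `>` discards).
#' @return Logical vector, `TRUE` = keep.
#' @export
polymorphism_filter <- function(variants, max_freq = 0.01) {
  over <- function(x) !is.na(x) & x > max_freq
  !(over(variants$freq_1000g) | over(variants$freq_esp6500) |
      over(variants$freq_exac))
}

# all available predictor calls benign -> reject; any damaging/unknown or
# no calls at all -> retain
.all_benign <- function(variants) {
  calls <- as.matrix(variants[intersect(.predictor_cols, names(variants))])
  if (!ncol(calls)) return(rep(FALSE, nrow(variants)))
  apply(calls, 1, function(r) {
    r <- r[!is.na(r) & r != "unknown"]
    length(r) > 0 && all(r == "benign")
  })
}

#' Matched tumor/normal somatic genotype filter
#'
#' Classifies each variant with a matched normal as `somatic_het`
#' (tumor allele fraction in `[0.1, 0.8]`, normal fraction `< 0.1` with at
#' most 2 alt-supporting normal reads), `somatic_hom_alt` (tumor fraction
#' `> 0.8`, normal fraction in `[0.4, 0.6]`), or `rejected`. Variants whose
#' available effect-predictor calls are unanimously benign are also
#' rejected (set `apply_predictors = FALSE` to skip that rule).
#'
#' The printed constitutional rule "x < 0.1 and depth <= 2" is read as at
#' most 2 alt-supporting reads in the normal: a total normal depth of 2
#' would contradict the depth >= 10 basic rule.
#'
#' @param variants Variant tibble with `vaf_tumor`, `vaf_normal`,
#'   `alt_reads_normal` and predictor columns.
#' @param apply_predictors Apply the unanimous-benign rejection rule.
#' @return Character vector: `somatic_het`, `somatic_hom_alt` or
#'   `rejected`.
#' @export
somatic_filter <- function(variants, apply_predictors = TRUE) {
  if (any(is.na(variants$vaf_normal)) || any(is.na(variants$alt_reads_normal))) {
    abort("missing matched-normal fields; use unmatched_filter() for tumor-only samples")
  }
  xt <- variants$vaf_tumor
  xn <- variants$vaf_normal
  het <- xt >= 0.1 & xt <= 0.8 & xn < 0.1 & variants$alt_reads_normal <= 2
  hom <- xt > 0.8 & xn >= 0.4 & xn <= 0.6
  out <- ifelse(het, "somatic_het", ifelse(hom, "somatic_hom_alt", "rejected"))
  if (apply_predictors) out[.all_benign(variants)] <- "rejected"
  out
}

#' Rescue filter for tumor-only samples
#'
#' Without a matched normal, a variant is conserved iff it carries a
#' COSMIC id or falls in a gene found somatically mutated in the matched
#' samples.
#'
#' @param variants Variant tibble with `cosmic_id` and `gene`.
#' @param recurrent_genes Character vector of genes mutated in matched
#'   samples.
#' @param apply_predictors Also apply the unanimous-benign rejection rule.
#' @return Logical vector, `TRUE` = keep.
#' @export
unmatched_filter <- function(variants, recurrent_genes = character(0),
                             apply_predictors = TRUE) {
  keep <- (!is.na(variants$cosmic_id) & nzchar(variants$cosmic_id)) |
    variants$gene %in% recurrent_genes
  if (apply_predictors) keep <- keep & !.all_benign(variants)
  keep
}

#' Run the full variant filter cascade
#'
#' Applies, in order: the basic quality filter, the polymorphism filter,
#' removal of synonymous variants, then the matched somatic genotype
#' filter (or the unmatched rescue filter). Returns the surviving records
#' and a per-stage attrition table.
#'
#' @param variants Variant tibble.
#' @param matched Whether matched-normal fields are present.
#' @param recurrent_genes Passed to [unmatched_filter()].
#' @param apply_predictors Apply the unanimous-benign predictor rule.
#' @return A list with `kept` (tibble; matched mode adds a
#'   `somatic_class` column) and `attrition` (tibble `stage`, `n_in`,
#'   `n_removed`, `n_out`).
#' @export
#' @examples
#' v <- sim_variants(5, 3, 4, matched = TRUE, seed = 1)
#' run_cascade(v, matched = TRUE)$attrition
run_cascade <- function(variants, matched = TRUE,
                        recurrent_genes = character(0),
                        apply_predictors = TRUE) {
  stages <- list()
  cur <- variants
  step <- function(name, keep) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = name, n_in = nrow(cur), n_removed = sum(!keep),
      n_out = sum(keep))
    cur <<- cur[keep, , drop = FALSE]
  }
  step("basic", if (nrow(cur)) basic_filter(cur) else logical(0))
  step("polymorphism", if (nrow(cur)) polymorphism_filter(cur) else logical(0))
  step("synonymous", if (nrow(cur)) !cur$synonymous else logical(0))
  if (matched) {
    cls <- if (nrow(cur)) somatic_filter(cur, apply_predictors) else character(0)
    step("somatic", cls != "rejected")
    if (nrow(cur)) cur$somatic_class <- cls[cls != "rejected"]
  } else {
    step("unmatched_rescue",
         if (nrow(cur)) unmatched_filter(cur, recurrent_genes, apply_predictors)
         else logical(0))
  }
  list(kept = cur, attrition = dplyr::bind_rows(stages))
}

#' Read a SEG-like copy-number segment table
#'
#' Tab-delimited with columns `sample_id`, `chrom`, `start`, `end`,
#' `copy_state` (`loss`/`neutral`/`gain`); 1-based inclusive coordinates.
#'
#' @param path Path to the file.
#' @return A tibble of segments.
#' @export
read_segments <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "copy_state")
  if (!all(need %in% names(df))) {
    abort(paste0("segment table missing column(s): ",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (any(df$start > df$end)) abort("segment with start > end")
  if (!all(df$copy_state %in% c("loss", "neutral", "gain"))) {
    abort("copy_state must be loss/neutral/gain")
  }
  tibble::as_tibble(df)
}

#' Per-sample CNV counts and per-group medians
#'
#' Counts non-neutral segments per sample and reports the median count per
#' group. Overlapping segments on the same sample and chromosome are a
#' validation error.
#'
#' @param segments Segment tibble (see [read_segments()]).
#' @param groups Named vector (or tibble `sample_id`, `group`) assigning
#'   each sample to a group (e.g. RT vs SD-NRT).
#' @return A list with `per_sample` (tibble `sample_id`, `group`,
#'   `n_cnv`) and `per_group` (tibble `group`, `median_cnv`, `n_samples`).
#' @export
cnv_summary <- function(segments, groups) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  split_sc <- split(segments, list(segments$sample_id, segments$chrom),
                    drop = TRUE)
  for (s in split_sc) {
    if (nrow(s) > 1) {
      s <- s[order(s$start), ]
      if (any(s$start[-1] <= s$end[-nrow(s)])) {
        abort(sprintf("overlapping segments for sample %s on %s",
                      s$sample_id[1], s$chrom[1]))
      }
    }
  }
  per_sample <- segments |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_cnv = sum(.data$copy_state != "neutral"),
                     .groups = "drop")
  # samples with a group but no segments count 0 CNV
  missing <- setdiff(names(groups), per_sample$sample_id)
  if (length(missing)) {
    per_sample <- dplyr::bind_rows(
      per_sample, tibble::tibble(sample_id = missing, n_cnv = 0L))
  }
  per_sample$group <- unname(groups[per_sample$sample_id])
  per_group <- per_sample |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_cnv = median(.data$n_cnv),
                     n_samples = dplyr::n(), .groups = "drop")
  list(per_sample = dplyr::relocate(per_sample, "group", .after = "sample_id"),
       per_group = per_group)
}

#' Chromothripsis flag per chromosome
#'
#' Flags chromosomes with many breakpoints (adjacent-segment copy-state
#' changes) concentrated on few chromosomes — the pattern suggestive of
#' chromothripsis. No chromosome is flagged when more than `max_chroms`
#' chromosomes carry state changes (genome-wide instability is not
#' chromothripsis).
#'
#' @param segments Segment tibble for a single sample.
#' @param min_breakpoints Breakpoints required to flag a chromosome.
#' @param max_chroms Maximum number of chromosomes with any state change
#'   for the localized-rearrangement pattern to hold.
#' @return A tibble `chrom`, `n_breakpoints`, `flagged`.
#' @export
chromothripsis_flag <- function(segments, min_breakpoints = 10, max_chroms = 3) {
  if (length(unique(segments$sample_id)) > 1) {
    abort("chromothripsis_flag expects segments of a single sample")
  }
  bp <- segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      n_breakpoints = if (dplyr::n() < 2) 0L
                      else sum(.data$copy_state[-1] !=
                                 .data$copy_state[-dplyr::n()]),
      .groups = "drop")
  affected <- sum(bp$n_breakpoints > 0)
  bp$flagged <- bp$n_breakpoints >= min_breakpoints & affected <= max_chroms
  bp
}
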