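base_variant <- function(...) {
  v <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T", gene = "GENE1",
    quality = 50, depth_tumor = 100L, alt_reads_tumor = 40L,
    vaf_tumor = 0.4, depth_normal = 100L, alt_reads_normal = 0L,
    vaf_normal = 0, freq_1000g = NA_real_, freq_esp6500 = NA_real_,
    freq_exac = NA_real_, synonymous = FALSE, cosmic_id = NA_character_,
    pp2_hdiv = "damaging", pp2_hvar = "unknown", lrt = "damaging",
    mutation_taster = "damaging", mutation_assessor = "unknown"
  )
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

test_that("basic filter boundaries are strict as printed", {
  expect_false(basic_filter(base_variant(quality = 19.9)))
  expect_true(basic_filter(base_variant(quality = 20, depth_tumor = 10L,
                                        alt_reads_tumor = 5L)))
  expect_false(basic_filter(base_variant(depth_tumor = 9L)))
  expect_false(basic_filter(base_variant(alt_reads_tumor = 4L)))
})

test_that("polymorphism filter uses a strict 1% cutoff over all panels", {
  expect_false(polymorphism_filter(base_variant(freq_exac = 0.011)))
  expect_true(polymorphism_filter(base_variant(freq_1000g = 0.01)))
  expect_true(polymorphism_filter(base_variant()))  # all missing
  expect_false(polymorphism_filter(base_variant(freq_esp6500 = 0.5)))
})

test_that("matched somatic genotype rules follow the printed VAF windows", {
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.5)), "somatic_het")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.1)), "somatic_het")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.8)), "somatic_het")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.05)), "rejected")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.81)), "rejected")
  # het requires a clean normal: <= 2 supporting reads and VAF < 0.1
  expect_equal(somatic_filter(base_variant(alt_reads_normal = 2L,
                                           vaf_normal = 0.02)), "somatic_het")
  expect_equal(somatic_filter(base_variant(alt_reads_normal = 3L,
                                           vaf_normal = 0.03)), "rejected")
  expect_equal(somatic_filter(base_variant(vaf_normal = 0.1)), "rejected")
  # hom-alt somatic over a het constitutional
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.9, vaf_normal = 0.5,
                                           alt_reads_normal = 50L)),
               "somatic_hom_alt")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.9, vaf_normal = 0.4,
                                           alt_reads_normal = 40L)),
               "somatic_hom_alt")
  expect_equal(somatic_filter(base_variant(vaf_tumor = 0.9, vaf_normal = 0.61,
                                           alt_reads_normal = 61L)),
               "rejected")
  # unanimously benign predictions reject the call
  ben <- base_variant(pp2_hdiv = "benign", pp2_hvar = "benign",
                      lrt = "benign", mutation_taster = "benign",
                      mutation_assessor = "benign")
  expect_equal(somatic_filter(ben), "rejected")
  one_dam <- base_variant(pp2_hdiv = "benign", pp2_hvar = "benign",
                          lrt = "damaging", mutation_taster = "benign",
                          mutation_assessor = "benign")
  expect_equal(somatic_filter(one_dam), "somatic_het")
  expect_equal(somatic_filter(ben, apply_predictors = FALSE), "somatic_het")

  expect_error(somatic_filter(base_variant(vaf_normal = NA_real_)),
               "unmatched")
})

test_that("unmatched rescue keeps COSMIC or recurrent-gene variants", {
  v <- base_variant(vaf_normal = NA_real_, alt_reads_normal = NA_integer_,
                    depth_normal = NA_integer_)
  expect_true(unmatched_filter(base_variant(cosmic_id = "COSM12345")))
  expect_true(unmatched_filter(v, recurrent_genes = "GENE1"))
  expect_false(unmatched_filter(v))
})

test_that("cascade applies stages in order and is idempotent", {
  v <- sim_variants(5, 4, 3, matched = TRUE, seed = 50)
  res <- run_cascade(v, matched = TRUE)
  expect_equal(res$attrition$stage,
               c("basic", "polymorphism", "synonymous", "somatic"))
  expect_equal(res$attrition$n_in[1], 12)
  expect_equal(res$attrition$n_out[4], nrow(res$kept))
  # precision and recall of the planted somatic variants are both 1
  expect_setequal(res$kept$truth, "somatic")
  expect_equal(nrow(res$kept), 5)

  again <- run_cascade(dplyr::select(res$kept, -"somatic_class"),
                       matched = TRUE)
  expect_equal(nrow(again$kept), nrow(res$kept))
  expect_equal(sum(again$attrition$n_removed), 0)

  # synonymous somatic variants are removed regardless of VAF
  syn <- base_variant(synonymous = TRUE)
  res_syn <- run_cascade(syn, matched = TRUE)
  expect_equal(nrow(res_syn$kept), 0)
  expect_equal(res_syn$attrition$n_removed[res_syn$attrition$stage == "synonymous"], 1)

  empty <- run_cascade(v[0, ], matched = TRUE)
  expect_equal(nrow(empty$kept), 0)
  expect_true(all(empty$attrition$n_removed == 0))

  # unmatched mode rescues the planted somatic variants via COSMIC ids
  vu <- sim_variants(5, 4, 3, matched = FALSE, seed = 51)
  resu <- run_cascade(vu, matched = FALSE)
  expect_setequal(resu$kept$truth, "somatic")
  expect_equal(nrow(resu$kept), 5)
})

test_that("CNV counts and group medians match a brute-force scan", {
  seg <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    chrom = c("chr1", "chr2", "chr3", "chr1", "chr2", "chr1", "chr2", "chr3"),
    start = 1L, end = 1000L,
    copy_state = c("loss", "gain", "neutral", "loss", "gain",
                   "loss", "gain", "gain")
  )
  groups <- c(s1 = "RT", s2 = "RT", s3 = "SD-NRT", s4 = "RT")
  out <- cnv_summary(seg, groups)
  counts <- setNames(out$per_sample$n_cnv, out$per_sample$sample_id)
  expect_equal(counts[["s1"]], 2)
  expect_equal(counts[["s4"]], 0)   # no segments -> zero CNV
  brute <- sapply(split(seg, seg$sample_id),
                  function(s) sum(s$copy_state != "neutral"))
  expect_equal(counts[names(brute)], brute)
  expect_equal(out$per_group$median_cnv[out$per_group$group == "RT"],
               median(c(2, 2, 0)))

  overlapping <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                                start = c(1L, 500L), end = c(600L, 900L),
                                copy_state = c("loss", "gain"))
  expect_error(cnv_summary(overlapping, groups), "overlapping")
})

test_that("chromothripsis flags dense localized breakpoints only", {
  alt <- tibble::tibble(
    sample_id = "s1", chrom = "chr22",
    start = seq(1, by = 1000, length.out = 13),
    end = seq(999, by = 1000, length.out = 13),
    copy_state = rep(c("loss", "gain"), length.out = 13)
  )
  flags <- chromothripsis_flag(alt)
  expect_equal(flags$n_breakpoints, 12)
  expect_true(flags$flagged)

  quiet <- tibble::tibble(sample_id = "s1",
                          chrom = paste0("chr", 1:5),
                          start = 1L, end = 1000L, copy_state = "neutral")
  expect_false(any(chromothripsis_flag(quiet)$flagged))

  # lowering min_breakpoints can only add flags
  f10 <- chromothripsis_flag(alt, min_breakpoints = 10)
  f5 <- chromothripsis_flag(alt, min_breakpoints = 5)
  expect_true(all(f5$flagged >= f10$flagged))

  # widespread instability is not chromothripsis
  wide <- dplyr::bind_rows(lapply(paste0("chr", 1:6), function(ch) {
    x <- alt; x$chrom <- ch; x
  }))
  expect_false(any(chromothripsis_flag(wide)$flagged))
})

test_that("segment reader validates the SEG schema", {
  tf <- withr::local_tempfile(fileext = ".seg")
  readr::write_tsv(tibble::tibble(sample_id = "s1", chrom = "chr1",
                                  start = 10L, end = 5L,
                                  copy_state = "loss"), tf)
  expect_error(read_segments(tf), "start > end")
  readr::write_tsv(tibble::tibble(sample_id = "s1", chrom = "chr1",
                                  start = 1L, end = 5L,
                                  copy_state = "amplified"), tf)
  expect_error(read_segments(tf), "copy_state")
})
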