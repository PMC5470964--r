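#' Relative quantification by the 2^-ddCt method
#'
#' `dCt_sample = Ct_target(sample) - Ct_reference(sample)`;
#' `dCt_calibrator` likewise; the fold change is
#' `2^-(dCt_sample - dCt_calibrator)`. A ddCt of -1 is a one-cycle
#' doubling (fold 2).
#'
#' @param ct_target_sample,ct_ref_sample Ct of the target and reference
#'   gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of the target and
#'   reference gene in the calibrator condition.
#' @return Positive fold change (vectorized).
#' @export
#' @examples
#' fold_change_ddct(25, 20, 28, 20) # ddCt = -3 -> fold 8
fold_change_ddct <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) abort("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' 2^-ddCt fold changes from a Ct table
#'
#' Computes per-sample fold changes of each target gene relative to a
#' reference gene (default `TBP`), calibrated against the mean Ct profile
#' of a designated calibrator sample group. Technical replicates (repeated
#' `sample_id` x `gene` rows) are averaged on the Ct scale first.
#'
#' @param ct_table Tibble with columns `sample_id`, `gene`, `ct`.
#' @param reference_gene Reference (housekeeping) gene id.
#' @param calibrator_samples Character vector of sample ids whose mean Ct
#'   defines the calibrator condition.
#' @return A tibble `sample_id`, `gene`, `dct`, `ddct`, `fold_change`
#'   (reference gene excluded).
#' @export
qpcr_fold_changes <- function(ct_table, reference_gene = "TBP",
                              calibrator_samples) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("ct_table needs columns sample_id, gene, ct")
  }
  if (!reference_gene %in% ct_table$gene) {
    abort(paste0("reference gene absent from table: ", reference_gene))
  }
  if (!all(calibrator_samples %in% ct_table$sample_id)) {
    abort("unknown calibrator sample(s)")
  }
  ct <- ct_table |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample_id", ref_ct = "ct")
  dct <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct)
  calib <- dct |>
    dplyr::filter(.data$sample_id %in% calibrator_samples) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dct_calibrator = mean(.data$dct), .groups = "drop")
  dct |>
    dplyr::inner_join(calib, by = "gene") |>
    dplyr::mutate(ddct = .data$dct - .data$dct_calibrator,
                  fold_change = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "gene", "dct", "ddct", "fold_change")
}
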