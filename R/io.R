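#' Read a log2 expression matrix
#'
#' Reads a genes-by-samples table of log2 intensities from a tab-delimited
#' file (first column gene ids, header row of sample ids) or a GCT v1.2 file
#' (two preamble lines, then `Name`, `Description` and one column per
#' sample; the description column is dropped).
#'
#' Values are assumed to be already log2-transformed (e.g. gcRMA output);
#' the returned tibble carries `attr(, "log2") = TRUE` to record that
#' assumption. Gene and sample identifiers are treated as opaque strings.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @return A tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(5.2, 7.1, 3.9, 6.4, 8.0, 4.1), nrow = 3,
#'             dimnames = list(c("TET1", "DNMT3B", "EPCAM"), c("s1", "s2")))
#' write_expression(m, tf)
#' read_expression(tf)
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  skip <- if (dialect == "gct") 2L else 0L
  df <- readr::read_tsv(path, skip = skip, show_col_types = FALSE,
                        progress = FALSE, name_repair = "minimal")
  if (dialect == "gct") {
    if (!all(c("Name", "Description") %in% names(df)[1:2])) {
      abort("not a GCT v1.2 file: expected Name and Description columns")
    }
    df <- df[setdiff(names(df), "Description")]
    names(df)[1] <- "gene_id"
  } else {
    names(df)[1] <- "gene_id"
  }
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  if (anyDuplicated(names(df))) abort("duplicate sample id(s) in header")
  vals <- df[setdiff(names(df), "gene_id")]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    abort(paste0("non-numeric expression column(s): ",
                 paste(names(vals)[bad], collapse = ", ")))
  }
  if (any(!is.finite(as.matrix(vals)))) {
    idx <- which(!is.finite(as.matrix(vals)), arr.ind = TRUE)[1, ]
    abort(sprintf("missing/non-finite value at gene row %d, sample column %s",
                  idx[1], names(vals)[idx[2]]))
  }
  out <- tibble::as_tibble(df)
  attr(out, "log2") <- TRUE
  out
}

#' Write an expression matrix to TSV
#'
#' Round-trips losslessly with [read_expression()].
#'
#' @param expr Expression tibble (`gene_id` + sample columns) or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  m <- expr_matrix(expr)
  readr::write_tsv(expr_tibble(m), path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Descriptions are discarded.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of unique gene ids.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !any(nzchar(f[-(1:2)]))) {
      abort(paste0("GMT line with empty member list: ", f[1]))
    }
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

# tokens denoting a missing value in the printed clinical tables
.missing_tokens <- c("NA", "?", "-", "")

# parse a follow-up / age field: plain number (days resp. years), "Nyrs"
# (years, converted to days for follow-up), "<N" (bound, taken at N).
.parse_clinical_number <- function(x, yrs_to_days = FALSE, missing_tokens = .missing_tokens) {
  x <- trimws(gsub("\\*", "", x))
  out <- rep(NA_real_, length(x))
  miss <- is.na(x) | x %in% missing_tokens
  rest <- !miss
  for (i in which(rest)) {
    v <- x[i]
    mult <- 1
    if (grepl("yrs?$", v, ignore.case = TRUE)) {
      v <- sub("yrs?$", "", v, ignore.case = TRUE)
      if (yrs_to_days) mult <- 365.25
    }
    v <- sub("^<", "", v)
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) abort(paste0("unparseable numeric clinical field: '", x[i], "'"))
    out[i] <- num * mult
  }
  out
}

#' Read a clinical annotation table
#'
#' Expects a CSV with columns `sample_id`, `cohort` (`training`/`study`),
#' `diagnosis_label` (`RT`, `ES`, `RMC`, `UC`, `SD-NRT`, `unknown`),
#' `age_years`, `location`, `outcome` (`DOD`, `NED` or missing),
#' `followup_days`. Extra columns are kept as-is. The tokens `NA`, `?`,
#' `-` and the empty string denote missing values (configurable); a
#' follow-up of the form `"13yrs"` is converted to days.
#'
#' @param path Path to the CSV.
#' @param missing_tokens Character vector of tokens mapped to missing.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path, missing_tokens = .missing_tokens) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("sample_id", "cohort", "diagnosis_label", "age_years", "outcome",
            "followup_days")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("clinical table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in clinical table")
  clean <- function(x) {
    x <- trimws(gsub("\\*", "", x))
    ifelse(is.na(x) | x %in% missing_tokens, NA_character_, x)
  }
  df$cohort <- clean(df$cohort)
  if (!all(df$cohort %in% c("training", "study"))) {
    abort("cohort must be 'training' or 'study'")
  }
  df$diagnosis_label <- clean(df$diagnosis_label)
  df$diagnosis_label[is.na(df$diagnosis_label)] <- "unknown"
  ok_lab <- c("RT", "ES", "RMC", "UC", "SD-NRT", "unknown")
  if (!all(df$diagnosis_label %in% ok_lab)) {
    abort(paste0("unknown diagnosis label(s): ",
                 paste(setdiff(df$diagnosis_label, ok_lab), collapse = ", ")))
  }
  if (any(df$cohort == "training" & df$diagnosis_label == "unknown")) {
    abort("training samples must have a known diagnosis label")
  }
  df$outcome <- clean(df$outcome)
  if (!all(is.na(df$outcome) | df$outcome %in% c("DOD", "NED"))) {
    abort(paste0("unknown outcome token(s): ",
                 paste(setdiff(df$outcome[!is.na(df$outcome)], c("DOD", "NED")),
                       collapse = ", ")))
  }
  df$age_years <- .parse_clinical_number(df$age_years, missing_tokens = missing_tokens)
  df$followup_days <- .parse_clinical_number(df$followup_days, yrs_to_days = TRUE,
                                             missing_tokens = missing_tokens)
  if (any(df$age_years < 0, na.rm = TRUE) || any(df$followup_days < 0, na.rm = TRUE)) {
    abort("negative age or follow-up in clinical table")
  }
  tibble::as_tibble(df)
}

#' Write a clinical annotation table to CSV
#' @param clinical Tibble as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Shipped clinical tables
#'
#' The training-set (32 tumors: 16 RT, 8 ES, 5 RMC, 3 UC) and study-set
#' (37 tumors of initially uncertain diagnosis) clinical tables transcribed
#' from the published cohort, used by the worked examples and the outcome
#' summaries.
#'
#' @param which `"training"` or `"study"`.
#' @return A clinical tibble (see [read_clinical()]).
#' @export
#' @examples
#' dplyr::count(cohort_table("training"), diagnosis_label)
cohort_table <- function(which = c("training", "study")) {
  which <- match.arg(which)
  fn <- c(training = "training_clinical.csv", study = "study_clinical.csv")[[which]]
  read_clinical(system.file("extdata", fn, package = "sdtclass", mustWork = TRUE))
}
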