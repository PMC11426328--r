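# TMM normalization, CPM computation and binary expression calls for exon
# count matrices.
#
# A count table is a tibble whose first column `exon_id` identifies exons
# and whose remaining columns are nonnegative integer counts, one column
# per sample. The sample sheet maps sample ids to patients and tissues.

count_matrix <- function(counts) {
  stopifnot("exon_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "exon_id"), drop = FALSE])
  rownames(m) <- counts$exon_id
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be nonnegative")
  m
}

#' TMM scaling factors and effective library sizes
#'
#' Trimmed-mean-of-M-values between-sample normalization: the reference
#' sample is the one whose upper-quartile CPM is closest to the mean upper
#' quartile; per sample, log2 ratios (M) and average log2 abundances (A)
#' against the reference are trimmed (30% of the M tails, 5% of the A
#' tails) and the scaling factor is two to the precision-weighted mean of
#' the retained M values. Factors are rescaled to geometric mean one. The
#' computation is delegated to the canonical implementation in edgeR.
#'
#' @param counts Count tibble (`exon_id` + one column per sample).
#' @return A tibble `sample_id`, `lib_size`, `norm_factor`,
#'   `effective_lib_size` (= `lib_size * norm_factor`).
#' @export
tmm_factors <- function(counts) {
  m <- count_matrix(counts)
  if (ncol(m) < 2) abort("TMM normalization requires at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM")
  tibble(
    sample_id = colnames(m),
    lib_size = unname(lib),
    norm_factor = unname(f),
    effective_lib_size = unname(lib * f)
  )
}

#' Counts per million on TMM-effective library sizes
#'
#' `CPM[i, s] = count[i, s] / effective_lib_size[s] * 1e6`.
#'
#' @param counts Count tibble.
#' @param normalization Tibble from [tmm_factors()]; must cover every
#'   sample column of `counts`.
#' @return A tibble of the same shape as `counts` holding CPM values.
#' @export
cpm <- function(counts, normalization) {
  m <- count_matrix(counts)
  missing <- setdiff(colnames(m), normalization$sample_id)
  if (length(missing) > 0) {
    abort(paste0("normalization lacks sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  eff <- normalization$effective_lib_size[
    match(colnames(m), normalization$sample_id)]
  out <- sweep(m, 2, eff, "/") * 1e6
  bind_cols(tibble(exon_id = counts$exon_id), as_tibble(out))
}

#' Binary expressed / not-expressed calls at a CPM threshold
#'
#' An exon is expressed in a sample when its CPM strictly exceeds the
#' threshold. The thresholds examined in this framework are 0.05, 0.1,
#' 0.2, 0.5, 1 and 2 CPM, with 0.5 as the default operating point.
#'
#' @param cpm_table CPM tibble from [cpm()].
#' @param threshold Strictly positive CPM threshold (default 0.5).
#' @return A tibble `exon_id` + one logical column per sample.
#' @export
expressed_exons <- function(cpm_table, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("expression threshold must be a single positive number")
  }
  m <- count_matrix(cpm_table)
  bind_cols(tibble(exon_id = cpm_table$exon_id), as_tibble(m > threshold))
}

#' Expressed exon ids of one sample
#'
#' @param calls Call tibble from [expressed_exons()].
#' @param sample_id Sample column name.
#' @return Character vector of expressed exon ids.
#' @export
expressed_exon_set <- function(calls, sample_id) {
  if (!sample_id %in% names(calls)) {
    abort(paste0("unknown sample: ", sample_id))
  }
  calls$exon_id[calls[[sample_id]]]
}

#' Resolve patients with multiple samples per tissue
#'
#' When a patient contributes several samples of the same tissue, the
#' sample with the largest raw library size is kept, deterministically
#' (ties broken by sample id).
#'
#' @param sample_sheet Tibble with `sample_id`, `patient_id`, `tissue`
#'   (`"healthy"` or `"cancer"`) and optionally `cancer_type`.
#' @param counts Count tibble covering the samples.
#' @return The filtered sample sheet, one row per (patient, tissue).
#' @export
dedupe_samples <- function(sample_sheet, counts) {
  m <- count_matrix(counts)
  lib <- colSums(m)
  sample_sheet |>
    mutate(.lib = lib[match(.data$sample_id, names(lib))]) |>
    group_by(.data$patient_id, .data$tissue) |>
    arrange(dplyr::desc(.data$.lib), .data$sample_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".lib")
}

#' Read an exon count table / sample sheet
#'
#' @param file TSV path. Count tables have an `exon_id` column followed by
#'   sample columns; sample sheets have `sample_id`, `patient_id`,
#'   `tissue` and optionally `cancer_type`.
#' @return A tibble.
#' @export
read_counts <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  stopifnot("exon_id" %in% names(x))
  x
}

#' @rdname read_counts
#' @export
read_sample_sheet <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(x)))
  if (!all(x$tissue %in% c("healthy", "cancer"))) {
    abort("tissue must be 'healthy' or 'cancer'")
  }
  if (anyDuplicated(x$sample_id) > 0) abort("duplicate sample ids")
  x
}
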