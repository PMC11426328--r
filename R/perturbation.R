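# Per-patient edge perturbation calls (gained / lost / non-perturbed) and
# the six per-cohort edge categories.

#' Edge presence matrix across samples
#'
#' An edge is present in a sample when both endpoint exons are expressed.
#' Exons absent from the call table are treated as not expressed (presence
#' requires positive evidence).
#'
#' @param network Edge tibble with `exon_a`, `exon_b`.
#' @param calls Expression call tibble from [expressed_exons()].
#' @param sample_ids Samples to evaluate (default: all call columns).
#' @return A logical matrix, edges (named `exon_a|exon_b`) by samples.
#' @export
edge_presence <- function(network, calls, sample_ids = NULL) {
  sample_ids <- sample_ids %||% setdiff(names(calls), "exon_id")
  m <- as.matrix(calls[, sample_ids, drop = FALSE])
  rownames(m) <- calls$exon_id
  ia <- match(network$exon_a, rownames(m))
  ib <- match(network$exon_b, rownames(m))
  pa <- m[ifelse(is.na(ia), 1L, ia), , drop = FALSE]
  pa[is.na(ia), ] <- FALSE
  pb <- m[ifelse(is.na(ib), 1L, ib), , drop = FALSE]
  pb[is.na(ib), ] <- FALSE
  out <- pa & pb
  rownames(out) <- edge_key(network$exon_a, network$exon_b)
  out
}

#' Per-patient edge status codes
#'
#' For every paired patient (one healthy and one cancer sample) and every
#' edge, concatenates the healthy and cancer presence bits into a status
#' code: `"01"` = gained (absent healthy, present cancer), `"10"` = lost,
#' `"00"` / `"11"` = non-perturbed.
#'
#' @param network Edge tibble.
#' @param calls Expression call tibble.
#' @param sample_sheet Sample sheet restricted to one sample per
#'   (patient, tissue) (see [dedupe_samples()]).
#' @return A tibble `edge`, `patient_id`, `code`.
#' @export
edge_status <- function(network, calls, sample_sheet) {
  pairs <- sample_sheet |>
    filter(.data$tissue %in% c("healthy", "cancer")) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "tissue",
                       values_from = "sample_id")
  if (!all(c("healthy", "cancer") %in% names(pairs))) {
    abort("paired analysis requires healthy and cancer samples")
  }
  pairs <- filter(pairs, !is.na(.data$healthy), !is.na(.data$cancer))
  if (nrow(pairs) == 0) {
    abort("no patient has a paired healthy/cancer sample")
  }
  pres <- edge_presence(network, calls,
                        unique(c(pairs$healthy, pairs$cancer)))
  h <- pres[, pairs$healthy, drop = FALSE]
  c_ <- pres[, pairs$cancer, drop = FALSE]
  tibble(
    edge = rep(rownames(pres), times = nrow(pairs)),
    patient_id = rep(pairs$patient_id, each = nrow(pres)),
    code = paste0(as.integer(h), as.integer(c_))
  )
}

# the six cohort categories, from the tallies of gained ('01') and lost
# ('10') statuses across patients
category_from_counts <- function(n01, n10) {
  dplyr::case_when(
    n01 >= 1 & n10 >= 1 ~ "gained_or_lost",
    n01 >= 2 & n10 == 0 ~ "strictly_gained",
    n10 >= 2 & n01 == 0 ~ "strictly_lost",
    n01 == 1 & n10 == 0 ~ "patient_specific_gained",
    n10 == 1 & n01 == 0 ~ "patient_specific_lost",
    TRUE ~ "non_perturbed"
  )
}

#' Cohort-level edge categories
#'
#' Groups per-patient status codes of each edge into one of six mutually
#' exclusive categories: `non_perturbed` (never perturbed in any patient),
#' `strictly_gained` (gained in at least two patients, lost in none),
#' `strictly_lost`, `patient_specific_gained` (gained in exactly one
#' patient, lost in none), `patient_specific_lost`, and `gained_or_lost`
#' (gained in at least one patient and lost in at least one other).
#'
#' @param statuses Tibble from [edge_status()].
#' @return A tibble `edge`, `n01`, `n10`, `n11`, `n00`, `category`.
#' @export
cohort_category <- function(statuses) {
  if (nrow(statuses) == 0) abort("empty status table")
  statuses |>
    group_by(.data$edge) |>
    summarise(
      n01 = sum(.data$code == "01"),
      n10 = sum(.data$code == "10"),
      n11 = sum(.data$code == "11"),
      n00 = sum(.data$code == "00"),
      .groups = "drop"
    ) |>
    mutate(category = category_from_counts(.data$n01, .data$n10))
}

#' Perturbed edges of a cohort
#'
#' An edge is perturbed when it falls in any category other than
#' `non_perturbed`.
#'
#' @param categories Tibble from [cohort_category()].
#' @return The rows of perturbed edges.
#' @export
perturbed_edges <- function(categories) {
  filter(categories, .data$category != "non_perturbed")
}
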