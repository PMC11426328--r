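# Hypergeometric pathway enrichment over exon sets, Benjamini-Hochberg
# correction and generic set-overlap tests.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' population of `N` of which `K` are successes. Computed via the
#' log-space survival function, so large counts stay numerically stable.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (any(!ok)) abort("inconsistent hypergeometric counts")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Lower-tail hypergeometric probability
#'
#' `P(X <= k)`; used to report depletion (smaller overlap than expected
#' by chance).
#'
#' @inheritParams hypergeom_upper_tail
#' @export
hypergeom_lower_tail <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (any(!ok)) abort("inconsistent hypergeometric counts")
  phyper(k, m = K, n = N - K, k = n, lower.tail = TRUE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min over j >= i of p_(j) * m / j`, with the input order
#' preserved in the output.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return The q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Read an exon-to-pathway annotation
#'
#' Every exon of a gene inherits all of the gene's pathway annotations,
#' so the annotation is supplied directly at exon level.
#'
#' @param file TSV with columns `exon_id`, `pathway_id`.
#' @return A tibble of annotation rows.
#' @export
read_pathway_annotation <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("exon_id", "pathway_id") %in% names(x)))
  distinct(x, .data$exon_id, .data$pathway_id)
}

#' Hypergeometric pathway enrichment of an exon set
#'
#' Tests each pathway for over-representation in the query exon set
#' against a background of annotated exons (typically all annotated exons
#' of the background EEIN). Only pathways annotated to at least two
#' background exons are tested. p-values are BH-corrected across the
#' tested pathways; a pathway is significant when its q-value is at most
#' `q_cutoff`.
#'
#' @param query_exons Character vector of query exon ids (must be a
#'   subset of the background).
#' @param background_exons Character vector of background exon ids.
#' @param annotation Tibble from [read_pathway_annotation()].
#' @param q_cutoff Significance cutoff on q (default 0.05).
#' @return A tibble of class `eein_enrichment`: `pathway_id`, `k` (query
#'   hits), `K` (background hits), `n` (annotated query size), `N`
#'   (annotated background size), `p`, `q`, `significant`.
#' @export
enrich_pathways <- function(query_exons, background_exons, annotation,
                            q_cutoff = 0.05) {
  if (length(query_exons) == 0) abort("empty query exon set")
  if (!all(query_exons %in% background_exons)) {
    abort("query exons must be a subset of the background")
  }
  ann <- filter(annotation, .data$exon_id %in% background_exons)
  bg <- unique(ann$exon_id)                # annotated background
  qy <- intersect(unique(query_exons), bg) # annotated query
  eligible <- ann |>
    count(.data$pathway_id, name = "K") |>
    filter(.data$K >= 2)
  if (nrow(eligible) == 0) {
    out <- tibble(pathway_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  q = numeric(), significant = logical())
    class(out) <- c("eein_enrichment", class(out))
    return(out)
  }
  hits <- ann |>
    filter(.data$exon_id %in% qy) |>
    count(.data$pathway_id, name = "k")
  out <- eligible |>
    left_join(hits, by = "pathway_id") |>
    mutate(
      k = ifelse(is.na(.data$k), 0L, .data$k),
      n = length(qy),
      N = length(bg),
      p = hypergeom_upper_tail(.data$k, .data$K, .data$n, .data$N)
    ) |>
    mutate(q = bh_adjust(.data$p), significant = .data$q <= q_cutoff) |>
    select("pathway_id", "k", "K", "n", "N", "p", "q", "significant") |>
    arrange(.data$p, .data$pathway_id)
  class(out) <- c("eein_enrichment", class(out))
  out
}

#' Hypergeometric overlap of two sets
#'
#' Tests whether the overlap of two sets drawn from a common background
#' is larger (`p_upper`) or smaller (`p_lower`) than expected by chance.
#' Used both for edge-set overlaps between cancer types and for overlaps
#' with externally derived survival gene lists.
#'
#' @param set_a,set_b Character vectors (elements of the background).
#' @param background_size Size of the common background universe.
#' @return A one-row tibble `n_a`, `n_b`, `overlap`, `p_upper`,
#'   `p_lower`.
#' @export
set_overlap_test <- function(set_a, set_b, background_size) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) > background_size || length(b) > background_size) {
    abort("set larger than the background universe")
  }
  k <- length(intersect(a, b))
  tibble(
    n_a = length(a), n_b = length(b), overlap = k,
    p_upper = hypergeom_upper_tail(k, length(a), length(b),
                                   background_size),
    p_lower = hypergeom_lower_tail(k, length(a), length(b),
                                   background_size)
  )
}

#' Survival-associated genes from an external Z-score list
#'
#' Filters a Cox-regression Z-score table (consumed from an external
#' resource) to the genes significantly associated with survival:
#' `|Z| > cutoff`, the default 1.96 corresponding to p < 0.05.
#'
#' @param z_table Tibble with `gene_id`, `z` (and optionally
#'   `cancer_type`).
#' @param cutoff Absolute Z cutoff (default 1.96).
#' @return The significant rows, with a `direction` column (`risk` for
#'   positive Z, `protective` for negative).
#' @export
significant_survival_genes <- function(z_table, cutoff = 1.96) {
  stopifnot(all(c("gene_id", "z") %in% names(z_table)))
  z_table |>
    filter(.data$z < -cutoff | .data$z > cutoff) |>
    mutate(direction = ifelse(.data$z > 0, "risk", "protective"))
}
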