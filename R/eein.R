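# Assembly of global exon-exon interaction networks (EEINs) and
# expression-induced sample-specific subnetworks.

# Canonical edge orientation: exon_a < exon_b lexicographically. All set
# arithmetic downstream relies on this key.
canonical_edges <- function(edges) {
  flip <- edges$exon_a > edges$exon_b
  out <- edges
  out$exon_a[flip] <- edges$exon_b[flip]
  out$exon_b[flip] <- edges$exon_a[flip]
  if (all(c("gene_a", "gene_b") %in% names(edges))) {
    out$gene_a[flip] <- edges$gene_b[flip]
    out$gene_b[flip] <- edges$gene_a[flip]
  }
  out
}

edge_key <- function(exon_a, exon_b) {
  paste(pmin(exon_a, exon_b), pmax(exon_a, exon_b), sep = "|")
}

#' Contact-based exon-exon interactions
#'
#' Tallies exon-labeled inter-chain residue contacts into candidate edges:
#' an exon pair interacts when it is supported by at least `min_contacts`
#' residue-residue contacts. Contacts with an unlabeled residue on either
#' side are ignored.
#'
#' @param labeled_contacts Tibble with one row per residue contact carrying
#'   exon labels `exon_a`, `exon_b` (NA = unlabeled) and gene labels
#'   `gene_a`, `gene_b`.
#' @param min_contacts Minimum number of supporting contacts (default 1;
#'   a stricter value of 5 is the usual robustness variant).
#' @return A tibble `exon_a`, `exon_b`, `gene_a`, `gene_b`, `method`
#'   (`"contact"`), `contact_count`, canonically ordered.
#' @export
contact_eeis <- function(labeled_contacts, min_contacts = 1) {
  stopifnot(min_contacts >= 1)
  x <- labeled_contacts |>
    filter(!is.na(.data$exon_a), !is.na(.data$exon_b)) |>
    canonical_edges() |>
    count(.data$exon_a, .data$exon_b, .data$gene_a, .data$gene_b,
          name = "contact_count") |>
    filter(.data$contact_count >= min_contacts) |>
    mutate(method = "contact", .before = "contact_count")
  arrange(x, .data$exon_a, .data$exon_b)
}

#' Interface-exon interactions from an external bio-relevance call
#'
#' For a chain-pair interface called biologically relevant by an external
#' classifier (solvation-energy or evolutionary), every pair of interface
#' exons across the two chains forms an edge. A non-relevant interface
#' contributes no edges.
#'
#' @param call One row of [read_interface_calls()] (fields `method`,
#'   `bio_relevant`).
#' @param exons_a,exons_b Tibbles of interface exons per chain with columns
#'   `exon_id`, `gene_id` (one row per exon).
#' @return A tibble `exon_a`, `exon_b`, `gene_a`, `gene_b`, `method`.
#' @export
interface_eeis <- function(call, exons_a, exons_b) {
  stopifnot(call$method %in% c("energy", "evolution"))
  empty <- tibble(exon_a = character(), exon_b = character(),
                  gene_a = character(), gene_b = character(),
                  method = character())
  if (!isTRUE(as.logical(call$bio_relevant))) return(empty)
  if (nrow(exons_a) == 0 || nrow(exons_b) == 0) return(empty)
  ea <- distinct(exons_a, .data$exon_id, .data$gene_id)
  eb <- distinct(exons_b, .data$exon_id, .data$gene_id)
  tidyr::crossing(
    tibble(exon_a = ea$exon_id, gene_a = ea$gene_id),
    tibble(exon_b = eb$exon_id, gene_b = eb$gene_id)
  ) |>
    canonical_edges() |>
    mutate(method = call$method) |>
    select("exon_a", "exon_b", "gene_a", "gene_b", "method") |>
    arrange(.data$exon_a, .data$exon_b)
}

#' Merge method-specific edge lists into a global EEIN
#'
#' Merges contact-, energy- and evolution-supported edges by canonical exon
#' pair, recording the union of supporting methods. Contact counts from
#' multiple structures are merged by their maximum. Confidence tiers are
#' obtained with [eein_tier()]: HIGH = all three methods, MEDIUM = at
#' least two, LOW = at least one, so the tiers are nested.
#'
#' @param ... Edge tibbles (as from [contact_eeis()] / [interface_eeis()]),
#'   each with `exon_a`, `exon_b`, `gene_a`, `gene_b`, `method` and
#'   optionally `contact_count`.
#' @return A tibble `exon_a`, `exon_b`, `gene_a`, `gene_b`, `methods`
#'   (comma-joined, sorted), `support_count`, `contact_count` (NA when no
#'   contact support).
#' @export
build_global_networks <- function(...) {
  edges <- bind_rows(...)
  if (nrow(edges) == 0) {
    return(tibble(exon_a = character(), exon_b = character(),
                  gene_a = character(), gene_b = character(),
                  methods = character(), support_count = integer(),
                  contact_count = integer()))
  }
  if (!"contact_count" %in% names(edges)) edges$contact_count <- NA_integer_
  edges <- canonical_edges(edges)
  if (any(edges$exon_a == edges$exon_b)) {
    abort("self-loop exon pair in edge list")
  }
  if (any(edges$gene_a == edges$gene_b)) {
    abort("intra-gene edge: EEIs are heterodimeric only")
  }
  edges |>
    group_by(.data$exon_a, .data$exon_b, .data$gene_a, .data$gene_b) |>
    summarise(
      methods = paste(sort(unique(.data$method)), collapse = ","),
      support_count = length(unique(.data$method)),
      contact_count = if (all(is.na(.data$contact_count))) NA_integer_
                      else max(.data$contact_count, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(.data$exon_a, .data$exon_b)
}

#' Extract a confidence tier of a global EEIN
#'
#' @param network Tibble from [build_global_networks()].
#' @param tier `"HIGH"` (support by all three methods), `"MEDIUM"` (at
#'   least two) or `"LOW"` (at least one).
#' @return The edge rows belonging to the tier.
#' @export
eein_tier <- function(network, tier = c("HIGH", "MEDIUM", "LOW")) {
  tier <- match.arg(tier)
  min_support <- c(HIGH = 3L, MEDIUM = 2L, LOW = 1L)[[tier]]
  filter(network, .data$support_count >= min_support)
}

#' Edge and node counts of the three EEIN tiers
#'
#' @param network Tibble from [build_global_networks()].
#' @return A tibble `tier`, `n_edges`, `n_nodes`.
#' @export
tier_sizes <- function(network) {
  purrr::map(c("HIGH", "MEDIUM", "LOW"), function(t) {
    e <- eein_tier(network, t)
    tibble(tier = t, n_edges = nrow(e),
           n_nodes = length(unique(c(e$exon_a, e$exon_b))))
  }) |> bind_rows()
}

#' Induce the sample-specific subnetwork of expressed exons
#'
#' Keeps exactly the edges whose both endpoint exons are expressed in the
#' sample: the sample-specific EEIN is the induced subgraph of the global
#' network on the expressed exon set.
#'
#' @param network Edge tibble with `exon_a`, `exon_b`.
#' @param expressed_exons Character vector of expressed exon ids.
#' @return The edge rows with both endpoints expressed.
#' @export
induce_sample_network <- function(network, expressed_exons) {
  filter(network, .data$exon_a %in% expressed_exons,
         .data$exon_b %in% expressed_exons)
}

#' Read / write EEIN edge tables
#'
#' TSV round-trip of the network tables produced by
#' [build_global_networks()].
#'
#' @param network Edge tibble.
#' @param file Path.
#' @export
write_eein <- function(network, file) {
  readr::write_tsv(network, file)
  invisible(file)
}

#' @rdname write_eein
#' @export
read_eein <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    support_count = readr::col_integer(),
                    contact_count = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}
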