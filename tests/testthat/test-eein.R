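lab_contact <- function(exon_a, exon_b, gene_a = "G1", gene_b = "G2") {
  tibble::tibble(exon_a = exon_a, exon_b = exon_b,
                 gene_a = gene_a, gene_b = gene_b)
}

test_that("contact EEIs respect the minimum contact count", {
  one <- lab_contact("e1", "e2")
  expect_equal(nrow(contact_eeis(one, min_contacts = 1)), 1)
  expect_equal(contact_eeis(one)$contact_count, 1)
  expect_equal(nrow(contact_eeis(one, min_contacts = 5)), 0)
  five <- dplyr::bind_rows(rep(list(one), 5))
  expect_equal(nrow(contact_eeis(five, min_contacts = 5)), 1)
})

test_that("contact EEIs match a brute-force tally and drop unlabeled residues", {
  set.seed(42)
  pairs <- c("a1|b1", "a1|b2", "a2|b1")
  draws <- sample(pairs, 50, replace = TRUE)
  contacts <- lab_contact(sub("\\|.*", "", draws), sub(".*\\|", "", draws))
  contacts$exon_a[1:3] <- NA # unlabeled residues are ignored
  got <- contact_eeis(contacts)
  want <- table(draws[-(1:3)])
  expect_equal(nrow(got), length(want))
  expect_equal(
    got$contact_count[match(names(want),
                            paste(got$exon_a, got$exon_b, sep = "|"))],
    as.integer(want)
  )
})

test_that("interface EEIs are the bipartite product gated by bio-relevance", {
  call_yes <- tibble::tibble(method = "energy", bio_relevant = TRUE)
  ea <- tibble::tibble(exon_id = c("a1", "a2"), gene_id = "G1")
  eb <- tibble::tibble(exon_id = c("b1", "b2", "b3"), gene_id = "G2")
  e <- interface_eeis(call_yes, ea, eb)
  expect_equal(nrow(e), 6)
  expect_equal(unique(e$method), "energy")
  call_no <- tibble::tibble(method = "energy", bio_relevant = FALSE)
  expect_equal(nrow(interface_eeis(call_no, ea, eb)), 0)
  expect_equal(nrow(interface_eeis(call_yes, ea[0, ], eb)), 0)
})

test_that("tier sizes follow inclusion-exclusion on disjoint toy lists", {
  # 2 exon pairs in all three lists, 1 pair in two lists, rest unique:
  # |HIGH| = 2, |MEDIUM| = 3, |LOW| = 3 + 4 + 5 - 2*2 - 1 = 7
  mk <- function(keys, method) {
    tibble::tibble(
      exon_a = paste0("x", keys), exon_b = paste0("y", keys),
      gene_a = "G1", gene_b = "G2", method = method
    )
  }
  contact <- mk(c(1, 2, 3), "contact")
  energy <- mk(c(1, 2, 4, 5), "energy")
  evol <- mk(c(1, 2, 4, 6, 7), "evolution")
  net <- build_global_networks(contact, energy, evol)
  sz <- tier_sizes(net)
  expect_equal(sz$n_edges, c(2L, 3L, 7L))
  # brute-force union tally agrees
  all_keys <- c(paste0("x", c(1, 2, 3)), paste0("x", c(1, 2, 4, 5)),
                paste0("x", c(1, 2, 4, 6, 7)))
  expect_equal(sz$n_edges[3], length(unique(all_keys)))
})

test_that("tier membership reflects support and tiers nest", {
  e1 <- lab_contact("e1", "e2") |> dplyr::mutate(method = "contact")
  e2 <- e1 |> dplyr::mutate(method = "energy")
  e3 <- e1 |> dplyr::mutate(method = "evolution")
  triple <- build_global_networks(e1, e2, e3)
  expect_equal(nrow(eein_tier(triple, "HIGH")), 1)
  single <- build_global_networks(e1)
  expect_equal(nrow(eein_tier(single, "HIGH")), 0)
  expect_equal(nrow(eein_tier(single, "MEDIUM")), 0)
  expect_equal(nrow(eein_tier(single, "LOW")), 1)
  # random networks: HIGH subset of MEDIUM subset of LOW
  set.seed(7)
  for (rep in 1:10) {
    lists <- purrr::map(c("contact", "energy", "evolution"), function(m) {
      k <- sample(1:12, sample(3:8, 1))
      tibble::tibble(exon_a = paste0("u", k), exon_b = paste0("v", k),
                     gene_a = "G1", gene_b = "G2", method = m)
    })
    net <- do.call(build_global_networks, lists)
    key <- function(x) paste(x$exon_a, x$exon_b)
    expect_true(all(key(eein_tier(net, "HIGH")) %in%
                      key(eein_tier(net, "MEDIUM"))))
    expect_true(all(key(eein_tier(net, "MEDIUM")) %in%
                      key(eein_tier(net, "LOW"))))
  }
})

test_that("network merge is canonical, idempotent and order-independent", {
  a <- lab_contact("e2", "e1", "G2", "G1") |>
    dplyr::mutate(method = "contact")
  b <- lab_contact("e1", "e2", "G1", "G2") |>
    dplyr::mutate(method = "energy")
  n1 <- build_global_networks(a, b)
  n2 <- build_global_networks(b, a)
  expect_equal(n1, n2)
  expect_equal(nrow(n1), 1)
  expect_equal(n1$exon_a, "e1") # canonical order
  expect_equal(n1$support_count, 2L)
  # self-loops and intra-gene edges are rejected
  expect_error(build_global_networks(lab_contact("e1", "e1") |>
                                       dplyr::mutate(method = "contact")),
               "self-loop")
  expect_error(build_global_networks(lab_contact("e1", "e2", "G1", "G1") |>
                                       dplyr::mutate(method = "contact")),
               "heterodimeric")
})

test_that("contact counts merge by maximum across structures", {
  s1 <- contact_eeis(dplyr::bind_rows(rep(list(lab_contact("e1", "e2")), 3)))
  s2 <- contact_eeis(lab_contact("e1", "e2"))
  net <- build_global_networks(s1, s2)
  expect_equal(net$contact_count, 3L)
  expect_equal(net$support_count, 1L)
})

test_that("induced sample networks keep edges with both endpoints expressed", {
  net <- tibble::tibble(
    exon_a = paste0("a", 1:100), exon_b = paste0("b", 1:100),
    gene_a = "G1", gene_b = "G2"
  )
  expect_equal(nrow(induce_sample_network(net, c(net$exon_a, net$exon_b))),
               100)
  expect_equal(nrow(induce_sample_network(net, character())), 0)
  set.seed(5)
  expressed <- sample(c(net$exon_a, net$exon_b), 100)
  got <- induce_sample_network(net, expressed)
  want <- net[net$exon_a %in% expressed & net$exon_b %in% expressed, ]
  expect_equal(got, want)
  # monotone: more expressed exons, never fewer edges
  bigger <- unique(c(expressed, sample(c(net$exon_a, net$exon_b), 50)))
  expect_gte(nrow(induce_sample_network(net, bigger)), nrow(got))
})

test_that("network TSVs round-trip losslessly", {
  e1 <- lab_contact("e1", "e2") |> dplyr::mutate(method = "contact")
  net <- build_global_networks(e1, dplyr::mutate(e1, method = "energy"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eein(net, f)
  expect_equal(read_eein(f), net)
})
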