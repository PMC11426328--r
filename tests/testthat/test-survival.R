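clin <- function(time, event, ids = paste0("p", seq_along(time))) {
  tibble::tibble(patient_id = ids, time = time, event = event)
}

test_that("Kaplan-Meier estimate matches hand products and the oracle", {
  km <- km_curve(clin(c(1, 2), c(1, 1)))
  expect_equal(km$survival, c(0.5, 0))
  km2 <- km_curve(clin(c(3, 5, 8), c(0, 0, 0)))
  expect_equal(km2$survival, rep(1, 3))
  set.seed(21)
  cl <- clin(sample(1:12, 10, replace = TRUE),
             rbinom(10, 1, 0.7))
  km3 <- km_curve(cl)
  want <- km_oracle(cl$time, cl$event)
  expect_equal(km3$time, want$time)
  expect_equal(km3$survival, want$survival, tolerance = 1e-12)
  # and the survival package agrees
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = cl)
  expect_equal(km3$survival, unname(sf$surv), tolerance = 1e-12)
  expect_error(km_curve(cl[0, ]), "empty")
})

test_that("km tidiers summarise the fit", {
  cl <- clin(c(1, 2, 3, 4), c(1, 1, 0, 1))
  km <- km_curve(cl)
  expect_s3_class(tidy(km), "tbl_df")
  g <- glance(km)
  expect_equal(g$n, 4)
  expect_equal(g$n_events, 3)
  expect_equal(g$n_censored, 1)
})

test_that("logrank of identical groups is null", {
  a <- clin(c(2, 4, 6), c(1, 1, 0))
  both <- dplyr::bind_rows(dplyr::mutate(a, present = TRUE),
                           dplyr::mutate(a, present = FALSE,
                                         patient_id = paste0(patient_id, "b")))
  r <- logrank_test(both)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
})

test_that("logrank reproduces a hand-computed O/E/V table", {
  # group A: events at 1 and 3, censored at 5; group B: events at 2, 4, 6
  # hand table gives O-E = 4/15, V = 433/450, chi-square = 32/433
  cl <- dplyr::bind_rows(
    clin(c(1, 3, 5), c(1, 1, 0), ids = paste0("a", 1:3)) |>
      dplyr::mutate(present = TRUE),
    clin(c(2, 4, 6), c(1, 1, 1), ids = paste0("b", 1:3)) |>
      dplyr::mutate(present = FALSE)
  )
  r <- logrank_test(cl)
  expect_equal(r$o_minus_e, 4 / 15, tolerance = 1e-9)
  expect_equal(r$chisq, 32 / 433, tolerance = 1e-9)
  expect_equal(r$p, pchisq(32 / 433, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("logrank is symmetric under label swap", {
  set.seed(5)
  cl <- clin(rexp(30, 1 / 100), rbinom(30, 1, 0.8)) |>
    dplyr::mutate(present = rep(c(TRUE, FALSE), 15))
  r1 <- logrank_test(cl)
  r2 <- logrank_test(dplyr::mutate(cl, present = !present))
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  # direction labels are exchange-antisymmetric
  expect_equal(r1$o_minus_e, -r2$o_minus_e, tolerance = 1e-12)
})

test_that("logrank matches the survival package on random fixtures", {
  set.seed(1234)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    cl <- clin(sample(1:20, n, replace = TRUE), rbinom(n, 1, 0.7)) |>
      dplyr::mutate(present = sample(c(TRUE, FALSE), n, replace = TRUE))
    if (all(cl$present) || all(!cl$present) || sum(cl$event) == 0) next
    r <- logrank_test(cl)
    sd <- survival::survdiff(survival::Surv(time, event) ~ present,
                             data = cl)
    expect_equal(r$chisq, unname(sd$chisq), tolerance = 1e-9)
    expect_equal(r$p, pchisq(unname(sd$chisq), 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("edge splits enforce the minimum group size", {
  cl <- clin(rexp(127, 1 / 100) + 1, rbinom(127, 1, 0.7))
  pres <- setNames(rep(c(TRUE, FALSE), c(15, 112)), cl$patient_id)
  s <- split_by_edge(pres, cl)
  expect_true(attr(s, "valid"))
  pres2 <- setNames(rep(c(TRUE, FALSE), c(9, 118)), cl$patient_id)
  expect_false(attr(split_by_edge(pres2, cl), "valid"))
  pres3 <- setNames(rep(TRUE, 127), cl$patient_id)
  expect_false(attr(split_by_edge(pres3, cl), "valid"))
  # patients without presence information count as absent
  s4 <- split_by_edge(pres[1:50], cl)
  expect_equal(sum(s4$present), 15)
})

test_that("crpe scan flags edges by the inclusive alpha rule", {
  set.seed(77)
  n <- 60
  cl <- clin(rexp(n, 1 / 500), rbinom(n, 1, 0.8))
  pres <- matrix(sample(c(TRUE, FALSE), 3 * n, replace = TRUE), nrow = 3,
                 dimnames = list(paste0("e", 1:3), cl$patient_id))
  scan_all <- crpe_scan(pres, cl, alpha = 0.999999)
  expect_true(all(scan_all$is_crpe[scan_all$tested]))
  scan_none <- crpe_scan(pres, cl, alpha = 1e-12)
  expect_false(any(scan_none$is_crpe))
  # scan restricted to a subset of edges
  scan_sub <- crpe_scan(pres, cl, edges = c("e1", "e3"))
  expect_setequal(scan_sub$edge, c("e1", "e3"))
  # a small present group is rejected, not an error
  pres2 <- pres
  pres2[1, ] <- c(rep(TRUE, 5), rep(FALSE, n - 5))
  expect_false(crpe_scan(pres2, cl)$tested[1])
})

test_that("a strong planted edge is detected by scan and biomarker test", {
  present <- setNames(rep(c(TRUE, FALSE), each = 100),
                      sprintf("p%03d", 1:200))
  cl <- synthetic_survival(present, hazard_ratio = 3,
                           censoring_fraction = 0.3, seed = 42)
  pres <- matrix(present, nrow = 1,
                 dimnames = list("edge1", names(present)))
  scan <- crpe_scan(pres, cl)
  expect_true(scan$is_crpe[1])
  expect_equal(scan$direction[1], "unfavorable") # carriers die faster
  bt <- biomarker_test(pres["edge1", ], cl, n_rand = 50, seed = 7)
  expect_true(bt$is_biomarker)
  # the reported flag follows the calling rule exactly
  expect_equal(
    bt$is_biomarker,
    bt$p_real < 0.05 &&
      min(bt$min_p_presence, bt$min_p_survival) > bt$p_real
  )
  # a null edge on the same cohort is not called
  set.seed(9)
  null_pres <- setNames(sample(present), names(present))
  bt0 <- biomarker_test(null_pres, cl, n_rand = 50, seed = 7)
  expect_false(bt0$is_biomarker)
})

test_that("presence randomization preserves counts and is uniform", {
  pres <- setNames(c(rep(TRUE, 5), rep(FALSE, 15)), paste0("p", 1:20))
  r <- randomize_edge_patients(pres, seed = 1)
  expect_equal(sum(r), 5)
  expect_equal(names(r), names(pres))
  expect_equal(randomize_edge_patients(pres, seed = 1), r) # deterministic
  expect_error(randomize_edge_patients(rep(TRUE, 5)), "0 < k < n")
  # each patient is present with frequency ~ k/n
  set.seed(2)
  freq <- rowMeans(vapply(1:4000, function(i) randomize_edge_patients(pres),
                          logical(20)))
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq - 0.25) < 3.5 * se + 0.02))
})

test_that("survival randomization permutes outcome pairs jointly", {
  cl <- clin(c(10, 20, 30, 40), c(1, 0, 1, 1))
  r <- randomize_survival(cl, seed = 3)
  expect_setequal(paste(r$time, r$event), paste(cl$time, cl$event))
  expect_equal(r$patient_id, cl$patient_id)
  # n = 2: identity or swap
  cl2 <- clin(c(1, 2), c(1, 0))
  r2 <- randomize_survival(cl2, seed = 4)
  expect_true(all(r2$time %in% c(1, 2)))
  expect_setequal(paste(r2$time, r2$event), c("1 1", "2 0"))
})

test_that("zero total events make the logrank test undefined", {
  cl <- clin(c(1, 2, 3, 4), c(0, 0, 0, 0)) |>
    dplyr::mutate(present = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(logrank_test(cl), "no events")
})
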