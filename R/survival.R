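# Kaplan-Meier estimation, two-group logrank testing, the edge-wise
# survival scan (CRPEs) and the dual-permutation biomarker test
# (BioCRPEs).
#
# A clinical table is a tibble with `patient_id`, `time` (days, > 0) and
# `event` (1 = death observed, 0 = censored).

check_clinical <- function(clinical) {
  stopifnot(all(c("time", "event") %in% names(clinical)))
  if (nrow(clinical) == 0) abort("empty clinical table")
  if (any(!is.finite(clinical$time)) || any(clinical$time <= 0)) {
    abort("survival times must be finite and positive")
  }
  if (!all(clinical$event %in% c(0, 1))) {
    abort("event must be 0 (censored) or 1 (death)")
  }
  invisible(clinical)
}

#' Kaplan-Meier product-limit curve
#'
#' @param clinical Clinical tibble (`time`, `event`).
#' @return A tibble of class `eein_km` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival` (the
#'   product-limit estimate just after `time`). Survival is 1 before the
#'   first event; censored subjects leave the risk set without reducing
#'   the product.
#' @export
km_curve <- function(clinical) {
  check_clinical(clinical)
  o <- order(clinical$time)
  t_s <- clinical$time[o]
  e_s <- clinical$event[o]
  u <- unique(t_s)
  first <- match(u, t_s)
  n_risk <- length(t_s) - first + 1
  n_event <- as.vector(rowsum(e_s, t_s))
  n_censor <- as.vector(rowsum(1 - e_s, t_s))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(time = u, n_risk = n_risk, n_event = n_event,
                n_censor = n_censor, survival = surv)
  class(out) <- c("eein_km", class(out))
  attr(out, "n") <- length(t_s)
  out
}

# Core logrank computation on a logical group indicator. Returns the
# chi-square statistic (1 df), its p-value and the observed-minus-expected
# event count of the TRUE group.
logrank_stat <- function(time, event, group) {
  o <- order(time)
  t_s <- time[o]
  e_s <- event[o]
  g_s <- as.logical(group)[o]
  u <- unique(t_s)
  first <- match(u, t_s)
  n_risk <- length(t_s) - first + 1
  nA_risk <- rev(cumsum(rev(g_s)))[first]
  d <- as.vector(rowsum(e_s, t_s))
  dA <- as.vector(rowsum(e_s * g_s, t_s))
  ev <- d > 0
  d <- d[ev]; dA <- dA[ev]
  n <- n_risk[ev]; nA <- nA_risk[ev]
  if (length(d) == 0) abort("logrank test undefined: no events")
  E <- d * nA / n
  V <- ifelse(n > 1, d * (n - d) * nA * (n - nA) / (n^2 * (n - 1)), 0)
  ome <- sum(dA) - sum(E)
  v <- sum(V)
  chisq <- if (v > 0) ome^2 / v else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       o_minus_e = ome, n_a = sum(g_s), n_b = sum(!g_s))
}

#' Two-group logrank test
#'
#' Standard logrank comparison of two survival curves: at each distinct
#' event time the expected events in the first group follow the
#' hypergeometric distribution of the risk sets; the statistic is
#' `(sum O - sum E)^2 / sum V` referred to a chi-square with one degree of
#' freedom (two-sided). Censoring ties at an event time remain at risk
#' through that time.
#'
#' @param clinical Clinical tibble (`time`, `event`) with a grouping
#'   column.
#' @param group Name of a logical column (TRUE = first group, e.g. edge
#'   present).
#' @return A one-row tibble of class `eein_logrank`: `chisq`, `df`, `p`,
#'   `n_a`, `n_b`, `o_minus_e` (observed minus expected events of the
#'   TRUE group; a negative value means that group died less than
#'   expected).
#' @export
logrank_test <- function(clinical, group = "present") {
  check_clinical(clinical)
  if (!group %in% names(clinical)) {
    abort(paste0("no grouping column '", group, "'"))
  }
  g <- as.logical(clinical[[group]])
  if (all(g) || all(!g)) abort("both groups must be non-empty")
  s <- logrank_stat(clinical$time, clinical$event, g)
  out <- tibble(chisq = s$chisq, df = 1L, p = s$p,
                n_a = s$n_a, n_b = s$n_b, o_minus_e = s$o_minus_e)
  class(out) <- c("eein_logrank", class(out))
  out
}

#' Split a survival cohort by edge presence
#'
#' Joins an edge's per-patient presence calls (on cancer samples) to the
#' clinical table. The split is usable for the survival scan only when
#' both groups hold at least `min_group` patients; otherwise it is
#' rejected (attribute `valid` is `FALSE`), not an error.
#'
#' @param present Named logical vector: edge presence per patient id.
#' @param clinical Clinical tibble with `patient_id`.
#' @param min_group Minimum group size (default 10).
#' @return A tibble `patient_id`, `present`, `time`, `event` over the
#'   evaluable cohort, with attribute `valid`.
#' @export
split_by_edge <- function(present, clinical, min_group = 10) {
  check_clinical(clinical)
  idx <- match(clinical$patient_id, names(present))
  out <- tibble(
    patient_id = clinical$patient_id,
    present = ifelse(is.na(idx), FALSE, unname(present)[idx]),
    time = clinical$time,
    event = clinical$event
  )
  attr(out, "valid") <- sum(out$present) >= min_group &&
    sum(!out$present) >= min_group
  out
}

#' Survival scan over perturbed edges (CRPE identification)
#'
#' For every edge, splits the cohort by edge presence in the cancer
#' sample and computes the logrank p-value; an edge is a cancer-relevant
#' perturbed edge (CRPE) when `p <= alpha`. Edges whose split leaves
#' fewer than `min_group` patients in either group are recorded as
#' untested. No multiple-testing correction is applied: the p-values act
#' as proxy scores, and a correction would not change their ranking.
#'
#' @param presence Logical matrix, edges by patients (as from
#'   [edge_presence()] on cancer samples, columns renamed to patient
#'   ids).
#' @param clinical Clinical tibble with `patient_id`.
#' @param alpha CRPE significance cutoff (default 0.05; 0.01 is the usual
#'   robustness variant).
#' @param min_group Minimum patients per group (default 10).
#' @param edges Optional character vector restricting the scan to those
#'   edge keys (typically the cohort's perturbed edges).
#' @return A tibble `edge`, `n_present`, `n_absent`, `tested`, `chisq`,
#'   `p`, `o_minus_e`, `direction` (`favorable` when the present group
#'   has fewer deaths than expected), `is_crpe`.
#' @export
crpe_scan <- function(presence, clinical, alpha = 0.05, min_group = 10,
                      edges = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  check_clinical(clinical)
  if (!is.null(edges)) {
    presence <- presence[intersect(edges, rownames(presence)), ,
                         drop = FALSE]
  }
  rows <- purrr::map(rownames(presence), function(ek) {
    pv <- presence[ek, ]
    sp <- split_by_edge(pv, clinical, min_group)
    n_p <- sum(sp$present)
    n_a <- sum(!sp$present)
    if (!attr(sp, "valid")) {
      return(tibble(edge = ek, n_present = n_p, n_absent = n_a,
                    tested = FALSE, chisq = NA_real_, p = NA_real_,
                    o_minus_e = NA_real_, direction = NA_character_,
                    is_crpe = FALSE))
    }
    s <- logrank_stat(sp$time, sp$event, sp$present)
    tibble(edge = ek, n_present = n_p, n_absent = n_a, tested = TRUE,
           chisq = s$chisq, p = s$p, o_minus_e = s$o_minus_e,
           direction = ifelse(s$o_minus_e < 0, "favorable",
                              "unfavorable"),
           is_crpe = s$p <= alpha)
  })
  bind_rows(rows)
}

#' Permute edge-to-patient assignment (count-preserving)
#'
#' Randomly reassigns the edge's presence calls to patients while keeping
#' the number of patients carrying the edge fixed.
#'
#' @param present Logical vector of presence calls.
#' @param seed Optional integer seed for reproducibility.
#' @return A logical vector with the same number of `TRUE` entries,
#'   uniformly repositioned.
#' @export
randomize_edge_patients <- function(present, seed = NULL) {
  k <- sum(present)
  n <- length(present)
  if (k == 0 || k == n) {
    abort("presence permutation requires 0 < k < n")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- rep(FALSE, n)
  out[sample.int(n, k)] <- TRUE
  names(out) <- names(present)
  out
}

#' Permute survival records across patients
#'
#' Jointly permutes `(time, event)` pairs over patient ids, preserving
#' the multiset of survival outcomes.
#'
#' @param clinical Clinical tibble.
#' @param seed Optional integer seed.
#' @return The clinical tibble with shuffled outcome pairs.
#' @export
randomize_survival <- function(clinical, seed = NULL) {
  check_clinical(clinical)
  if (nrow(clinical) < 2) abort("need at least 2 records to permute")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(clinical))
  out <- clinical
  out$time <- clinical$time[idx]
  out$event <- clinical$event[idx]
  out
}

#' Dual-permutation survival biomarker test for one edge
#'
#' Compares the edge's real logrank p-value against two permutation
#' nulls, each run `n_rand` times: (1) presence labels reassigned to
#' patients with the presence count fixed, survival kept; (2) survival
#' outcomes permuted over patients, presence kept. The edge is called a
#' biomarker when its real p-value is below `alpha` (strictly) and
#' every random p-value from both schemes exceeds the real one. The
#' direction is `favorable` when the present group shows fewer deaths
#' than expected.
#'
#' @param present Named logical vector of presence per patient id.
#' @param clinical Clinical tibble with `patient_id`.
#' @param n_rand Permutations per scheme (default 100).
#' @param seed Base seed; replicate `i` of the presence scheme uses
#'   `seed + i` and of the survival scheme `seed + n_rand + i`, so the
#'   two schemes are seeded independently.
#' @param alpha Real-p cutoff (default 0.05, strict).
#' @return A one-row tibble of class `eein_biomarker`: `p_real`,
#'   `direction`, `min_p_presence`, `min_p_survival`, `is_biomarker`,
#'   plus list-columns `p_rand_presence`, `p_rand_survival` with the
#'   `n_rand` p-values of each scheme.
#' @export
biomarker_test <- function(present, clinical, n_rand = 100, seed = 1,
                           alpha = 0.05) {
  sp <- split_by_edge(present, clinical, min_group = 0)
  g <- sp$present
  if (all(g) || all(!g)) abort("degenerate split: one group is empty")
  real <- logrank_stat(sp$time, sp$event, g)
  p1 <- vapply(seq_len(n_rand), function(i) {
    gp <- randomize_edge_patients(g, seed = seed + i)
    logrank_stat(sp$time, sp$event, gp)$p
  }, numeric(1))
  p2 <- vapply(seq_len(n_rand), function(i) {
    cl <- randomize_survival(sp, seed = seed + n_rand + i)
    logrank_stat(cl$time, cl$event, g)$p
  }, numeric(1))
  out <- tibble(
    p_real = real$p,
    direction = ifelse(real$o_minus_e < 0, "favorable", "unfavorable"),
    min_p_presence = min(p1),
    min_p_survival = min(p2),
    is_biomarker = real$p < alpha && min(c(p1, p2)) > real$p,
    p_rand_presence = list(p1),
    p_rand_survival = list(p2)
  )
  class(out) <- c("eein_biomarker", class(out))
  out
}

#' Biomarker scan over CRPEs
#'
#' Runs [biomarker_test()] for every CRPE of a survival scan, with
#' disjoint per-edge seed blocks derived from the base seed.
#'
#' @param scan Tibble from [crpe_scan()].
#' @param presence Logical matrix, edges by patients.
#' @param clinical Clinical tibble.
#' @inheritParams biomarker_test
#' @return A tibble, one row per CRPE, with the [biomarker_test()]
#'   columns prefixed by `edge`.
#' @export
biomarker_scan <- function(scan, presence, clinical, n_rand = 100,
                           seed = 1, alpha = 0.05) {
  crpes <- scan$edge[scan$is_crpe]
  if (length(crpes) == 0) {
    return(tibble(edge = character(), p_real = numeric(),
                  direction = character(), min_p_presence = numeric(),
                  min_p_survival = numeric(), is_biomarker = logical(),
                  p_rand_presence = list(), p_rand_survival = list()))
  }
  rows <- purrr::imap(crpes, function(ek, i) {
    bt <- biomarker_test(presence[ek, ], clinical, n_rand = n_rand,
                         seed = seed + (i - 1) * (2 * n_rand + 1),
                         alpha = alpha)
    bind_cols(tibble(edge = ek), bt)
  })
  bind_rows(rows)
}

#' Read a clinical survival table
#'
#' @param file TSV with columns `patient_id`, `time_days`, `event`.
#' @return A tibble `patient_id`, `time`, `event`.
#' @export
read_clinical <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  stopifnot(all(c("patient_id", "time_days", "event") %in% names(x)))
  out <- tibble(patient_id = as.character(x$patient_id),
                time = as.numeric(x$time_days),
                event = as.integer(x$event))
  check_clinical(out)
  out
}
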