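# Independent oracles used to cross-check the package implementations.
# Each is coded directly from the method definitions, without reusing
# package internals.

# all-pairs double-loop residue contact scan over heavy atoms
brute_force_contacts <- function(atoms, chain_a, chain_b, cutoff) {
  a <- atoms[atoms$chain == chain_a & atoms$is_heavy, ]
  b <- atoms[atoms$chain == chain_b & atoms$is_heavy, ]
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        key <- paste(a$resno[i], a$insert[i], b$resno[j], b$insert[j])
        if (is.null(out[[key]]) || d < out[[key]]$distance) {
          out[[key]] <- data.frame(
            resno_a = a$resno[i], insert_a = a$insert[i],
            resno_b = b$resno[j], insert_b = b$insert[j], distance = d)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(resno_a = integer(), insert_a = character(),
                      resno_b = integer(), insert_b = character(),
                      distance = numeric()))
  }
  res <- do.call(rbind, unname(out))
  res[order(res$resno_a, res$insert_a, res$resno_b, res$insert_b), ]
}

# trimmed mean of M-values, coded from the published algorithm:
# upper-quartile reference, 30%/5% trims, inverse-variance weights,
# geometric-mean-one rescaling
tmm_oracle <- function(m) {
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(j) unname(quantile(m[, j], 0.75)) / lib[j],
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(j) {
    obs <- m[, j]
    rc <- m[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    pos <- obs > 0 & rc > 0
    obs <- obs[pos]
    rc <- rc[pos]
    logR <- log2((obs / nO) / (rc / nR))
    absE <- (log2(obs / nO) + log2(rc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rc) / (nR * rc)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    2^f
  }, numeric(1))
  fac / exp(mean(log(fac)))
}

# exact hypergeometric upper tail by summation of binomial-coefficient
# terms
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# product-limit estimator by direct recursion over sorted times
km_oracle <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# random two-chain atom sets for contact-oracle comparisons
random_atoms <- function(n_per_chain, seed, box = 15) {
  set.seed(seed)
  n <- 2 * n_per_chain
  tibble::tibble(
    structure_id = "RND",
    chain = rep(c("A", "B"), each = n_per_chain),
    # several atoms may share a residue number, giving multi-atom residues
    resno = c(sort(sample(seq_len(max(2, n_per_chain %/% 3)),
                          n_per_chain, replace = TRUE)),
              sort(sample(seq_len(max(2, n_per_chain %/% 3)),
                          n_per_chain, replace = TRUE))),
    insert = "",
    resid = "ALA",
    atom = "CA",
    element = sample(c("C", "N", "O", "H"), n, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1)),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    occupancy = 1
  ) |>
    dplyr::mutate(is_heavy = element != "H")
}
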