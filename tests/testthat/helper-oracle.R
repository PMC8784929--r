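# Independent brute-force oracles: deliberately written as plain loops,
# sharing no code with the package implementations they check.

# spherical law of cosines on the same 6371.0 km sphere
oracle_distance_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  cosd <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  6371.0 * acos(min(max(cosd, -1), 1))
}

# per-locus summaries for one population, by explicit loops
oracle_locus <- function(calls) {
  n <- 0L; alt <- 0L; het <- 0L
  for (g in calls) {
    if (is.na(g)) next
    n <- n + 1L
    alt <- alt + g
    if (g == 1L) het <- het + 1L
  }
  if (n == 0L) return(list(n = 0L, p = NA_real_, ho = NA_real_))
  list(n = n, p = alt / (2 * n), ho = het / n)
}

oracle_pop_stats <- function(m, unbiased = TRUE) {
  ho <- he <- rep(NA_real_, ncol(m))
  for (l in seq_len(ncol(m))) {
    s <- oracle_locus(m[, l])
    if (s$n == 0L) next
    ho[l] <- s$ho
    he[l] <- 2 * s$p * (1 - s$p)
    if (unbiased) he[l] <- he[l] * 2 * s$n / (2 * s$n - 1)
  }
  ok <- !is.na(ho)
  fis <- if (!any(ok) || sum(he[ok]) == 0) NA_real_ else
    1 - sum(ho[ok]) / sum(he[ok])
  list(ho = ho, he = he,
       ho_mean = mean(ho, na.rm = TRUE), he_mean = mean(he, na.rm = TRUE),
       fis = fis)
}

# Weir & Cockerham (1984) variance components for one locus over r
# populations, general-r textbook form
oracle_wc_locus <- function(pop_calls) {
  r <- length(pop_calls)
  ni <- pi <- hi <- numeric(r)
  for (k in seq_len(r)) {
    s <- oracle_locus(pop_calls[[k]])
    ni[k] <- s$n; pi[k] <- ifelse(s$n > 0, s$p, 0); hi[k] <- ifelse(s$n > 0, s$ho, 0)
  }
  if (any(ni < 1) || sum(ni) < 3) return(NULL)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi) / sum(ni)
  hbar <- sum(ni * hi) / sum(ni)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_theta <- function(m1, m2) {
  num <- den <- 0
  for (l in seq_len(ncol(m1))) {
    comp <- oracle_wc_locus(list(m1[, l], m2[, l]))
    if (is.null(comp)) next
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  if (den == 0) NA_real_ else unname(num / den)
}

# private alleles by explicit enumeration over the presence table
oracle_private <- function(calls, group, min_count = 1) {
  groups <- sort(unique(group))
  out <- stats::setNames(integer(length(groups)), groups)
  for (l in seq_len(ncol(calls))) {
    for (allele in c("ref", "alt")) {
      present <- character(0)
      for (g in groups) {
        m <- calls[group == g, l]
        copies <- if (allele == "alt") sum(m, na.rm = TRUE) else
          sum(2 - m, na.rm = TRUE)
        if (copies >= min_count) present <- c(present, g)
      }
      if (length(present) == 1L) out[present] <- out[present] + 1L
    }
  }
  out
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# random genotype instance with labelled populations
random_gm <- function(n_pops, n_loci, n_per_pop, missing_rate = 0.1,
                      seed = 1) {
  set.seed(seed)
  pops <- sprintf("p%02d", seq_len(n_pops))
  calls <- NULL
  for (k in pops) {
    p <- runif(n_loci, 0.02, 0.98)
    g <- matrix(rbinom(n_per_pop * n_loci, 2, rep(p, each = n_per_pop)),
                nrow = n_per_pop)
    calls <- rbind(calls, g)
  }
  if (missing_rate > 0) calls[runif(length(calls)) < missing_rate] <- NA
  rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("l%03d", seq_len(n_loci))
  genotype_matrix(calls, rep(pops, each = n_per_pop))
}
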