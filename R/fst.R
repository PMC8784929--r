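#' Pairwise Weir-Cockerham F_ST (theta) for two populations
#'
#' Per-locus variance components after Weir & Cockerham (1984): `a` among
#' populations, `b` among individuals within populations, `c` within
#' individuals, computed from the per-population sample sizes, allele
#' frequencies and observed heterozygote frequencies. The multilocus
#' estimate is the ratio of sums, `theta = sum(a) / sum(a + b + c)`,
#' which is stable for low-diversity loci. Loci with fewer than one
#' genotyped diploid in either population, or fewer than three genotyped
#' diploids overall, are excluded (pairwise deletion). Small negative
#' estimates are a normal property of the estimator and are not truncated.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Site labels of the two populations.
#' @return List with `theta` (multilocus, `NA` when no locus is usable or
#'   the denominator is zero), `components` (data frame `locus, a, b, c`
#'   over used loci) and `n_loci`.
#' @export
wc_fst_pair <- function(gm, pop_a, pop_b) {
  s1 <- pop_locus_summary(gm, pop_a)
  s2 <- pop_locus_summary(gm, pop_b)
  use <- s1$n >= 1L & s2$n >= 1L & (s1$n + s2$n) >= 3L
  if (!any(use)) {
    return(list(theta = NA_real_,
                components = data.frame(locus = character(), a = numeric(),
                                        b = numeric(), c = numeric()),
                n_loci = 0L))
  }
  n1 <- s1$n[use]; p1 <- s1$p[use]; h1 <- s1$h[use]
  n2 <- s2$n[use]; p2 <- s2$p[use]; h2 <- s2$h[use]

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- sum(a + b + cc)
  theta <- if (denom == 0) NA_real_ else sum(a) / denom
  list(theta = theta,
       components = data.frame(locus = colnames(gm$calls)[use],
                               a = a, b = b, c = cc,
                               stringsAsFactors = FALSE),
       n_loci = sum(use))
}

#' Pairwise multilocus F_ST matrix over all sites
#'
#' Symmetric matrix of multilocus Weir-Cockerham theta over all unordered
#' site pairs, diagonal 0 by convention. Pairs without a usable locus get
#' `NA`. The per-pair locus counts are attached as the `n_loci` attribute.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric matrix with class `fst_matrix`.
#' @export
fst_matrix <- function(gm) {
  sites <- sort(unique(gm$pop))
  if (length(sites) < 2L) stop("F_ST needs at least 2 sites")
  k <- length(sites)
  theta <- matrix(0, k, k, dimnames = list(sites, sites))
  nl <- matrix(0L, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      fit <- wc_fst_pair(gm, sites[i], sites[j])
      theta[i, j] <- theta[j, i] <- fit$theta
      nl[i, j] <- nl[j, i] <- fit$n_loci
    }
  }
  attr(theta, "n_loci") <- nl
  class(theta) <- c("fst_matrix", class(theta))
  theta
}

#' Region-level mean F_ST table
#'
#' Arithmetic mean of pairwise theta over all site pairs spanning each
#' unordered region pair; within-region entries average the pairs of
#' sites inside one region and are flagged by `within`. Missing pairwise
#' values are excluded from the means with the pair counts reported.
#' Regions with no mapped site are dropped with a warning.
#'
#' @param fst An [fst_matrix()] (or any symmetric named matrix of
#'   pairwise values).
#' @param region_of Named character vector, site label -> region label;
#'   defaults to the map stored in the genotype matrix used to build
#'   `fst` if supplied there.
#' @return Data frame `region_a, region_b, mean_fst, n_pairs, within`.
#' @export
region_mean_fst <- function(fst, region_of) {
  sites <- rownames(fst)
  unmapped <- setdiff(sites, names(region_of))
  if (length(unmapped) > 0L) {
    stop("site(s) without a region: ", paste(unmapped, collapse = ", "))
  }
  reg <- unname(region_of[sites])
  regions <- sort(unique(unname(region_of)))
  empty <- setdiff(regions, reg)
  if (length(empty) > 0L) {
    warning("region(s) with no site excluded: ", paste(empty, collapse = ", "))
    regions <- setdiff(regions, empty)
  }
  rows <- list()
  for (i in seq_along(regions)) {
    for (j in seq(i, length(regions))) {
      ra <- regions[i]; rb <- regions[j]
      sa <- which(reg == ra); sb <- which(reg == rb)
      if (ra == rb) {
        if (length(sa) < 2L) next
        pairs <- utils::combn(sa, 2)
        vals <- fst[t(pairs)]
      } else {
        vals <- as.vector(fst[sa, sb, drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_a = ra, region_b = rb,
        mean_fst = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
        n_pairs = sum(!is.na(vals)),
        within = ra == rb,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
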