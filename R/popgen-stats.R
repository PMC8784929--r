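# Per-population per-locus summaries: genotyped diploids, alternate-allele
# frequency, observed heterozygote frequency. Missing calls are excluded
# locus-wise (pairwise deletion); no imputation anywhere.
pop_locus_summary <- function(gm, pop) {
  m <- gm$calls[gm$pop == pop, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown or empty population: ", pop)
  n <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  het <- colSums(m == 1L, na.rm = TRUE)
  p <- ifelse(n > 0L, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0L, het / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Alternate-allele frequencies for one population
#'
#' Per-locus alternate-allele frequency `p_alt = alt copies / (2 n)` with
#' missing calls excluded from numerator and denominator. Loci with no
#' genotyped individual in the population are flagged `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param pop Site label.
#' @return Data frame `locus, p_alt, n_genotyped`.
#' @export
allele_freq <- function(gm, pop) {
  s <- pop_locus_summary(gm, pop)
  data.frame(locus = colnames(gm$calls), p_alt = unname(s$p),
             n_genotyped = unname(s$n), stringsAsFactors = FALSE)
}

#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygous calls among genotyped individuals,
#' and the multilocus mean over loci with data (loci weighted equally).
#'
#' @inheritParams allele_freq
#' @return List with `per_locus` (named numeric) and `mean`.
#' @export
observed_het <- function(gm, pop) {
  s <- pop_locus_summary(gm, pop)
  list(per_locus = s$h, mean = mean(s$h, na.rm = TRUE))
}

#' Expected heterozygosity (gene diversity)
#'
#' Per-locus gene diversity `2 p (1 - p)`; with `unbiased = TRUE` (the
#' default) the Nei (1978) small-sample correction `2n / (2n - 1)` is
#' applied, where `n` is the number of genotyped diploids at the locus.
#' The multilocus value is the equal-weight mean over loci with data.
#'
#' @inheritParams allele_freq
#' @param unbiased Apply the small-sample correction (default `TRUE`).
#' @return List with `per_locus` and `mean`.
#' @export
expected_het <- function(gm, pop, unbiased = TRUE) {
  s <- pop_locus_summary(gm, pop)
  he <- 2 * s$p * (1 - s$p)
  if (unbiased) {
    corr <- ifelse(s$n > 0L, 2 * s$n / pmax(2 * s$n - 1, 1), NA_real_)
    he <- he * corr
  }
  list(per_locus = he, mean = mean(he, na.rm = TRUE))
}

#' Multilocus inbreeding coefficient
#'
#' `F_IS = 1 - sum(H_O) / sum(H_E)` with sums over loci (ratio of sums,
#' consistent with the multilocus F_ST convention). Undefined — returned
#' as `NA`, never 0 — when the population is monomorphic at every locus.
#' Per-locus values are attached as the `per_locus` attribute.
#'
#' @inheritParams expected_het
#' @return Numeric scalar (or `NA`).
#' @export
f_is <- function(gm, pop, unbiased = TRUE) {
  ho <- observed_het(gm, pop)$per_locus
  he <- expected_het(gm, pop, unbiased = unbiased)$per_locus
  ok <- !is.na(ho) & !is.na(he)
  if (!any(ok) || sum(he[ok]) == 0) {
    fis <- NA_real_
  } else {
    fis <- 1 - sum(ho[ok]) / sum(he[ok])
  }
  per_locus <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  attr(fis, "per_locus") <- per_locus
  fis
}

#' Private-allele counts per group
#'
#' An allele (REF or ALT at a locus) is private to a group when it is
#' observed there (at least `min_count` copies) and in no other group.
#' Groups are sampling sites by default, or regions via the site -> region
#' map of the genotype matrix.
#'
#' @inheritParams allele_freq
#' @param grouping `"site"` or `"region"`.
#' @param min_count Minimum copy number for an allele to count as present
#'   (default 1: presence/absence).
#' @return Named integer vector of private-allele counts per group.
#' @export
private_alleles <- function(gm, grouping = c("site", "region"), min_count = 1) {
  grouping <- match.arg(grouping)
  group <- if (grouping == "site") gm$pop else {
    if (is.null(gm$region_of)) stop("genotype matrix has no site -> region map")
    unname(gm$region_of[gm$pop])
  }
  groups <- sort(unique(group))
  if (length(groups) < 2L) stop("private alleles need at least 2 groups")
  alt <- rowsum(ifelse(is.na(gm$calls), 0L, gm$calls), group)
  tot <- rowsum((!is.na(gm$calls)) * 2L, group)
  ref <- tot - alt
  alt_present <- alt >= min_count
  ref_present <- ref >= min_count
  private_in <- function(pres) {
    one_group <- colSums(pres) == 1L
    rowSums(pres[, one_group, drop = FALSE])
  }
  out <- private_in(alt_present) + private_in(ref_present)
  stats::setNames(as.integer(out[groups]), groups)
}

#' Per-site diversity summary table
#'
#' One row per sampling site: mean number of genotyped diploids per locus,
#' multilocus observed and expected heterozygosity, multilocus F_IS, and
#' the private-allele count (site grouping).
#'
#' @inheritParams expected_het
#' @return Data frame `site, n_mean, H_O, H_E, F_IS, n_private`.
#' @export
pop_stats <- function(gm, unbiased = TRUE) {
  sites <- sort(unique(gm$pop))
  priv <- if (length(sites) >= 2L) private_alleles(gm, "site") else
    stats::setNames(rep(NA_integer_, length(sites)), sites)
  rows <- lapply(sites, function(s) {
    sm <- pop_locus_summary(gm, s)
    data.frame(site = s,
               n_mean = mean(sm$n),
               H_O = observed_het(gm, s)$mean,
               H_E = expected_het(gm, s, unbiased = unbiased)$mean,
               F_IS = as.numeric(f_is(gm, s, unbiased = unbiased)),
               n_private = unname(priv[s]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
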