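gm_from <- function(..., pop) {
  calls <- rbind(...)
  genotype_matrix(calls, pop)
}

test_that("allele frequencies exclude missing calls", {
  gm <- genotype_matrix(matrix(c(0, 1, 2,
                                 0, 0, NA,
                                 2, 2, 2), nrow = 3, byrow = FALSE),
                        pop = rep("p1", 3))
  af <- allele_freq(gm, "p1")
  expect_equal(af$p_alt, c(0.5, 0, 1))  # {0,1,2}, {0,0,NA}, {2,2,2}
  expect_equal(af$n_genotyped, c(3L, 2L, 3L))
})

test_that("observed heterozygosity is the heterozygote fraction", {
  gm <- genotype_matrix(cbind(c(1, 1, 1, 1), c(0, 2, 0, 2), c(0, 1, 1, 2)),
                        pop = rep("p1", 4))
  ho <- observed_het(gm, "p1")
  expect_equal(unname(ho$per_locus), c(1, 0, 0.5))
  expect_equal(ho$mean, 0.5)
})

test_that("expected heterozygosity honours the small-sample correction", {
  # 10 diploids at p = 0.5: plain 0.5, unbiased 0.5 * 20/19
  gm <- genotype_matrix(matrix(c(rep(0, 5), rep(2, 5)), ncol = 1),
                        pop = rep("p1", 10))
  expect_equal(unname(expected_het(gm, "p1", unbiased = FALSE)$per_locus), 0.5)
  expect_equal(unname(expected_het(gm, "p1", unbiased = TRUE)$per_locus),
               0.5 * 20 / 19)
  # monomorphic locus is 0 under both conventions
  mono <- genotype_matrix(matrix(0L, nrow = 4, ncol = 1), pop = rep("p1", 4))
  expect_equal(unname(expected_het(mono, "p1", TRUE)$per_locus), 0)
  expect_equal(unname(expected_het(mono, "p1", FALSE)$per_locus), 0)
})

test_that("statistics are invariant to REF/ALT label swaps", {
  gm <- random_gm(3, 30, 12, missing_rate = 0.15, seed = 99)
  swapped <- gm
  flip <- seq(1, 30, by = 2)
  swapped$calls[, flip] <- 2L - swapped$calls[, flip]
  for (p in unique(gm$pop)) {
    expect_equal(observed_het(gm, p), observed_het(swapped, p))
    expect_equal(expected_het(gm, p), expected_het(swapped, p))
    expect_equal(f_is(gm, p), f_is(swapped, p))
  }
  expect_equal(private_alleles(gm, "site"), private_alleles(swapped, "site"))
  expect_equal(fst_matrix(gm), fst_matrix(swapped))
})

test_that("F_IS is the ratio-of-sums across loci", {
  # locus 1: 10 diploids, p = 0.5, 2 heterozygotes  -> H_O 0.2, plain H_E 0.5
  # locus 2: 10 diploids, p = 0.5, 4 heterozygotes  -> H_O 0.4, plain H_E 0.5
  l1 <- c(rep(0, 4), rep(1, 2), rep(2, 4))
  l2 <- c(rep(0, 3), rep(1, 4), rep(2, 3))
  gm <- genotype_matrix(cbind(l1, l2), pop = rep("p1", 10))
  expect_equal(as.numeric(f_is(gm, "p1", unbiased = FALSE)), 1 - 0.6 / 1.0)
})

test_that("F_IS hits its boundary cases", {
  # all homozygotes at a polymorphic locus: F_IS = 1
  gm1 <- genotype_matrix(matrix(c(0, 0, 2, 2), ncol = 1), pop = rep("p1", 4))
  expect_equal(as.numeric(f_is(gm1, "p1")), 1)
  # H_O = H_E at every locus: F_IS = 0 (plain convention)
  gm0 <- genotype_matrix(matrix(c(1, 1, 0, 2), ncol = 1), pop = rep("p1", 4))
  expect_equal(as.numeric(f_is(gm0, "p1", unbiased = FALSE)), 0)
  # monomorphic population: undefined, not zero
  mono <- genotype_matrix(matrix(2L, nrow = 4, ncol = 3), pop = rep("p1", 4))
  expect_true(is.na(f_is(mono, "p1")))
})

test_that("private alleles follow the presence table", {
  # locus 1: ALT only in p1; locus 2: ALT in both; locus 3: fixed difference
  calls <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 1), c(2, 2, 0, 0))
  gm <- genotype_matrix(calls, pop = c("p1", "p1", "p2", "p2"))
  priv <- private_alleles(gm, "site")
  # p1: private ALT at locus 1 + private ALT at locus 3
  # p2: private REF at locus 3
  expect_equal(priv, c(p1 = 2L, p2 = 1L))
  expect_error(private_alleles(genotype_matrix(calls, rep("p1", 4)), "site"),
               "2 groups")
})

test_that("private alleles match the enumeration oracle and honour grouping", {
  gm <- random_gm(4, 40, 8, missing_rate = 0.2, seed = 13)
  expect_equal(private_alleles(gm, "site"),
               oracle_private(gm$calls, gm$pop))
  expect_equal(private_alleles(gm, "site", min_count = 3),
               oracle_private(gm$calls, gm$pop, min_count = 3))
  gm$region_of <- c(p01 = "native", p02 = "native",
                    p03 = "introduced", p04 = "introduced")
  reg <- private_alleles(gm, "region")
  expect_equal(reg, oracle_private(gm$calls, unname(gm$region_of[gm$pop])))
})

test_that("diversity statistics match brute-force oracles", {
  for (seed in 1:5) {
    gm <- random_gm(n_pops = 3, n_loci = 25, n_per_pop = 10,
                    missing_rate = 0.15, seed = seed)
    for (p in unique(gm$pop)) {
      m <- gm$calls[gm$pop == p, , drop = FALSE]
      orc <- oracle_pop_stats(m, unbiased = TRUE)
      expect_equal(observed_het(gm, p)$mean, orc$ho_mean, tolerance = 1e-10)
      expect_equal(expected_het(gm, p)$mean, orc$he_mean, tolerance = 1e-10)
      expect_equal(as.numeric(f_is(gm, p)), orc$fis, tolerance = 1e-10)
    }
  }
})

test_that("fully missing added samples change no statistic", {
  gm <- random_gm(2, 20, 8, missing_rate = 0.1, seed = 3)
  before <- pop_stats(gm)
  aug <- rbind(gm$calls,
               matrix(NA_integer_, nrow = 4, ncol = ncol(gm$calls),
                      dimnames = list(sprintf("ghost%d", 1:4), NULL)))
  gm2 <- genotype_matrix(aug, c(gm$pop, c("p01", "p01", "p02", "p02")))
  after <- pop_stats(gm2)
  expect_equal(after[c("H_O", "H_E", "F_IS", "n_private")],
               before[c("H_O", "H_E", "F_IS", "n_private")])
  expect_equal(fst_matrix(gm2), fst_matrix(gm))
})

test_that("pop_stats respects its documented bounds", {
  gm <- random_gm(4, 30, 10, missing_rate = 0.2, seed = 21)
  st <- pop_stats(gm)
  expect_true(all(st$H_O >= 0 & st$H_O <= 1))
  expect_true(all(st$H_E >= 0 & st$H_E <= 0.6))
  expect_true(all(st$F_IS >= -1 & st$F_IS <= 1, na.rm = TRUE))
  expect_true(all(st$n_private >= 0))
})

test_that("VCF/popmap round-trip preserves calls and labels", {
  sim <- simulate_genotypes(scenario_spec(seed = 17, n_loci = 40,
                                          pop_size = 6, n_pops = 3))
  vcf <- tempfile(fileext = ".vcf")
  popmap <- tempfile(fileext = ".tsv")
  write_vcf(sim$gm, vcf)
  write_popmap(sim$gm, popmap)
  back <- read_genotypes(vcf, popmap)
  expect_equal(back$calls, sim$gm$calls)
  expect_equal(back$pop, sim$gm$pop)
})

test_that("non-biallelic loci are dropped and unmapped samples error", {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "sA", "sB"), collapse = "\t"),
             paste(c("1", "1", "snp1", "A", "T", ".", "PASS", ".", "GT",
                     "0/0", "0/1"), collapse = "\t"),
             paste(c("1", "2", "snp2", "A", "T,G", ".", "PASS", ".", "GT",
                     "0/1", "1/2"), collapse = "\t"))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(lines, vcf)
  popmap <- tempfile(fileext = ".tsv")
  writeLines(c("sA\tp1", "sB\tp2"), popmap)
  expect_message(gm <- read_genotypes(vcf, popmap), "non-biallelic")
  expect_equal(colnames(gm$calls), "snp1")

  writeLines("sA\tp1", popmap)
  expect_error(read_genotypes(vcf, popmap), "sB")
})
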