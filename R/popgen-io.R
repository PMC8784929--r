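#' Construct a genotype matrix object
#'
#' Container for diploid biallelic SNP calls with population (sampling
#' site) labels and an optional site -> region map. Calls count copies of
#' the alternate allele (0, 1, 2) with `NA` for missing genotypes.
#'
#' @param calls Integer matrix, samples (rows) x loci (columns), values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names locus ids.
#' @param pop Character vector of site labels, one per sample.
#' @param region_of Optional named character vector mapping site label to
#'   region label.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, pop, region_of = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(length(pop) == nrow(calls),
            all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  }
  pop <- as.character(pop)
  if (!is.null(region_of)) {
    missing_sites <- setdiff(unique(pop), names(region_of))
    if (length(missing_sites) > 0L) {
      stop("site(s) without a region: ", paste(missing_sites, collapse = ", "))
    }
  }
  structure(list(calls = calls, pop = pop, region_of = region_of),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "sample(s) x", ncol(x$calls),
      "biallelic SNP locus/loci;", length(unique(x$pop)), "site(s)\n")
  print(table(site = x$pop))
  invisible(x)
}

#' Read diploid biallelic genotypes from VCF with a population map
#'
#' Parses GT fields from a VCF (other fields are ignored), drops
#' non-biallelic and all-missing loci with counts logged, and attaches
#' site labels (and optional regions) from a headerless popmap TSV with
#' columns `sample`, `site` and optionally `region`. Every sample in the
#' VCF must appear in the popmap.
#'
#' @param vcf_path Path to a VCF file (plain or gzipped).
#' @param popmap_path Path to the popmap TSV.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  popmap <- utils::read.table(popmap_path, sep = "\t", header = FALSE,
                              colClasses = "character", strip.white = TRUE)
  if (ncol(popmap) < 2L) stop("popmap must have columns sample<TAB>site[<TAB>region]")
  names(popmap)[1:2] <- c("sample", "site")
  region_of <- NULL
  if (ncol(popmap) >= 3L) {
    names(popmap)[3] <- "region"
    site_region <- unique(popmap[c("site", "region")])
    if (anyDuplicated(site_region$site)) {
      stop("popmap assigns a site to more than one region")
    }
    region_of <- stats::setNames(site_region$region, site_region$site)
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("no variant records in ", vcf_path)
  biallelic <- vcfR::is.biallelic(vcf)
  n_dropped_multi <- sum(!biallelic)
  vcf <- vcf[biallelic, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")

  # GT strings -> alternate-allele dosage; anything with a missing allele
  # is a missing call
  dose <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  gts <- t(gt)  # samples x loci
  calls <- matrix(dose(gts), nrow = nrow(gts), ncol = ncol(gts),
                  dimnames = dimnames(gts))

  all_missing <- colSums(!is.na(calls)) == 0L
  n_dropped_missing <- sum(all_missing)
  calls <- calls[, !all_missing, drop = FALSE]
  if (n_dropped_multi > 0L || n_dropped_missing > 0L) {
    message("dropped ", n_dropped_multi, " non-biallelic and ",
            n_dropped_missing, " all-missing locus/loci")
  }
  if (ncol(calls) == 0L) stop("no usable biallelic loci left")

  unmapped <- setdiff(rownames(calls), popmap$sample)
  if (length(unmapped) > 0L) {
    stop("sample(s) missing from popmap: ", paste(unmapped, collapse = ", "))
  }
  extra <- setdiff(popmap$sample, rownames(calls))
  if (length(extra) > 0L) {
    warning(length(extra), " popmap sample(s) absent from the VCF ignored")
  }
  pop <- popmap$site[match(rownames(calls), popmap$sample)]
  genotype_matrix(calls, pop, region_of)
}
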