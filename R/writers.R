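#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file carrying only GT fields (placeholder chromosome,
#' positions and REF/ALT alleles), which is all the downstream statistics
#' consume. Missing calls become `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  calls <- gm$calls
  gt <- matrix("./.", nrow = nrow(calls), ncol = ncol(calls))
  gt[!is.na(calls) & calls == 0L] <- "0/0"
  gt[!is.na(calls) & calls == 1L] <- "0/1"
  gt[!is.na(calls) & calls == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  body <- vapply(seq_len(ncol(calls)), function(j) {
    paste(c("1", j, colnames(calls)[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a popmap TSV
#'
#' Headerless `sample<TAB>site[<TAB>region]` table matching the contract
#' of [read_genotypes()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(gm, path) {
  df <- data.frame(sample = rownames(gm$calls), site = gm$pop,
                   stringsAsFactors = FALSE)
  if (!is.null(gm$region_of)) {
    df$region <- unname(gm$region_of[gm$pop])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a shipping tensor as a long-format CSV
#'
#' One row per (period, origin region, destination region) cell, zeros
#' included, so [read_tensor()] reproduces the tensor exactly.
#'
#' @param tensor A `shipping_tensor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "shipping_tensor"))
  grid <- expand.grid(period = seq_len(nrow(tensor$periods)),
                      origin = tensor$regions, dest = tensor$regions,
                      stringsAsFactors = FALSE)
  df <- data.frame(
    period_start = tensor$periods$start_year[grid$period],
    period_end = tensor$periods$end_year[grid$period],
    origin_region = grid$origin,
    dest_region = grid$dest,
    count = tensor$counts[cbind(grid$period,
                                match(grid$origin, tensor$regions),
                                match(grid$dest, tensor$regions))],
    stringsAsFactors = FALSE)
  df <- df[order(df$period_start, df$origin_region, df$dest_region), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format shipping tensor CSV
#'
#' Inverse of [write_tensor()].
#'
#' @param path Path to a `period_start,period_end,origin_region,
#'   dest_region,count` CSV.
#' @return A `shipping_tensor`.
#' @export
read_tensor <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("period_start", "period_end", "origin_region", "dest_region",
            "count")
  if (!all(need %in% names(df))) {
    stop("tensor CSV must have header ", paste(need, collapse = ","))
  }
  periods <- unique(df[c("period_start", "period_end")])
  periods <- periods[order(periods$period_start), , drop = FALSE]
  names(periods) <- c("start_year", "end_year")
  rownames(periods) <- NULL
  periods <- check_periods(periods)
  regions <- sort(unique(c(df$origin_region, df$dest_region)))
  counts <- array(0L, dim = c(nrow(periods), length(regions), length(regions)),
                  dimnames = list(period = period_labels(periods),
                                  origin = regions, dest = regions))
  counts[cbind(match(df$period_start, periods$start_year),
               match(df$origin_region, regions),
               match(df$dest_region, regions))] <- as.integer(df$count)
  structure(list(counts = counts, periods = periods, regions = regions,
                 n_unbinned = 0L),
            class = "shipping_tensor")
}

#' Write all files of a simulated scenario
#'
#' Serializes a scenario so every pipeline stage can be driven from disk:
#' positions and ports CSVs, genotypes VCF, popmap TSV, shipping-tensor
#' CSV (coupled scenarios), planted truth tables, and a metadata sidecar
#' recording the seed.
#'
#' @param sim Result of [simulate_trajectories()], [simulate_genotypes()]
#'   or [simulate_coupled()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the metadata sidecar.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(sim$positions)) {
    utils::write.csv(sim$positions, p("positions.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(sim$ports)) {
    utils::write.csv(sim$ports, p("ports.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(sim$gm)) {
    write_vcf(sim$gm, p("genotypes.vcf"))
    write_popmap(sim$gm, p("popmap.tsv"))
  }
  if (!is.null(sim$tensor)) write_tensor(sim$tensor, p("tensor.csv"))
  if (!is.null(sim$truth$calls)) {
    utils::write.table(sim$truth$calls, p("truth_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$truth$events)) {
    utils::write.table(sim$truth$events, p("truth_events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(c(paste0("seed\t", seed),
               paste0("generated\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             p("metadata.tsv"))
  invisible(dir)
}
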