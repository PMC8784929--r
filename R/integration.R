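#' Shipping intensity per unordered region pair
#'
#' Aggregates a shipping tensor over the periods covered by a year window.
#' With `symmetrize = TRUE` (the default) the two directed counts of a
#' pair are added — F_ST is unordered, so the genetic side cannot resolve
#' direction — and with `average = TRUE` the per-period pair totals are
#' averaged over the periods in the window ("average shipping intensity");
#' `average = FALSE` returns the raw total instead. Self-pairs are
#' excluded.
#'
#' @param tensor A `shipping_tensor` from [bin_events()].
#' @param window Length-2 numeric, first and last year of the aggregation
#'   window (default `c(1750, 2000)`); must be covered by the tensor's
#'   periods.
#' @param symmetrize Add the two directions of each pair (default `TRUE`);
#'   `FALSE` emits directed pairs separately.
#' @param average Mean over periods (default `TRUE`) or raw total.
#' @return Data frame `region_a, region_b, intensity` (directed columns
#'   `origin, dest` when `symmetrize = FALSE`).
#' @export
pair_shipping_intensity <- function(tensor, window = c(1750, 2000),
                                    symmetrize = TRUE, average = TRUE) {
  stopifnot(inherits(tensor, "shipping_tensor"), length(window) == 2L)
  in_window <- tensor$periods$start_year >= window[1] &
    tensor$periods$end_year <= window[2]
  if (!any(in_window)) stop("window covers no tensor period")
  counts <- tensor$counts[in_window, , , drop = FALSE]
  agg <- apply(counts, c(2, 3), if (average) mean else sum)
  regions <- tensor$regions
  if (!symmetrize) {
    idx <- which(row(agg) != col(agg), arr.ind = TRUE)
    out <- data.frame(origin = regions[idx[, 1]], dest = regions[idx[, 2]],
                      intensity = agg[idx], stringsAsFactors = FALSE)
    out <- out[order(out$origin, out$dest), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  sym <- agg + t(agg)
  idx <- which(upper.tri(sym), arr.ind = TRUE)
  out <- data.frame(region_a = regions[idx[, 1]], region_b = regions[idx[, 2]],
                    intensity = sym[idx], stringsAsFactors = FALSE)
  out <- out[order(out$region_a, out$region_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors (average ranks for ties), takes the Pearson
#' correlation of the ranks, and computes the two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom — appropriate here
#' because the number of region pairs is small. A constant input vector
#' has no defined rank correlation and yields `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Pair region-level shipping intensity with region-mean F_ST
#'
#' Joins the unordered region-pair intensity table with the between-region
#' rows of a region-mean F_ST table. Pairs with missing F_ST are dropped
#' with a message.
#'
#' @param intensity Data frame from [pair_shipping_intensity()]
#'   (symmetrized).
#' @param region_fst Data frame from [region_mean_fst()].
#' @return Data frame `region_a, region_b, intensity, mean_fst`.
#' @export
pair_shipping_fst <- function(intensity, region_fst) {
  fst <- region_fst[!region_fst$within, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  fst_of <- stats::setNames(fst$mean_fst, key(fst$region_a, fst$region_b))
  paired <- intensity
  paired$mean_fst <- unname(fst_of[key(paired$region_a, paired$region_b)])
  drop <- is.na(paired$mean_fst)
  if (any(drop)) {
    message(sum(drop), " region pair(s) without an F_ST value dropped")
    paired <- paired[!drop, , drop = FALSE]
  }
  rownames(paired) <- NULL
  paired
}

#' Correlate shipping intensity with genetic differentiation
#'
#' Spearman rank correlation between per-pair shipping intensity and
#' region-mean F_ST. The p-value comes from the t-approximation by
#' default; `method = "permutation"` computes a seeded two-sided
#' permutation p instead, which is preferable at the very small n of
#' region-pair designs.
#'
#' @param paired Data frame from [pair_shipping_fst()].
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation method.
#' @param window Year window annotation carried into the result.
#' @return List with `rho`, `p_value`, `n`, `window`, `method` and the
#'   `paired` table used (for plotting and audit).
#' @export
correlate_shipping_fst <- function(paired, method = c("t", "permutation"),
                                   n_perm = 9999, seed = 1,
                                   window = c(1750, 2000)) {
  method <- match.arg(method)
  if (nrow(paired) < 3L) stop("need at least 3 complete region pairs")
  res <- spearman_cor(paired$intensity, paired$mean_fst)
  if (method == "permutation" && !is.na(res$rho)) {
    set.seed(seed)
    perm <- replicate(n_perm, {
      spearman_cor(paired$intensity, sample(paired$mean_fst))$rho
    })
    res$p_value <- (1 + sum(abs(perm) >= abs(res$rho) - 1e-12)) / (n_perm + 1)
  }
  list(rho = res$rho, p_value = res$p_value, n = res$n,
       window = window, method = method, paired = paired)
}
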