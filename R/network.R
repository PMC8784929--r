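#' Default 50-year analysis periods, 1750-2000
#'
#' Five inclusive intervals: 1750-1800, 1801-1850, 1851-1900, 1901-1950,
#' 1951-2000. Both endpoint years belong to the interval.
#'
#' @return Data frame with columns `start_year`, `end_year`.
#' @export
default_periods <- function() {
  data.frame(start_year = c(1750L, 1801L, 1851L, 1901L, 1951L),
             end_year = c(1800L, 1850L, 1900L, 1950L, 2000L))
}

period_labels <- function(periods) {
  paste0(periods$start_year, "-", periods$end_year)
}

check_periods <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("start_year", "end_year") %in% names(periods)),
            all(periods$start_year <= periods$end_year))
  periods <- periods[order(periods$start_year), , drop = FALSE]
  if (nrow(periods) > 1L &&
      any(periods$start_year[-1] <= periods$end_year[-nrow(periods)])) {
    stop("periods overlap")
  }
  periods
}

# index of the period containing each year (NA when outside all periods)
period_index <- function(years, periods) {
  idx <- rep(NA_integer_, length(years))
  for (k in seq_len(nrow(periods))) {
    idx[years >= periods$start_year[k] & years <= periods$end_year[k]] <- k
  }
  idx
}

#' Bin travel events into a period x region x region shipping tensor
#'
#' Counts directed travel events per (period, origin region, destination
#' region) cell, assigning each event to the period containing its arrival
#' date. Within-region cells (origin = destination) are kept: within-region
#' shipping is part of the reconstruction. Events dated outside every
#' period are tallied separately, never silently dropped.
#'
#' @param events Data frame from [extract_travel_events()].
#' @param periods Data frame of inclusive `start_year`/`end_year`
#'   intervals; default [default_periods()].
#' @param regions Optional character vector fixing the region axis (e.g.
#'   all regions of the port index); defaults to the regions present in
#'   `events`.
#' @return An object of class `shipping_tensor`: a list with `counts`
#'   (3-d integer array period x origin x dest), `periods`, `regions` and
#'   `n_unbinned`.
#' @export
bin_events <- function(events, periods = default_periods(), regions = NULL) {
  periods <- check_periods(periods)
  if (is.null(regions)) {
    regions <- sort(unique(c(events$origin_region, events$dest_region)))
  }
  labels <- period_labels(periods)
  counts <- array(0L, dim = c(nrow(periods), length(regions), length(regions)),
                  dimnames = list(period = labels, origin = regions,
                                  dest = regions))
  idx <- period_index(as.integer(format(events$arrive_date, "%Y")), periods)
  binned <- !is.na(idx)
  if (any(binned)) {
    tab <- table(factor(labels[idx[binned]], levels = labels),
                 factor(events$origin_region[binned], levels = regions),
                 factor(events$dest_region[binned], levels = regions))
    counts[] <- as.integer(tab)
  }
  n_unbinned <- sum(!binned)
  if (n_unbinned > 0L) {
    message(n_unbinned, " event(s) dated outside all periods left unbinned")
  }
  structure(list(counts = counts, periods = periods, regions = regions,
                 n_unbinned = n_unbinned),
            class = "shipping_tensor")
}

#' @export
print.shipping_tensor <- function(x, ...) {
  cat("Shipping tensor:", nrow(x$periods), "period(s) x",
      length(x$regions), "region(s);",
      sum(x$counts), "travel event(s) binned,",
      x$n_unbinned, "unbinned\n")
  per <- apply(x$counts, 1, sum)
  print(data.frame(period = names(per), events = as.integer(per),
                   row.names = NULL))
  invisible(x)
}

#' Port-visit series per period and region
#'
#' Each port call contributes one visit to its port's region in the period
#' containing its arrival date. Visits count calls, not distinct ships: a
#' ship calling twice in one period is two visits.
#'
#' @param calls Data frame from [detect_port_calls()].
#' @param periods Period table as for [bin_events()].
#' @param ports Data frame from [read_ports()] (supplies port -> region).
#' @return Integer matrix, periods (rows) x regions (columns).
#' @export
port_visit_series <- function(calls, periods = default_periods(), ports) {
  periods <- check_periods(periods)
  region_of <- stats::setNames(ports$region, ports$port_id)
  regions <- sort(unique(ports$region))
  labels <- period_labels(periods)
  idx <- period_index(as.integer(format(calls$arrival_date, "%Y")), periods)
  keep <- !is.na(idx)
  tab <- table(factor(labels[idx[keep]], levels = labels),
               factor(unname(region_of[calls$port_id[keep]]), levels = regions))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(period = labels, region = regions))
  m
}

#' Sensitivity of the reconstruction to the port-call distance threshold
#'
#' Re-runs port-call detection and travel-event extraction at each
#' threshold and tabulates the resulting counts. Call counts are
#' non-decreasing in the threshold (a position within 5 km is within
#' 10 km); event counts are reported as computed from each call set.
#'
#' @param positions,ports As for [detect_port_calls()].
#' @param thresholds_km Thresholds in km; default `c(5, 10, 20, 50)`, which
#'   includes the 10 km primary analysis as one row.
#' @param gap_days Voyage-segmentation gap, passed through.
#' @return Data frame `threshold_km, n_calls, n_events`.
#' @export
threshold_sensitivity <- function(positions, ports,
                                  thresholds_km = c(5, 10, 20, 50),
                                  gap_days = 30) {
  stopifnot(all(thresholds_km > 0))
  if (anyDuplicated(thresholds_km)) {
    warning("duplicate thresholds dropped")
    thresholds_km <- unique(thresholds_km)
  }
  thresholds_km <- sort(thresholds_km)
  rows <- lapply(thresholds_km, function(th) {
    calls <- detect_port_calls(positions, ports, threshold_km = th,
                               gap_days = gap_days)
    events <- extract_travel_events(calls, ports)
    data.frame(threshold_km = th, n_calls = nrow(calls),
               n_events = nrow(events))
  })
  do.call(rbind, rows)
}

#' Export one period slice of a shipping tensor as a chord-diagram table
#'
#' Long-format `origin,dest,count` table with one row per ordered region
#' pair with a positive count — the input contract of circular flow plots.
#' Re-importing the table reproduces the tensor slice exactly.
#'
#' @param tensor A `shipping_tensor` from [bin_events()].
#' @param period Period label (e.g. `"1750-1800"`) or index.
#' @param path Optional path; when given the table is also written as CSV.
#' @return Data frame `origin, dest, count` (invisibly when written).
#' @export
export_chord_table <- function(tensor, period, path = NULL) {
  stopifnot(inherits(tensor, "shipping_tensor"))
  labels <- period_labels(tensor$periods)
  k <- if (is.numeric(period)) as.integer(period) else match(period, labels)
  if (is.na(k) || k < 1L || k > length(labels)) {
    stop("unknown period: ", period)
  }
  slice <- tensor$counts[k, , , drop = FALSE]
  dim(slice) <- dim(tensor$counts)[2:3]
  idx <- which(slice > 0L, arr.ind = TRUE)
  tab <- data.frame(origin = tensor$regions[idx[, 1]],
                    dest = tensor$regions[idx[, 2]],
                    count = as.integer(slice[idx]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$origin, tab$dest), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
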