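#' Infer port calls from daily ship positions
#'
#' A position is assigned to its nearest indexed port; when that distance
#' is at most `threshold_km` the position opens (or extends) a port call.
#' Consecutive in-threshold positions at the same port extend one call; a
#' second call at the same port requires at least one intervening position
#' outside the threshold or a call at a different port. The arrival date
#' of a call is the first in-threshold date, the date the approach becomes
#' observable in a once-daily record.
#'
#' A gap of more than `gap_days` days between consecutive fixes of one
#' ship splits its record into separate voyages (ship identifiers recur
#' across unrelated cruises in the source archives); travel events never
#' span such a split.
#'
#' When two ports tie exactly on distance the lexicographically smallest
#' `port_id` wins, so the output is deterministic.
#'
#' @param positions Data frame from [read_positions()].
#' @param ports Data frame from [read_ports()].
#' @param threshold_km Port-call distance threshold in km (default 10, the
#'   primary analysis value; vary it with [threshold_sensitivity()]).
#' @param gap_days Voyage-segmentation gap in days (default 30).
#' @return Data frame `ship_id, voyage, port_id, arrival_date,
#'   distance_km`, ordered by ship, voyage and arrival date.
#' @export
detect_port_calls <- function(positions, ports, threshold_km = 10,
                              gap_days = 30) {
  if (nrow(ports) == 0L) stop("port index is empty")
  stopifnot(threshold_km > 0, gap_days > 0)
  if (nrow(positions) == 0L) {
    return(data.frame(ship_id = character(), voyage = integer(),
                      port_id = character(), arrival_date = as.Date(character()),
                      distance_km = numeric(), stringsAsFactors = FALSE))
  }
  ports <- ports[order(ports$port_id), , drop = FALSE]
  positions <- positions[order(positions$ship_id, positions$date), , drop = FALSE]

  # nearest port per position; ports are id-sorted so "first" breaks ties
  # toward the lexicographically smallest port_id
  n <- nrow(positions)
  nearest <- integer(n)
  ndist <- numeric(n)
  chunk <- 20000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- outer(seq_len(e - s + 1L), seq_len(nrow(ports)), function(i, j) {
      haversine_km(positions$lat[s:e][i], positions$lon[s:e][i],
                   ports$lat[j], ports$lon[j])
    })
    nearest[s:e] <- max.col(-d, ties.method = "first")
    ndist[s:e] <- d[cbind(seq_len(e - s + 1L), nearest[s:e])]
  }

  in_call <- ndist <= threshold_km
  call_port <- ifelse(in_call, ports$port_id[nearest], NA_character_)

  # voyage index: increments at ship change or a gap > gap_days
  new_ship <- c(TRUE, positions$ship_id[-1] != positions$ship_id[-n])
  gap <- c(FALSE, as.numeric(diff(positions$date)) > gap_days) & !new_ship
  voyage_of <- cumsum(new_ship | gap)
  voyage <- stats::ave(voyage_of, positions$ship_id,
                       FUN = function(v) v - v[1] + 1L)

  # a call is a maximal run of one port within a voyage; NA runs separate
  # re-entries at the same port
  key <- paste(voyage_of, call_port, sep = "\r")
  run_start <- c(TRUE, key[-1] != key[-n]) | new_ship | gap
  starts <- which(run_start & in_call)
  data.frame(
    ship_id = positions$ship_id[starts],
    voyage = as.integer(voyage[starts]),
    port_id = call_port[starts],
    arrival_date = positions$date[starts],
    distance_km = ndist[starts],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Extract directed travel events from port calls
#'
#' Each consecutive pair of calls by one ship within one voyage yields a
#' directed origin -> destination event; the departure date is the origin
#' call's arrival date and the arrival date the destination call's. Pairs
#' sharing a port (a ship that left the threshold and returned to the same
#' port) are not movements between ports and are suppressed. Region labels
#' are joined from the port index, so within-region events (origin and
#' destination ports in the same region) are retained.
#'
#' @param calls Data frame from [detect_port_calls()].
#' @param ports Data frame from [read_ports()].
#' @return Data frame `ship_id, origin_port, dest_port, origin_region,
#'   dest_region, depart_date, arrive_date`.
#' @export
extract_travel_events <- function(calls, ports) {
  empty <- data.frame(ship_id = character(), origin_port = character(),
                      dest_port = character(), origin_region = character(),
                      dest_region = character(),
                      depart_date = as.Date(character()),
                      arrive_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  if (nrow(calls) < 2L) return(empty)
  calls <- calls[order(calls$ship_id, calls$voyage, calls$arrival_date), ,
                 drop = FALSE]
  n <- nrow(calls)
  i <- seq_len(n - 1L)
  j <- i + 1L
  same_leg <- calls$ship_id[i] == calls$ship_id[j] &
    calls$voyage[i] == calls$voyage[j]
  keep <- same_leg & calls$port_id[i] != calls$port_id[j]
  if (!any(keep)) return(empty)
  region_of <- stats::setNames(ports$region, ports$port_id)
  ev <- data.frame(
    ship_id = calls$ship_id[i][keep],
    origin_port = calls$port_id[i][keep],
    dest_port = calls$port_id[j][keep],
    stringsAsFactors = FALSE
  )
  ev$origin_region <- unname(region_of[ev$origin_port])
  ev$dest_region <- unname(region_of[ev$dest_port])
  ev$depart_date <- calls$arrival_date[i][keep]
  ev$arrive_date <- calls$arrival_date[j][keep]
  if (anyNA(ev$origin_region) || anyNA(ev$dest_region)) {
    stop("call(s) at port(s) absent from the port index")
  }
  rownames(ev) <- NULL
  ev
}
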