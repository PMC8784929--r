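#' Read daily ship positions from CSV
#'
#' Expects a header `ship_id,date,lat,lon` with ISO-8601 dates and decimal
#' degrees. Malformed rows (unparseable date, latitude outside \[-90, 90\],
#' non-numeric coordinates) are rejected with a logged reason; longitudes
#' are normalized to \[-180, 180). When a ship has two fixes on the same
#' date the first parsed row is kept, with a warning: the source archives
#' provide at most one position per ship per day.
#'
#' @param path Path to the positions CSV.
#' @return A data frame with columns `ship_id`, `date` (`Date`), `lat`,
#'   `lon`, sorted by ship then date, with attributes `n_parsed`,
#'   `n_rejected` and `rejects` (a data frame of row number and reason).
#' @export
read_positions <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("ship_id", "date", "lat", "lon") %in% names(raw))) {
    stop("positions CSV must have header ship_id,date,lat,lon")
  }
  if (nrow(raw) == 0L) stop("positions file is empty: ", path)

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(reason) & is.na(lat)] <- "non-numeric lat"
  reason[is.na(reason) & is.na(lon)] <- "non-numeric lon"
  reason[is.na(reason) & (lat < -90 | lat > 90)] <- "lat out of [-90, 90]"
  reason[is.na(reason) & (lon < -360 | lon > 360)] <- "lon out of range"

  bad <- !is.na(reason)
  rejects <- data.frame(row = which(bad), reason = reason[bad],
                        stringsAsFactors = FALSE)
  if (nrow(rejects) > 0L) {
    message(nrow(rejects), " position row(s) rejected: ",
            paste(unique(rejects$reason), collapse = "; "))
  }

  pos <- data.frame(ship_id = raw$ship_id[!bad], date = date[!bad],
                    lat = lat[!bad], lon = normalize_lon(lon[!bad]),
                    stringsAsFactors = FALSE)
  dup <- duplicated(pos[c("ship_id", "date")])
  if (any(dup)) {
    warning(sum(dup), " duplicate ship/date fix(es) collapsed to the first occurrence")
    pos <- pos[!dup, , drop = FALSE]
  }
  pos <- pos[order(pos$ship_id, pos$date), , drop = FALSE]
  rownames(pos) <- NULL
  attr(pos, "n_parsed") <- nrow(pos)
  attr(pos, "n_rejected") <- nrow(rejects)
  attr(pos, "rejects") <- rejects
  pos
}

#' Read a geocoded port index from CSV
#'
#' Expects a header `port_id,name,lat,lon,region`. Each port must have a
#' unique id and exactly one region label; longitudes are normalized to
#' \[-180, 180) with a warning when a value lies outside it.
#'
#' @param path Path to the port index CSV.
#' @return A data frame `port_id,name,lat,lon,region`, ordered by
#'   `port_id`.
#' @export
read_ports <- function(path) {
  ports <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("port_id", "name", "lat", "lon", "region")
  if (!all(need %in% names(ports))) {
    stop("ports CSV must have header port_id,name,lat,lon,region")
  }
  ports <- ports[need]
  dup <- unique(ports$port_id[duplicated(ports$port_id)])
  if (length(dup) > 0L) {
    stop("duplicate port_id(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.na(ports$region) | ports$region == "")) {
    stop("port(s) without a region label: ",
         paste(ports$port_id[is.na(ports$region) | ports$region == ""],
               collapse = ", "))
  }
  ports$lat <- as.numeric(ports$lat)
  ports$lon <- as.numeric(ports$lon)
  if (any(is.na(ports$lat)) || any(is.na(ports$lon)) ||
      any(ports$lat < -90 | ports$lat > 90)) {
    stop("port coordinates malformed or out of bounds")
  }
  out_of_dialect <- ports$lon < -180 | ports$lon >= 180
  if (any(out_of_dialect)) {
    warning(sum(out_of_dialect), " port longitude(s) normalized to [-180, 180)")
  }
  ports$lon <- normalize_lon(ports$lon)
  ports <- ports[order(ports$port_id), , drop = FALSE]
  rownames(ports) <- NULL
  ports
}
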