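# fixture builders for the shipping module (all in code, no files)

km_per_deg <- 6371.0 * pi / 180  # one degree of latitude on the sphere

# a point `km` kilometres due north of (lat, lon)
north_of <- function(lat, lon, km) c(lat = lat + km / km_per_deg, lon = lon)

make_ports <- function(lat = 0, lon = c(0, 20), ids = NULL,
                       region = "R1") {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  data.frame(port_id = ids, name = ids, lat = lat, lon = lon,
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

make_positions <- function(ship = "s1", days, lat, lon,
                           origin = as.Date("1900-01-01")) {
  data.frame(ship_id = rep_len(ship, length(days)), date = origin + days,
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}

write_positions_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
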