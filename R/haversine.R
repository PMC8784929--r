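#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. All arguments are
#' recycled to a common length, so the function works element-wise on
#' vectors of coordinates.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * R * asin(sqrt(a))
}

# normalize longitudes to [-180, 180); accepts the [0, 360) dialect too
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}
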