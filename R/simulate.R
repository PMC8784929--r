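#' Scenario specification for the synthetic-data generator
#'
#' One declarative object driving every simulator. Defaults describe the
#' study conditions the pipeline is built for: a 10 km port-call rule with
#' a 3 km detection margin and 2 km positional jitter (once-daily fixes at
#' logbook precision), six marine regions with three large ports each,
#' voyages spread over 1750-2000, and GBS-scale SNP matrices (2000 loci,
#' 30 diploids per site, 5% missing calls) diverged at F = 0.1 under the
#' Balding-Nichols drift model.
#'
#' @param seed Integer seed; every simulator is deterministic given it.
#' @param n_regions,ports_per_region Port-index geometry (ports are placed
#'   at least 300 km apart so calls are unambiguous).
#' @param n_ships Number of ships for [simulate_trajectories()].
#' @param legs_per_ship Port-to-port legs per ship itinerary.
#' @param start_year,end_year Year window over which voyages start.
#' @param threshold_km,margin_km Detection threshold and safety margin: on
#'   call days the planted position is within `threshold_km - margin_km`
#'   of the port; on transit days farther than `threshold_km + margin_km`
#'   from every port.
#' @param noise_km Positional jitter magnitude, km.
#' @param speed_km_day Cruising speed used to time legs, km/day.
#' @param n_pops,pop_size Populations and diploids per population for
#'   [simulate_genotypes()].
#' @param n_loci Biallelic SNP loci.
#' @param F Balding-Nichols divergence parameter, `0 <= F < 1`.
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param S Optional symmetric non-negative integer shipping matrix for
#'   [simulate_coupled()] (`NULL`: drawn from the spec's seed).
#' @param ports Optional custom port index (as from [read_ports()])
#'   overriding the auto-placed one.
#' @param F_max,coupling_c Coupled-scenario link parameters: the planted
#'   divergence of pair (i, j) is `F_max / (1 + coupling_c * s_ij)` with
#'   `s_ij` the shipping matrix scaled to a maximum of 1. The default
#'   `coupling_c = 4` is strong coupling: shipping spans most of the
#'   divergence range.
#' @return An object of class `scenario_spec` (a validated list).
#' @export
scenario_spec <- function(seed = 1,
                          n_regions = 6, ports_per_region = 3,
                          n_ships = 20, legs_per_ship = 5,
                          start_year = 1750, end_year = 2000,
                          threshold_km = 10, margin_km = 3, noise_km = 2,
                          speed_km_day = 300,
                          n_pops = 2, pop_size = 30, n_loci = 2000,
                          F = 0.1, missing_rate = 0.05,
                          S = NULL, F_max = 0.2, coupling_c = 4,
                          ports = NULL) {
  stopifnot(seed == as.integer(seed),
            n_regions >= 1, ports_per_region >= 1,
            threshold_km > 0, margin_km > 0, margin_km < threshold_km,
            noise_km >= 0, noise_km < threshold_km - margin_km,
            F >= 0, F < 1, F_max > 0, F_max < 1, coupling_c >= 0,
            missing_rate >= 0, missing_rate < 1,
            pop_size >= 1, n_loci >= 1, n_pops >= 1)
  if (!is.null(S)) {
    S <- as.matrix(S)
    if (nrow(S) != ncol(S) || any(S < 0)) {
      stop("S must be a square non-negative matrix")
    }
  }
  structure(as.list(environment()), class = "scenario_spec")
}

region_names <- function(n) paste0("region", seq_len(n))

# deterministic port index: random placement with a 300 km minimum
# separation so a position can never be near two ports at once
synthetic_ports <- function(spec) {
  set.seed(spec$seed %% 2147483647L)
  n <- spec$n_regions * spec$ports_per_region
  lat <- numeric(0); lon <- numeric(0)
  tries <- 0L
  while (length(lat) < n) {
    la <- stats::runif(1, -50, 50)
    lo <- stats::runif(1, -180, 180)
    if (length(lat) == 0L || min(haversine_km(la, lo, lat, lon)) > 300) {
      lat <- c(lat, la); lon <- c(lon, lo)
    }
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place ports 300 km apart")
  }
  ids <- sprintf("P%02d", seq_len(n))
  data.frame(port_id = ids, name = paste("Port", ids), lat = lat, lon = lon,
             region = rep(region_names(spec$n_regions),
                          each = spec$ports_per_region),
             stringsAsFactors = FALSE)
}

# planted calls are only unambiguous when no two ports can share a
# threshold disc; reject port indexes violating that
check_port_spacing <- function(ports, spec) {
  n <- nrow(ports)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    d <- haversine_km(ports$lat[i], ports$lon[i],
                      ports$lat[(i + 1L):n], ports$lon[(i + 1L):n])
    if (min(d) < 2 * spec$threshold_km) {
      stop("ports closer together than twice the detection threshold; ",
           "use a sparser port index")
    }
  }
  invisible(TRUE)
}

# jitter a (lat, lon) point by <= radius_km in a uniform random direction
jitter_point <- function(lat, lon, radius_km) {
  if (radius_km <= 0) return(c(lat, lon))
  d <- stats::runif(1, 0, radius_km) * 1000
  b <- stats::runif(1, 0, 360)
  p <- geosphere::destPoint(c(lon, lat), b, d, r = 6371000)
  c(p[2], p[1])
}

# one voyage: daily fixes from port a (day t0) to port b (day t1);
# interior days follow the great circle, pushed clear of any port that
# happens to lie close to the track
leg_positions <- function(pa, pb, t0, t1, ports, spec) {
  ndays <- t1 - t0
  clear_km <- spec$threshold_km + spec$margin_km
  out <- matrix(NA_real_, nrow = ndays + 1L, ncol = 2)
  out[1, ] <- jitter_point(pa$lat, pa$lon, min(spec$noise_km,
                                               spec$threshold_km - spec$margin_km))
  out[ndays + 1L, ] <- jitter_point(pb$lat, pb$lon,
                                    min(spec$noise_km,
                                        spec$threshold_km - spec$margin_km))
  if (ndays >= 2L) {
    mid <- geosphere::gcIntermediate(c(pa$lon, pa$lat), c(pb$lon, pb$lat),
                                     n = ndays - 1L, addStartEnd = FALSE)
    mid <- matrix(mid, ncol = 2)
    for (k in seq_len(nrow(mid))) {
      pt <- jitter_point(mid[k, 2], mid[k, 1], spec$noise_km)
      d <- haversine_km(pt[1], pt[2], ports$lat, ports$lon)
      if (min(d) <= clear_km) {
        # push the fix away from the on-track port
        j <- which.min(d)
        b <- geosphere::bearing(c(ports$lon[j], ports$lat[j]),
                                c(pt[2], pt[1]))
        if (is.na(b)) b <- 90
        p2 <- geosphere::destPoint(c(ports$lon[j], ports$lat[j]), b,
                                   (clear_km + 20) * 1000, r = 6371000)
        pt <- c(p2[2], p2[1])
        if (min(haversine_km(pt[1], pt[2], ports$lat, ports$lon)) <= clear_km) {
          stop("ports too dense along a leg; use a sparser port index")
        }
      }
      out[k + 1L, ] <- pt
    }
  }
  out
}

#' Simulate ship trajectories with planted port calls
#'
#' Emits one daily position per ship along great-circle legs between the
#' ports of a random itinerary. On planned call days the position lies
#' within `threshold_km - margin_km` of the intended port; on transit days
#' it lies farther than `threshold_km + margin_km` from every port, so
#' [detect_port_calls()] at the scenario threshold recovers the planted
#' call sequence exactly. Deterministic given the scenario seed.
#'
#' @param spec A [scenario_spec()].
#' @return List with `positions` (as from [read_positions()]), `ports`
#'   (as from [read_ports()]) and `truth`: the planted `calls` and
#'   `events` data frames.
#' @export
simulate_trajectories <- function(spec) {
  ports <- if (!is.null(spec[["ports"]])) spec[["ports"]] else synthetic_ports(spec)
  check_port_spacing(ports, spec)
  set.seed((spec$seed + 1L) %% 2147483647L)
  region_of <- stats::setNames(ports$region, ports$port_id)
  pos_list <- list()
  call_list <- list()
  for (s in seq_len(spec$n_ships)) {
    ship <- sprintf("ship%03d", s)
    stops <- integer(spec$legs_per_ship + 1L)
    stops[1] <- sample.int(nrow(ports), 1)
    for (k in seq_len(spec$legs_per_ship)) {
      stops[k + 1L] <- sample(setdiff(seq_len(nrow(ports)), stops[k]), 1)
    }
    day0 <- as.Date(sprintf("%d-01-01", spec$start_year)) +
      floor(stats::runif(1) * (spec$end_year - spec$start_year - 5) * 365.25)
    days <- integer(length(stops))
    days[1] <- 0L
    for (k in seq_len(spec$legs_per_ship)) {
      d <- haversine_km(ports$lat[stops[k]], ports$lon[stops[k]],
                        ports$lat[stops[k + 1L]], ports$lon[stops[k + 1L]])
      days[k + 1L] <- days[k] + max(2L, ceiling(d / spec$speed_km_day))
    }
    ship_pos <- list()
    for (k in seq_len(spec$legs_per_ship)) {
      leg <- leg_positions(ports[stops[k], ], ports[stops[k + 1L], ],
                           days[k], days[k + 1L], ports, spec)
      rows <- if (k == 1L) seq_len(nrow(leg)) else 2:nrow(leg)
      ship_pos[[k]] <- data.frame(
        ship_id = ship,
        date = day0 + seq(days[k], days[k + 1L])[rows],
        lat = leg[rows, 1], lon = leg[rows, 2],
        stringsAsFactors = FALSE)
    }
    pos_list[[s]] <- do.call(rbind, ship_pos)
    call_list[[s]] <- data.frame(
      ship_id = ship,
      port_id = ports$port_id[stops],
      arrival_date = day0 + days,
      stringsAsFactors = FALSE)
  }
  positions <- do.call(rbind, pos_list)
  positions$lon <- normalize_lon(positions$lon)
  positions <- positions[order(positions$ship_id, positions$date), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  calls <- do.call(rbind, call_list)
  n <- nrow(calls)
  i <- which(calls$ship_id[-n] == calls$ship_id[-1])
  events <- data.frame(
    ship_id = calls$ship_id[i],
    origin_port = calls$port_id[i],
    dest_port = calls$port_id[i + 1L],
    origin_region = unname(region_of[calls$port_id[i]]),
    dest_region = unname(region_of[calls$port_id[i + 1L]]),
    depart_date = calls$arrival_date[i],
    arrive_date = calls$arrival_date[i + 1L],
    stringsAsFactors = FALSE)
  list(positions = positions, ports = ports,
       truth = list(calls = calls, events = events))
}

# Balding-Nichols population frequencies around ancestral p0
bn_freqs <- function(p0, F) {
  if (F == 0) return(p0)
  stats::rbeta(length(p0), p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
}

genotypes_from_freqs <- function(freqs, pop_names, pop_size, missing_rate) {
  n_loci <- ncol(freqs)
  calls <- matrix(NA_integer_, nrow = 0, ncol = n_loci)
  pop <- character(0)
  for (k in seq_len(nrow(freqs))) {
    g <- matrix(stats::rbinom(pop_size * n_loci, 2L,
                              rep(freqs[k, ], each = pop_size)),
                nrow = pop_size)
    calls <- rbind(calls, g)
    pop <- c(pop, rep(pop_names[k], pop_size))
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  rownames(calls) <- sprintf("%s_i%02d", pop,
                             stats::ave(seq_along(pop), pop, FUN = seq_along))
  colnames(calls) <- sprintf("snp%05d", seq_len(n_loci))
  calls
}

#' Simulate SNP genotypes under the Balding-Nichols drift model
#'
#' Ancestral alternate-allele frequencies are drawn uniform on
#' `[0.05, 0.95]` per locus; each population's frequency is an independent
#' Beta draw `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)` at divergence
#' `F` (at `F = 0` the populations share `p0` exactly); diploid genotypes
#' are binomial(2, p_pop); calls are masked missing at `missing_rate`.
#' Deterministic given the scenario seed.
#'
#' @param spec A [scenario_spec()].
#' @return List with `gm` (a [genotype_matrix()]) and `truth` (`p0`,
#'   `pop_freqs`, `F`).
#' @export
simulate_genotypes <- function(spec) {
  set.seed((spec$seed + 2L) %% 2147483647L)
  p0 <- stats::runif(spec$n_loci, 0.05, 0.95)
  pops <- sprintf("pop%02d", seq_len(spec$n_pops))
  freqs <- t(vapply(pops, function(p) bn_freqs(p0, spec$F),
                    numeric(spec$n_loci)))
  calls <- genotypes_from_freqs(freqs, pops, spec$pop_size,
                                spec$missing_rate)
  pop <- sub("_i[0-9]+$", "", rownames(calls))
  gm <- genotype_matrix(calls, pop)
  list(gm = gm, truth = list(p0 = p0, pop_freqs = freqs, F = spec$F))
}

# symmetric integer shipping matrix with a wide intensity spread
random_shipping_matrix <- function(n_regions) {
  S <- matrix(0L, n_regions, n_regions,
              dimnames = list(region_names(n_regions),
                              region_names(n_regions)))
  ut <- upper.tri(S)
  S[ut] <- as.integer(round(stats::runif(sum(ut))^2 * 40))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Simulate a shipping-coupled genotype scenario
#'
#' Realizes the premise that shipping drives connectivity: pairs of
#' regions with more shipping are genetically less differentiated. Each
#' region's allele frequency is an admixture of an independent
#' Balding-Nichols drift component at `F_max` and one shared component
#' per partner region, with the shared weight `coupling_c` times the
#' scaled shipping intensity of the pair. Shared ancestry therefore grows
#' with shipping and realized pairwise theta decreases monotonically in
#' it in expectation (the declared per-pair target is
#' `F_max / (1 + coupling_c * s_ij)`). The shipping matrix is also
#' emitted as a `shipping_tensor` (the same counts in each default
#' period), and optionally as trajectories whose detected travel events
#' reproduce those counts, so the whole pipeline runs end-to-end.
#'
#' @param spec A [scenario_spec()]; one population per region.
#' @param trajectories Also generate voyages realizing the shipping
#'   matrix (default `FALSE`; genotype draws are unaffected either way).
#' @return List with `gm`, `tensor`, `S`, `ports`, `positions` (when
#'   requested) and `truth` (`p0`, admixed `pop_freqs`, per-pair target
#'   divergence `F_pair`).
#' @export
simulate_coupled <- function(spec, trajectories = FALSE) {
  set.seed((spec$seed + 3L) %% 2147483647L)
  regions <- region_names(spec$n_regions)
  S <- if (!is.null(spec$S)) spec$S else random_shipping_matrix(spec$n_regions)
  if (nrow(S) != spec$n_regions) stop("S must be n_regions x n_regions")
  dimnames(S) <- list(regions, regions)

  p0 <- stats::runif(spec$n_loci, 0.05, 0.95)
  s_scaled <- if (max(S) > 0) S / max(S) else S
  # each region mixes a private drift component with one shared component
  # per partner pair; the shared weight grows with shipping, so the pair's
  # frequencies correlate and realized theta falls monotonically in S
  private <- t(vapply(regions, function(r) bn_freqs(p0, spec$F_max),
                      numeric(spec$n_loci)))
  shared <- array(NA_real_, dim = c(spec$n_regions, spec$n_regions,
                                    spec$n_loci))
  for (i in seq_len(spec$n_regions - 1L)) {
    for (j in seq((i + 1L), spec$n_regions)) {
      shared[i, j, ] <- shared[j, i, ] <- bn_freqs(p0, spec$F_max)
    }
  }
  freqs <- matrix(NA_real_, spec$n_regions, spec$n_loci,
                  dimnames = list(regions, NULL))
  for (i in seq_len(spec$n_regions)) {
    w <- spec$coupling_c * s_scaled[i, ]
    w[i] <- 0
    mix <- private[i, ]
    for (j in seq_len(spec$n_regions)) {
      if (w[j] > 0) mix <- mix + w[j] * shared[i, j, ]
    }
    freqs[i, ] <- mix / (1 + sum(w))
  }
  calls <- genotypes_from_freqs(freqs, regions, spec$pop_size,
                                spec$missing_rate)
  pop <- sub("_i[0-9]+$", "", rownames(calls))
  gm <- genotype_matrix(calls, pop,
                        region_of = stats::setNames(regions, regions))

  periods <- default_periods()
  counts <- array(0L, dim = c(nrow(periods), length(regions), length(regions)),
                  dimnames = list(period = period_labels(periods),
                                  origin = regions, dest = regions))
  for (k in seq_len(nrow(periods))) counts[k, , ] <- S
  tensor <- structure(list(counts = counts, periods = periods,
                           regions = regions, n_unbinned = 0L),
                      class = "shipping_tensor")
  F_pair <- spec$F_max / (1 + spec$coupling_c * s_scaled)
  diag(F_pair) <- 0
  out <- list(gm = gm, tensor = tensor, S = S,
              truth = list(p0 = p0, pop_freqs = freqs, F_pair = F_pair))
  if (trajectories) {
    tr <- coupled_trajectories(spec, S)
    out$ports <- tr$ports
    out$positions <- tr$positions
    out$truth$calls <- tr$truth$calls
    out$truth$events <- tr$truth$events
  }
  out
}

# voyages realizing a shipping matrix: one single-leg voyage per planted
# travel event, dated uniformly over the default periods
coupled_trajectories <- function(spec, S) {
  ports <- if (!is.null(spec[["ports"]])) spec[["ports"]] else synthetic_ports(spec)
  check_port_spacing(ports, spec)
  set.seed((spec$seed + 4L) %% 2147483647L)
  region_of <- stats::setNames(ports$region, ports$port_id)
  regions <- rownames(S)
  pos_list <- list(); call_list <- list()
  ship_n <- 0L
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i == j || S[i, j] == 0L) next
      from_ports <- which(ports$region == regions[i])
      to_ports <- which(ports$region == regions[j])
      for (e in seq_len(S[i, j])) {
        ship_n <- ship_n + 1L
        ship <- sprintf("cship%04d", ship_n)
        a <- sample(from_ports, 1); b <- sample(to_ports, 1)
        d <- haversine_km(ports$lat[a], ports$lon[a],
                          ports$lat[b], ports$lon[b])
        ndays <- max(2L, ceiling(d / spec$speed_km_day))
        day0 <- as.Date("1750-01-01") +
          floor(stats::runif(1) * (2000 - 1751) * 365.25)
        leg <- leg_positions(ports[a, ], ports[b, ], 0L, ndays, ports, spec)
        pos_list[[ship_n]] <- data.frame(
          ship_id = ship, date = day0 + 0:ndays,
          lat = leg[, 1], lon = leg[, 2], stringsAsFactors = FALSE)
        call_list[[ship_n]] <- data.frame(
          ship_id = ship, port_id = ports$port_id[c(a, b)],
          arrival_date = day0 + c(0L, ndays), stringsAsFactors = FALSE)
      }
    }
  }
  positions <- do.call(rbind, pos_list)
  positions$lon <- normalize_lon(positions$lon)
  positions <- positions[order(positions$ship_id, positions$date), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  calls <- do.call(rbind, call_list)
  n <- nrow(calls)
  i <- which(calls$ship_id[-n] == calls$ship_id[-1])
  events <- data.frame(
    ship_id = calls$ship_id[i],
    origin_port = calls$port_id[i], dest_port = calls$port_id[i + 1L],
    origin_region = unname(region_of[calls$port_id[i]]),
    dest_region = unname(region_of[calls$port_id[i + 1L]]),
    depart_date = calls$arrival_date[i],
    arrive_date = calls$arrival_date[i + 1L],
    stringsAsFactors = FALSE)
  list(ports = ports, positions = positions,
       truth = list(calls = calls, events = events))
}
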