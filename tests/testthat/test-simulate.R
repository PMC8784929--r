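test_that("trajectory simulation is deterministic given the seed", {
  a <- simulate_trajectories(scenario_spec(seed = 9, n_ships = 3))
  b <- simulate_trajectories(scenario_spec(seed = 9, n_ships = 3))
  expect_identical(a$positions, b$positions)
  expect_identical(a$ports, b$ports)
  c <- simulate_trajectories(scenario_spec(seed = 10, n_ships = 3))
  expect_false(identical(a$positions, c$positions))
})

test_that("planted geometry honours the detection margins", {
  spec <- scenario_spec(seed = 19, n_ships = 5)
  tr <- simulate_trajectories(spec)
  dmat <- outer(seq_len(nrow(tr$positions)), seq_len(nrow(tr$ports)),
                function(i, j) haversine_km(tr$positions$lat[i],
                                            tr$positions$lon[i],
                                            tr$ports$lat[j], tr$ports$lon[j]))
  dmin <- apply(dmat, 1, min)
  key <- paste(tr$positions$ship_id, tr$positions$date)
  call_key <- paste(tr$truth$calls$ship_id, tr$truth$calls$arrival_date)
  is_call_day <- key %in% call_key
  expect_true(all(dmin[is_call_day] <= spec$threshold_km - spec$margin_km))
  expect_true(all(dmin[!is_call_day] > spec$threshold_km + spec$margin_km))
})

test_that("simulated files round-trip through every reader", {
  dir <- tempfile("scenario")
  tr <- simulate_trajectories(scenario_spec(seed = 23, n_ships = 4))
  write_scenario(tr, dir, seed = 23)
  pos <- read_positions(file.path(dir, "positions.csv"))
  ports <- read_ports(file.path(dir, "ports.csv"))
  expect_equal(nrow(pos), nrow(tr$positions))
  expect_equal(ports$port_id, sort(tr$ports$port_id))
  calls <- detect_port_calls(pos, ports)
  expect_equal(nrow(calls), nrow(tr$truth$calls))
})

test_that("genotype simulation is deterministic and frequency-sane", {
  a <- simulate_genotypes(scenario_spec(seed = 41, n_loci = 300))
  b <- simulate_genotypes(scenario_spec(seed = 41, n_loci = 300))
  expect_identical(a$gm$calls, b$gm$calls)
  # write the same scenario twice: byte-identical VCF
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(a$gm, f1); write_vcf(b$gm, f2)
  expect_identical(readLines(f1), readLines(f2))
  # ancestral frequencies are uniform on [0.05, 0.95]: mean near 0.5
  big <- simulate_genotypes(scenario_spec(seed = 4, n_loci = 3000,
                                          missing_rate = 0))
  expect_lt(abs(mean(big$truth$p0) - 0.5), 0.02)
  realized <- colMeans(big$gm$calls) / 2
  expect_lt(abs(mean(realized) - 0.5), 0.02)
})

test_that("F = 0 shares the ancestral frequency and F >= 1 is rejected", {
  sim <- simulate_genotypes(scenario_spec(seed = 2, F = 0, n_loci = 100))
  expect_equal(sim$truth$pop_freqs[1, ], sim$truth$pop_freqs[2, ])
  expect_equal(unname(sim$truth$pop_freqs[1, ]), sim$truth$p0)
  expect_error(scenario_spec(F = 1), "F")
})

test_that("divergence tracks the Balding-Nichols parameter at the limits", {
  lo <- simulate_genotypes(scenario_spec(seed = 6, F = 0, n_loci = 2000))
  expect_lt(abs(wc_fst_pair(lo$gm, "pop01", "pop02")$theta), 0.01)
  hi <- simulate_genotypes(scenario_spec(seed = 6, F = 0.9, n_loci = 1000,
                                         pop_size = 20))
  expect_gt(wc_fst_pair(hi$gm, "pop01", "pop02")$theta, 0.75)
})

test_that("coupled scenarios are deterministic and emit consistent pieces", {
  a <- simulate_coupled(scenario_spec(seed = 77, n_loci = 200, pop_size = 10))
  b <- simulate_coupled(scenario_spec(seed = 77, n_loci = 200, pop_size = 10))
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$S, b$S)
  expect_equal(a$S, t(a$S))
  expect_true(all(a$S >= 0))
  # tensor carries the same counts in every default period
  for (k in 1:5) expect_equal(a$tensor$counts[k, , ], a$S,
                              ignore_attr = TRUE)
  # planted pairwise divergence falls with shipping
  ut <- upper.tri(a$S)
  expect_lte(stats::cor(a$S[ut], a$truth$F_pair[ut], method = "spearman"), 0)
  # decoupled limit: all pairs share F_max
  dec <- simulate_coupled(scenario_spec(seed = 77, n_loci = 50, pop_size = 5,
                                        coupling_c = 0))
  expect_true(all(abs(dec$truth$F_pair[upper.tri(dec$S)] - 0.2) < 1e-12))
})

test_that("coupled trajectories realize the shipping matrix exactly", {
  spec <- scenario_spec(seed = 12, n_loci = 50, pop_size = 5)
  sim <- simulate_coupled(spec, trajectories = TRUE)
  calls <- detect_port_calls(sim$positions, sim$ports,
                             threshold_km = spec$threshold_km,
                             gap_days = 1e6)
  events <- extract_travel_events(calls, sim$ports)
  tensor <- bin_events(events, regions = sim$tensor$regions)
  recovered <- apply(tensor$counts, c(2, 3), sum)
  expect_equal(recovered, unname(sim$S) + 0L,
               ignore_attr = TRUE)
  # genotype draws are unaffected by the trajectories flag
  plain <- simulate_coupled(spec, trajectories = FALSE)
  expect_identical(plain$gm$calls, sim$gm$calls)
})

test_that("an overcrowded custom port index is rejected", {
  close_ports <- make_ports(lat = c(0, 0.05), lon = 0, ids = c("PA", "PB"),
                            region = c("R1", "R2"))
  spec <- scenario_spec(seed = 3, n_ships = 2, n_regions = 2,
                        ports_per_region = 1, ports = close_ports)
  expect_error(simulate_trajectories(spec), "dense|apart|sparser")
})
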