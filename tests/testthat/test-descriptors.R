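test_that("registry contract: 204 deterministic, categorized features", {
  reg <- feature_registry("v1")
  expect_equal(nrow(reg), 204L)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_setequal(unique(reg$category),
                  c("general activity", "burst structure", "synchronization",
                    "oscillation"))
  expect_true(all(named_parameters() %in% reg$name))
  expect_error(feature_registry("v2"), "unknown")

  rec <- generate_network(synth_config(n_units = 6, duration = 180000,
                                       seed = 2))
  f1 <- assemble_features(rec)
  f2 <- assemble_features(rec)
  expect_identical(f1, f2)
  expect_equal(setdiff(names(f1), c("network_id", "group", "div")), reg$name)
})

test_that("spike rate averages over trains per 60 s bin", {
  # one unit, 60 spikes in each of five bins -> 1.0 Hz
  t <- as.numeric(outer(seq(0.5, 59999.5, length.out = 60),
                        (0:4) * 60000, "+"))
  rec <- make_recording(list(u1 = sort(t)), window = c(0, 300000))
  b <- detect_bursts(rec)
  ga <- general_activity(rec, b)
  expect_equal(ga$spike_rate, 1.0)
  # two units at 0 and 2 Hz average to 1.0 Hz
  t2 <- sort(as.numeric(outer(seq(0.25, 59999.75, length.out = 120),
                              (0:4) * 60000, "+")))
  rec2 <- mea_recording(tibble::tibble(unit_id = "u2", time_ms = t2),
                        window = c(0, 300000), units = c("silent", "u2"))
  ga2 <- general_activity(rec2, detect_bursts(rec2))
  expect_equal(ga2$spike_rate, 1.0)
  # planted-rate recount on a synthetic network
  rec3 <- generate_network(synth_config(n_units = 12, duration = 300000,
                                        seed = 31))
  ga3 <- general_activity(rec3, detect_bursts(rec3))
  span <- 300000
  brute <- mean(vapply(rec3$units,
                       function(u) length(unit_spikes(rec3, u)) / (span / 1000),
                       1))
  expect_equal(ga3$spike_rate, brute, tolerance = 1e-12)
  expect_equal(ga3$spike_rate, network_spike_rate(rec3), tolerance = 1e-12)
})

test_that("burst structure has closed-form values on constructed bursts", {
  # a single 4-spike burst: duration 30 ms, mean ISI 10 ms -> 100 Hz density
  rec <- make_recording(list(u1 = c(0, 10, 20, 30) + 5000),
                        window = c(0, 60000))
  b <- detect_bursts(rec)
  expect_equal(nrow(b), 1L)
  bs <- burst_structure(rec, b)
  expect_equal(bs$burst_duration, 30)
  expect_equal(bs$burst_spike_density, 100)
  expect_equal(bs$spikes_in_burst, 4)
  # two bursts of 20 and 40 ms average to 30 ms
  rec2 <- make_recording(list(u1 = c(0, 20, 2000, 2020, 2040) + 5000),
                         window = c(0, 60000))
  bs2 <- burst_structure(rec2, detect_bursts(rec2))
  expect_equal(bs2$burst_duration, 30)
  # no bursts: missing, not zero
  rec3 <- make_recording(list(u1 = c(0, 5000, 10000)), window = c(0, 60000))
  bs3 <- burst_structure(rec3, detect_bursts(rec3))
  expect_true(is.na(bs3$burst_duration))
  expect_true(is.na(bs3$burst_amplitude))
})

test_that("burst profile amplitude and area match a numerical oracle", {
  spikes <- c(0, 10, 20, 30, 40)
  bp <- burst_profiles(list(spikes), bandwidth = 10, grid_step = 0.25)
  # oracle: dense numerical evaluation of the Gaussian mixture
  grid <- seq(-30, 70, by = 0.01)
  prof <- 1000 * rowSums(vapply(spikes, function(m) dnorm(grid, m, 10),
                                numeric(length(grid))))
  expect_equal(bp$per_burst$amplitude, max(prof), tolerance = 1e-3)
  # the smoothed count integrates back to the number of spikes
  expect_equal(bp$per_burst$area, 5, tolerance = 1e-3)
  expect_equal(bp$per_burst$peak_time, 20, tolerance = 0.3)
  # plateau: width of the region >= 90% of peak, from the oracle profile
  oracle_plateau <- diff(range(grid[prof >= 0.9 * max(prof)]))
  expect_equal(bp$per_burst$plateau, oracle_plateau, tolerance = 1)
})

test_that("spike density rises with count at fixed duration and falls with duration", {
  mk <- function(times) {
    rec <- make_recording(list(u1 = times + 1000), window = c(0, 60000))
    burst_structure(rec, detect_bursts(rec))$burst_spike_density
  }
  base <- mk(c(0, 30, 60, 90))          # 4 spikes / 90 ms
  denser <- mk(seq(0, 90, length.out = 7))  # 7 spikes / 90 ms
  shorter <- mk(c(0, 15, 30, 45))       # 4 spikes / 45 ms
  expect_gt(denser, base)
  expect_gt(shorter, base)
})

test_that("perfect synchrony gives the exact synchronization fixed point", {
  rec <- perfect_sync_recording(n_units = 10, onsets = c(10000),
                                window = c(0, 60000))
  b <- detect_bursts(rec)
  s <- synchronization(rec, b)
  expect_equal(s$event_rate, 1 / 60)
  expect_equal(s$syn_share, 1.0)
  expect_equal(s$hamming_factor, 1.0)
  expect_equal(s$syn_all, 0)
  expect_equal(s$burst_rate_cvnet, 0)
})

test_that("events need at least the unit-fraction threshold", {
  # 4 of 10 units burst together: fraction 0.4 < 0.5 -> no event
  unit_times <- c(
    setNames(rep(list(c(10000, 10010, 10020)), 4), sprintf("b%d", 1:4)),
    setNames(rep(list(c(30000)), 6), sprintf("q%d", 1:6))
  )
  rec <- make_recording(unit_times, window = c(0, 60000))
  b <- detect_bursts(rec)
  s <- synchronization(rec, b)
  expect_equal(s$event_rate, 0)
  # raising the required fraction never increases the event rate
  rec2 <- generate_network(synth_config(n_units = 10, duration = 300000,
                                        participation_prob = 0.6, seed = 5))
  b2 <- detect_bursts(rec2)
  rates <- vapply(c(0.3, 0.5, 0.7, 0.9), function(fr) {
    nrow(detect_population_bursts(rec2, b2, fraction = fr))
  }, 1)
  expect_true(all(diff(rates) <= 0))
})

test_that("hamming factor matches the independence expectation", {
  # independent occupancy with p = 0.5 -> expected pairwise agreement 0.5
  withr::local_seed(12)
  reps <- vapply(1:12, function(i) {
    n_bins <- 60
    unit_times <- lapply(1:8, function(u) {
      occ <- which(runif(n_bins) < 0.5)
      sort(unlist(lapply(occ, function(k) (k - 1) * 10000 + c(0, 10, 20))))
    })
    names(unit_times) <- sprintf("u%d", 1:8)
    rec <- make_recording(unit_times, window = c(0, 600000))
    hamming_similarity(rec, detect_bursts(rec))$factor
  }, 1)
  se <- sqrt(0.25 / (60 * 28 * 12))  # binomial se, pooled over pairs & reps
  expect_lt(abs(mean(reps) - 0.5), 5 * se + 0.01)
})

test_that("oscillation metrics are zero for constant series and match sd()", {
  # identical per-bin rates -> cvtime 0
  t <- as.numeric(outer(seq(100, 59900, length.out = 30), (0:4) * 60000, "+"))
  rec <- make_recording(list(u1 = sort(t)), window = c(0, 300000))
  o <- oscillation(rec, detect_bursts(rec))
  expect_equal(o$spike_rate_cvtime, 0)
  expect_equal(o$spike_rate_sd, 0)
  # per-bin network rates {1, 3} Hz -> sample sd
  t2 <- sort(c(seq(0.5, 59999.5, length.out = 60),
               60000 + seq(0.5, 59999.5, length.out = 180)))
  rec2 <- make_recording(list(u1 = t2), window = c(0, 120000))
  o2 <- oscillation(rec2, detect_bursts(rec2))
  expect_equal(o2$spike_rate_sd, sd(c(1, 3)))
  # stationary Poisson network: cvtime equals the brute-force recount
  rec3 <- generate_network(synth_config(n_units = 5, duration = 300000,
                                        pop_event_rate = 0,
                                        independent_burst_rate = 0,
                                        background_rate = 2, seed = 8))
  o3 <- oscillation(rec3, detect_bursts(rec3))
  brute <- mean(vapply(rec3$units, function(u) {
    counts <- bin_counts(unit_spikes(rec3, u), rec3$window, 60000)
    sd(counts / 60) / mean(counts / 60)
  }, 1))
  expect_equal(o3$spike_rate_cvtime, brute, tolerance = 1e-12)
})

test_that("assembled features agree with the standalone operations", {
  rec <- generate_network(synth_config(n_units = 8, duration = 300000,
                                       seed = 21))
  b <- detect_bursts(rec)
  f <- assemble_features(rec)
  ga <- general_activity(rec, b)
  bs <- burst_structure(rec, b)
  sy <- synchronization(rec, b)
  os <- oscillation(rec, b)
  expect_equal(f$spike_rate, ga$spike_rate)
  expect_equal(f$burst_rate, ga$burst_rate)
  expect_equal(f$spike_contrast, ga$spike_contrast)
  expect_equal(f$burst_period, ga$burst_period)
  expect_equal(f$burst_duration, bs$burst_duration)
  expect_equal(f$burst_amplitude, bs$burst_amplitude)
  expect_equal(f$burst_spike_density, bs$burst_spike_density)
  expect_equal(f$syn_all, sy$syn_all)
  expect_equal(f$syn_share, sy$syn_share)
  expect_equal(f$event_rate, sy$event_rate)
  expect_equal(f$hamming_factor, sy$hamming_factor)
  expect_equal(f$burst_rate_cvnet, sy$burst_rate_cvnet)
  expect_equal(f$burst_rate_sd, os$burst_rate_sd)
})

test_that("descriptors are invariant under unit relabeling", {
  rec <- generate_network(synth_config(n_units = 6, duration = 180000,
                                       seed = 14))
  relabeled <- mea_recording(
    dplyr::mutate(rec$spikes, unit_id = paste0("zz_", unit_id)),
    window = rec$window, network_id = rec$network_id,
    units = paste0("zz_", rec$units))
  f1 <- assemble_features(rec)
  f2 <- assemble_features(relabeled)
  expect_equal(as.numeric(f1[, -(1:3)]), as.numeric(f2[, -(1:3)]),
               tolerance = 1e-12)
})

test_that("cvnet is zero for identical units and NA when degenerate", {
  expect_equal(cvnet(rep(3.3, 8)), 0)
  expect_true(is.na(cvnet(2)))
  expect_true(is.na(cvnet(c(1, -1))))
  rec <- perfect_sync_recording(n_units = 4)
  f <- assemble_features(rec)
  expect_equal(f$spike_rate_cvnet, 0)
})

test_that("feature export writes the table and the registry manifest", {
  rec <- generate_network(synth_config(n_units = 4, duration = 120000,
                                       seed = 3))
  f <- assemble_cohort_features(list(rec))
  d <- withr::local_tempdir()
  write_feature_table(f, file.path(d, "features.csv"))
  expect_true(file.exists(file.path(d, "features.csv")))
  man <- readr::read_csv(file.path(d, "features_registry.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(man), 204L)
})
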