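test_that("silent configuration generates empty trains", {
  cfg <- synth_config(n_units = 5, duration = 60000, pop_event_rate = 0,
                      background_rate = 0, independent_burst_rate = 0,
                      seed = 1)
  rec <- generate_network(cfg)
  expect_equal(nrow(rec$spikes), 0L)
  expect_equal(length(rec$units), 5L)
})

test_that("generation is reproducible and seed-sensitive", {
  cfg <- synth_config(n_units = 6, duration = 120000, seed = 42)
  r1 <- generate_network(cfg)
  r2 <- generate_network(cfg)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- generate_network(synth_config(n_units = 6, duration = 120000,
                                      seed = 43))
  expect_false(identical(r1$spikes, r3$spikes))
  # generation does not disturb the caller's RNG stream
  set.seed(10); a <- runif(1)
  set.seed(10); invisible(generate_network(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("generated recordings satisfy the recording invariants", {
  for (s in 1:5) {
    rec <- generate_network(synth_config(n_units = 10, duration = 300000,
                                         seed = s))
    expect_s3_class(rec, "mea_recording")  # constructor validates
    per_unit <- split(rec$spikes$time_ms, rec$spikes$unit_id)
    expect_true(all(vapply(per_unit,
                           function(t) !is.unsorted(t, strictly = TRUE),
                           TRUE)))
    expect_true(all(rec$spikes$time_ms >= 0 & rec$spikes$time_ms < 300000))
  }
})

test_that("detected burst rate matches the generative expectation", {
  # expected per-unit burst rate = event rate x participation + independent
  cfg <- synth_config(n_units = 24, duration = 1800000, pop_event_rate = 0.15,
                      participation_prob = 0.9, independent_burst_rate = 0,
                      background_rate = 0.05, seed = 77)
  rec <- generate_network(cfg)
  b <- detect_bursts(rec)
  rate <- nrow(b) / 24 / 1800
  expected <- 0.15 * 0.9
  # compound binomial-Poisson: the Poisson event-count fluctuation is shared
  # by all units, the participation noise averages over units
  lambda <- 0.15 * 1800; n <- 24; p <- 0.9
  se <- sqrt(lambda * (n^2 * p^2 + n * p * (1 - p))) / (n * 1800)
  expect_lt(abs(rate - expected), 3 * se + 0.005)
})

test_that("maturation scale multiplies the stated drivers", {
  prof28 <- maturation_profile(28)
  cfg14 <- synth_config(n_units = 12, duration = 600000, seed = 4)
  cfg28 <- synth_config(n_units = 12, duration = 600000, seed = 4,
                        maturation_scale = prof28)
  r14 <- generate_network(cfg14, div = 14)
  r28 <- generate_network(cfg28, div = 28)
  ratio <- network_spike_rate(r28) / network_spike_rate(r14)
  expect_gt(ratio, 2)   # maturation roughly triples the spike rate
  expect_lt(ratio, 4.5)
  b14 <- detect_bursts(r14); b28 <- detect_bursts(r28)
  expect_gt(nrow(b28) / nrow(b14), 1.4)  # bursting roughly doubles
})

test_that("more onset jitter degrades synchrony monotonically on average", {
  metrics <- vapply(c(5, 150, 600), function(jit) {
    hf <- vapply(1:4, function(s) {
      cfg <- synth_config(n_units = 10, duration = 300000,
                          onset_jitter_sd = jit, background_rate = 0.05,
                          seed = 300 + s)
      rec <- generate_network(cfg)
      b <- detect_bursts(rec)
      c(hamming_similarity(rec, b)$factor,
        mean(detect_population_bursts(rec, b)$fraction))
    }, numeric(2))
    rowMeans(hf)
  }, numeric(2))
  expect_true(all(diff(metrics[1, ]) < 0))  # hamming factor falls
  expect_true(all(diff(metrics[2, ]) < 0))  # participation falls
})

test_that("perfect-participation, zero-jitter networks are fully synchronous", {
  cfg <- synth_config(n_units = 8, duration = 300000, participation_prob = 1,
                      onset_jitter_sd = 0, background_rate = 0,
                      independent_burst_rate = 0, seed = 13)
  rec <- generate_network(cfg)
  b <- detect_bursts(rec)
  s <- synchronization(rec, b)
  expect_equal(s$syn_share, 1.0, tolerance = 0.02)
  expect_equal(s$hamming_factor, 1.0, tolerance = 0.02)
})

test_that("cohorts are deterministic and treatment multipliers act", {
  co1 <- generate_cohort(synth_config(n_units = 6, duration = 120000),
                         spike_driver_multipliers(1.5), n_per_group = 3,
                         base_seed = 9)
  co2 <- generate_cohort(synth_config(n_units = 6, duration = 120000),
                         spike_driver_multipliers(1.5), n_per_group = 3,
                         base_seed = 9)
  expect_identical(purrr::map(co1$treatment, "spikes"),
                   purrr::map(co2$treatment, "spikes"))
  expect_equal(purrr::map_chr(co1$control, function(r) r$meta$group),
               rep("control", 3))
  # null multipliers leave the two groups exchangeable in distribution:
  # same config, different seeds only
  con <- generate_cohort(synth_config(n_units = 6, duration = 120000),
                         NULL, n_per_group = 3, base_seed = 9)
  expect_false(identical(con$control[[1]]$spikes, con$treatment[[1]]$spikes))
  # multiplied spike drivers raise spike counts
  m_ctl <- mean(purrr::map_dbl(co1$control, network_spike_rate))
  m_trt <- mean(purrr::map_dbl(co1$treatment, network_spike_rate))
  expect_gt(m_trt / m_ctl, 1.2)
  expect_error(generate_cohort(synth_config(), c(bogus = 2), 2, 1),
               "unknown")
})

test_that("ground truth side-car describes the planted events", {
  cfg <- synth_config(n_units = 6, duration = 300000, seed = 6)
  rec <- generate_network(cfg)
  gt <- attr(rec, "ground_truth")
  expect_true(all(c("event_times", "bursts") %in% names(gt)))
  expect_true(all(gt$event_times >= 0 & gt$event_times <= 300000))
  expect_true(all(gt$bursts$unit_id %in% rec$units))
  # population onsets cluster near events: each population onset within
  # 5 jitter SDs of some event
  pop <- gt$bursts$onset_ms[gt$bursts$population]
  near <- vapply(pop, function(o) min(abs(o - gt$event_times)), 1)
  expect_lt(max(near), 5 * cfg$onset_jitter_sd)
})
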