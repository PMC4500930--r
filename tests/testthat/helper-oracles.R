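# Independent oracles and fixture builders used across the suite.

# Brute-force burst oracle: an explicit per-spike state machine over the ISI
# sequence (seed on ISI <= max_isi_start, stay open while ISI < min_isi_end),
# followed by repeated pairwise merge passes to a fixpoint, then filtering.
# Deliberately naive and loop-based; the package implementation is a
# vectorized run-length construction.
oracle_detect_bursts <- function(times, criteria = burst_criteria()) {
  n <- length(times)
  bursts <- list()
  i <- 1L
  while (i < n) {
    if (times[i + 1L] - times[i] <= criteria$max_isi_start) {
      j <- i + 1L
      while (j < n && times[j + 1L] - times[j] < criteria$min_isi_end) {
        j <- j + 1L
      }
      bursts[[length(bursts) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # exhaustive merge closure
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < length(bursts)) {
      gap <- times[bursts[[k + 1L]][1L]] - times[bursts[[k]][2L]]
      if (gap < criteria$min_interburst_interval) {
        bursts[[k]] <- c(bursts[[k]][1L], bursts[[k + 1L]][2L])
        bursts[[k + 1L]] <- NULL
        merged <- TRUE
      } else {
        k <- k + 1L
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(b) {
    n_sp <- b[2L] - b[1L] + 1L
    dur <- times[b[2L]] - times[b[1L]]
    n_sp >= criteria$min_spikes && dur >= criteria$min_burst_duration
  }, bursts)
  if (length(keep) == 0L) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      n_spikes = integer(0)))
  }
  data.frame(
    start_ms = vapply(keep, function(b) times[b[1L]], 1),
    end_ms = vapply(keep, function(b) times[b[2L]], 1),
    n_spikes = vapply(keep, function(b) b[2L] - b[1L] + 1L, 1L)
  )
}

# random spike train mixing Poisson background with planted bursts
random_train <- function(duration_ms = 60000, bg_rate_hz = 1,
                         n_bursts = 5, burst_isi_ms = 20) {
  bg <- sort(runif(rpois(1, bg_rate_hz * duration_ms / 1000), 0, duration_ms))
  planted <- unlist(lapply(seq_len(rpois(1, n_bursts)), function(i) {
    onset <- runif(1, 0, duration_ms)
    onset + cumsum(c(0, rexp(1 + rpois(1, 6), 1 / burst_isi_ms)))
  }))
  t <- sort(c(bg, planted))
  t <- t[t < duration_ms]
  t[!duplicated(t)]
}

# recording with hand-placed spikes: `unit_times` is a named list
make_recording <- function(unit_times, window, network_id = "net1", ...) {
  spikes <- dplyr::bind_rows(lapply(names(unit_times), function(u) {
    tibble::tibble(unit_id = u, time_ms = unit_times[[u]])
  }))
  mea_recording(spikes, window = window, network_id = network_id,
                units = names(unit_times), ...)
}

# a small network where every unit bursts identically (perfect synchrony)
perfect_sync_recording <- function(n_units = 10, onsets = c(10000, 40000),
                                   window = c(0, 60000),
                                   burst_pattern = c(0, 10, 20, 30)) {
  unit_times <- setNames(
    rep(list(sort(unlist(lapply(onsets, function(o) o + burst_pattern)))),
        n_units),
    sprintf("u%02d", seq_len(n_units)))
  make_recording(unit_times, window = window)
}
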