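#' Configuration of the synthetic network-activity generator
#'
#' The generator emulates the spontaneous activity of a developing cortical
#' culture on a multiwell microelectrode array. Network-wide population
#' events arrive as a homogeneous Poisson process; each unit joins an event
#' with `participation_prob`, placing a burst whose onset is jittered by a
#' Gaussian of SD `onset_jitter_sd`, whose spike count is 2 plus a Poisson
#' draw, and whose intra-burst intervals are gamma-distributed. Units add
#' independent (non-population) bursts and tonic background Poisson spiking.
#'
#' Defaults describe an active culture around two weeks in vitro: 24 units,
#' 30 min, ~6 bursts/min/unit (0.1 Hz events x 0.8 participation + 0.02 Hz
#' independent bursts), ~165 ms bursts of ~12 spikes, ~1.5 Hz unit spike
#' rate. `maturation_scale` multiplies the named drivers to emulate network
#' maturation (see [maturation_profile()]); `treatment_multipliers` applies
#' multiplicative treatment effects to any numeric field.
#'
#' @param n_units number of units in the network.
#' @param duration recording length, ms.
#' @param pop_event_rate rate of network population events, Hz.
#' @param participation_prob probability a unit joins an event.
#' @param onset_jitter_sd SD of the burst-onset jitter around the event, ms.
#' @param spikes_per_burst_mean mean spikes per burst (floor of 2 enforced by
#'   a shifted Poisson).
#' @param intra_burst_isi_shape,intra_burst_isi_mean gamma shape and mean
#'   (ms) of intra-burst interspike intervals.
#' @param background_rate tonic Poisson spike rate per unit, Hz.
#' @param independent_burst_rate rate of non-population bursts per unit, Hz.
#' @param maturation_scale named multipliers over
#'   `pop_event_rate`, `spikes_per_burst_mean`, `background_rate`.
#' @param treatment_multipliers optional named multipliers over any numeric
#'   scalar fields.
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_units = 24, duration = 1800000,
                         pop_event_rate = 0.1, participation_prob = 0.8,
                         onset_jitter_sd = 50, spikes_per_burst_mean = 12,
                         intra_burst_isi_shape = 2, intra_burst_isi_mean = 15,
                         background_rate = 0.3, independent_burst_rate = 0.02,
                         maturation_scale = c(pop_event_rate = 1,
                                              spikes_per_burst_mean = 1,
                                              background_rate = 1),
                         treatment_multipliers = NULL, seed = 1L) {
  stopifnot(n_units >= 1, duration > 0, pop_event_rate >= 0,
            participation_prob >= 0, participation_prob <= 1,
            onset_jitter_sd >= 0, spikes_per_burst_mean >= 2,
            intra_burst_isi_shape > 0, intra_burst_isi_mean > 0,
            background_rate >= 0, independent_burst_rate >= 0)
  structure(list(n_units = n_units, duration = duration,
                 pop_event_rate = pop_event_rate,
                 participation_prob = participation_prob,
                 onset_jitter_sd = onset_jitter_sd,
                 spikes_per_burst_mean = spikes_per_burst_mean,
                 intra_burst_isi_shape = intra_burst_isi_shape,
                 intra_burst_isi_mean = intra_burst_isi_mean,
                 background_rate = background_rate,
                 independent_burst_rate = independent_burst_rate,
                 maturation_scale = maturation_scale,
                 treatment_multipliers = treatment_multipliers,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Maturation multipliers for a culture age
#'
#' Linear interpolation of the generator's maturation drivers between 14 and
#' 28 days in vitro: at 28 div the event rate doubles and spikes per burst
#' and background rate grow so the overall spike rate roughly triples,
#' matching how bursting roughly doubles (about 6 to 12 bursts/min) and
#' spiking triples as such cultures mature.
#'
#' @param div culture age, days in vitro (clamped to `[14, 28]`).
#' @return Named multiplier vector usable as `maturation_scale`.
#' @export
maturation_profile <- function(div = 14) {
  f <- (min(max(div, 14), 28) - 14) / 14
  c(pop_event_rate = 1 + f * 1.0,         # 2x at 28 div
    spikes_per_burst_mean = 1 + f * 0.25, # 1.25x
    background_rate = 1 + f * 2.0)        # 3x
}

apply_multipliers <- function(config, mult) {
  if (is.null(mult) || length(mult) == 0L) return(config)
  for (nm in names(mult)) {
    if (!nm %in% names(config) || !is.numeric(config[[nm]])) {
      abort(sprintf("unknown or non-numeric config field: %s", nm))
    }
    config[[nm]] <- config[[nm]] * mult[[nm]]
  }
  config
}

# spike times for a set of bursts: onsets + gamma ISI increments, vectorized
burst_spike_times <- function(onsets, n_spikes, shape, mean_isi) {
  total <- sum(n_spikes)
  if (total == 0L) return(list(times = numeric(0), burst = integer(0)))
  gaps <- rgamma(total, shape = shape, scale = mean_isi / shape)
  first <- cumsum(c(1L, head(n_spikes, -1L)))
  gaps[first] <- 0
  cs <- cumsum(gaps)
  offset <- rep(cs[first], times = n_spikes)
  rel <- cs - offset
  list(times = rep(onsets, times = n_spikes) + rel,
       burst = rep(seq_along(onsets), times = n_spikes))
}

#' Simulate one network recording
#'
#' Draws a recording from the generative model in [synth_config()] after
#' applying the configuration's maturation scale and treatment multipliers.
#' Spikes falling outside the window are clipped; exact duplicate spike times
#' within a unit are dropped so trains stay strictly ascending. The ground
#' truth (population event times and planted per-unit burst onsets) is
#' attached as attribute `"ground_truth"`.
#'
#' @param config a [synth_config()].
#' @param network_id,group,div,well recording metadata.
#' @return An [mea_recording()].
#' @export
generate_network <- function(config, network_id = "net1",
                             group = "control", div = 14,
                             well = NA_character_) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- apply_multipliers(config, config$maturation_scale)
  cfg <- apply_multipliers(cfg, cfg$treatment_multipliers)
  dur_s <- cfg$duration / 1000
  with_seed(cfg$seed, {
    n_ev <- rpois(1L, cfg$pop_event_rate * dur_s)
    event_times <- sort(runif(n_ev, 0, cfg$duration))
    units <- sprintf("u%02d", seq_len(cfg$n_units))
    spk_t <- vector("list", cfg$n_units)
    gt_on <- vector("list", cfg$n_units)
    gt_pop <- vector("list", cfg$n_units)
    for (ui in seq_len(cfg$n_units)) {
      join <- if (n_ev > 0L) runif(n_ev) < cfg$participation_prob else logical(0)
      onsets <- event_times[join] +
        rnorm(sum(join), 0, cfg$onset_jitter_sd)
      n_ind <- rpois(1L, cfg$independent_burst_rate * dur_s)
      onsets <- c(onsets, runif(n_ind, 0, cfg$duration))
      n_in_burst <- 2L + rpois(length(onsets),
                               max(cfg$spikes_per_burst_mean - 2, 0))
      bs <- burst_spike_times(onsets, n_in_burst,
                              cfg$intra_burst_isi_shape,
                              cfg$intra_burst_isi_mean)
      n_bg <- rpois(1L, cfg$background_rate * dur_s)
      times <- c(bs$times, runif(n_bg, 0, cfg$duration))
      times <- times[times >= 0 & times < cfg$duration]
      times <- sort(times)
      spk_t[[ui]] <- times[!duplicated(times)]
      o <- order(onsets)
      gt_on[[ui]] <- onsets[o]
      gt_pop[[ui]] <- c(rep(TRUE, sum(join)), rep(FALSE, n_ind))[o]
    }
    n_per_unit <- lengths(spk_t)
    spikes <- tibble(unit_id = rep(units, times = n_per_unit),
                     time_ms = unlist(spk_t, use.names = FALSE))
    rec <- mea_recording(spikes, window = c(0, cfg$duration),
                         network_id = network_id, units = units,
                         group = group, div = div, well = well)
    attr(rec, "ground_truth") <- list(
      event_times = event_times,
      bursts = tibble(unit_id = rep(units, times = lengths(gt_on)),
                      onset_ms = unlist(gt_on, use.names = FALSE),
                      population = unlist(gt_pop, use.names = FALSE)))
    rec
  })
}

#' Simulate a control/treatment cohort
#'
#' Control networks are drawn from `control`; treatment networks from the
#' same configuration with `treatment_multipliers` applied. Per-network seeds
#' are derived deterministically from `base_seed`, so cohorts are
#' reproducible and order-independent.
#'
#' @param control a [synth_config()] for the control condition.
#' @param treatment_multipliers named multipliers defining the treatment
#'   effect (e.g. `c(background_rate = 1.5, spikes_per_burst_mean = 1.5)`).
#' @param n_per_group networks per group, >= 2.
#' @param base_seed integer seed for the cohort.
#' @param div culture age stamped on the recordings.
#' @return A list with elements `control` and `treatment`, each a list of
#'   [mea_recording()] objects with group metadata set.
#' @export
generate_cohort <- function(control, treatment_multipliers = NULL,
                            n_per_group = 12, base_seed = 1L, div = 14) {
  stopifnot(inherits(control, "synth_config"), n_per_group >= 2)
  make <- function(grp, mult, offset) {
    purrr::map(seq_len(n_per_group), function(i) {
      cfg <- control
      cfg$treatment_multipliers <- mult
      cfg$seed <- derive_seed(base_seed, offset + i)
      generate_network(cfg, network_id = sprintf("%s_%02d", grp, i),
                       group = grp, div = div,
                       well = sprintf("%s%02d", toupper(substr(grp, 1, 1)), i))
    })
  }
  list(control = make("control", NULL, 0L),
       treatment = make("treatment", treatment_multipliers, n_per_group))
}

#' Convenience spike-driver treatment multipliers
#'
#' Scales the two spike-count drivers of the generator (background rate and
#' spikes per burst) by a common factor.
#'
#' @param factor multiplicative effect size.
#' @return Named multiplier vector.
#' @export
spike_driver_multipliers <- function(factor = 1.5) {
  c(background_rate = factor, spikes_per_burst_mean = factor)
}

#' Mean per-unit spike rate of a recording
#'
#' Mean over units of each unit's spike count over the complete statistics
#' bins divided by the binned span — the "spike rate" headline parameter,
#' computed without the full descriptor engine.
#'
#' @param rec an [mea_recording()].
#' @param bin_width statistics bin width, ms.
#' @return Spike rate in Hz.
#' @export
network_spike_rate <- function(rec, bin_width = 60000) {
  span <- analysis_span(rec, bin_width)
  if (span <= 0) return(NA_real_)
  hi <- rec$window[1] + span
  counts <- table(factor(
    rec$spikes$unit_id[rec$spikes$time_ms < hi], levels = rec$units))
  mean(as.numeric(counts)) / (span / 1000)
}
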