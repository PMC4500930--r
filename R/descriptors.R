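#' Descriptor configuration
#'
#' Constants of the multiparametric description. Defaults follow the analysis
#' conventions for developing cortical networks: 60 s statistics bins, 500 ms
#' spike-contrast segments, a 10 ms Gaussian kernel for burst rate profiles, a
#' 300 ms / 50%-of-units rule for network events, 10 s bins for the hamming
#' factor, and a 50% participation threshold for population bursts.
#'
#' @param bin_width statistics bin width, ms.
#' @param contrast_segment spike-contrast segment length, ms.
#' @param amplitude_kernel_bandwidth Gaussian kernel bandwidth for burst
#'   profiles, ms.
#' @param event_window coincidence window for network events, ms.
#' @param event_unit_fraction unit fraction required for an event, in (0, 1].
#' @param hamming_bin occupancy bin for the hamming factor, ms.
#' @param population_burst_fraction unit fraction required for a population
#'   burst, in (0, 1].
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(bin_width = 60000, contrast_segment = 500,
                              amplitude_kernel_bandwidth = 10,
                              event_window = 300, event_unit_fraction = 0.5,
                              hamming_bin = 10000,
                              population_burst_fraction = 0.5) {
  vals <- list(bin_width = bin_width, contrast_segment = contrast_segment,
               amplitude_kernel_bandwidth = amplitude_kernel_bandwidth,
               event_window = event_window,
               event_unit_fraction = event_unit_fraction,
               hamming_bin = hamming_bin,
               population_burst_fraction = population_burst_fraction)
  stopifnot(all(unlist(vals) > 0), event_unit_fraction <= 1,
            population_burst_fraction <= 1)
  structure(vals, class = "descriptor_config")
}

# length (ms) of the analysed span: the complete bins of the window
analysis_span <- function(rec, bin_width) {
  floor(diff(rec$window) / bin_width) * bin_width
}

primary_general <- c(
  "spike_count", "spike_rate", "isi_mean", "isi_median", "isi_min", "isi_max",
  "isi_cv", "burst_count", "burst_rate", "burst_period", "burst_period_cv",
  "spike_contrast", "pct_spikes_in_bursts", "tonic_spike_rate",
  "burst_duty_pct"
)
primary_burst <- c(
  "burst_duration", "burst_duration_cv", "spikes_in_burst",
  "spikes_in_burst_cv", "burst_spike_density", "burst_spike_density_cv",
  "burst_amplitude", "burst_area", "burst_area_cv", "burst_plateau",
  "burst_plateau_fraction", "burst_peak_time", "intra_burst_isi_mean",
  "intra_burst_isi_median", "intra_burst_isi_min", "intra_burst_isi_max",
  "intra_burst_isi_cv"
)
sync_feature_names <- c(
  "syn_all", "syn_all_cv", "syn_share", "syn_share_cv", "event_rate",
  "event_count", "pop_burst_duration", "pop_burst_spikes",
  "pop_burst_period", "pop_burst_period_cv", "hamming_factor",
  "hamming_factor_sd"
)

#' The activity feature registry
#'
#' The multiparametric description emits exactly 204 named features per
#' network: 32 primary per-unit scalars, each in six variants — the network
#' mean (the primary's own category), the SD / max / min across statistics
#' bins and the CVtime (all "oscillation"), and the CVnet (coefficient of
#' variation over units, "synchronization") — plus 12 network-level
#' synchronization features. The registry is versioned so feature tables are
#' comparable only within a registry version.
#'
#' @param version registry version identifier; only `"v1"` is defined.
#' @return A tibble with columns `name`, `category`, `primary`, `variant`,
#'   in the canonical feature order.
#' @export
feature_registry <- function(version = "v1") {
  if (!identical(version, "v1")) abort("unknown registry version.")
  prim <- tibble(
    primary = c(primary_general, primary_burst),
    base_category = c(rep("general activity", length(primary_general)),
                      rep("burst structure", length(primary_burst)))
  )
  variants <- tibble(
    variant = c("mean", "sd", "cvtime", "cvnet", "binmax", "binmin"),
    suffix = c("", "_sd", "_cvtime", "_cvnet", "_binmax", "_binmin")
  )
  reg <- tidyr::crossing(prim, variants) %>%
    mutate(
      name = paste0(.data$primary, .data$suffix),
      category = dplyr::case_when(
        .data$variant == "mean" ~ .data$base_category,
        .data$variant == "cvnet" ~ "synchronization",
        TRUE ~ "oscillation"
      )
    ) %>%
    arrange(match(.data$primary, prim$primary),
            match(.data$variant, variants$variant)) %>%
    select("name", "category", "primary", "variant")
  sync <- tibble(name = sync_feature_names, category = "synchronization",
                 primary = NA_character_, variant = "network")
  out <- bind_rows(reg, sync)
  stopifnot(nrow(out) == 204L, !anyDuplicated(out$name))
  out
}

#' The twelve headline parameters
#'
#' Canonical names of the twelve most descriptive features, three per
#' category.
#' @return Named character vector (names = category).
#' @export
named_parameters <- function() {
  c("general activity" = "spike_rate",
    "general activity" = "burst_rate",
    "general activity" = "spike_contrast",
    "burst structure" = "burst_duration",
    "burst structure" = "burst_amplitude",
    "burst structure" = "burst_spike_density",
    "synchronization" = "syn_all",
    "synchronization" = "syn_share",
    "synchronization" = "burst_rate_cvnet",
    "oscillation" = "burst_rate_sd",
    "oscillation" = "event_rate",
    "oscillation" = "hamming_factor")
}

# ---- burst rate profiles --------------------------------------------------

#' Onset-aligned burst rate profiles
#'
#' Each burst's instantaneous spike rate is estimated by Gaussian-kernel
#' smoothing of its spike times, aligned at burst onset and evaluated on a
#' common grid. Per burst the profile yields: `amplitude` (peak rate, Hz),
#' `area` (integral of the rate, i.e. the smoothed spike count), `plateau`
#' (width of the contiguous region around the peak at >= 90% of the peak, ms)
#' and `peak_time` (ms after onset).
#'
#' @param spike_list list of numeric spike-time vectors, one per burst (ms).
#' @param bandwidth Gaussian kernel bandwidth, ms.
#' @param grid_step profile grid step, ms; defaults to `bandwidth / 2`.
#' @return A list with `per_burst` (tibble of the four per-burst features),
#'   `grid` (ms, onset-aligned), and `mean_profile` (Hz, averaged over
#'   bursts).
#' @export
burst_profiles <- function(spike_list, bandwidth = 10, grid_step = NULL) {
  stopifnot(length(spike_list) > 0L)
  grid_step <- grid_step %||% max(bandwidth / 2, 0.5)
  rel <- purrr::map(spike_list, function(s) s - s[1L])
  max_dur <- max(purrr::map_dbl(rel, max))
  grid <- seq(-3 * bandwidth, max_dur + 3 * bandwidth, by = grid_step)
  prof <- vapply(rel, function(s) {
    # spikes/ms: sum of unit-mass Gaussians centred on the spikes
    rowSums(outer(grid, s, function(t, mu) dnorm(t, mu, bandwidth)))
  }, numeric(length(grid)))
  prof <- prof * 1000  # Hz
  feat_one <- function(p) {
    pk <- which.max(p)
    thr <- 0.9 * p[pk]
    lo <- pk
    while (lo > 1L && p[lo - 1L] >= thr) lo <- lo - 1L
    hi <- pk
    while (hi < length(p) && p[hi + 1L] >= thr) hi <- hi + 1L
    c(amplitude = p[pk],
      area = sum((p[-1L] + p[-length(p)]) / 2) * grid_step / 1000,
      plateau = (hi - lo) * grid_step,
      peak_time = grid[pk])
  }
  per_burst <- as_tibble(t(apply(prof, 2L, feat_one)))
  list(per_burst = per_burst, grid = grid,
       mean_profile = rowMeans(prof))
}

# ---- per-unit scalar engine ----------------------------------------------

# all 32 primary scalars for one unit over one sub-window [lo, hi) of the
# analysis span. `bursts_started`: bursts starting in [lo, hi) with per-burst
# profile columns; `bursts_all`: every burst of the unit (for duty overlap).
scalar_block <- function(times, member, bursts_started, bursts_all,
                         lo, hi, config) {
  span_s <- (hi - lo) / 1000
  n_sp <- length(times)
  isis <- if (n_sp >= 2L) diff(times) else numeric(0)
  # spike-contrast over complete segments of the sub-window
  nseg <- floor((hi - lo) / config$contrast_segment)
  contrast <- NA_real_
  if (nseg >= 2L) {
    cnt <- bin_counts(times, c(lo, hi), config$contrast_segment)
    a <- cnt[-length(cnt)]; b <- cnt[-1L]
    ok <- (a + b) > 0
    if (any(ok)) contrast <- mean(abs(a - b)[ok] / (a + b)[ok])
  }
  nb <- nrow(bursts_started)
  ibi <- if (nb >= 2L) {
    bursts_started$start_ms[-1L] - bursts_started$end_ms[-nb]
  } else numeric(0)
  duty <- 0
  if (nrow(bursts_all) > 0L) {
    ov <- pmin(bursts_all$end_ms, hi) - pmax(bursts_all$start_ms, lo)
    duty <- 100 * sum(pmax(ov, 0)) / (hi - lo)
  }
  intra <- if (nb > 0L) unlist(purrr::map(bursts_started$spikes, diff)) else numeric(0)
  dens <- if (nb > 0L) {
    purrr::map_dbl(bursts_started$spikes, function(s) 1000 / mean(diff(s)))
  } else numeric(0)
  c(
    spike_count = as.numeric(n_sp),
    spike_rate = n_sp / span_s,
    isi_mean = mean_or_na(isis), isi_median = if (length(isis)) median(isis) else NA_real_,
    isi_min = if (length(isis)) min(isis) else NA_real_,
    isi_max = if (length(isis)) max(isis) else NA_real_,
    isi_cv = cv(isis),
    burst_count = as.numeric(nb),
    burst_rate = nb / span_s,
    burst_period = mean_or_na(ibi), burst_period_cv = cv(ibi),
    spike_contrast = contrast,
    pct_spikes_in_bursts = if (n_sp > 0L) 100 * sum(member) / n_sp else NA_real_,
    tonic_spike_rate = sum(!member) / span_s,
    burst_duty_pct = duty,
    burst_duration = if (nb) mean(bursts_started$duration_ms) else NA_real_,
    burst_duration_cv = cv(bursts_started$duration_ms),
    spikes_in_burst = if (nb) mean(bursts_started$n_spikes) else NA_real_,
    spikes_in_burst_cv = cv(as.numeric(bursts_started$n_spikes)),
    burst_spike_density = mean_or_na(dens),
    burst_spike_density_cv = cv(dens),
    burst_amplitude = if (nb) mean(bursts_started$pb_amplitude) else NA_real_,
    burst_area = if (nb) mean(bursts_started$pb_area) else NA_real_,
    burst_area_cv = cv(bursts_started$pb_area),
    burst_plateau = if (nb) mean(bursts_started$pb_plateau) else NA_real_,
    burst_plateau_fraction = if (nb && mean(bursts_started$duration_ms) > 0) {
      mean(bursts_started$pb_plateau) / mean(bursts_started$duration_ms)
    } else NA_real_,
    burst_peak_time = if (nb) mean(bursts_started$pb_peak_time) else NA_real_,
    intra_burst_isi_mean = mean_or_na(intra),
    intra_burst_isi_median = if (length(intra)) median(intra) else NA_real_,
    intra_burst_isi_min = if (length(intra)) min(intra) else NA_real_,
    intra_burst_isi_max = if (length(intra)) max(intra) else NA_real_,
    intra_burst_isi_cv = cv(intra)
  )
}

#' Per-unit feature tables
#'
#' Computes the 32 primary per-unit scalars over the whole analysis span
#' (the complete statistics bins of the recording window) and per bin. Unit
#' values of `burst_amplitude`, `burst_area`, `burst_plateau` and
#' `burst_peak_time` come from the unit's onset-aligned *mean* burst profile;
#' per-bin values average the per-burst profile features of bursts starting in
#' the bin.
#'
#' @inheritParams detect_population_bursts
#' @param config a [descriptor_config()].
#' @return A list with `scalars` (tibble units x scalars) and `bins`
#'   (tibble unit x bin x scalars).
#' @export
unit_feature_tables <- function(rec, bursts, config = descriptor_config()) {
  span <- analysis_span(rec, config$bin_width)
  lo0 <- rec$window[1]
  n_bins <- span / config$bin_width
  res_scal <- vector("list", length(rec$units))
  res_bins <- vector("list", length(rec$units))
  for (ui in seq_along(rec$units)) {
    u <- rec$units[ui]
    times <- unit_spikes(rec, u)
    times <- times[times < lo0 + span]
    bu <- if (nrow(bursts) && "unit_id" %in% names(bursts)) {
      bursts[bursts$unit_id == u & bursts$start_ms < lo0 + span, , drop = FALSE]
    } else bursts[0, , drop = FALSE]
    # spike membership in bursts (bursts are disjoint and ordered)
    member <- rep(FALSE, length(times))
    if (nrow(bu) > 0L && length(times) > 0L) {
      idx <- findInterval(times, bu$start_ms)
      member <- idx > 0L & times <= bu$end_ms[pmax(idx, 1L)]
    }
    # per-burst profile features, computed once per unit
    if (nrow(bu) > 0L) {
      bp <- burst_profiles(bu$spikes, bandwidth = config$amplitude_kernel_bandwidth)
      bu$pb_amplitude <- bp$per_burst$amplitude
      bu$pb_area <- bp$per_burst$area
      bu$pb_plateau <- bp$per_burst$plateau
      bu$pb_peak_time <- bp$per_burst$peak_time
      mp <- profile_features(bp$grid, bp$mean_profile)
    } else {
      bu$pb_amplitude <- bu$pb_area <- bu$pb_plateau <-
        bu$pb_peak_time <- numeric(0)
      mp <- c(amplitude = NA_real_, area = NA_real_, plateau = NA_real_,
              peak_time = NA_real_)
    }
    sc <- scalar_block(times, member, bu, bu, lo0, lo0 + span, config)
    # unit-level profile features use the averaged profile
    sc["burst_amplitude"] <- mp[["amplitude"]]
    sc["burst_area"] <- mp[["area"]]
    sc["burst_plateau"] <- mp[["plateau"]]
    sc["burst_peak_time"] <- mp[["peak_time"]]
    sc["burst_plateau_fraction"] <-
      if (!is.na(mp[["plateau"]]) && !is.na(sc[["burst_duration"]]) &&
          sc[["burst_duration"]] > 0) mp[["plateau"]] / sc[["burst_duration"]]
      else NA_real_
    res_scal[[ui]] <- dplyr::bind_cols(tibble(unit_id = u), as_tibble(as.list(sc)))
    bb <- purrr::map(seq_len(n_bins), function(k) {
      blo <- lo0 + (k - 1) * config$bin_width
      bhi <- blo + config$bin_width
      in_bin <- times >= blo & times < bhi
      bu_k <- bu[bu$start_ms >= blo & bu$start_ms < bhi, , drop = FALSE]
      v <- scalar_block(times[in_bin], member[in_bin], bu_k, bu, blo, bhi,
                        config)
      dplyr::bind_cols(tibble(unit_id = u, bin = k), as_tibble(as.list(v)))
    })
    res_bins[[ui]] <- bind_rows(bb)
  }
  list(scalars = bind_rows(res_scal), bins = bind_rows(res_bins))
}

# profile features of an already-averaged profile
profile_features <- function(grid, p) {
  step <- grid[2L] - grid[1L]
  pk <- which.max(p)
  thr <- 0.9 * p[pk]
  lo <- pk
  while (lo > 1L && p[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk
  while (hi < length(p) && p[hi + 1L] >= thr) hi <- hi + 1L
  c(amplitude = p[pk],
    area = sum((p[-1L] + p[-length(p)]) / 2) * step / 1000,
    plateau = (hi - lo) * step,
    peak_time = grid[pk])
}

# variant aggregation over the per-unit tables
aggregate_variants <- function(uf) {
  scal <- uf$scalars
  bins <- uf$bins
  prim <- c(primary_general, primary_burst)
  out <- numeric(0)
  for (p in prim) {
    unit_vals <- scal[[p]]
    net_bin <- bins %>%
      group_by(.data$bin) %>%
      summarise(v = mean_or_na(.data[[p]])) %>%
      pull("v")
    ok_bins <- net_bin[is.finite(net_bin)]
    per_unit_cvtime <- bins %>%
      group_by(.data$unit_id) %>%
      summarise(v = cv(.data[[p]])) %>%
      pull("v")
    vals <- c(
      mean_or_na(unit_vals),
      if (length(ok_bins) >= 2L) stats::sd(ok_bins) else NA_real_,
      mean_or_na(per_unit_cvtime),
      cv(unit_vals),
      if (length(ok_bins)) max(ok_bins) else NA_real_,
      if (length(ok_bins)) min(ok_bins) else NA_real_
    )
    names(vals) <- paste0(p, c("", "_sd", "_cvtime", "_cvnet",
                               "_binmax", "_binmin"))
    out <- c(out, vals)
  }
  out
}

#' Assemble the full feature table of a network
#'
#' Runs burst detection (unless a burst table is supplied), the per-unit
#' scalar engine, and the network-level synchronization block, and returns the
#' complete 204-feature description of one network in registry order.
#' Undefined features of degenerate recordings (e.g. burst structure without
#' bursts) are reported as `NA`, never as zero.
#'
#' @inheritParams unit_feature_tables
#' @param bursts optional precomputed burst table from [detect_bursts()].
#' @param criteria a [burst_criteria()], used when `bursts` is missing.
#' @return A one-row tibble: `network_id`, `group`, `div`, then the 204
#'   registry features. The registry tibble is attached as attribute
#'   `"registry"`; `registry_version` as an attribute too.
#' @export
assemble_features <- function(rec, config = descriptor_config(),
                              criteria = burst_criteria(), bursts = NULL) {
  stopifnot(inherits(rec, "mea_recording"))
  bursts <- bursts %||% detect_bursts(rec, criteria)
  uf <- unit_feature_tables(rec, bursts, config)
  vals <- c(aggregate_variants(uf), sync_feature_block(rec, bursts, config))
  reg <- feature_registry("v1")
  stopifnot(all(reg$name %in% names(vals)))
  vals <- vals[reg$name]
  out <- dplyr::bind_cols(
    tibble(network_id = rec$network_id,
           group = rec$meta$group, div = rec$meta$div),
    as_tibble(as.list(vals))
  )
  attr(out, "registry") <- reg
  attr(out, "registry_version") <- "v1"
  out
}

#' Assemble feature tables for many recordings
#'
#' @param recs list of [mea_recording()] objects.
#' @inheritParams assemble_features
#' @return Tibble with one row per network (204 features + metadata).
#' @export
assemble_cohort_features <- function(recs, config = descriptor_config(),
                                     criteria = burst_criteria()) {
  out <- bind_rows(purrr::map(recs, assemble_features, config = config,
                              criteria = criteria))
  attr(out, "registry") <- feature_registry("v1")
  attr(out, "registry_version") <- "v1"
  out
}

# ---- the four standalone category operations ------------------------------

#' General activity descriptors
#'
#' Network means (over units) of spike rate, burst rate, spike contrast and
#' burst period. Units with fewer than two bursts contribute no interburst
#' interval; `burst_period_n_units` reports how many units did contribute.
#'
#' @inheritParams unit_feature_tables
#' @return One-row tibble: `spike_rate` (Hz), `burst_rate` (Hz),
#'   `spike_contrast`, `burst_period` (ms), `burst_period_n_units`.
#' @export
general_activity <- function(rec, bursts, config = descriptor_config()) {
  uf <- unit_feature_tables(rec, bursts, config)
  s <- uf$scalars
  tibble(
    spike_rate = mean_or_na(s$spike_rate),
    burst_rate = mean_or_na(s$burst_rate),
    spike_contrast = mean_or_na(s$spike_contrast),
    burst_period = mean_or_na(s$burst_period),
    burst_period_n_units = sum(is.finite(s$burst_period))
  )
}

#' Burst structure descriptors
#'
#' Network means (over units) of burst duration, spike density, spike count,
#' and the profile-based amplitude, area and plateau. All `NA` when the
#' network has no bursts.
#'
#' @inheritParams unit_feature_tables
#' @return One-row tibble: `burst_duration` (ms), `burst_amplitude` (Hz),
#'   `burst_spike_density` (Hz), `burst_area` (smoothed spikes per burst),
#'   `burst_plateau` (ms), `spikes_in_burst`.
#' @export
burst_structure <- function(rec, bursts, config = descriptor_config()) {
  uf <- unit_feature_tables(rec, bursts, config)
  s <- uf$scalars
  tibble(
    burst_duration = mean_or_na(s$burst_duration),
    burst_amplitude = mean_or_na(s$burst_amplitude),
    burst_spike_density = mean_or_na(s$burst_spike_density),
    burst_area = mean_or_na(s$burst_area),
    burst_plateau = mean_or_na(s$burst_plateau),
    spikes_in_burst = mean_or_na(s$spikes_in_burst)
  )
}

#' Synchronization descriptors
#'
#' Population-burst metrics, event rate, hamming factor, and the CVnet
#' (coefficient of variation over units) of a chosen primary feature.
#'
#' @inheritParams unit_feature_tables
#' @param cvnet_of primary per-unit scalar whose CVnet is reported.
#' @return One-row tibble: `syn_all` (ms), `syn_share`, `event_rate` (Hz),
#'   `hamming_factor`, `<cvnet_of>_cvnet`.
#' @export
synchronization <- function(rec, bursts, config = descriptor_config(),
                            cvnet_of = "burst_rate") {
  stopifnot(cvnet_of %in% c(primary_general, primary_burst))
  if (length(rec$units) < 2L) {
    warn("fewer than 2 units: pairwise synchronization metrics are undefined.")
  }
  sy <- sync_feature_block(rec, bursts, config)
  uf <- unit_feature_tables(rec, bursts, config)
  out <- tibble(
    syn_all = sy[["syn_all"]],
    syn_share = sy[["syn_share"]],
    event_rate = sy[["event_rate"]],
    hamming_factor = sy[["hamming_factor"]]
  )
  out[[paste0(cvnet_of, "_cvnet")]] <- cv(uf$scalars[[cvnet_of]])
  out
}

#' Oscillation descriptors
#'
#' Temporal-irregularity measures: SDs across 60 s bins of the network-mean
#' per-bin values and CVtime (mean over units of each unit's across-bin
#' coefficient of variation) of primary activity features. Higher values mean
#' less regular general activity or burst structure.
#'
#' @inheritParams unit_feature_tables
#' @return One-row tibble: `spike_rate_sd`, `burst_rate_sd`,
#'   `spike_rate_cvtime`, `burst_rate_cvtime`, `burst_duration_cvtime`.
#' @export
oscillation <- function(rec, bursts, config = descriptor_config()) {
  if (floor(diff(rec$window) / config$bin_width) < 2L) {
    warn("fewer than 2 complete bins: oscillation metrics are undefined.")
    return(tibble(spike_rate_sd = NA_real_, burst_rate_sd = NA_real_,
                  spike_rate_cvtime = NA_real_, burst_rate_cvtime = NA_real_,
                  burst_duration_cvtime = NA_real_))
  }
  v <- aggregate_variants(unit_feature_tables(rec, bursts, config))
  tibble(
    spike_rate_sd = v[["spike_rate_sd"]],
    burst_rate_sd = v[["burst_rate_sd"]],
    spike_rate_cvtime = v[["spike_rate_cvtime"]],
    burst_rate_cvtime = v[["burst_rate_cvtime"]],
    burst_duration_cvtime = v[["burst_duration_cvtime"]]
  )
}

#' Coefficient of variation over the network
#'
#' `sd / mean` (sample SD) of a per-unit feature vector; the spatial
#' variability of a feature across the units of one network. Zero when all
#' units agree; `NA` below two finite values or at zero mean.
#'
#' @param x numeric per-unit values.
#' @return Scalar CVnet.
#' @export
cvnet <- function(x) cv(x)

#' Write a cohort feature table and its category manifest
#'
#' @param features tibble from [assemble_cohort_features()].
#' @param path output path for the feature table (CSV); the category manifest
#'   is written next to it as `<stem>_registry.csv`.
#' @return `features`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  readr::write_csv(feature_registry("v1"),
                   paste0(tools::file_path_sans_ext(path), "_registry.csv"))
  invisible(features)
}
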