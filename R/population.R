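#' Detect population bursts
#'
#' A population burst is an episode in which at least a required fraction of
#' the network's units burst near-simultaneously. The detector slides a
#' half-open coincidence window of `window_ms` across the recording and counts
#' the units having a burst overlapping the window; maximal regions where this
#' count reaches `fraction` of all units (overlapping regions merged) become
#' population bursts. With `fraction = 0.5` and `window_ms = 300` the same
#' detector defines the *events* behind the event rate.
#'
#' @param rec an [mea_recording()].
#' @param bursts recording-level burst table from [detect_bursts()].
#' @param window_ms coincidence window, ms.
#' @param fraction required participating fraction of units, in (0, 1].
#' @return A tibble with one row per population burst: `pb_index`, `start_ms`,
#'   `end_ms`, `center_ms` (spike-count-weighted mean of member burst
#'   midpoints), `n_units`, `fraction` (participating units / all units),
#'   `n_member_bursts`, `n_spikes` (spikes in member bursts), and a `member`
#'   list-column of per-burst rows (`unit_id`, `midpoint_ms`, `n_spikes`).
#' @export
detect_population_bursts <- function(rec, bursts, window_ms = 300,
                                     fraction = 0.5) {
  stopifnot(inherits(rec, "mea_recording"), window_ms > 0,
            fraction > 0, fraction <= 1)
  n_units <- length(rec$units)
  empty <- tibble(pb_index = integer(0), start_ms = numeric(0),
                  end_ms = numeric(0), center_ms = numeric(0),
                  n_units = integer(0), fraction = numeric(0),
                  n_member_bursts = integer(0), n_spikes = integer(0),
                  member = list())
  if (!is.data.frame(bursts) || nrow(bursts) == 0L) return(empty)
  # per unit: merged occupancy intervals in window-start space; a window
  # [t, t + w) sees burst [s, e] iff t is in (s - w, e]
  occ <- bursts %>%
    mutate(lo = .data$start_ms - window_ms, hi = .data$end_ms) %>%
    group_by(.data$unit_id) %>%
    arrange(.data$lo, .by_group = TRUE) %>%
    mutate(grp = cumsum(.data$lo > dplyr::lag(cummax(.data$hi),
                                              default = -Inf))) %>%
    group_by(.data$unit_id, .data$grp) %>%
    summarise(lo = min(.data$lo), hi = max(.data$hi), .groups = "drop")
  # sweep unit counts over interval boundaries
  ev <- bind_rows(
    tibble(t = occ$lo, d = 1L),
    tibble(t = occ$hi, d = -1L)
  ) %>% arrange(.data$t, dplyr::desc(.data$d))
  b <- cumsum(ev$d)
  need <- fraction * n_units - 1e-9
  hot <- b >= need
  if (!any(hot)) return(empty)
  r <- rle(hot)
  seg_end_idx <- cumsum(r$lengths)
  seg_start_idx <- seg_end_idx - r$lengths + 1L
  hot_k <- which(r$values)
  reg_lo <- ev$t[seg_start_idx[hot_k]]
  # a hot stretch ends when the count drops at the next boundary
  reg_hi <- ev$t[pmin(seg_end_idx[hot_k] + 1L, nrow(ev))]
  # extend by the coincidence window back into spike time, then merge
  # overlapping extended regions
  lo <- reg_lo
  hi <- reg_hi + window_ms
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  grp <- cumsum(c(1L, as.integer(lo[-1L] > cummax(hi)[-length(hi)])))
  lo <- as.numeric(tapply(lo, grp, min))
  hi <- as.numeric(tapply(hi, grp, max))
  lo <- pmax(lo, rec$window[1])
  hi <- pmin(hi, rec$window[2])
  mid <- (bursts$start_ms + bursts$end_ms) / 2
  res <- purrr::map(seq_along(lo), function(i) {
    in_pb <- bursts$start_ms < hi[i] & bursts$end_ms >= lo[i]
    mb <- bursts[in_pb, , drop = FALSE]
    if (nrow(mb) == 0L) return(NULL)
    mids <- mid[in_pb]
    ctr <- sum(mids * mb$n_spikes) / sum(mb$n_spikes)
    n_part <- dplyr::n_distinct(mb$unit_id)
    tibble(
      start_ms = lo[i], end_ms = hi[i], center_ms = ctr,
      n_units = n_part,
      fraction = n_part / .env$n_units,
      n_member_bursts = nrow(mb), n_spikes = as.integer(sum(mb$n_spikes)),
      member = list(tibble(unit_id = mb$unit_id, midpoint_ms = mids,
                           n_spikes = mb$n_spikes))
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) return(empty)
  mutate(out, pb_index = dplyr::row_number(), .before = 1)
}

#' Hamming similarity of burst occupancy patterns
#'
#' Each unit is reduced to a binary vector over consecutive bins
#' (`bin_ms`, default 10 s): 1 if any burst overlaps the bin. The hamming
#' factor of a unit pair is `1 - hamming_distance / n_bins`; the network value
#' is the mean over all unit pairs. It is 1 exactly when all units share the
#' same burst occupancy pattern.
#'
#' @inheritParams detect_population_bursts
#' @param bin_ms occupancy bin width, ms.
#' @return A list with `factor` (mean pairwise similarity), `sd` (sd over
#'   pairs), and the binary `occupancy` matrix (units x bins).
#' @export
hamming_similarity <- function(rec, bursts, bin_ms = 10000) {
  n_bins <- floor(diff(rec$window) / bin_ms)
  units <- rec$units
  if (length(units) < 2L || n_bins < 1L) {
    return(list(factor = NA_real_, sd = NA_real_,
                occupancy = matrix(0L, length(units), max(n_bins, 0L))))
  }
  edges0 <- rec$window[1] + (seq_len(n_bins) - 1L) * bin_ms
  occ <- matrix(0L, nrow = length(units), ncol = n_bins,
                dimnames = list(units, NULL))
  if (is.data.frame(bursts) && nrow(bursts) > 0L) {
    for (i in seq_len(nrow(bursts))) {
      b0 <- max(1L, floor((bursts$start_ms[i] - rec$window[1]) / bin_ms) + 1L)
      b1 <- min(n_bins, floor((bursts$end_ms[i] - rec$window[1]) / bin_ms) + 1L)
      if (b0 <= b1) occ[bursts$unit_id[i], b0:b1] <- 1L
    }
  }
  agree <- (occ %*% t(occ) + (1L - occ) %*% t(1L - occ)) / n_bins
  pairs <- agree[upper.tri(agree)]
  list(factor = mean(pairs),
       sd = if (length(pairs) > 1L) stats::sd(pairs) else NA_real_,
       occupancy = occ)
}

# the 12 network-level synchronization features of the registry
sync_feature_block <- function(rec, bursts, config) {
  span_s <- analysis_span(rec, config$bin_width) / 1000
  pb <- detect_population_bursts(rec, bursts,
                                 window_ms = config$event_window,
                                 fraction = config$population_burst_fraction)
  evs <- if (identical(config$event_window, 300) &&
             identical(config$population_burst_fraction,
                       config$event_unit_fraction)) {
    pb
  } else {
    detect_population_bursts(rec, bursts, window_ms = 300,
                             fraction = config$event_unit_fraction)
  }
  hm <- hamming_similarity(rec, bursts, bin_ms = config$hamming_bin)
  if (nrow(pb) > 0L) {
    dists <- purrr::map(pb$member, function(m) {
      ctr <- sum(m$midpoint_ms * m$n_spikes) / sum(m$n_spikes)
      abs(m$midpoint_ms - ctr)
    })
    per_pb_dist <- purrr::map_dbl(dists, mean)
    syn_all <- mean(unlist(dists))
    syn_all_cv <- cv(per_pb_dist)
    syn_share <- mean(pb$fraction)
    syn_share_cv <- cv(pb$fraction)
    centers <- pb$center_ms
    per <- if (length(centers) > 1L) diff(sort(centers)) else numeric(0)
    pop_burst_period <- mean_or_na(per)
    pop_burst_period_cv <- cv(per)
    pop_burst_duration <- mean(pb$end_ms - pb$start_ms)
    pop_burst_spikes <- mean(pb$n_spikes)
  } else {
    syn_all <- syn_all_cv <- syn_share <- syn_share_cv <- NA_real_
    pop_burst_period <- pop_burst_period_cv <- NA_real_
    pop_burst_duration <- pop_burst_spikes <- NA_real_
  }
  c(syn_all = syn_all, syn_all_cv = syn_all_cv,
    syn_share = syn_share, syn_share_cv = syn_share_cv,
    event_rate = nrow(evs) / span_s, event_count = as.numeric(nrow(evs)),
    pop_burst_duration = pop_burst_duration,
    pop_burst_spikes = pop_burst_spikes,
    pop_burst_period = pop_burst_period,
    pop_burst_period_cv = pop_burst_period_cv,
    hamming_factor = hm$factor, hamming_factor_sd = hm$sd)
}
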