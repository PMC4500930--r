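#' Burst detection criteria (max-interval / ISI method)
#'
#' Five thresholds define a single-unit burst. A burst is *seeded* by a spike
#' pair whose interspike interval (ISI) is at most `max_isi_start`; once open
#' it keeps absorbing spikes while the ISI stays strictly below `min_isi_end`,
#' and closes at the last absorbed spike when an ISI reaches `min_isi_end`.
#' Consecutive bursts separated by a gap strictly smaller than
#' `min_interburst_interval` are merged (transitively), and only merged bursts
#' with at least `min_spikes` spikes and a duration of at least
#' `min_burst_duration` are kept. The defaults are the standard values for
#' developing cortical cultures: 40 / 200 / 100 / 10 ms and 2 spikes.
#'
#' @param max_isi_start maximum ISI to start a burst, ms.
#' @param min_isi_end minimum ISI to end a burst, ms.
#' @param min_interburst_interval minimum gap between bursts, ms; closer
#'   bursts are merged.
#' @param min_burst_duration minimum burst duration, ms.
#' @param min_spikes minimum number of spikes in a burst.
#' @return A list of class `burst_criteria`.
#' @export
burst_criteria <- function(max_isi_start = 40, min_isi_end = 200,
                           min_interburst_interval = 100,
                           min_burst_duration = 10, min_spikes = 2) {
  stopifnot(max_isi_start > 0, min_isi_end > 0, min_interburst_interval > 0,
            min_burst_duration > 0, min_spikes >= 2,
            max_isi_start <= min_isi_end)
  structure(list(max_isi_start = max_isi_start, min_isi_end = min_isi_end,
                 min_interburst_interval = min_interburst_interval,
                 min_burst_duration = min_burst_duration,
                 min_spikes = min_spikes),
            class = "burst_criteria")
}

empty_burst_table <- function(unit_col = FALSE) {
  out <- tibble(burst_index = integer(0), start_ms = numeric(0),
                end_ms = numeric(0), duration_ms = numeric(0),
                n_spikes = integer(0), spikes = list())
  if (unit_col) out <- mutate(out, unit_id = character(0), .before = 1)
  out
}

#' Detect bursts in spike trains
#'
#' Applies the ISI (max-interval) burst detector described in
#' [burst_criteria()]. The method is generic: on a numeric vector it treats the
#' vector as one unit's ordered spike times; on an [mea_recording()] it runs
#' per unit and stacks the results.
#'
#' @param x numeric spike times (ms, ascending) or an [mea_recording()].
#' @param criteria a [burst_criteria()].
#' @param ... unused.
#' @return A tibble with one row per burst: `start_ms`, `end_ms`,
#'   `duration_ms`, `n_spikes`, and a `spikes` list-column holding the member
#'   spike times. The recording method prepends `unit_id`. Bursts of one unit
#'   are disjoint, ordered, and each is a contiguous run of the unit's spikes.
#' @examples
#' detect_bursts(c(0, 20, 40, 60, 400, 420, 1400))
#' @export
detect_bursts <- function(x, criteria = burst_criteria(), ...) {
  UseMethod("detect_bursts")
}

#' @rdname detect_bursts
#' @export
detect_bursts.numeric <- function(x, criteria = burst_criteria(), ...) {
  n <- length(x)
  if (n < 2L) return(empty_burst_table())
  if (is.unsorted(x, strictly = TRUE)) {
    abort("spike times must be strictly ascending.")
  }
  isi <- diff(x)
  cont <- isi < criteria$min_isi_end     # ISI that keeps an open burst open
  open <- isi <= criteria$max_isi_start  # ISI that can seed a burst
  # maximal runs of continuation ISIs; a burst occupies the suffix of a run
  # starting at its first seeding ISI
  r <- rle(cont)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_sp <- integer(0); last_sp <- integer(0)
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    seed_rel <- which(open[a:b])
    if (length(seed_rel) == 0L) next
    s <- a + seed_rel[1L] - 1L
    first_sp <- c(first_sp, s)        # spike index opening the burst
    last_sp <- c(last_sp, b + 1L)     # last spike of the run
  }
  if (length(first_sp) == 0L) return(empty_burst_table())
  # merge bursts separated by a gap < min_interburst_interval (transitive)
  if (length(first_sp) > 1L) {
    gap <- x[first_sp[-1L]] - x[last_sp[-length(last_sp)]]
    grp <- cumsum(c(1L, as.integer(gap >= criteria$min_interburst_interval)))
    first_sp <- tapply(first_sp, grp, min)
    last_sp <- tapply(last_sp, grp, max)
  }
  out <- tibble(
    start_ms = x[first_sp], end_ms = x[last_sp],
    n_spikes = as.integer(last_sp - first_sp + 1L),
    spikes = purrr::map2(first_sp, last_sp, function(i, j) x[i:j])
  ) %>%
    mutate(duration_ms = .data$end_ms - .data$start_ms) %>%
    filter(.data$n_spikes >= criteria$min_spikes,
           .data$duration_ms >= criteria$min_burst_duration) %>%
    mutate(burst_index = dplyr::row_number()) %>%
    select("burst_index", "start_ms", "end_ms", "duration_ms",
           "n_spikes", "spikes")
  out
}

#' @rdname detect_bursts
#' @export
detect_bursts.mea_recording <- function(x, criteria = burst_criteria(), ...) {
  per_unit <- purrr::map(x$units, function(u) {
    b <- detect_bursts(unit_spikes(x, u), criteria)
    if (nrow(b)) mutate(b, unit_id = u, .before = 1) else NULL
  })
  out <- bind_rows(per_unit)
  if (nrow(out) == 0L) return(empty_burst_table(unit_col = TRUE))
  out
}

#' Per-bin burst counts and interburst intervals
#'
#' Each burst is assigned to the complete bin containing its start; interburst
#' intervals are the gaps from one burst's end to the next burst's start.
#'
#' @param bursts a one-unit burst table from [detect_bursts()], ordered and
#'   disjoint.
#' @param window half-open recording window, ms.
#' @param bin_width bin width, ms.
#' @return A list with `counts` (integer per complete bin) and
#'   `interburst_intervals_ms` (numeric, length `nrow(bursts) - 1` or 0).
#' @export
burst_train_summary <- function(bursts, window, bin_width) {
  stopifnot(is.data.frame(bursts))
  if (nrow(bursts) > 1L) {
    o <- order(bursts$start_ms)
    bursts <- bursts[o, , drop = FALSE]
    if (any(bursts$start_ms[-1L] <= bursts$end_ms[-nrow(bursts)])) {
      abort("bursts overlap; upstream invariant breached.")
    }
  }
  counts <- bin_counts(bursts$start_ms, window, bin_width)
  ibi <- if (nrow(bursts) > 1L) {
    bursts$start_ms[-1L] - bursts$end_ms[-nrow(bursts)]
  } else numeric(0)
  list(counts = counts, interburst_intervals_ms = ibi)
}

#' Export a burst table
#'
#' Writes `network_id,unit_id,burst_index,start_ms,end_ms,n_spikes` as
#' delimiter-separated text.
#'
#' @param bursts recording-level burst table from [detect_bursts()].
#' @param network_id network identifier stamped on every row.
#' @param path output file path.
#' @return The written tibble, invisibly.
#' @export
write_burst_table <- function(bursts, network_id, path) {
  out <- bursts %>%
    mutate(network_id = network_id) %>%
    select("network_id", "unit_id", "burst_index", "start_ms", "end_ms",
           "n_spikes")
  readr::write_csv(out, path)
  invisible(out)
}
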