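#' Construct a network recording
#'
#' A network recording holds the spike trains of all sorted units of one
#' cultured network over a common, half-open observation window
#' `[window[1], window[2])` in milliseconds. Spike times are stored as a tidy
#' tibble with one row per spike; silent units (zero spikes) are retained via
#' the `units` argument because they enter network-level denominators.
#'
#' @param spikes data frame with columns `unit_id`, `time_ms` and optionally
#'   `electrode_id`; one row per spike.
#' @param window numeric length-2, `c(t_start_ms, t_end_ms)`; the half-open
#'   recording window.
#' @param network_id identifier of the network (well).
#' @param units character vector of all unit identifiers, including units
#'   without spikes. Defaults to the units present in `spikes`.
#' @param group,div,well optional metadata: treatment group label, culture age
#'   in days in vitro, and well identifier.
#' @return An object of class `mea_recording`: a list with elements `network_id`,
#'   `spikes` (tibble, sorted by unit and time), `window`, `units`, and `meta`.
#' @examples
#' rec <- mea_recording(
#'   tibble::tibble(unit_id = "u1", time_ms = c(10, 50, 400)),
#'   window = c(0, 1000)
#' )
#' rec
#' @export
mea_recording <- function(spikes, window, network_id = "net1", units = NULL,
                          group = NA_character_, div = NA_real_,
                          well = NA_character_) {
  if (!is.data.frame(spikes)) abort("`spikes` must be a data frame.")
  spikes <- as_tibble(spikes)
  if (!all(c("unit_id", "time_ms") %in% names(spikes))) {
    abort("`spikes` needs columns `unit_id` and `time_ms`.")
  }
  if (!"electrode_id" %in% names(spikes)) spikes$electrode_id <- NA_character_
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$time_ms <- as.numeric(spikes$time_ms)
  if (length(window) != 2L || !is.numeric(window) || diff(window) <= 0) {
    abort("`window` must be c(start, end) with end > start (ms).")
  }
  window <- as.numeric(window)
  units <- as.character(units %||% unique(spikes$unit_id))
  if (anyDuplicated(units)) abort("unit identifiers must be unique.")
  if (length(units) < 1L) abort("a recording needs at least one unit.")
  if (!all(spikes$unit_id %in% units)) {
    abort("`spikes` contains unit_ids absent from `units`.")
  }
  spikes <- spikes[order(spikes$unit_id, spikes$time_ms), , drop = FALSE]
  bad <- spikes$time_ms < window[1] | spikes$time_ms >= window[2]
  if (any(bad)) {
    abort(sprintf(
      "%d spike(s) outside the declared window [%g, %g); first offender: unit %s at %g ms.",
      sum(bad), window[1], window[2],
      spikes$unit_id[which(bad)[1]], spikes$time_ms[which(bad)[1]]
    ))
  }
  if (nrow(spikes) > 1L) {
    same_unit <- spikes$unit_id[-1L] == spikes$unit_id[-nrow(spikes)]
    tied <- same_unit & diff(spikes$time_ms) <= 0
    if (any(tied)) {
      abort(sprintf(
        "spike times must be strictly ascending within a unit; offending unit(s): %s",
        paste(unique(spikes$unit_id[which(tied)]), collapse = ", ")
      ))
    }
  }
  structure(
    list(
      network_id = as.character(network_id),
      spikes = spikes[, c("unit_id", "electrode_id", "time_ms")],
      window = window,
      units = units,
      meta = list(group = group, div = div, well = well)
    ),
    class = "mea_recording"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %s: %d unit(s), %d spikes, window [%g, %g) ms (%.1f min)\n",
    x$network_id, length(x$units), nrow(x$spikes),
    x$window[1], x$window[2], diff(x$window) / 60000
  ))
  if (!is.na(x$meta$group)) {
    cat(sprintf("  group=%s div=%s well=%s\n", x$meta$group,
                format(x$meta$div), format(x$meta$well)))
  }
  invisible(x)
}

#' Spike times of one unit
#'
#' @param rec an [mea_recording()].
#' @param unit_id unit identifier.
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
unit_spikes <- function(rec, unit_id) {
  stopifnot(inherits(rec, "mea_recording"))
  rec$spikes$time_ms[rec$spikes$unit_id == unit_id]
}

#' Analysis window policy
#'
#' Recordings are analysed over the stable activity phase, taken as the final
#' `stable_phase_duration` of the recording, and summarised in consecutive
#' bins of `bin_width`. Defaults correspond to the last 30 min analysed in
#' 60 s bins.
#'
#' @param stable_phase_duration length of the analysed tail, ms.
#' @param bin_width bin width for per-bin statistics, ms.
#' @return A list of class `analysis_window_policy`.
#' @export
analysis_window_policy <- function(stable_phase_duration = 1800000,
                                   bin_width = 60000) {
  stopifnot(stable_phase_duration > 0, bin_width > 0,
            stable_phase_duration >= bin_width)
  structure(list(stable_phase_duration = stable_phase_duration,
                 bin_width = bin_width),
            class = "analysis_window_policy")
}

#' Restrict a recording to its stable activity phase
#'
#' Keeps the final `policy$stable_phase_duration` milliseconds of the
#' recording and re-references spike times to the new start, so the returned
#' window is `[0, stable_phase_duration)`. Applying the operation twice equals
#' applying it once.
#'
#' @inheritParams unit_spikes
#' @param policy an [analysis_window_policy()].
#' @return A new `mea_recording`.
#' @export
select_stable_phase <- function(rec, policy = analysis_window_policy()) {
  stopifnot(inherits(rec, "mea_recording"))
  dur <- policy$stable_phase_duration
  if (diff(rec$window) < dur) {
    abort(sprintf(
      "recording %s is %.0f ms long; cannot select a %.0f ms stable phase.",
      rec$network_id, diff(rec$window), dur
    ))
  }
  t0 <- rec$window[2] - dur
  keep <- rec$spikes$time_ms >= t0
  spikes <- rec$spikes[keep, , drop = FALSE]
  spikes$time_ms <- spikes$time_ms - t0
  mea_recording(spikes, window = c(0, dur), network_id = rec$network_id,
                units = rec$units, group = rec$meta$group, div = rec$meta$div,
                well = rec$meta$well)
}

#' Per-bin spike counts
#'
#' Counts events in consecutive half-open bins `[k*w, (k+1)*w)` covering the
#' window. A trailing partial bin (window length not a multiple of the bin
#' width) is dropped, so only complete bins are reported.
#'
#' @param times numeric event times, ms.
#' @param window numeric length-2 half-open window, ms.
#' @param bin_width bin width, ms.
#' @return Integer vector of per-bin counts over the complete bins.
#' @export
bin_counts <- function(times, window, bin_width) {
  stopifnot(bin_width > 0, length(window) == 2L)
  n_bins <- floor((window[2] - window[1]) / bin_width)
  if (n_bins < 1L) return(integer(0))
  span_end <- window[1] + n_bins * bin_width
  times <- times[times >= window[1] & times < span_end]
  idx <- floor((times - window[1]) / bin_width) + 1L
  tabulate(idx, nbins = n_bins)
}

# ---- tabular / hierarchical I/O ------------------------------------------

meta_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.", tools::file_ext(path))
}

#' Read a network recording
#'
#' Two on-disk layouts are supported. `"tabular"` is delimiter-separated text
#' with header `network_id,unit_id,electrode_id,time_ms` plus a side-car
#' metadata file (`<stem>_meta.<ext>`) with header
#' `network_id,group,div,well,window_start_ms,window_end_ms`; the metadata
#' file also fixes the full unit roster when a `units` column
#' (semicolon-separated) is present, so silent units survive the round trip.
#' `"hierarchical"` is a nested native-serialization layout: one node per
#' network holding one numeric vector of spike times per unit, with window
#' and metadata stored as attributes.
#'
#' @param path file path.
#' @param format `"tabular"` or `"hierarchical"`.
#' @param network_id which network to return when the file holds several;
#'   mandatory in that case.
#' @param meta_path side-car path for the tabular layout; defaults to
#'   `<stem>_meta.<ext>`.
#' @return An [mea_recording()].
#' @export
read_recording <- function(path, format = c("tabular", "hierarchical"),
                           network_id = NULL, meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tabular") {
    spikes <- readr::read_csv(path, show_col_types = FALSE,
                              col_types = readr::cols(
                                network_id = readr::col_character(),
                                unit_id = readr::col_character(),
                                electrode_id = readr::col_character(),
                                time_ms = readr::col_double()
                              ))
    mp <- meta_path %||% meta_path_for(path)
    if (!file.exists(mp)) abort(sprintf("metadata side-car not found: %s", mp))
    meta <- readr::read_csv(mp, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character(),
                                                    div = readr::col_double(),
                                                    window_start_ms = readr::col_double(),
                                                    window_end_ms = readr::col_double()))
    ids <- unique(meta$network_id)
    network_id <- network_id %||% if (length(ids) == 1L) ids else
      abort("file holds several networks; pass `network_id`.")
    m <- meta[meta$network_id == network_id, , drop = FALSE]
    if (nrow(m) != 1L) abort(sprintf("network %s not found in metadata.", network_id))
    sp <- spikes[spikes$network_id == network_id, , drop = FALSE]
    units <- if ("units" %in% names(m) && !is.na(m$units)) {
      strsplit(m$units, ";", fixed = TRUE)[[1]]
    } else unique(sp$unit_id)
    mea_recording(sp[, c("unit_id", "electrode_id", "time_ms")],
                  window = c(m$window_start_ms, m$window_end_ms),
                  network_id = network_id, units = units,
                  group = m$group, div = m$div, well = m$well)
  } else {
    obj <- readRDS(path)
    ids <- names(obj)
    network_id <- network_id %||% if (length(ids) == 1L) ids else
      abort("file holds several networks; pass `network_id`.")
    node <- obj[[network_id]]
    if (is.null(node)) abort(sprintf("network %s not found.", network_id))
    spikes <- purrr::imap_dfr(node, function(times, uid) {
      tibble(unit_id = uid, time_ms = as.numeric(times))
    })
    mea_recording(spikes, window = attr(node, "window"),
                  network_id = network_id,
                  units = names(node),
                  group = attr(node, "group") %||% NA_character_,
                  div = attr(node, "div") %||% NA_real_,
                  well = attr(node, "well") %||% NA_character_)
  }
}

#' Write a network recording
#'
#' Inverse of [read_recording()]; both layouts round-trip recordings exactly.
#'
#' @inheritParams unit_spikes
#' @inheritParams read_recording
#' @return The input `rec`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tabular", "hierarchical"),
                            meta_path = NULL) {
  stopifnot(inherits(rec, "mea_recording"))
  format <- match.arg(format)
  if (format == "tabular") {
    out <- mutate(rec$spikes, network_id = rec$network_id) %>%
      select("network_id", "unit_id", "electrode_id", "time_ms")
    readr::write_csv(out, path)
    meta <- tibble(
      network_id = rec$network_id,
      group = rec$meta$group, div = rec$meta$div, well = rec$meta$well,
      window_start_ms = rec$window[1], window_end_ms = rec$window[2],
      units = paste(rec$units, collapse = ";")
    )
    readr::write_csv(meta, meta_path %||% meta_path_for(path))
  } else {
    node <- lapply(rec$units, function(u) unit_spikes(rec, u))
    names(node) <- rec$units
    attr(node, "window") <- rec$window
    attr(node, "group") <- rec$meta$group
    attr(node, "div") <- rec$meta$div
    attr(node, "well") <- rec$meta$well
    obj <- setNames(list(node), rec$network_id)
    saveRDS(obj, path)
  }
  invisible(rec)
}
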