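#' Stimulation plan (modulation-envelope timing)
#'
#' Describes the timing of a pulse-modulated field-exposure protocol: a
#' high-frequency carrier (kept as metadata only — the computable content is
#' the low-frequency on/off envelope) is switched on for a fixed fraction
#' (`duty`) of every modulation cycle. The default plan is two consecutive
#' 30 min sessions modulated at 10 Hz then 16 Hz with 50% duty, i.e. 100 ms
#' cycles with 50 ms on-phase followed by 62.5 ms cycles with 31.25 ms
#' on-phase.
#'
#' @param session_sequence ordered modulation frequencies, Hz, one per
#'   session.
#' @param duty on-fraction of each cycle, in (0, 1).
#' @param session_duration duration of each session, ms.
#' @param carrier_frequency carrier frequency, Hz (metadata).
#' @return A list of class `stimulus_plan`.
#' @export
stimulus_plan <- function(session_sequence = c(10, 16), duty = 0.5,
                          session_duration = 1800000,
                          carrier_frequency = 150e6) {
  stopifnot(length(session_sequence) >= 1L, all(session_sequence > 0),
            duty > 0, duty < 1, session_duration > 0)
  structure(list(session_sequence = session_sequence, duty = duty,
                 session_duration = session_duration,
                 carrier_frequency = carrier_frequency),
            class = "stimulus_plan")
}

#' Cycle timing of a stimulation plan
#'
#' @param plan a [stimulus_plan()].
#' @return One row per session: `session`, `modulation_hz`, `cycle_ms`
#'   (`1000 / f`), `on_ms` (`duty * cycle`), `off_ms`.
#' @examples
#' cycle_timing(stimulus_plan())  # 100/50 ms at 10 Hz, 62.5/31.25 ms at 16 Hz
#' @export
cycle_timing <- function(plan) {
  stopifnot(inherits(plan, "stimulus_plan"))
  if (any(plan$session_sequence <= 0)) abort("modulation frequency must be > 0.")
  tibble(
    session = seq_along(plan$session_sequence),
    modulation_hz = plan$session_sequence,
    cycle_ms = 1000 / plan$session_sequence,
    on_ms = plan$duty * 1000 / plan$session_sequence,
    off_ms = (1 - plan$duty) * 1000 / plan$session_sequence
  )
}

#' On-intervals of the stimulation envelope
#'
#' Enumerates the on-phases of every cycle over the concatenated sessions.
#' Within a session, cycle `k` (0-based) is on during
#' `[k * cycle, k * cycle + on_phase)`, re-referenced to session start. A
#' final cycle cut short by the session end is emitted truncated, so total
#' on-time stays `duty * total_duration` up to at most one truncated cycle.
#'
#' @param plan a [stimulus_plan()].
#' @return A tibble: `session`, `modulation_hz`, `cycle_index` (1-based),
#'   `on_start_ms`, `on_end_ms` (relative to session start), and
#'   `session_start_ms` (session offset in the concatenated protocol).
#' @export
stimulus_envelope <- function(plan) {
  ct <- cycle_timing(plan)
  purrr::pmap_dfr(ct, function(session, modulation_hz, cycle_ms, on_ms,
                               off_ms) {
    n_cycles <- ceiling(plan$session_duration / cycle_ms)
    starts <- (seq_len(n_cycles) - 1) * cycle_ms
    ends <- pmin(starts + on_ms, plan$session_duration)
    keep <- starts < plan$session_duration
    tibble(session = session, modulation_hz = modulation_hz,
           cycle_index = seq_len(n_cycles)[keep],
           on_start_ms = starts[keep], on_end_ms = ends[keep],
           session_start_ms = (session - 1) * plan$session_duration)
  })
}

#' Export a stimulation envelope
#'
#' Writes `session,cycle_index,on_start_ms,on_end_ms` as delimiter-separated
#' text.
#'
#' @param plan a [stimulus_plan()].
#' @param path output path.
#' @return The envelope tibble, invisibly.
#' @export
write_envelope <- function(plan, path) {
  env <- stimulus_envelope(plan) %>%
    select("session", "cycle_index", "on_start_ms", "on_end_ms")
  readr::write_csv(env, path)
  invisible(env)
}
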