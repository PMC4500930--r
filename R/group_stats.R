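#' Compare a parameter between control and treatment groups
#'
#' Classical per-parameter group comparison: means with standard errors,
#' treatment expressed as percent of control, and an unpaired Student's
#' t-test (pooled variance by default; Welch via `var_equal = FALSE`).
#' Significance stars follow the usual thresholds: `*` p <= 0.05,
#' `**` p <= 0.01, `***` p <= 0.001, otherwise `ns`.
#'
#' @param control,treatment numeric vectors of per-network values; at least
#'   two finite values each.
#' @param parameter parameter name carried into the output.
#' @param var_equal pooled-variance Student's test (`TRUE`, default) or
#'   Welch's approximation.
#' @return One-row tibble: `parameter`, `control_mean`, `control_sem`,
#'   `control_n`, `treatment_mean`, `treatment_sem`, `treatment_n`,
#'   `pct_of_control`, `t_stat`, `df`, `p_value`, `stars`. `t_stat` is signed
#'   treatment minus control. `pct_of_control` is `NA` (flagged by a warning)
#'   when the control mean is zero.
#' @examples
#' compare_groups(c(1, 1.1, 0.9), c(3.0, 3.2, 3.4), "spike_rate")
#' @export
compare_groups <- function(control, treatment, parameter = "parameter",
                           var_equal = TRUE) {
  control <- control[is.finite(control)]
  treatment <- treatment[is.finite(treatment)]
  n1 <- length(control); n2 <- length(treatment)
  if (n1 < 2L || n2 < 2L) abort("need >= 2 finite values per group.")
  m1 <- mean(control); m2 <- mean(treatment)
  s1 <- sd(control); s2 <- sd(treatment)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  t_stat <- if (se > 0) (m2 - m1) / se else 0
  p <- if (se > 0) 2 * pt(-abs(t_stat), df) else 1
  pct <- if (m1 != 0) 100 * m2 / m1 else {
    warn(sprintf("%s: control mean is zero; percent of control undefined.",
                 parameter))
    NA_real_
  }
  tibble(
    parameter = parameter,
    control_mean = m1, control_sem = s1 / sqrt(n1), control_n = n1,
    treatment_mean = m2, treatment_sem = s2 / sqrt(n2), treatment_n = n2,
    pct_of_control = pct, t_stat = t_stat, df = df, p_value = p,
    stars = significance_stars(p)
  )
}

#' Significance stars
#'
#' @param p numeric p-values.
#' @return Character vector: `***` (p <= 0.001), `**` (p <= 0.01),
#'   `*` (p <= 0.05), else `ns`.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare every feature of a cohort feature table between two groups
#'
#' Maps [compare_groups()] over the feature columns of a cohort table.
#' Features with fewer than two finite values in either group are skipped.
#' No multiple-testing correction is applied by default, mirroring
#' per-parameter testing; `adjust = "BH"` adds a Benjamini-Hochberg adjusted
#' column (interpret the unadjusted stars with caution when screening all
#' features).
#'
#' @param features tibble from [assemble_cohort_features()] with a `group`
#'   column.
#' @param control_label,treatment_label the two group labels to compare.
#' @param parameters feature names to test; defaults to all registry features
#'   present.
#' @param adjust `"none"` (default) or `"BH"`.
#' @inheritParams compare_groups
#' @return Tibble with one row per tested parameter (see [compare_groups()]);
#'   with `adjust = "BH"` an extra `p_adjusted` column.
#' @export
compare_feature_tables <- function(features, control_label, treatment_label,
                                   parameters = NULL, var_equal = TRUE,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(features), "group" %in% names(features))
  parameters <- parameters %||%
    setdiff(names(features), c("network_id", "group", "div"))
  rows <- purrr::map(parameters, function(p) {
    a <- features[[p]][features$group == control_label]
    b <- features[[p]][features$group == treatment_label]
    if (sum(is.finite(a)) < 2L || sum(is.finite(b)) < 2L) return(NULL)
    compare_groups(a, b, parameter = p, var_equal = var_equal)
  })
  out <- bind_rows(rows)
  if (adjust == "BH" && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Derived morphometry parameters from per-image counts
#'
#' Validates and extends a per-image morphology count table (cells, neurons,
#' neurites, synapses, GABA-immunopositive neurons) with the derived ratios
#' reported in immunocytochemistry screens: percent neurons of all cells,
#' neurites per neuron, synapses per neurite, and percent GABAergic neurons
#' of neurons. Ratios with a zero denominator are `NA` (with the exception
#' that zero neurons among positive cells gives 0% neurons).
#'
#' @param counts data frame with numeric columns `cells`, `neurons`,
#'   `neurites`, `synapses`, `gaba_neurons`; other columns (image id, group,
#'   div) pass through.
#' @return The input tibble plus `pct_neurons`, `neurites_per_neuron`,
#'   `synapses_per_neurite`, `pct_gaba_of_neurons`.
#' @export
morph_derive <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("cells", "neurons", "neurites", "synapses", "gaba_neurons")
  if (!all(need %in% names(counts))) {
    abort(sprintf("missing count column(s): %s",
                  paste(setdiff(need, names(counts)), collapse = ", ")))
  }
  counts <- as_tibble(counts)
  bad_neg <- purrr::map_lgl(need, function(cc) any(counts[[cc]] < 0))
  if (any(bad_neg)) abort("counts must be non-negative.")
  if (any(counts$neurons > counts$cells)) {
    abort("invariant violated: neurons exceed cells in some image(s).")
  }
  if (any(counts$gaba_neurons > counts$neurons)) {
    abort("invariant violated: GABAergic neurons exceed neurons in some image(s).")
  }
  counts %>%
    mutate(
      pct_neurons = dplyr::if_else(.data$cells > 0,
                                   100 * .data$neurons / .data$cells,
                                   NA_real_),
      neurites_per_neuron = dplyr::if_else(.data$neurons > 0,
                                           .data$neurites / .data$neurons,
                                           NA_real_),
      synapses_per_neurite = dplyr::if_else(.data$neurites > 0,
                                            .data$synapses / .data$neurites,
                                            NA_real_),
      pct_gaba_of_neurons = dplyr::if_else(.data$neurons > 0,
                                           100 * .data$gaba_neurons / .data$neurons,
                                           NA_real_)
    )
}

#' Optional normality diagnostics
#'
#' Shapiro-Wilk statistic and p per group, as a diagnostic report only;
#' group comparisons never gate on it.
#'
#' @param values numeric vector.
#' @param group grouping vector.
#' @return Tibble: `group`, `n`, `shapiro_w`, `shapiro_p` (`NA` when n < 3).
#' @export
normality_report <- function(values, group) {
  purrr::imap_dfr(split(values, group), function(v, g) {
    v <- v[is.finite(v)]
    ok <- length(v) >= 3L && length(unique(v)) > 1L
    sh <- if (ok) stats::shapiro.test(v) else NULL
    tibble(group = g, n = length(v),
           shapiro_w = if (ok) unname(sh$statistic) else NA_real_,
           shapiro_p = if (ok) sh$p.value else NA_real_)
  })
}
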