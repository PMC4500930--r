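#' Pipeline configuration
#'
#' Bundles every stage configuration of the simulate - analyze - classify -
#' compare - report pipeline. All randomness funnels through `seed`; two runs
#' with identical configurations produce byte-identical report bundles.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed integer master seed.
#' @param synth a [synth_config()] for the simulated cohort.
#' @param n_per_group networks per group.
#' @param treatment_multipliers treatment effect, see [generate_cohort()].
#' @param div culture age stamped on the cohort.
#' @param criteria a [burst_criteria()].
#' @param descriptor a [descriptor_config()].
#' @param perceptron a [perceptron_spec()].
#' @param policy an [analysis_window_policy()]; its stable-phase duration must
#'   not exceed the simulated duration.
#' @param recordings optional list with elements `control` and `treatment`
#'   (lists of [mea_recording()]); when given, the simulate stage is skipped.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synth = synth_config(),
                            n_per_group = 8,
                            treatment_multipliers = spike_driver_multipliers(1.5),
                            div = 14,
                            criteria = burst_criteria(),
                            descriptor = descriptor_config(),
                            perceptron = perceptron_spec(),
                            policy = analysis_window_policy(
                              stable_phase_duration = min(synth$duration, 1800000)),
                            recordings = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 n_per_group = n_per_group,
                 treatment_multipliers = treatment_multipliers, div = div,
                 criteria = criteria, descriptor = descriptor,
                 perceptron = perceptron, policy = policy,
                 recordings = recordings),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a two-group cohort, restricts every recording to
#' its stable activity phase, assembles the 204-feature table, compares the
#' twelve headline parameters between groups, cross-validates the
#' two-group perceptron classification, and writes the report bundle:
#' `features.csv` (+ `features_registry.csv`), `comparisons.csv`,
#' `recognition.csv` and `manifest.txt` (versions, seed, configuration hash).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `features`, `comparisons`, `recognition`
#'   (an `mea_cv`), and `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: %d + %d networks", config$n_per_group, config$n_per_group)
  cohort <- stage("simulate", {
    config$recordings %||% generate_cohort(
      config$synth, config$treatment_multipliers,
      n_per_group = config$n_per_group, base_seed = config$seed,
      div = config$div)
  })
  recs <- c(cohort$control, cohort$treatment)

  say("analyze: stable phase + %d features per network", 204L)
  features <- stage("analyze", {
    recs <- purrr::map(recs, select_stable_phase, policy = config$policy)
    assemble_cohort_features(recs, config = config$descriptor,
                             criteria = config$criteria)
  })

  say("compare: headline parameters")
  comparisons <- stage("compare", {
    compare_feature_tables(features, "control", "treatment",
                           parameters = unname(named_parameters()))
  })

  say("classify: leave-one-out cross-validation")
  recognition <- stage("classify", {
    spec <- config$perceptron
    spec$seed <- derive_seed(config$seed, 10000L)
    cross_validate(features, features$group, spec = spec)
  })

  say("report: writing bundle to %s", config$out_dir)
  paths <- stage("report", {
    p <- list(
      features = file.path(config$out_dir, "features.csv"),
      comparisons = file.path(config$out_dir, "comparisons.csv"),
      recognition = file.path(config$out_dir, "recognition.csv"),
      manifest = file.path(config$out_dir, "manifest.txt")
    )
    write_feature_table(features, p$features)
    readr::write_csv(comparisons, p$comparisons)
    write_recognition_table(recognition, p$recognition)
    writeLines(c(
      sprintf("package: meaburst %s", utils::packageVersion("meaburst")),
      "registry_version: v1",
      sprintf("seed: %d", config$seed),
      sprintf("networks: %d control + %d treatment",
              length(cohort$control), length(cohort$treatment)),
      sprintf("config_hash: %s", config_hash(config))
    ), p$manifest)
    p
  })
  invisible(list(features = features, comparisons = comparisons,
                 recognition = recognition, paths = paths))
}

# md5 of the deparsed configuration (output directory excluded, so the same
# analysis written elsewhere hashes identically)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}
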