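# End-to-end orchestration: simulate -> (render/track | direct traces) ->
# kinematics -> classify -> stats, from a single declarative config.

#' Default pipeline configuration
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param n_clutches,fish_per_clutch_per_genotype cohort layout.
#' @param slow_duration,slow_rate slow-swim session length (s) and rate (Hz).
#' @param n_trials,escape_rate,trial_len,stim_time escape protocol.
#' @param effect_scale genotype effect multiplier (0 = null generator).
#' @param cutoff_deg forward/turn cutoff.
#' @param render whether to render+track frames instead of using the
#'   generator's traces directly (slow; for demonstration scale only).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1, n_clutches = 4,
                           fish_per_clutch_per_genotype = 15,
                           slow_duration = 300, slow_rate = 100,
                           n_trials = 10, escape_rate = 650,
                           trial_len = 1, stim_time = 0.2,
                           effect_scale = 1, cutoff_deg = 25,
                           min_bouts = 30, render = FALSE) {
  list(seed = as.integer(seed),
       cohort = list(n_clutches = n_clutches,
                     fish_per_clutch_per_genotype = fish_per_clutch_per_genotype,
                     effect_scale = effect_scale),
       slow = list(duration = slow_duration, rate = slow_rate),
       escape = list(n_trials = n_trials, rate = escape_rate,
                     trial_len = trial_len, stim_time = stim_time),
       classify = list(cutoff_deg = cutoff_deg, min_bouts = min_bouts),
       render = render)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipelineConfig()]; missing keys take the defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipelineConfig()
  utils::modifyList(base, y)
}

# simulate + segment + summarize one fish (slow session and escape trials)
processFish <- function(fish, cfg, fish_seed) {
  set.seed(fish_seed)
  tr <- simulateSlowSession(fish, duration = cfg$slow$duration,
                            rate = cfg$slow$rate)
  if (isTRUE(cfg$render)) {
    stack <- renderFrames(tr)
    tr2 <- trackStack(stack)
    tr2@meta <- tr@meta
    tr <- tr2
  }
  bouts <- sessionBouts(tr)
  escapes <- do.call(rbind, lapply(seq_len(cfg$escape$n_trials), function(j) {
    et <- simulateEscapeTrial(fish, trial_len = cfg$escape$trial_len,
                              stim_time = cfg$escape$stim_time,
                              rate = cfg$escape$rate)
    eb <- sessionBouts(et)
    cbind(trial = j, selectEscape(eb, cfg$escape$stim_time, cfg$escape$rate))
  }))
  summ <- summarizeFish(bouts, escapes, meta = as.list(fish),
                        session_duration = cfg$slow$duration,
                        cutoff = cfg$classify$cutoff_deg,
                        min_bouts = cfg$classify$min_bouts %||% 30)
  list(summary = summ, n_bouts = if (is.null(bouts)) 0L else nrow(bouts))
}

#' Run the full analysis pipeline
#'
#' Generates the cohort, simulates every fish's slow-swim session and escape
#' trials, segments bouts, classifies and aggregates, and runs the four
#' genotype comparisons (forward, turn, escape families and the standalone
#' bout rate). Writes all stage outputs plus a run manifest when
#' \code{out_dir} is given. Identical config + seed reproduce identical
#' outputs.
#'
#' @param config a [pipelineConfig()] list (or path to a YAML file).
#' @param out_dir optional output directory for the stage tables and the
#'   manifest.
#' @param verbose print per-stage progress.
#' @return list with \code{summaries}, \code{comparisons} (named list of
#'   [compareGroups()] tables), \code{ratio} ([categoryRatio()]), and the
#'   \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL,
                        verbose = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cc <- cohortConfig(n_clutches = config$cohort$n_clutches,
                     fish_per_clutch_per_genotype =
                       config$cohort$fish_per_clutch_per_genotype,
                     effect_scale = config$cohort$effect_scale,
                     seed = config$seed)
  cohort <- generateCohort(cc)
  if (verbose) message("cohort: ", nrow(cohort), " fish")
  res <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    res[[i]] <- processFish(cohort[i, ], config,
                            childSeed(config$seed, i))
    if (verbose && i %% 20 == 0) message("  fish ", i, "/", nrow(cohort))
  }
  summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
  comparisons <- list(
    forward = compareGroups(summaries, "forward"),
    turn = compareGroups(summaries, "turn"),
    escape = compareGroups(summaries, "escape"),
    boutrate = compareGroups(summaries, "boutrate")
  )
  ratio <- categoryRatio(summaries)
  manifest <- list(
    tool_version = as.character(utils::packageVersion("larvakin")),
    seed = config$seed,
    config = config,
    stages = c("simulate", if (isTRUE(config$render)) c("render", "track"),
               "kinematics", "classify", "stats"),
    counts = list(n_fish = nrow(cohort),
                  n_bouts = sum(vapply(res, `[[`, integer(1), "n_bouts")),
                  n_qc_fail = sum(!summaries$qc_pass)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- list(summaries = summaries, comparisons = comparisons,
              ratio = ratio, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeTable(summaries, file.path(out_dir, "fish_summaries.tsv"))
    for (a in names(comparisons))
      writeTable(comparisons[[a]], file.path(out_dir,
                                             paste0("comparison_", a, ".tsv")))
    writeTable(ratio, file.path(out_dir, "category_ratio.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
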