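# Calibrated default parameters for the synthetic cohort generator.
#
# Group-level location values are the published group statistics for
# sst1.1 mutant larvae versus wild-type siblings: slow-swim values are means
# (across fish) of per-fish medians, escape values are means of per-fish
# means over ten trials. Between-fish dispersions for the six forward-swim
# parameters are set so that the expected genotype Wald chi-square at the
# study's sample size (58 vs 62 fish) matches the published statistics;
# dispersions for the other families are derived from the published SEMs
# (SD = SEM * sqrt(n)). Positive parameters vary lognormally between fish,
# angles normally.

.larvakinCal <- list(
  genotypes = c("wt", "mut"),

  forward = list(
    distance = c(wt = 0.48, mut = 0.56),      # mm, per-bout median target
    speed    = c(wt = 1.78, mut = 1.96),      # mm/s
    bend     = c(wt = 2.57, mut = 2.88),      # deg, median |bend amplitude|
    n_osc    = c(wt = 3.29, mut = 3.47),      # oscillations per bout
    fish_cv  = c(distance = 0.289, speed = 0.191, bend = 0.231, n_osc = 0.170),
    fish_rho_ds = 0.97,                       # fish-level cor(log dist, log speed)
    bout_sdlog  = c(distance = 0.25, speed = 0.18, bend = 0.25, n_osc = 0.18),
    bout_rho_ds = 0.65,
    peak_decay = 0.78,                        # geometric decay of bend peaks
    peak_floor = 0.55                         # min |peak| as fraction of median bend
  ),

  turn = list(
    distance = c(wt = 1.49, mut = 1.57),
    speed    = c(wt = 3.86, mut = 3.86),
    bend     = c(wt = 4.60, mut = 4.87),
    n_osc    = c(wt = 5.12, mut = 5.42),
    fish_cv  = c(distance = 0.194, speed = 0.099, bend = 0.219, n_osc = 0.225),
    fish_rho_ds = 0.32,
    bout_sdlog  = c(distance = 0.25, speed = 0.18, bend = 0.25, n_osc = 0.18),
    bout_rho_ds = 0.65,
    peak_decay = 0.80,
    peak_floor = 0.32,
    first_bend_mean = 45, first_bend_sd = 8,  # deg, initial turn bend
    first_bend_range = c(28, 90)
  ),

  session = list(
    bout_rate = c(wt = 0.95, mut = 0.91),     # bouts/s over 5 min
    p_forward = c(wt = 0.7524, mut = 0.7534),
    rate_cv = 0.33,
    min_gap = 0.10,                           # s, minimum glide between bouts
    gap_shape = 2                             # gamma shape of the glide time
  ),

  escape = list(
    distance = c(wt = 8.73, mut = 9.12),      # mm
    tbf      = c(wt = 37.45, mut = 37.56),    # Hz
    n_osc    = c(wt = 8.22, mut = 8.27),
    latency  = c(wt = 5.34, mut = 5.45),      # ms
    cbend    = c(wt = 100.20, mut = 100.60),  # deg
    counter  = c(wt = 45.15, mut = 46.51),    # deg
    fish_cv  = c(distance = 0.148, tbf = 0.148, n_osc = 0.178, latency = 0.257),
    fish_sd  = c(cbend = 6.21, counter = 8.33),
    trial_cv = c(distance = 0.20, tbf = 0.10, n_osc = 0.20, latency = 0.25),
    trial_sd = c(cbend = 10, counter = 8),
    peak_decay = 0.75,
    peak_floor = 0.15                          # fraction of the C-bend
  ),

  noise = list(angle_sd = 0.15, pos_sd = 0.01), # deg / mm additive sensor noise
  min_bend = 1.5,                              # deg, floor on per-bout median bend
  heading_gain = 0.6,                          # heading change per deg of first bend
  clutch_frac = 0.1                            # clutch share of between-fish SD
)

#' Calibrated generator defaults
#'
#' Returns the full table of default parameters used by the synthetic
#' generator: genotype-level locations for slow forward swims, routine turns,
#' escape responses and the session-level bout-onset process, together with
#' the between-fish / between-clutch and within-fish dispersions and the
#' waveform constants. See the methods vignette for how each value was
#' chosen.
#'
#' @return a named list of calibration blocks.
#' @export
defaultCalibration <- function() .larvakinCal

#' Cohort configuration
#'
#' Assembles and validates the configuration of a synthetic cohort: the
#' clutch/genotype layout, the effect structure (genotype-level parameter
#' values per block) and the dispersion scalings.
#'
#' @param n_clutches number of clutches (>= 1).
#' @param fish_per_clutch_per_genotype fish per clutch for each genotype.
#' @param genotype_labels two labels, reference first.
#' @param clutch_frac fraction of the between-fish SD attributed to the
#'   clutch level (shared by both genotypes of a clutch).
#' @param sd_scale multiplier on all between-fish/clutch dispersions (0 gives
#'   identical latents within genotype).
#' @param effect_scale multiplier on the genotype effect: 1 keeps the
#'   calibrated mutant values, 0 sets the mutant equal to the reference
#'   (null generator).
#' @param seed integer seed that fully determines the cohort.
#' @param calibration calibration list, see [defaultCalibration()].
#' @return an object of class \code{cohortConfig} (a validated list).
#' @export
cohortConfig <- function(n_clutches = 4, fish_per_clutch_per_genotype = 15,
                         genotype_labels = c("wt", "mut"),
                         clutch_frac = NULL, sd_scale = 1, effect_scale = 1,
                         seed = 1, calibration = defaultCalibration()) {
  if (n_clutches < 1 || fish_per_clutch_per_genotype < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (length(genotype_labels) != 2 || anyDuplicated(genotype_labels))
    stop("genotype_labels must be two distinct labels", call. = FALSE)
  if (sd_scale < 0) stop("sd_scale must be >= 0", call. = FALSE)
  cfg <- list(
    n_clutches = as.integer(n_clutches),
    fish_per_clutch_per_genotype = as.integer(fish_per_clutch_per_genotype),
    genotype_labels = genotype_labels,
    clutch_frac = clutch_frac %||% calibration$clutch_frac,
    sd_scale = sd_scale,
    effect_scale = effect_scale,
    seed = as.integer(seed),
    calibration = calibration
  )
  class(cfg) <- "cohortConfig"
  cfg
}
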