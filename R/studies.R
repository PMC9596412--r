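#' Simulation studies: error control and sensitivity
#'
#' Monte-Carlo characterization of the two-level contrast test: family-wise
#' error rate under a global null (no planted effects) and sensitivity under
#' planted effects, both run through the same fitting path as the main
#' pipeline.
#'
#' @name studies
NULL

#' Family-wise error rate of the Bonferroni group test under the null
#'
#' Builds the design once (transcript, toy LM, metric regressor, nuisances)
#' and then, for each replicate, simulates S subjects x 2 conditions of
#' pure AR(1) noise BOLD (all planted betas zero), fits the two-level GLM,
#' and records whether any ROI is flagged. The FWER estimate is the
#' fraction of replicates with at least one (false) rejection.
#'
#' @param n_reps Number of replicates.
#' @param config Pipeline configuration overrides; betas are forced to zero.
#' @param window_s Window used for the interest regressor.
#' @param seed Base seed; replicate r uses sim seed `seed + r`.
#' @return List: `fwer`, `mc_se` (binomial Monte-Carlo standard error),
#'   `n_reps`, `rejections` (per-replicate false-positive counts).
#' @export
null_fwer_study <- function(n_reps = 200, config = list(), window_s = 30,
                            seed = 1L) {
  cfg <- validate_config(utils::modifyList(
    list(metric = "surprisal", windows = window_s, seed = seed), config))
  cfg$sim$beta_surprisal <- 0
  cfg$sim$beta_saliency <- 0

  x <- simulate_transcript(cfg$sim)
  lmod <- simulate_toy_lm(cfg$sim)
  env <- simulate_envelope(cfg$sim)
  kernel <- hrf_kernel(cfg$hrf, dt = cfg$dt)
  nuisance <- build_nuisance_set(x, env, cfg, kernel)
  met <- compute_all_metrics(x, lmod, window_s)
  interest <- build_interest_predictor(x, met, "surprisal", cfg, kernel)
  design <- build_design(interest, nuisance, standardize = cfg$standardize)

  rejections <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    sim_r <- cfg$sim
    sim_r$seed <- cfg$sim$seed + r
    brain <- simulate_brain(sim_r, list(surprisal = interest), nuisance$WS)
    res <- run_group_analysis(brain$fw, brain$bw, design, cfg,
                              column = "surprisal")
    rejections[r] <- sum(res$group$significant)
  }
  fwer <- mean(rejections > 0)
  list(fwer = fwer,
       mc_se = sqrt(fwer * (1 - fwer) / n_reps),
       n_reps = n_reps,
       rejections = rejections)
}

#' Sensitivity of the full pipeline under planted effects
#'
#' Runs the complete pipeline (simulate, metrics, predictors, GLM, group
#' test) for several seeds with effects planted in the configured ROIs and
#' scores recovery: sensitivity is the fraction of planted ROIs flagged,
#' and false positives are flags outside the planted set.
#'
#' @param n_reps Number of independent seeded runs.
#' @param config Pipeline configuration overrides.
#' @param seed Base seed; run r uses `seed + 100 * r`.
#' @return List: `sensitivity` (mean over runs), `per_run` data.frame
#'   (seed, n_detected, n_planted, n_false_positives).
#' @export
power_study <- function(n_reps = 10, config = list(), seed = 1L) {
  per_run <- NULL
  for (r in seq_len(n_reps)) {
    s <- seed + 100L * r
    rep_r <- run_pipeline(utils::modifyList(
      list(metric = "surprisal", windows = 30, seed = s), config))
    planted <- rep_r$roi_labels[rep_r$effect_rois]
    for (key in names(rep_r$results)) {
      g <- rep_r$results[[key]]$group
      flagged <- g$roi[g$significant]
      per_run <- rbind(per_run, data.frame(
        seed = s, window = rep_r$results[[key]]$window_s,
        n_detected = length(intersect(flagged, planted)),
        n_planted = length(planted),
        n_false_positives = length(setdiff(flagged, planted))))
    }
  }
  list(sensitivity = sum(per_run$n_detected) / sum(per_run$n_planted),
       per_run = per_run)
}
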