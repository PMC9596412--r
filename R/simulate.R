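#' Synthetic study generator
#'
#' Generates every input the pipeline needs — a timed transcript at a
#' naturalistic speech rate, a seeded toy language model, a word-sound
#' envelope, and multi-subject two-condition ROI BOLD with effects planted
#' in designated ROIs — so every stage is testable without external data.
#' The default profile mirrors the study conditions it emulates: a ~12-min
#' narrative of ~2500 tokens (~63% full words), 709 volumes at TR = 1 s,
#' 27 subjects, two conditions (forward/backward), with 100 ROIs at desk
#' scale (1000 behind the "paper-scale" profile).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param profile "default" (study scale, 100 ROIs), "tiny" (fast smoke
#'   scale), or "paper-scale" (1000 ROIs).
#' @param seed Integer seed; every artifact is a pure function of the
#'   config including this seed.
#' @param ... Named overrides of any config field.
#' @return List of class `sim_config`. Fields: seed, V, d, gamma, n_tokens,
#'   narrative_duration_s, rate_cv (gap jitter, coefficient of variation),
#'   word_fraction, S, R, T, tr, effect_rois, beta_surprisal, beta_saliency,
#'   beta_ws, noise_sd, ar1, plant_window_s.
#' @export
sim_config <- function(profile = c("default", "tiny", "paper-scale"),
                       seed = 1L, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile, seed = as.integer(seed),
    V = 100L, d = 16L, gamma = 0.9,
    n_tokens = 2512L, narrative_duration_s = 720,
    rate_cv = 0.6, word_fraction = 0.63,
    S = 27L, R = 100L, T = 709L, tr = 1,
    effect_rois = c(10L, 30L, 50L, 70L, 90L),
    beta_surprisal = 1, beta_saliency = 1, beta_ws = 0.5,
    noise_sd = 1, ar1 = 0.3,
    plant_window_s = 30
  )
  if (profile == "tiny") {
    cfg <- utils::modifyList(cfg, list(
      V = 50L, d = 8L, n_tokens = 450L, narrative_duration_s = 155,
      S = 5L, R = 20L, T = 150L, effect_rois = c(4L, 11L, 17L)))
  } else if (profile == "paper-scale") {
    cfg <- utils::modifyList(cfg, list(
      R = 1000L,
      effect_rois = as.integer(seq(10, 990, by = 20))))
  }
  cfg <- utils::modifyList(cfg, list(...))
  if (max(cfg$effect_rois) > cfg$R) {
    # keep the planted set valid when R is overridden below the profile default
    cfg$effect_rois <- unique(pmin(cfg$effect_rois, cfg$R))
  }
  stopifnot(cfg$n_tokens >= 1, cfg$S >= 1, cfg$R >= 1, cfg$T >= 1,
            cfg$tr > 0, cfg$ar1 >= 0, cfg$ar1 < 1,
            all(cfg$effect_rois >= 1))
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a timed transcript
#'
#' Token onsets come from a jittered renewal process (gamma-distributed
#' gaps) rescaled to span the narrative, giving a mean rate of
#' n_tokens / duration (~3.5 tokens/s at study scale, which reproduces the
#' reported ~53 tokens per 15-s window). Token ids are Zipf-distributed and
#' lexical frequencies (occurrences per million) follow the same Zipf law;
#' a `word_fraction` share of tokens are flagged as full words.
#'
#' @param config A [sim_config()].
#' @return A `transcript` with a `token_id` column and Zipf-consistent
#'   `lex_freq` (NA for non-word tokens).
#' @export
simulate_transcript <- function(config) {
  if (config$n_tokens < 2) stop_surpsal("too-sparse", "need at least 2 tokens")
  set.seed(config$seed)
  n <- config$n_tokens
  # gamma gaps with cv = rate_cv, rescaled so the last onset sits just
  # inside the narrative
  shape <- 1 / config$rate_cv^2
  gaps <- stats::rgamma(n, shape = shape, rate = shape)
  onsets <- cumsum(gaps)
  onsets <- (onsets - onsets[1]) / (onsets[n] - onsets[1]) *
    (config$narrative_duration_s * 0.995)
  durations <- pmin(c(diff(onsets), config$narrative_duration_s - onsets[n]) * 0.8,
                    1.5)
  zipf_p <- (1 / seq_len(config$V)) / sum(1 / seq_len(config$V))
  ids <- sample.int(config$V, n, replace = TRUE, prob = zipf_p)
  is_word <- stats::runif(n) < config$word_fraction
  lex_freq <- ifelse(is_word, zipf_p[ids] * 1e6, NA_real_)
  transcript(data.frame(
    token = paste0("tok", ids),
    onset_s = onsets, duration_s = durations,
    is_word = is_word, lex_freq = lex_freq,
    token_id = ids
  ), total_duration_s = config$narrative_duration_s)
}

#' Simulate a seeded toy language model
#'
#' Gaussian embedding and output tables scaled by 1/sqrt(d); vocabulary
#' strings "tok1".."tokV" matching [simulate_transcript()].
#'
#' @param config A [sim_config()].
#' @return A [toy_decay_lm()].
#' @export
simulate_toy_lm <- function(config) {
  set.seed(config$seed + 1L)
  E <- matrix(stats::rnorm(config$V * config$d, sd = 1 / sqrt(config$d)),
              config$V, config$d)
  U <- matrix(stats::rnorm(config$V * config$d, sd = 1 / sqrt(config$d)),
              config$V, config$d)
  toy_decay_lm(E, U, config$gamma, paste0("tok", seq_len(config$V)))
}

#' Simulate a word-sound (audio energy) envelope
#'
#' A smooth strictly positive series on a 0.5-s grid: low-pass filtered
#' Gaussian noise, exponentiated. A stand-in for the broadband energy of
#' the narrated speech.
#'
#' @param config A [sim_config()].
#' @return data.frame(time_s, value).
#' @export
simulate_envelope <- function(config) {
  set.seed(config$seed + 2L)
  t <- seq(0, config$narrative_duration_s, by = 0.5)
  raw <- stats::rnorm(length(t))
  sm <- stats::filter(raw, rep(1 / 8, 8), sides = 1)
  sm[is.na(sm)] <- 0
  data.frame(time_s = t, value = exp(as.numeric(sm)))
}

#' Stationary AR(1) Gaussian noise matrix
#'
#' @param n_time,n_series Matrix dimensions.
#' @param phi AR(1) coefficient in \[0, 1).
#' @param sd Marginal (stationary) standard deviation.
#' @return n_time x n_series matrix.
#' @export
ar1_noise <- function(n_time, n_series, phi, sd = 1) {
  if (phi < 0 || phi >= 1) stop_surpsal("bad-ar1", "AR(1) coefficient must be in [0, 1)")
  E <- matrix(stats::rnorm(n_time * n_series, sd = sd * sqrt(1 - phi^2)),
              n_time, n_series)
  E[1, ] <- stats::rnorm(n_series, sd = sd)
  if (phi > 0 && n_time > 1) {
    for (t in 2:n_time) E[t, ] <- phi * E[t - 1, ] + E[t, ]
  }
  E
}

#' Simulate multi-subject two-condition ROI BOLD with planted effects
#'
#' Forward (FW) runs carry the planted metric effects in the designated
#' ROIs: for each interest predictor named `nm`, effect ROIs receive
#' `beta_<nm>` times the z-scored predictor. The word-sound envelope effect
#' (`beta_ws`) is present in every ROI of both conditions — the backward
#' (BW) control is acoustically matched but carries no linguistic effect.
#' Noise is stationary AR(1) Gaussian, independent across ROIs and subjects.
#'
#' @param config A [sim_config()].
#' @param predictors Named list of interest `predictor_series` on the
#'   (tr, T) grid; names must have a matching `beta_<name>` config field
#'   (e.g. "surprisal", "saliency").
#' @param ws Optional word-sound `predictor_series` (same grid).
#' @return List: `fw` and `bw` (each a length-S list of T x R matrices with
#'   ROI column names), `roi_labels`, `ground_truth` (planted beta matrix
#'   per condition and the z-scored generating series).
#' @export
simulate_brain <- function(config, predictors, ws = NULL) {
  set.seed(config$seed + 3L)
  Tn <- config$T; R <- config$R; S <- config$S
  roi_labels <- sprintf("ROI%03d", seq_len(R))
  zpred <- lapply(predictors, function(p) zscore_masked(p$values))
  zws <- if (!is.null(ws)) zscore_masked(ws$values) else NULL

  B_fw <- matrix(0, R, length(zpred),
                 dimnames = list(roi_labels, names(zpred)))
  for (nm in names(zpred)) {
    b <- config[[paste0("beta_", nm)]]
    if (is.null(b)) stop_surpsal("bad-schema",
                                 sprintf("no beta_%s in the config", nm))
    B_fw[config$effect_rois, nm] <- b
  }
  signal_fw <- matrix(0, Tn, R)
  for (nm in names(zpred)) {
    signal_fw <- signal_fw + outer(zpred[[nm]], B_fw[, nm])
  }
  ws_part <- if (!is.null(zws)) config$beta_ws * zws else numeric(Tn)

  make_run <- function(base_signal) {
    lapply(seq_len(S), function(s) {
      Y <- base_signal + ws_part +
        ar1_noise(Tn, R, config$ar1, config$noise_sd)
      colnames(Y) <- roi_labels
      Y
    })
  }
  fw <- make_run(signal_fw)
  bw <- make_run(matrix(0, Tn, R))
  list(fw = fw, bw = bw, roi_labels = roi_labels,
       ground_truth = list(beta_fw = B_fw,
                           beta_bw = B_fw * 0,
                           beta_ws = config$beta_ws,
                           effect_rois = config$effect_rois,
                           predictors = zpred))
}

#' Write a complete fixture suite to a directory
#'
#' Produces every file the pipeline consumes: transcript TSV, toy-LM JSON,
#' word-sound envelope TSV, per-subject/condition ROI BOLD TSVs, an ROI
#' label table, a ground-truth JSON and a manifest with md5 checksums.
#' The planted interest predictor is the surprisal series computed at
#' `config$plant_window_s`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr_ <- simulate_transcript(config)
  lm_ <- simulate_toy_lm(config)
  env_ <- simulate_envelope(config)

  met <- compute_all_metrics(tr_, lm_, config$plant_window_s)
  hrf <- hrf_kernel(hrf_spec(), dt = 0.1)
  surp_ps <- convolve_resample(
    event_series(tr_, met$surprisal$surprisal, dt = 0.1),
    hrf, config$tr, config$T, name = "surprisal")
  ws_ps <- resample_envelope(env_$time_s, env_$value, config$tr, config$T)
  brain <- simulate_brain(config, list(surprisal = surp_ps), ws_ps)

  write_transcript(tr_, file.path(dir, "transcript.tsv"))
  write_toy_lm(lm_, file.path(dir, "toy_lm.json"))
  utils::write.table(env_, file.path(dir, "ws_envelope.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(roi_id = seq_len(config$R), label = brain$roi_labels,
               network = "synthetic", hemisphere = rep_len(c("L", "R"), config$R)),
    file.path(dir, "roi_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (s in seq_len(config$S)) {
    for (cond in c("fw", "bw")) {
      utils::write.table(
        round(brain[[cond]][[s]], 6),
        file.path(dir, sprintf("sub-%02d_%s_bold.tsv", s, toupper(cond))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(effect_rois = config$effect_rois,
         beta_fw = brain$ground_truth$beta_fw,
         beta_ws = config$beta_ws,
         plant_window_s = config$plant_window_s),
    file.path(dir, "ground_truth.json"), digits = NA)

  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(dir, sort(files))))
  )
  names(manifest$checksums) <- sort(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
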