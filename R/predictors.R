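#' From token-level metrics to fMRI regressors
#'
#' Token-level metric values become amplitude-modulated impulses at token
#' onsets on a fine time grid, are convolved with a canonical double-gamma
#' hemodynamic response function, and are resampled at the scanner's TR to
#' yield regressors aligned with the BOLD series. A validity mask drops the
#' initial time points whose windows could not yet be full.
#'
#' @name predictor_builder
NULL

#' Double-gamma HRF specification
#'
#' Canonical shape: a gamma density peaking at `peak_delay_s` minus a scaled
#' gamma density peaking at `undershoot_delay_s`. Defaults are the widely
#' used canonical values (peak 6 s, undershoot 16 s, ratio 1/6, 32 s kernel).
#'
#' @param peak_delay_s Time to peak of the positive lobe (s).
#' @param undershoot_delay_s Time to trough of the undershoot (s).
#' @param dispersion_s Width parameter of the positive lobe (s).
#' @param undershoot_dispersion_s Width parameter of the undershoot (s).
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak.
#' @param kernel_length_s Support of the sampled kernel (s).
#' @return List of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     dispersion_s = 1, undershoot_dispersion_s = 1,
                     undershoot_ratio = 1 / 6, kernel_length_s = 32) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > peak_delay_s,
            kernel_length_s >= undershoot_delay_s, undershoot_ratio >= 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 dispersion_s = dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length_s = kernel_length_s),
            class = "hrf_spec")
}

#' Sample a double-gamma HRF kernel
#'
#' Gamma densities are parameterized so their modes land exactly on the
#' specified delays; the kernel is normalized to unit peak.
#'
#' @param spec An [hrf_spec()].
#' @param dt Sampling step in seconds (0 < dt <= 1).
#' @return Numeric kernel of length `kernel_length_s / dt + 1`.
#' @export
hrf_kernel <- function(spec = hrf_spec(), dt = 0.1) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 1) {
    stop_surpsal("bad-dt", "dt must be in (0, 1] seconds")
  }
  t <- seq(0, spec$kernel_length_s, by = dt)
  # mode of Gamma(shape, scale) is (shape - 1) * scale
  sh1 <- spec$peak_delay_s / spec$dispersion_s + 1
  sh2 <- spec$undershoot_delay_s / spec$undershoot_dispersion_s + 1
  h <- stats::dgamma(t, shape = sh1, scale = spec$dispersion_s) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = sh2, scale = spec$undershoot_dispersion_s)
  h / max(h)
}

#' Build an impulse event series on a fine grid
#'
#' Places each token's metric value as an impulse in the grid bin containing
#' its onset; multiple tokens in one bin add. NA values (null-flagged
#' tokens, e.g. no full-window prediction) contribute nothing.
#'
#' @param x A `transcript`.
#' @param values One metric value per token (NA allowed).
#' @param dt Grid step in seconds.
#' @param duration_s Span of the grid; defaults to the transcript's total
#'   duration.
#' @return List with `series` (numeric), `dt`, `duration_s`.
#' @export
event_series <- function(x, values, dt = 0.1,
                         duration_s = attr(x, "total_duration_s")) {
  stopifnot(length(values) == nrow(x), dt > 0)
  if (any(x$onset_s > duration_s)) {
    stop_surpsal("event-out-of-range", "token onset beyond the series span")
  }
  nbin <- ceiling(duration_s / dt) + 1L
  s <- numeric(nbin)
  keep <- !is.na(values)
  bin <- floor(x$onset_s[keep] / dt) + 1L
  for (i in seq_along(bin)) s[bin[i]] <- s[bin[i]] + values[keep][i]
  list(series = s, dt = dt, duration_s = duration_s)
}

#' Convolve an event series with an HRF kernel and resample at the TR
#'
#' Discrete convolution on the fine grid, then sampling at t = k * tr for
#' k = 0..T-1. Sampling beyond the convolved span is zero-padded with a
#' warning.
#'
#' @param es Event series from [event_series()].
#' @param kernel HRF kernel sampled at the same dt ([hrf_kernel()]).
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of fMRI volumes T.
#' @param name Regressor name.
#' @return A `predictor_series`: list(values, valid, tr, name) with values
#'   of length T (valid is all-TRUE here; see [valid_timepoint_mask()]).
#' @export
convolve_resample <- function(es, kernel, tr, n_volumes, name = "predictor") {
  stopifnot(tr > 0, n_volumes >= 1)
  x <- es$series
  conv <- stats::convolve(x, rev(kernel), type = "open")  # length n + m - 1
  idx <- round(seq(0, by = tr, length.out = n_volumes) / es$dt) + 1L
  out <- numeric(n_volumes)
  inside <- idx <= length(conv)
  if (!all(inside)) {
    warning(sprintf("%d of %d sample points beyond the series span; zero-padded",
                    sum(!inside), n_volumes))
  }
  out[inside] <- conv[idx[inside]]
  predictor_series(out, tr = tr, name = name)
}

#' Construct a predictor series on the fMRI grid
#'
#' @param values Length-T numeric vector.
#' @param valid Logical length-T validity mask (default all TRUE).
#' @param tr Repetition time (s).
#' @param name Regressor name.
#' @export
predictor_series <- function(values, valid = rep(TRUE, length(values)),
                             tr = 1, name = "predictor") {
  stopifnot(length(valid) == length(values))
  structure(list(values = as.numeric(values), valid = as.logical(valid),
                 tr = tr, name = name),
            class = "predictor_series")
}

#' Validity mask over fMRI time points for a window length
#'
#' The saliency analysis only uses predictions whose context window is full,
#' so scan time before the first possible full window (plus a hemodynamic
#' settling buffer) is dropped: the first `ceiling((W + buffer) / tr)` time
#' points are marked invalid.
#'
#' @param window_s Window length W (s); 0 keeps everything.
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes T.
#' @param buffer_s Extra settling time (s) beyond the window itself.
#' @return Logical vector of length T; TRUE = retained.
#' @export
valid_timepoint_mask <- function(window_s, tr, n_volumes, buffer_s = 11) {
  stopifnot(window_s >= 0, buffer_s >= 0, tr > 0)
  n_bad <- ceiling((window_s + buffer_s) / tr)
  if (n_bad >= n_volumes) {
    stop_surpsal("empty-mask", "mask would drop every time point")
  }
  c(rep(FALSE, n_bad), rep(TRUE, n_volumes - n_bad))
}

#' Resample a sampled envelope (e.g. word-sound energy) onto the fMRI grid
#'
#' Linear interpolation of a (time, value) table onto t = 0, tr, ..., (T-1)*tr,
#' holding the boundary values outside the sampled range.
#'
#' @param time_s Sample times (s).
#' @param value Sample values.
#' @inheritParams convolve_resample
#' @export
resample_envelope <- function(time_s, value, tr, n_volumes, name = "WS") {
  grid <- seq(0, by = tr, length.out = n_volumes)
  v <- stats::approx(time_s, value, xout = grid, rule = 2)$y
  predictor_series(v, tr = tr, name = name)
}

#' Assemble a GLM design matrix
#'
#' Columns: intercept, the predictor of interest, and the nuisance
#' regressors — word duration (WD) and lexical frequency (LF) built through
#' the same event-to-HRF path as the interest regressor, and word sound (WS)
#' resampled from a supplied envelope. Non-intercept columns are z-scored
#' within the joint validity mask when `standardize` is on.
#'
#' @param interest A `predictor_series` for the metric of interest.
#' @param nuisance Named list of `predictor_series` (e.g. WD, LF, WS).
#' @param standardize Z-score non-intercept columns within the mask.
#' @return List of class `design_matrix`: `X` (T x p), `mask` (length-T
#'   logical), `colnames`, `tr`.
#' @export
build_design <- function(interest, nuisance = list(), standardize = TRUE) {
  stopifnot(inherits(interest, "predictor_series"))
  if (all(is.na(interest$values)) || all(interest$values == 0, na.rm = TRUE)) {
    stop_surpsal("empty-predictor", "interest regressor carries no signal")
  }
  series <- c(list(interest), unname(nuisance))
  nm <- c(interest$name, unname(vapply(nuisance, `[[`, "", "name")))
  if (anyDuplicated(nm)) {
    stop_surpsal("collinear-design", "duplicated regressor names")
  }
  Tn <- length(interest$values)
  trs <- vapply(series, `[[`, 0, "tr")
  lens <- vapply(series, function(s) length(s$values), 0L)
  if (any(lens != Tn) || any(trs != interest$tr)) {
    stop_surpsal("bad-schema", "all regressors must share T and tr")
  }
  mask <- Reduce(`&`, lapply(series, `[[`, "valid"))
  cols <- lapply(series, function(s) {
    v <- s$values
    if (standardize) zscore_masked(v, mask) else v
  })
  X <- cbind(intercept = 1, do.call(cbind, cols))
  colnames(X) <- c("intercept", nm)
  if (qr(X[mask, , drop = FALSE])$rank < ncol(X)) {
    stop_surpsal("collinear-design", "design matrix is rank deficient after masking")
  }
  structure(list(X = X, mask = mask, colnames = colnames(X), tr = interest$tr),
            class = "design_matrix")
}

#' Write / read a predictor series as TSV (time_s, value, valid)
#'
#' @param ps A `predictor_series`.
#' @param path TSV path.
#' @export
write_predictor_tsv <- function(ps, path) {
  df <- data.frame(time_s = seq(0, by = ps$tr, length.out = length(ps$values)),
                   value = ps$values, valid = as.integer(ps$valid))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictor_tsv
#' @param name Regressor name for the reconstructed series.
#' @export
read_predictor_tsv <- function(path, name = "predictor") {
  df <- utils::read.delim(path, sep = "\t")
  tr <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  predictor_series(df$value, valid = df$valid == 1, tr = tr, name = name)
}
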