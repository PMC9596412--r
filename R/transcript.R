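#' Timed transcripts and sliding context windows
#'
#' A transcript is a data.frame of timed tokens — the narrative split into
#' words or sub-word units, each with an onset and duration in seconds, a
#' word flag, and a lexical frequency (occurrences per million, word tokens
#' only). For every target token and window length W, the context is the set
#' of preceding tokens whose onsets fall in the half-open interval
#' \[target_onset - W, target_onset).
#'
#' @name stimulus_windows
NULL

transcript_cols <- c("token", "onset_s", "duration_s", "is_word", "lex_freq")

#' Construct a validated transcript
#'
#' @param tokens data.frame with columns token, onset_s, duration_s,
#'   is_word, lex_freq and (optionally) token_id.
#' @param condition Condition tag, "FW" (forward) or "BW" (backward).
#' @param total_duration_s Total narrative duration; defaults to the end of
#'   the last token.
#' @return A data.frame of class `transcript` with attributes `condition`
#'   and `total_duration_s`.
#' @export
transcript <- function(tokens, condition = "FW", total_duration_s = NULL) {
  miss <- setdiff(transcript_cols, names(tokens))
  if (length(miss) > 0) {
    stop_surpsal("bad-schema",
                 paste("missing transcript column(s):", paste(miss, collapse = ", ")))
  }
  if (nrow(tokens) < 1) stop_surpsal("bad-schema", "transcript has no tokens")
  if (is.unsorted(tokens$onset_s)) {
    stop_surpsal("unsorted-transcript", "token onsets must be non-decreasing")
  }
  if (any(tokens$duration_s < 0) || any(tokens$onset_s < 0)) {
    stop_surpsal("bad-schema", "onsets and durations must be non-negative")
  }
  end <- max(tokens$onset_s + tokens$duration_s)
  total_duration_s <- total_duration_s %||% end
  if (total_duration_s < end) {
    stop_surpsal("bad-schema", "total_duration_s shorter than the last token")
  }
  structure(as.data.frame(tokens), class = c("transcript", "data.frame"),
            condition = match.arg(condition, c("FW", "BW")),
            total_duration_s = total_duration_s)
}

#' Read a timed transcript from TSV
#'
#' Expects a tab-separated UTF-8 file with header columns `token`, `onset_s`,
#' `duration_s`, `is_word`, `lex_freq`. Token ids are assigned by vocabulary
#' lookup; tokens absent from the vocabulary either raise an error or map to
#' a reserved id, per `unknown`.
#'
#' @param path TSV path.
#' @param vocab Character vector of vocabulary token strings, or a
#'   `toy_decay_lm` (its vocab is used).
#' @param unknown Policy for out-of-vocabulary tokens: "error" (default) or
#'   an integer reserved id.
#' @inheritParams transcript
#' @return A `transcript`.
#' @export
read_transcript <- function(path, vocab = NULL, unknown = "error",
                            condition = "FW") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          encoding = "UTF-8", check.names = FALSE)
  miss <- setdiff(transcript_cols, names(df))
  if (length(miss) > 0) {
    stop_surpsal("bad-schema",
                 paste("missing transcript column(s):", paste(miss, collapse = ", ")))
  }
  df$is_word <- as.logical(df$is_word)
  if (!is.null(vocab)) {
    if (inherits(vocab, "toy_decay_lm")) vocab <- vocab$vocab
    id <- match(df$token, vocab)
    if (anyNA(id)) {
      if (identical(unknown, "error")) {
        stop_surpsal("oov-token", sprintf(
          "%d transcript token(s) not in the vocabulary", sum(is.na(id))))
      }
      id[is.na(id)] <- as.integer(unknown)
    }
    df$token_id <- id
  }
  transcript(df, condition = condition)
}

#' Write a transcript to TSV
#'
#' @param x A `transcript` (or compatible data.frame).
#' @param path Output path.
#' @export
write_transcript <- function(x, path) {
  cols <- intersect(c(transcript_cols, "token_id"), names(x))
  df <- as.data.frame(x)[, cols]
  df$is_word <- as.integer(df$is_word)
  df$onset_s <- sprintf("%.4f", df$onset_s)
  df$duration_s <- sprintf("%.4f", df$duration_s)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble the left-context window for one target token
#'
#' Context membership is by token onset: all tokens with index < target and
#' onset in \[target_onset - W, target_onset). The window is "full" when the
#' target's onset is at least W seconds into the narrative, i.e. the context
#' could span the whole window; earlier targets get a truncated context.
#'
#' @param x A `transcript`.
#' @param target_index 1-based index of the target token.
#' @param window_s Window length W in seconds.
#' @param empty_context Policy when the context is empty: "truncate"
#'   (default; returns an empty context, flagged) or "error".
#' @return List with `target_index`, `context_indices` (ordered by onset),
#'   `window_s`, `is_full`, `n_context`.
#' @export
build_window <- function(x, target_index, window_s,
                         empty_context = c("truncate", "error")) {
  empty_context <- match.arg(empty_context)
  n <- nrow(x)
  stopifnot(target_index >= 1, target_index <= n, window_s > 0)
  t0 <- x$onset_s[target_index]
  prev <- seq_len(target_index - 1L)
  on <- x$onset_s[prev]
  ctx <- prev[on >= t0 - window_s & on < t0]
  if (length(ctx) == 0 && empty_context == "error") {
    stop_surpsal("no-context", sprintf(
      "target token %d has no context within %g s", target_index, window_s))
  }
  list(target_index = as.integer(target_index),
       context_indices = as.integer(ctx),
       window_s = window_s,
       is_full = t0 >= window_s,
       n_context = length(ctx))
}

#' Per-window context-size summary
#'
#' Mean and sd of context length, in tokens and in word tokens, across all
#' targets of a transcript at a given window size — the bookkeeping used to
#' relate window length to the amount of context the model receives.
#'
#' @inheritParams build_window
#' @return One-row data.frame: window_s, mean_tokens, sd_tokens, mean_words,
#'   sd_words, n_targets.
#' @export
window_stats <- function(x, window_s) {
  n <- nrow(x)
  len_tok <- numeric(n)
  len_word <- numeric(n)
  for (i in seq_len(n)) {
    w <- build_window(x, i, window_s)
    len_tok[i] <- w$n_context
    len_word[i] <- sum(x$is_word[w$context_indices])
  }
  data.frame(window_s = window_s,
             mean_tokens = mean(len_tok),
             sd_tokens = stats::sd(len_tok),
             mean_words = mean(len_word),
             sd_words = stats::sd(len_word),
             n_targets = n)
}

#' Published per-window descriptive statistics of the original narrative study
#'
#' The study this pipeline emulates reported, for each sliding-window length,
#' the mean +/- sd context size (tokens and words), the mean +/- sd surprisal
#' of the convolved predictor, and the number of fMRI time points retained
#' for the saliency analysis. These printed values serve as plausibility
#' targets for the synthetic generator and as input to the context-size
#' versus surprisal correlation.
#'
#' @return data.frame with columns window_s, mean_tokens, sd_tokens,
#'   mean_words, sd_words, mean_surprisal, sd_surprisal, n_timepoints.
#' @export
reference_window_stats <- function() {
  data.frame(
    window_s = c(15, 30, 45, 60, 75, 90),
    mean_tokens = c(53.52, 105.62, 156.47, 206.1, 254.51, 301.59),
    sd_tokens = c(7.2, 15.36, 26.24, 39.17, 53.64, 69.23),
    mean_words = c(45.4, 89.55, 132.56, 174.61, 215.53, 255.32),
    sd_words = c(5.4, 12.02, 20.94, 31.42, 43.17, 69.23),
    mean_surprisal = c(3.76, 3.69, 3.8, 3.87, 3.93, 3.99),
    sd_surprisal = c(1.64, 1.17, 1.87, 1.93, 1.97, 2.02),
    n_timepoints = c(683, 668, 653, 638, 623, 608)
  )
}
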