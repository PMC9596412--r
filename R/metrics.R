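#' Surprisal and saliency metrics
#'
#' Surprisal of a token is the negative base-10 logarithm of its conditional
#' probability given the left context:
#' \deqn{\mathrm{surprisal}(t) = -\log_{10} P(t \mid \mathrm{context})}
#' Saliency of each context token is the gradient-times-input attribution:
#' the L2 norm of the elementwise product between the context token's
#' embedding and the gradient of the predicted token's score with respect to
#' that embedding, normalized so the vector sums to one.
#'
#' @name metrics_core
NULL

#' Token surprisal from a next-token distribution
#'
#' @param dist Probability vector over the vocabulary (from
#'   [next_token_distribution()]).
#' @param target_id 1-based vocabulary index of the observed token.
#' @param p_floor Probabilities below this are clamped before the log so the
#'   result stays finite (softmax outputs are strictly positive, but a
#'   serialized or truncated distribution may carry exact zeros).
#' @return Non-negative surprisal in base-10 log units (bans x log2(10)).
#' @export
surprisal <- function(dist, target_id, p_floor = 1e-12) {
  if (target_id < 1L || target_id > length(dist)) {
    stop_surpsal("oov-token", "target_id outside the distribution's support")
  }
  p <- max(dist[[target_id]], p_floor)
  -log10(p) + 0   # + 0 avoids IEEE negative zero at p = 1
}

#' Gradient-times-input saliency vector
#'
#' Per context token j, the raw score is
#' \eqn{\|\mathrm{grad}_j \odot x_j\|_2}; the vector is then divided by its
#' sum so the weights form a probability vector over the context.
#'
#' @param grads n_context x d gradient matrix ([class_score_gradient()]).
#' @param embeds n_context x d context embedding matrix.
#' @param zero_policy What to do when every raw score is zero (degenerate
#'   gradient): "uniform" (default) spreads weight evenly, "error" aborts.
#' @return Numeric vector of length n_context, non-negative, summing to 1.
#' @export
saliency_vector <- function(grads, embeds, zero_policy = c("uniform", "error")) {
  zero_policy <- match.arg(zero_policy)
  grads <- as.matrix(grads); embeds <- as.matrix(embeds)
  if (!all(dim(grads) == dim(embeds)) || nrow(grads) < 1) {
    stop_surpsal("bad-schema", "gradient and embedding shapes must match")
  }
  raw <- sqrt(rowSums((grads * embeds)^2))
  s <- sum(raw)
  if (s == 0) {
    if (zero_policy == "error") {
      stop_surpsal("degenerate-gradient", "all saliency scores are zero")
    }
    return(rep(1 / length(raw), length(raw)))
  }
  raw / s
}

#' Compute surprisal and saliency for every token of a transcript
#'
#' Slides over the transcript one token at a time: for each target, the
#' context is every preceding token within `window_s` seconds
#' ([build_window()]); the language model supplies the next-token
#' distribution and the score gradient. Targets whose truncated context is
#' empty get NA surprisal and no saliency vector.
#'
#' @param x A `transcript` with a `token_id` column.
#' @param lm A language-model adapter (e.g. [toy_decay_lm()]).
#' @param window_s Window length in seconds.
#' @param words_only If TRUE, saliency vectors are computed only for word
#'   targets (surprisal is always computed for every token).
#' @param score Score convention passed to [class_score_gradient()].
#' @return List with components:
#'   `surprisal` — data.frame(token_index, onset_s, surprisal, is_full,
#'   n_context); `saliency` — list of per-target records (target_index,
#'   context_indices, weights, is_full); `window_s`.
#' @export
compute_all_metrics <- function(x, lm, window_s, words_only = FALSE,
                                score = "logit") {
  if (is.null(x$token_id)) {
    stop_surpsal("bad-schema", "transcript needs a token_id column (read with a vocab)")
  }
  n <- nrow(x)
  surp <- rep(NA_real_, n)
  full <- logical(n)
  nctx <- integer(n)
  sal <- vector("list", n)
  for (i in seq_len(n)) {
    w <- build_window(x, i, window_s)
    full[i] <- w$is_full
    nctx[i] <- w$n_context
    if (w$n_context == 0) next
    ids <- x$token_id[w$context_indices]
    tid <- x$token_id[i]
    surp[i] <- surprisal(next_token_distribution(lm, ids), tid)
    if (!words_only || isTRUE(x$is_word[i])) {
      G <- class_score_gradient(lm, ids, tid, score = score)
      X <- context_embeddings(lm, ids)
      sal[[i]] <- list(target_index = i,
                       context_indices = w$context_indices,
                       weights = saliency_vector(G, X),
                       is_full = w$is_full)
    }
  }
  list(surprisal = data.frame(token_index = seq_len(n),
                              onset_s = x$onset_s,
                              surprisal = surp,
                              is_full = full,
                              n_context = nctx),
       saliency = Filter(Negate(is.null), sal),
       window_s = window_s)
}

#' Aggregate per-prediction saliency vectors into a token-level series
#'
#' Each full-window prediction distributes a unit of normalized saliency over
#' its context tokens; this operation maps those per-prediction vectors back
#' onto transcript positions to obtain one value per token, usable as an
#' fMRI predictor. Predictions with a truncated window (is_full = FALSE) are
#' excluded, which is why the downstream analysis retains fewer fMRI time
#' points for saliency than for surprisal. Tokens appearing in no retained
#' context are NA.
#'
#' @param saliency List of per-target saliency records (from
#'   [compute_all_metrics()]).
#' @param x The `transcript` the records index into.
#' @param mode "mean_received" (default): mean weight a token receives over
#'   all retained predictions containing it; "sum_received": the sum (mass
#'   over tokens then totals the number of retained predictions);
#'   "last_prediction": the weight from the most recent retained prediction
#'   containing the token.
#' @return data.frame(token_index, onset_s, value, n_predictions).
#' @export
aggregate_received_saliency <- function(saliency, x,
                                        mode = "mean_received") {
  if (!mode %in% c("mean_received", "sum_received", "last_prediction")) {
    stop_surpsal("bad-mode", sprintf("unknown aggregation mode '%s'", mode))
  }
  n <- nrow(x)
  acc <- numeric(n)
  cnt <- integer(n)
  last <- rep(NA_real_, n)
  for (rec in saliency) {
    if (!isTRUE(rec$is_full)) next
    idx <- rec$context_indices
    acc[idx] <- acc[idx] + rec$weights
    cnt[idx] <- cnt[idx] + 1L
    last[idx] <- rec$weights            # records arrive in target order
  }
  value <- switch(mode,
    mean_received = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
    sum_received = ifelse(cnt > 0, acc, NA_real_),
    last_prediction = last
  )
  data.frame(token_index = seq_len(n), onset_s = x$onset_s,
             value = value, n_predictions = cnt)
}

#' Correlation between mean context size and mean surprisal across windows
#'
#' Longer windows hand the model more (and more heterogeneous) context; the
#' study quantified the resulting drift in average surprisal as the Pearson
#' correlation between per-window mean context size (tokens) and per-window
#' mean surprisal.
#'
#' @param mean_tokens Numeric vector of per-window mean context sizes.
#' @param mean_surprisal Numeric vector of per-window mean surprisals.
#' @return List with `r` (Pearson coefficient) and `p` (two-sided p value).
#' @export
tokens_vs_surprisal_correlation <- function(mean_tokens, mean_surprisal) {
  stopifnot(length(mean_tokens) == length(mean_surprisal))
  if (length(mean_tokens) < 3) {
    stop_surpsal("degenerate-correlation", "need at least 3 paired values")
  }
  if (stats::sd(mean_tokens) == 0 || stats::sd(mean_surprisal) == 0) {
    stop_surpsal("degenerate-correlation", "zero variance in an input")
  }
  ct <- stats::cor.test(mean_tokens, mean_surprisal)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Write a per-window metrics table to TSV
#'
#' Columns: token_index, onset_s, surprisal, received_saliency, is_full.
#'
#' @param metrics Output of [compute_all_metrics()].
#' @param received Output of [aggregate_received_saliency()] on the same
#'   metrics (optional; NA column if absent).
#' @param path Output TSV path.
#' @export
write_metrics_tsv <- function(metrics, received = NULL, path) {
  df <- metrics$surprisal
  df$received_saliency <- if (is.null(received)) NA_real_ else received$value
  df$is_full <- as.integer(df$is_full)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
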