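# Seeded builders shared across test files.

rand_toy_lm <- function(seed, V = 10, d = 4, gamma = 0.7) {
  set.seed(seed)
  toy_decay_lm(matrix(rnorm(V * d), V, d),
               matrix(rnorm(V * d), V, d),
               gamma,
               paste0("tok", seq_len(V)))
}

rand_transcript <- function(seed, n = 40, duration = 60, V = 10) {
  set.seed(seed)
  onsets <- sort(runif(n, 0, duration * 0.98))
  transcript(data.frame(
    token = paste0("tok", sample.int(V, n, replace = TRUE)),
    onset_s = onsets,
    duration_s = runif(n, 0.05, 0.4),
    is_word = runif(n) < 0.6,
    lex_freq = runif(n, 1, 1000),
    token_id = sample.int(V, n, replace = TRUE)
  ), total_duration_s = duration)
}

# analytic saliency for the toy decay model: gamma^(n-j) * ||U_c (*) X_j||_2,
# sum-normalized — used as the closed-form oracle
toy_saliency_closed_form <- function(lm, context_ids, target_id) {
  n <- length(context_ids)
  raw <- numeric(n)
  for (j in seq_len(n)) {
    x <- lm$E[context_ids[j], ]
    raw[j] <- lm$gamma^(n - j) * sqrt(sum((lm$U[target_id, ] * x)^2))
  }
  raw / sum(raw)
}
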