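test_that("surprisal unit cases follow the -log10 definition", {
  expect_equal(surprisal(c(1, 0), 1), 0)
  expect_equal(surprisal(c(0.1, 0.9), 1), 1)
  expect_equal(surprisal(rep(1 / 1000, 1000), 17), 3)
  expect_error(surprisal(c(0.5, 0.5), 3), class = "surpsal_error_oov_token")
})

test_that("zero probabilities are clamped, keeping surprisal finite", {
  expect_equal(surprisal(c(1, 0), 2), 12)           # default floor 1e-12
  expect_equal(surprisal(c(1, 0), 2, p_floor = 1e-6), 6)
})

test_that("saliency on the decay model follows the closed form", {
  # gamma = 0: only the most recent context token contributes
  lm0 <- rand_toy_lm(2, V = 8, d = 3, gamma = 0)
  ctx <- c(3L, 1L, 5L)
  s0 <- saliency_vector(class_score_gradient(lm0, ctx, 2L),
                        context_embeddings(lm0, ctx))
  expect_equal(s0, c(0, 0, 1))

  # gamma = 0.5, identical embeddings: weights (1/3, 2/3)
  E <- matrix(rep(c(1, 2), each = 4), 4, 2, byrow = FALSE)
  E[1, ] <- c(1, 2); E[2, ] <- c(1, 2)
  lmI <- toy_decay_lm(E, matrix(rnorm(8), 4, 2), 0.5, paste0("t", 1:4))
  sI <- saliency_vector(class_score_gradient(lmI, c(1L, 2L), 3L),
                        context_embeddings(lmI, c(1L, 2L)))
  expect_equal(sI, c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("saliency matches the analytic expression on random models", {
  for (seed in 1:15) {
    lm <- rand_toy_lm(seed + 100, V = 6 + seed %% 8, d = 2 + seed %% 5,
                      gamma = 0.05 + 0.09 * (seed %% 10))
    set.seed(seed)
    ctx <- sample.int(lm$V, 2 + seed %% 10, replace = TRUE)
    tid <- sample.int(lm$V, 1)
    s <- saliency_vector(class_score_gradient(lm, ctx, tid),
                         context_embeddings(lm, ctx))
    expect_equal(s, toy_saliency_closed_form(lm, ctx, tid), tolerance = 1e-10)
    expect_true(all(s >= 0))
    expect_equal(sum(s), 1, tolerance = 1e-9)
  }
})

test_that("degenerate all-zero saliency follows the configured policy", {
  G <- matrix(0, 3, 2)
  X <- matrix(1, 3, 2)
  expect_equal(saliency_vector(G, X), rep(1 / 3, 3))
  expect_error(saliency_vector(G, X, zero_policy = "error"),
               class = "surpsal_error_degenerate_gradient")
})

test_that("compute_all_metrics matches a step-by-step scalar oracle", {
  x <- rand_transcript(5, n = 5, duration = 8, V = 6)
  lm <- rand_toy_lm(6, V = 6, d = 3, gamma = 0.7)
  met <- compute_all_metrics(x, lm, 15)
  # independent re-computation with plain arithmetic
  for (i in 2:5) {
    ctx_idx <- which(x$onset_s >= x$onset_s[i] - 15 &
                       x$onset_s < x$onset_s[i] & seq_len(5) < i)
    ids <- x$token_id[ctx_idx]
    n <- length(ids)
    g <- rep(0, 3)
    for (j in seq_len(n)) g <- g + 0.7^(n - j) * lm$E[ids[j], ]
    z <- as.numeric(lm$U %*% g)
    p <- exp(z - max(z)); p <- p / sum(p)
    expect_equal(met$surprisal$surprisal[i], -log10(p[x$token_id[i]]),
                 tolerance = 1e-12)
    raw <- sapply(seq_len(n), function(j)
      0.7^(n - j) * sqrt(sum((lm$U[x$token_id[i], ] * lm$E[ids[j], ])^2)))
    rec <- met$saliency[[i - 1]]
    expect_equal(rec$weights, raw / sum(raw), tolerance = 1e-12)
  }
  expect_true(is.na(met$surprisal$surprisal[1]))  # empty context
})

test_that("a near-deterministic transition model yields near-zero surprisal", {
  n <- 12; V <- 5
  ids <- rep_len(1:V, n)
  x <- transcript(data.frame(token = paste0("t", ids),
                             onset_s = seq(0, by = 0.5, length.out = n),
                             duration_s = 0.1, is_word = TRUE, lex_freq = 1,
                             token_id = ids))
  U <- matrix(0, V, V)
  for (j in 1:V) U[ifelse(j == V, 1, j + 1), j] <- 60  # next id gets a huge logit
  lm <- toy_decay_lm(diag(V), U, 0, paste0("t", 1:V))  # gamma 0: last token only
  met <- compute_all_metrics(x, lm, 15)
  expect_lt(max(met$surprisal$surprisal[-1]), 1e-8)
})

test_that("widening the window changes surprisal only where the context grew", {
  x <- rand_transcript(9, n = 30, duration = 60, V = 8)
  lm <- rand_toy_lm(9, V = 8, d = 4, gamma = 0.8)
  m15 <- compute_all_metrics(x, lm, 15)$surprisal$surprisal
  m45 <- compute_all_metrics(x, lm, 45)$surprisal$surprisal
  for (i in 2:30) {
    same_ctx <- identical(build_window(x, i, 15)$context_indices,
                          build_window(x, i, 45)$context_indices)
    if (same_ctx) expect_equal(m45[i], m15[i])
  }
  # at least some contexts must differ on a 60-s transcript
  expect_false(identical(m15, m45))
})

test_that("received-saliency aggregation matches a brute-force oracle", {
  x <- rand_transcript(12, n = 25, duration = 50, V = 8)
  lm <- rand_toy_lm(13, V = 8, d = 3, gamma = 0.6)
  met <- compute_all_metrics(x, lm, 15)
  agg <- aggregate_received_saliency(met$saliency, x, mode = "mean_received")
  sums <- numeric(25); cnts <- integer(25)
  for (rec in met$saliency) {
    if (!rec$is_full) next
    sums[rec$context_indices] <- sums[rec$context_indices] + rec$weights
    cnts[rec$context_indices] <- cnts[rec$context_indices] + 1L
  }
  expect_equal(agg$value[cnts > 0], (sums / pmax(cnts, 1))[cnts > 0])
  expect_true(all(is.na(agg$value[cnts == 0])))

  # sum_received conserves total mass: one unit per retained prediction
  agg_sum <- aggregate_received_saliency(met$saliency, x, mode = "sum_received")
  n_full <- sum(vapply(met$saliency, function(r) isTRUE(r$is_full), TRUE))
  expect_equal(sum(agg_sum$value, na.rm = TRUE), n_full, tolerance = 1e-9)

  expect_error(aggregate_received_saliency(met$saliency, x, mode = "median"),
               class = "surpsal_error_bad_mode")
})

test_that("last_prediction mode maps a single vector onto its context", {
  x <- rand_transcript(20, n = 6, duration = 10, V = 5)
  lm <- rand_toy_lm(21, V = 5, d = 3, gamma = 0.5)
  met <- compute_all_metrics(x, lm, 15)
  keep <- met$saliency[length(met$saliency)]
  keep[[1]]$is_full <- TRUE
  agg <- aggregate_received_saliency(keep, x, mode = "last_prediction")
  expect_equal(agg$value[keep[[1]]$context_indices], keep[[1]]$weights)
  expect_true(all(is.na(agg$value[-keep[[1]]$context_indices])))
})

test_that("context-size versus surprisal correlation behaves as a Pearson r", {
  ref <- reference_window_stats()
  r <- tokens_vs_surprisal_correlation(ref$mean_tokens, ref$mean_surprisal)
  expect_equal(round(r$r, 2), 0.93)
  expect_lt(r$p, 0.05)
  expect_equal(tokens_vs_surprisal_correlation(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(tokens_vs_surprisal_correlation(1:5, -2 * (1:5))$r, -1)
  expect_error(tokens_vs_surprisal_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "surpsal_error_degenerate_correlation")
  expect_error(tokens_vs_surprisal_correlation(c(1, 2), c(1, 2)),
               class = "surpsal_error_degenerate_correlation")
})
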