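test_that("double-gamma kernel peaks at the specified delay with unit peak", {
  k <- hrf_kernel(hrf_spec(), dt = 0.1)
  expect_equal((which.max(k) - 1) * 0.1, 6, tolerance = 0.1)
  expect_equal(max(k), 1)
  expect_lt(min(k), 0)   # undershoot present
  expect_gt(sum(k), 0)   # net positive response
  expect_error(hrf_kernel(hrf_spec(), dt = 0), class = "surpsal_error_bad_dt")
})

test_that("event series places amplitude-modulated impulses at onsets", {
  x <- transcript(data.frame(token = "a", onset_s = 10, duration_s = 0.2,
                             is_word = TRUE, lex_freq = 1),
                  total_duration_s = 20)
  es <- event_series(x, 3.5, dt = 0.1)
  expect_equal(es$series[101], 3.5)
  expect_equal(sum(es$series != 0), 1)

  x2 <- transcript(data.frame(token = c("a", "b"), onset_s = c(5.01, 5.07),
                              duration_s = 0.1, is_word = TRUE, lex_freq = 1),
                   total_duration_s = 10)
  es2 <- event_series(x2, c(1, 2), dt = 0.1)
  expect_equal(es2$series[51], 3)   # same bin: amplitudes add

  expect_equal(sum(event_series(x2, c(0, 0), dt = 0.1)$series), 0)
  expect_equal(sum(event_series(x2, c(NA, 2), dt = 0.1)$series), 2)
  expect_error(event_series(x2, c(1, 2), dt = 0.1, duration_s = 4),
               class = "surpsal_error_event_out_of_range")
})

test_that("convolution reproduces shifted scaled kernels and is linear", {
  x <- transcript(data.frame(token = "a", onset_s = 0, duration_s = 0.1,
                             is_word = TRUE, lex_freq = 1),
                  total_duration_s = 60)
  k <- hrf_kernel(hrf_spec(), dt = 0.1)
  ps <- convolve_resample(event_series(x, 2, dt = 0.1), k, tr = 1, n_volumes = 30)
  # impulse of amplitude 2 at t = 0: samples are 2 * kernel at 1-s lags
  expect_equal(ps$values, 2 * k[seq(1, by = 10, length.out = 30)],
               tolerance = 1e-10)

  x2 <- rand_transcript(31, n = 20, duration = 60)
  set.seed(31)
  a <- runif(20); b <- runif(20)
  pa <- convolve_resample(event_series(x2, a, dt = 0.1), k, 1, 60)$values
  pb <- convolve_resample(event_series(x2, b, dt = 0.1), k, 1, 60)$values
  pab <- convolve_resample(event_series(x2, a + b, dt = 0.1), k, 1, 60)$values
  expect_lt(max(abs(pab - (pa + pb))), 1e-10)
  p3a <- convolve_resample(event_series(x2, 3 * a, dt = 0.1), k, 1, 60)$values
  expect_lt(max(abs(p3a - 3 * pa)), 1e-10)
})

test_that("resampling to the scan grid returns exactly T volumes", {
  x <- rand_transcript(7, n = 100, duration = 715)
  set.seed(7)
  k <- hrf_kernel(hrf_spec(), dt = 0.1)
  ps <- convolve_resample(event_series(x, runif(100), dt = 0.1), k,
                          tr = 1, n_volumes = 709)
  expect_length(ps$values, 709)
})

test_that("validity mask drops the initial window-plus-buffer span", {
  expect_equal(sum(valid_timepoint_mask(15, 1, 709, 11)), 683)
  expect_equal(sum(valid_timepoint_mask(0, 1, 709, 0)), 709)
  counts <- sapply(seq(15, 90, 15), function(W)
    sum(valid_timepoint_mask(W, 1, 709, 11)))
  expect_equal(diff(counts), rep(-15, 5))   # one step per window increment
  expect_error(valid_timepoint_mask(200, 1, 150, 11),
               class = "surpsal_error_empty_mask")
})

test_that("design assembly standardizes within the mask and checks rank", {
  set.seed(101)
  v <- rnorm(100)
  mask <- valid_timepoint_mask(15, 1, 100, 5)
  interest <- predictor_series(v, valid = mask, tr = 1, name = "surprisal")
  nuis <- list(WD = predictor_series(rnorm(100), tr = 1, name = "WD"))
  d <- build_design(interest, nuis)
  expect_equal(colnames(d$X), c("intercept", "surprisal", "WD"))
  for (j in 2:3) {
    expect_equal(mean(d$X[d$mask, j]), 0, tolerance = 1e-9)
    expect_equal(sd(d$X[d$mask, j]), 1, tolerance = 1e-9)
  }

  dup <- list(S2 = predictor_series(v, tr = 1, name = "S2"))
  expect_error(build_design(interest, dup),
               class = "surpsal_error_collinear_design")
  expect_error(
    build_design(predictor_series(rep(0, 100), tr = 1, name = "x"), nuis),
    class = "surpsal_error_empty_predictor")
  expect_error(
    build_design(interest, list(WD = predictor_series(rnorm(50), tr = 1,
                                                      name = "WD"))),
    class = "surpsal_error_bad_schema")
})

test_that("predictor TSV round-trips values and mask", {
  set.seed(55)
  ps <- predictor_series(rnorm(40), valid = c(rep(FALSE, 5), rep(TRUE, 35)),
                         tr = 1.5, name = "surprisal")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictor_tsv(ps, path)
  ps2 <- read_predictor_tsv(path, name = "surprisal")
  expect_equal(ps2$values, ps$values, tolerance = 1e-12)
  expect_identical(ps2$valid, ps$valid)
  expect_equal(ps2$tr, 1.5)
})
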