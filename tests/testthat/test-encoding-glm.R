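make_design <- function(Tn = 60, seed = 1) {
  set.seed(seed)
  interest <- predictor_series(rnorm(Tn), tr = 1, name = "surprisal")
  nuis <- list(WD = predictor_series(rnorm(Tn), tr = 1, name = "WD"))
  build_design(interest, nuis)
}

test_that("noiseless signals are recovered exactly by the first-level OLS", {
  d <- make_design(80, seed = 2)
  y <- 1 + 2 * d$X[, "surprisal"] + 0.5 * d$X[, "WD"]
  fit <- fit_subject(cbind(roiA = y, roiB = 2 * y), d)
  expect_equal(unname(fit$beta["surprisal", "roiA"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$beta["intercept", "roiA"]), 1, tolerance = 1e-8)
  expect_equal(unname(fit$beta["surprisal", "roiB"]), 4, tolerance = 1e-8)
  expect_equal(fit$dof, 80 - 3)
})

test_that("first-level betas match the closed-form normal-equations oracle", {
  d <- make_design(10, seed = 3)
  set.seed(4)
  Y <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("r", 1:3)))
  fit <- fit_subject(Y, d)
  X <- d$X[d$mask, ]
  beta_oracle <- solve(t(X) %*% X, t(X) %*% Y[d$mask, ])
  expect_equal(unname(fit$beta), unname(beta_oracle), tolerance = 1e-10)
  # residuals orthogonal to every design column
  res <- Y[d$mask, ] - X %*% fit$beta
  expect_lt(max(abs(t(X) %*% res)), 1e-8)
})

test_that("signal made purely of nuisance leaves the interest beta near zero", {
  d <- make_design(200, seed = 5)
  set.seed(6)
  y <- 3 * d$X[, "WD"] + rnorm(200, sd = 0.1)
  fit <- fit_subject(matrix(y, dimnames = list(NULL, "r1")), d)
  se <- sqrt(fit$sigma2[1] * solve(crossprod(d$X))["surprisal", "surprisal"])
  expect_lt(abs(fit$beta["surprisal", 1]), 3 * se)
})

test_that("orthogonal designs reduce betas to simple projections", {
  Tn <- 64
  x1 <- rep(c(-1, 1), Tn / 2)
  x2 <- rep(c(-1, -1, 1, 1), Tn / 4)
  d <- build_design(predictor_series(x1, tr = 1, name = "a"),
                    list(b = predictor_series(x2, tr = 1, name = "b")),
                    standardize = FALSE)
  set.seed(8)
  y <- rnorm(Tn)
  fit <- fit_subject(matrix(y, dimnames = list(NULL, "r")), d)
  expect_equal(unname(fit$beta["a", 1]), sum(x1 * y) / sum(x1^2), tolerance = 1e-10)
  expect_equal(unname(fit$beta["b", 1]), sum(x2 * y) / sum(x2^2), tolerance = 1e-10)
})

test_that("FW-BW contrast subtracts interest betas and validates labels", {
  d <- make_design(40, seed = 9)
  set.seed(10)
  Y <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("r1", "r2")))
  f1 <- fit_subject(Y, d)
  expect_equal(unname(contrast_fw_bw(f1, f1)), c(0, 0))

  f2 <- f1
  f2$beta["surprisal", ] <- f1$beta["surprisal", ] - c(1.5, 2)
  expect_equal(unname(contrast_fw_bw(f1, f2)), c(1.5, 2))

  f3 <- f1
  f3$roi_labels <- rev(f1$roi_labels)
  expect_error(contrast_fw_bw(f1, f3), class = "surpsal_error_roi_mismatch")
})

test_that("group test matches t.test and applies Bonferroni arithmetic", {
  set.seed(11)
  C <- matrix(rnorm(27 * 6, mean = rep(c(0, 0.5), each = 3 * 27)), 27, 6)
  colnames(C) <- paste0("r", 1:6)
  g <- group_test(C, n_comparisons = 1000, sided = "two")
  for (j in 1:6) {
    tt <- t.test(C[, j])
    expect_equal(g$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(g$p[j], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(g$p_bonferroni, pmin(1, g$p * 1000))
  expect_identical(g$significant, g$p_bonferroni < 0.05)
  expect_equal(g$dof[1], 26)
})

test_that("one-sided test is sign-sensitive, two-sided is symmetric", {
  set.seed(12)
  C <- matrix(rnorm(20 * 4, mean = 0.3), 20, 4)
  g_pos <- group_test(C, sided = "one")
  g_neg <- group_test(-C, sided = "one")
  expect_true(all(g_pos$p + g_neg$p > 1 - 1e-12))  # complementary tails
  g2_pos <- group_test(C, sided = "two")
  g2_neg <- group_test(-C, sided = "two")
  expect_equal(g2_pos$p, g2_neg$p)
})

test_that("degenerate ROIs get sentinel t values", {
  C <- cbind(zero = rep(0, 10), const = rep(1, 10))
  expect_warning(g <- group_test(C), "zero-variance")
  expect_equal(g$t[1], 0)
  expect_false(g$significant[1])
  expect_equal(g$t[2], Inf)
  expect_error(group_test(C[1:2, ]), class = "surpsal_error_insufficient_dof")
})

test_that("cross-window overlap matches brute-force set algebra", {
  mk <- function(flags) {
    data.frame(roi = paste0("r", seq_along(flags)), significant = flags)
  }
  same <- list(a = mk(c(TRUE, FALSE, TRUE)), b = mk(c(TRUE, FALSE, TRUE)))
  s1 <- summarize_across_windows(same)
  expect_equal(s1$n_union, s1$n_intersection)

  disj <- lapply(1:6, function(i) mk(seq_len(6) == i))
  names(disj) <- paste0("w", 1:6)
  s2 <- summarize_across_windows(disj)
  expect_equal(s2$n_union, 6)
  expect_equal(s2$n_intersection, 0)

  set.seed(13)
  rnd <- lapply(1:4, function(i) mk(runif(50) < 0.3))
  names(rnd) <- paste0("w", 1:4)
  s3 <- summarize_across_windows(rnd)
  sets <- lapply(rnd, function(r) r$roi[r$significant])
  expect_setequal(s3$union, Reduce(union, sets))
  expect_setequal(s3$intersection, Reduce(intersect, sets))
  expect_equal(s3$per_window$n_significant,
               vapply(sets, length, 0L), ignore_attr = TRUE)
})
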