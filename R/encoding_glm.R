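#' Two-level ROI encoding GLM
#'
#' First level: per subject and condition, ordinary least squares of each
#' ROI-averaged BOLD series on the design matrix (valid time points only).
#' Second level: the per-subject forward-minus-backward difference of the
#' interest beta is tested per ROI with a one-sample t test (dof = S - 1),
#' the standard summary-statistics implementation of a mixed-effects group
#' analysis, with Bonferroni correction over ROIs.
#'
#' @name encoding_glm
NULL

#' Fit the first-level GLM for one subject and condition
#'
#' @param roi_matrix T x R matrix of ROI-averaged BOLD values (columns named
#'   by ROI label).
#' @param design A `design_matrix` from [build_design()].
#' @param ar1 Optional AR(1) coefficient for prewhitening (both sides of the
#'   regression are filtered with \eqn{y_t - \rho y_{t-1}}); NULL = off.
#' @return List of class `subject_fit`: `beta` (p x R), `sigma2` (length R
#'   residual variances), `dof`, `colnames`, `roi_labels`.
#' @export
fit_subject <- function(roi_matrix, design, ar1 = NULL) {
  roi_matrix <- as.matrix(roi_matrix)
  if (nrow(roi_matrix) != nrow(design$X)) {
    stop_surpsal("bad-schema", "BOLD series length does not match the design")
  }
  X <- design$X[design$mask, , drop = FALSE]
  Y <- roi_matrix[design$mask, , drop = FALSE]
  if (!is.null(ar1)) {
    stopifnot(abs(ar1) < 1)
    X <- X[-1, , drop = FALSE] - ar1 * X[-nrow(X), , drop = FALSE]
    Y <- Y[-1, , drop = FALSE] - ar1 * Y[-nrow(Y), , drop = FALSE]
  }
  dof <- nrow(X) - ncol(X)
  if (dof <= 0) stop_surpsal("insufficient-dof", "more regressors than valid time points")
  fit <- stats::lm.fit(X, Y)
  beta <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  structure(list(beta = beta,
                 sigma2 = colSums(res^2) / dof,
                 dof = dof,
                 colnames = design$colnames,
                 roi_labels = colnames(roi_matrix) %||%
                   paste0("ROI", seq_len(ncol(roi_matrix)))),
            class = "subject_fit")
}

#' Forward-minus-backward contrast of the interest beta
#'
#' @param fit_fw,fit_bw `subject_fit` objects for the two conditions; must
#'   share ROI labels and design columns.
#' @param column Name of the interest column (default: the first
#'   non-intercept column).
#' @return Named numeric vector of per-ROI contrast values (FW - BW).
#' @export
contrast_fw_bw <- function(fit_fw, fit_bw, column = NULL) {
  if (!identical(fit_fw$roi_labels, fit_bw$roi_labels) ||
      !identical(fit_fw$colnames, fit_bw$colnames)) {
    stop_surpsal("roi-mismatch", "fits disagree on ROI labels or design columns")
  }
  column <- column %||% setdiff(fit_fw$colnames, "intercept")[1]
  stats::setNames(fit_fw$beta[column, ] - fit_bw$beta[column, ],
                  fit_fw$roi_labels)
}

#' Group-level one-sample t test with Bonferroni correction
#'
#' @param contrasts S x R matrix of per-subject, per-ROI contrast values.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_comparisons Number of comparisons for the Bonferroni factor;
#'   defaults to the number of ROIs analyzed, overridable (e.g. to 1000 when
#'   a subset of a 1000-region parcellation is analyzed).
#' @param sided "one" (default; tests contrast > 0) or "two".
#' @return data.frame of class `group_result`: roi, mean_contrast, t, dof,
#'   p, p_bonferroni, significant.
#' @export
group_test <- function(contrasts, alpha = 0.05, n_comparisons = NULL,
                       sided = c("one", "two")) {
  sided <- match.arg(sided)
  contrasts <- as.matrix(contrasts)
  S <- nrow(contrasts)
  if (S < 3) stop_surpsal("insufficient-dof", "need at least 3 subjects")
  n_comparisons <- n_comparisons %||% ncol(contrasts)
  m <- colMeans(contrasts)
  se <- apply(contrasts, 2, stats::sd) / sqrt(S)
  tval <- ifelse(se == 0 & m == 0, 0,
                 ifelse(se == 0, sign(m) * Inf, m / se))
  if (any(se == 0 & m != 0)) {
    warning("zero-variance ROI(s) with nonzero mean: t set to +/-Inf")
  }
  dof <- S - 1
  p <- if (sided == "one") stats::pt(tval, dof, lower.tail = FALSE)
       else 2 * stats::pt(abs(tval), dof, lower.tail = FALSE)
  p_bonf <- pmin(1, p * n_comparisons)
  res <- data.frame(roi = colnames(contrasts) %||%
                      paste0("ROI", seq_len(ncol(contrasts))),
                    mean_contrast = m, t = tval, dof = dof, p = p,
                    p_bonferroni = p_bonf,
                    significant = p_bonf < alpha,
                    row.names = NULL)
  class(res) <- c("group_result", "data.frame")
  res
}

#' Significant-ROI overlap across window lengths
#'
#' @param results Named list of `group_result` objects, one per window.
#' @return List: `per_window` (data.frame window, n_significant),
#'   `n_union`, `n_intersection`, `union`, `intersection` (ROI label sets).
#' @export
summarize_across_windows <- function(results) {
  stopifnot(length(results) >= 1)
  sig_sets <- lapply(results, function(r) r$roi[r$significant])
  union_set <- Reduce(union, sig_sets)
  inter_set <- Reduce(intersect, sig_sets)
  list(per_window = data.frame(window = names(results) %||%
                                 as.character(seq_along(results)),
                               n_significant = vapply(sig_sets, length, 0L),
                               row.names = NULL),
       n_union = length(union_set),
       n_intersection = length(inter_set),
       union = union_set,
       intersection = inter_set)
}

#' Write per-window group results to TSV
#'
#' @param fw_betas,bw_betas Optional per-ROI interest betas (group means)
#'   to include alongside the contrast statistics.
#' @param result A `group_result`.
#' @param path TSV path.
#' @export
write_group_result_tsv <- function(result, path, fw_betas = NULL, bw_betas = NULL) {
  df <- as.data.frame(result)
  if (!is.null(fw_betas)) df$beta_fw <- fw_betas
  if (!is.null(bw_betas)) df$beta_bw <- bw_betas
  df$significant <- as.integer(df$significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
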