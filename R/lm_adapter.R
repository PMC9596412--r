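#' Language-model adapter contract
#'
#' The encoding pipeline needs three things from an autoregressive language
#' model: (i) a next-token probability distribution given a left context,
#' (ii) the embedding matrix of the context tokens, and (iii) the gradient
#' of the predicted token's score with respect to those embeddings. Any
#' object implementing the S3 generics [next_token_distribution()],
#' [context_embeddings()] and [class_score_gradient()] can drive the
#' pipeline; the package ships an analytic toy model ([toy_decay_lm()])
#' whose gradients have a closed form, plus a finite-difference oracle
#' ([finite_difference_gradient()]) to verify any adapter's gradients.
#'
#' @name lm_adapter
NULL

#' Analytic toy autoregressive language model with exponential recency decay
#'
#' A deterministic, fully differentiable stand-in for a transformer language
#' model. Context embeddings are pooled with exponential recency weights
#' (mimicking the recency bias of attention) and mapped to vocabulary logits:
#' \deqn{g = \sum_{j=1}^{n} \gamma^{\,n-j} X_j, \qquad z = U g}
#' where \eqn{X_j} is the embedding of the j-th context token, \eqn{\gamma}
#' the decay, and \eqn{U} the output matrix. Probabilities are
#' \eqn{\mathrm{softmax}(z)}. Because the score \eqn{z_c = U_c \cdot g} is
#' linear in the embeddings, the gradient of the target logit with respect
#' to context row j is exactly \eqn{\gamma^{\,n-j} U_c}, which makes every
#' downstream saliency computation checkable against a closed form.
#'
#' @param embedding V x d embedding table (numeric matrix).
#' @param output V x d output (unembedding) matrix.
#' @param gamma Recency decay in \[0, 1\]; 0 = only the last context token
#'   matters, 1 = uniform pooling.
#' @param vocab Character vector of V unique token strings.
#' @return An object of class `toy_decay_lm`.
#' @examples
#' lm <- toy_decay_lm(matrix(0, 3, 2), matrix(0, 3, 2), 0.5, c("a", "b", "c"))
#' next_token_distribution(lm, 1L)  # uniform: zero logits
#' @export
toy_decay_lm <- function(embedding, output, gamma, vocab) {
  embedding <- as.matrix(embedding)
  output <- as.matrix(output)
  stopifnot(
    nrow(embedding) == nrow(output),
    ncol(embedding) == ncol(output),
    length(vocab) == nrow(embedding),
    !anyDuplicated(vocab),
    gamma >= 0, gamma <= 1
  )
  structure(
    list(E = embedding, U = output, gamma = gamma, vocab = as.character(vocab),
         V = nrow(embedding), d = ncol(embedding)),
    class = "toy_decay_lm"
  )
}

#' @export
print.toy_decay_lm <- function(x, ...) {
  cat(sprintf("<toy_decay_lm> V=%d d=%d gamma=%.3f\n", x$V, x$d, x$gamma))
  invisible(x)
}

check_context <- function(lm, context_ids) {
  if (length(context_ids) == 0) {
    stop_surpsal("empty-context", "context must contain at least one token")
  }
  if (any(context_ids < 1L | context_ids > lm$V | context_ids != floor(context_ids))) {
    stop_surpsal("oov-token", sprintf(
      "context ids must be integers in 1..%d", lm$V))
  }
  as.integer(context_ids)
}

#' Recency pooling weights gamma^(n-j) for a context of length n
#' @keywords internal
decay_weights <- function(gamma, n) {
  # gamma^0 for the last token; 0^0 == 1 handles the gamma = 0 case
  gamma ^ ((n - 1):0)
}

#' Next-token probability distribution
#'
#' Returns the model's conditional distribution over the vocabulary given
#' the left-context token ids, i.e. the softmax-normalized scores attached
#' to the final context position.
#'
#' @param lm A language-model adapter object.
#' @param context_ids Integer vector of token ids (1-based vocabulary
#'   indices), oldest first.
#' @param ... Passed to methods.
#' @return Numeric vector of length V, non-negative, summing to 1.
#' @export
next_token_distribution <- function(lm, context_ids, ...) {
  UseMethod("next_token_distribution")
}

#' @export
next_token_distribution.toy_decay_lm <- function(lm, context_ids, ...) {
  context_ids <- check_context(lm, context_ids)
  z <- toy_logits(lm, context_ids)
  z <- z - max(z)                       # stabilized natural-log softmax
  p <- exp(z)
  p / sum(p)
}

toy_logits <- function(lm, context_ids) {
  n <- length(context_ids)
  w <- decay_weights(lm$gamma, n)
  X <- lm$E[context_ids, , drop = FALSE]
  g <- drop(crossprod(X, w))            # d-vector: sum_j w_j X_j
  drop(lm$U %*% g)
}

#' Context embedding matrix
#'
#' @inheritParams next_token_distribution
#' @return n_context x d numeric matrix, one row per context token.
#' @export
context_embeddings <- function(lm, context_ids, ...) {
  UseMethod("context_embeddings")
}

#' @export
context_embeddings.toy_decay_lm <- function(lm, context_ids, ...) {
  context_ids <- check_context(lm, context_ids)
  lm$E[context_ids, , drop = FALSE]
}

#' Gradient of the predicted token's score w.r.t. the context embeddings
#'
#' The "score assigned to the predicted token" is the pre-softmax logit of
#' the target class by default (`score = "logit"`, the common
#' gradient-times-input convention); `score = "logprob"` differentiates the
#' log-probability instead. For the toy model with the logit score, row j
#' of the gradient is exactly \eqn{\gamma^{\,n-j} U_c}.
#'
#' @inheritParams next_token_distribution
#' @param target_id Vocabulary index (1-based) of the predicted token.
#' @param score Which score to differentiate: "logit" (default) or "logprob".
#' @return n_context x d numeric matrix with attribute `target_id`.
#' @export
class_score_gradient <- function(lm, context_ids, target_id,
                                 score = c("logit", "logprob"), ...) {
  UseMethod("class_score_gradient")
}

#' @export
class_score_gradient.toy_decay_lm <- function(lm, context_ids, target_id,
                                              score = c("logit", "logprob"),
                                              ...) {
  score <- match.arg(score)
  context_ids <- check_context(lm, context_ids)
  if (target_id < 1L || target_id > lm$V) {
    stop_surpsal("oov-token", sprintf("target_id must be in 1..%d", lm$V))
  }
  n <- length(context_ids)
  w <- decay_weights(lm$gamma, n)
  if (score == "logit") {
    # d z_c / d X_j = gamma^(n-j) U_c
    G <- outer(w, lm$U[target_id, ])
  } else {
    # d log p_c / d X_j = gamma^(n-j) (U_c - sum_k p_k U_k)
    p <- next_token_distribution(lm, context_ids)
    G <- outer(w, lm$U[target_id, ] - drop(crossprod(lm$U, p)))
  }
  attr(G, "target_id") <- as.integer(target_id)
  G
}

#' Central finite-difference gradient oracle
#'
#' Approximates [class_score_gradient()] by perturbing one coordinate of one
#' context-embedding row at a time and evaluating the score. Intended as an
#' independent check of any adapter's analytic gradients; O(n*d) score
#' evaluations, so keep contexts small.
#'
#' @inheritParams class_score_gradient
#' @param step Central-difference step (> 0), e.g. 1e-5.
#' @return n_context x d matrix of central-difference gradient estimates.
#' @export
finite_difference_gradient <- function(lm, context_ids, target_id,
                                       step = 1e-5,
                                       score = c("logit", "logprob")) {
  score <- match.arg(score)
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop_surpsal("bad-step", "finite-difference step must be a positive scalar")
  }
  context_ids <- check_context(lm, context_ids)
  if (target_id < 1L || target_id > lm$V) {
    stop_surpsal("oov-token", sprintf("target_id must be in 1..%d", lm$V))
  }
  X <- context_embeddings(lm, context_ids)
  n <- nrow(X); d <- ncol(X)
  score_of <- function(Xmat) toy_score_from_embeddings(lm, Xmat, target_id, score)
  G <- matrix(0, n, d)
  for (j in seq_len(n)) {
    for (k in seq_len(d)) {
      Xp <- X; Xp[j, k] <- Xp[j, k] + step
      Xm <- X; Xm[j, k] <- Xm[j, k] - step
      G[j, k] <- (score_of(Xp) - score_of(Xm)) / (2 * step)
    }
  }
  attr(G, "target_id") <- as.integer(target_id)
  G
}

# Score of the target class given an explicit (possibly perturbed) context
# embedding matrix. Treats the context rows as free variables, so repeated
# tokens are perturbed independently, matching the per-position gradient.
toy_score_from_embeddings <- function(lm, Xmat, target_id, score) {
  n <- nrow(Xmat)
  w <- decay_weights(lm$gamma, n)
  g <- drop(crossprod(Xmat, w))
  z <- drop(lm$U %*% g)
  if (score == "logit") {
    z[target_id]
  } else {
    z <- z - max(z)
    z[target_id] - log(sum(exp(z)))
  }
}

#' Write / read a toy language model as a JSON sidecar
#'
#' @param lm A `toy_decay_lm`.
#' @param path Output JSON path.
#' @return `write_toy_lm` returns `path` invisibly; `read_toy_lm` returns
#'   the reconstructed `toy_decay_lm`.
#' @export
write_toy_lm <- function(lm, path) {
  stopifnot(inherits(lm, "toy_decay_lm"))
  obj <- list(
    vocab = lm$vocab, gamma = lm$gamma, d = lm$d,
    embedding = lm$E, output = lm$U
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_toy_lm
#' @export
read_toy_lm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toy_decay_lm(obj$embedding, obj$output, obj$gamma, obj$vocab)
}
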