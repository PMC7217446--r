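# Label-generation heads over context outputs: a per-report softmax layer and a
# linear-chain conditional random field. The CRF scores a label sequence by
# per-position emission terms (a linear projection of the context output) plus
# adjacent-label transition terms, normalised by the forward algorithm; all path
# computations are done in log-space.

#' Construct softmax head parameters
#' @param d input dimension
#' @param classes number of classes
#' @return `softmax_params` list with weight `W` (classes x d) and bias `b`
#' @export
softmax_params <- function(d, classes) {
  structure(list(W = init_mat(classes, d), b = init_vec(classes)),
            class = "softmax_params", classes = as.integer(classes))
}

#' Per-report softmax class distribution
#'
#' Computes P(y_i = k) = exp(w_k o_i + b_k) / sum_j exp(w_j o_i + b_j) for each
#' row o_i, in log-space for numerical stability.
#'
#' @param O numeric matrix of context outputs, one report per row
#' @param params a [softmax_params()] object
#' @return matrix of class probabilities, rows summing to 1
#' @export
softmax_predict <- function(O, params) {
  logits <- sweep(O %*% t(params$W), 2L, params$b, "+")
  softmax_rows(logits)
}

# mean cross-entropy loss over labelled rows; y is an integer vector in
# 1..classes, NA rows are excluded from the loss. Returns loss, dO and grads.
softmax_loss_backward <- function(O, y, params) {
  keep <- which(!is.na(y))
  probs <- softmax_predict(O, params)
  n <- length(keep)
  if (n == 0L)
    return(list(loss = 0, dO = O * 0,
                grads = list(W = params$W * 0, b = params$b * 0),
                probs = probs))
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(keep, y[keep])] + eps))
  dlogits <- probs
  dlogits[cbind(keep, y[keep])] <- dlogits[cbind(keep, y[keep])] - 1
  dlogits[setdiff(seq_along(y), keep), ] <- 0
  dlogits <- dlogits / n
  list(loss = loss,
       dO = dlogits %*% params$W,
       grads = list(W = crossprod(dlogits, O), b = colSums(dlogits)),
       probs = probs)
}

## ---- linear-chain CRF -------------------------------------------------------

#' Construct linear-chain CRF head parameters
#'
#' Emission scores come from a linear projection of each context output; the
#' transition matrix `T` holds a score for every ordered pair of adjacent
#' labels. No explicit start/stop scores are used: the first label is scored by
#' its emission alone.
#'
#' @param d input dimension
#' @param classes number of classes
#' @return `crf_params` list with `W` (classes x d), `b` (classes) and
#'   `T` (classes x classes, `T[j, k]` scoring a j -> k transition)
#' @export
crf_params <- function(d, classes) {
  structure(list(W = init_mat(classes, d), b = init_vec(classes),
                 T = matrix(0, classes, classes)),
            class = "crf_params", classes = as.integer(classes))
}

crf_emissions <- function(O, params) {
  sweep(O %*% t(params$W), 2L, params$b, "+")
}

# forward algorithm in log space; returns alpha matrix (n x K) and logZ
crf_forward_alg <- function(E, Tm) {
  n <- nrow(E); K <- ncol(E)
  alpha <- matrix(0, n, K)
  alpha[1L, ] <- E[1L, ]
  if (n > 1L) {
    for (t in 2L:n) {
      for (k in seq_len(K))
        alpha[t, k] <- E[t, k] + logsumexp(alpha[t - 1L, ] + Tm[, k])
    }
  }
  list(alpha = alpha, logZ = logsumexp(alpha[n, ]))
}

crf_backward_alg <- function(E, Tm) {
  n <- nrow(E); K <- ncol(E)
  beta <- matrix(0, n, K)
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      for (j in seq_len(K))
        beta[t, j] <- logsumexp(Tm[j, ] + E[t + 1L, ] + beta[t + 1L, ])
    }
  }
  beta
}

#' Log-likelihood of a label sequence under the CRF
#'
#' The path score is the sum of per-position emission scores plus transition
#' scores between adjacent labels; the log-partition is computed with the
#' forward algorithm in log-space.
#'
#' @param O context-output matrix, one report per row
#' @param y integer label sequence (1-based), same length as `nrow(O)`
#' @param params a [crf_params()] object
#' @return scalar `log P(y | O)`
#' @export
crf_loglik <- function(O, y, params) {
  K <- attr(params, "classes")
  if (any(is.na(y)) || any(y < 1L | y > K))
    stop("labels must be integers in 1..", K)
  E <- crf_emissions(O, params)
  n <- nrow(E)
  score <- sum(E[cbind(seq_len(n), y)])
  if (n > 1L)
    score <- score + sum(params$T[cbind(y[-n], y[-1L])])
  score - crf_forward_alg(E, params$T)$logZ
}

#' Viterbi decoding of the most likely label sequence
#'
#' Ties are broken toward the lowest class index.
#'
#' @inheritParams crf_loglik
#' @return integer vector of decoded labels (1-based)
#' @export
crf_decode <- function(O, params) {
  E <- crf_emissions(O, params)
  n <- nrow(E); K <- ncol(E)
  delta <- matrix(0, n, K)
  back <- matrix(1L, n, K)
  delta[1L, ] <- E[1L, ]
  if (n > 1L) {
    for (t in 2L:n) {
      for (k in seq_len(K)) {
        cand <- delta[t - 1L, ] + params$T[, k]
        j <- which.max(cand)          # first max = lowest index on ties
        back[t, k] <- j
        delta[t, k] <- E[t, k] + cand[j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L)
    for (t in (n - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  path
}

# negative mean (per report) log-likelihood plus gradients via forward-backward
# marginals. Returns loss, dO and grads {W, b, T}.
crf_loss_backward <- function(O, y, params) {
  E <- crf_emissions(O, params)
  n <- nrow(E); K <- ncol(E)
  fa <- crf_forward_alg(E, params$T)
  beta <- crf_backward_alg(E, params$T)
  logZ <- fa$logZ
  marg <- exp(fa$alpha + beta - logZ)           # n x K unary marginals
  dE <- marg
  dE[cbind(seq_len(n), y)] <- dE[cbind(seq_len(n), y)] - 1
  dT <- params$T * 0
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      pair <- exp(outer(fa$alpha[t, ], E[t + 1L, ] + beta[t + 1L, ], "+") +
                    params$T - logZ)
      dT <- dT + pair
    }
    for (t in seq_len(n - 1L))
      dT[y[t], y[t + 1L]] <- dT[y[t], y[t + 1L]] - 1
  }
  loss <- -crf_loglik_from(E, y, params$T, logZ) / n
  dE <- dE / n
  dT <- dT / n
  list(loss = loss,
       dO = dE %*% params$W,
       grads = list(W = crossprod(dE, O), b = colSums(dE), T = dT))
}

crf_loglik_from <- function(E, y, Tm, logZ) {
  n <- nrow(E)
  score <- sum(E[cbind(seq_len(n), y)])
  if (n > 1L) score <- score + sum(Tm[cbind(y[-n], y[-1L])])
  score - logZ
}
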