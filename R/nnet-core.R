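# Shared numeric primitives for the hand-rolled neural components: activations,
# parameter initialisation, the Adam optimizer, and the multi-head self-attention
# block used both by the case-level context module and the hierarchical encoder.
# All forward passes return a cache consumed by the matching backward pass.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded helpers (model construction, data generation) do not disturb the
#' surrounding random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# derivative of ELU expressed via pre-activation z
elu_deriv <- function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))

#' Numerically stable row-wise softmax
#' @param x numeric matrix
#' @return matrix of the same shape whose rows sum to 1
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Glorot/Xavier uniform initialisation; draws from the current RNG stream so
# that model construction is reproducible under set.seed().
init_mat <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_vec <- function(n) numeric(n)

## ---- Adam optimizer over flat named lists of numeric arrays ----------------

#' Initialise Adam optimizer state for a parameter list
#' @param params flat named list of numeric vectors/matrices
#' @keywords internal
adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

#' One Adam update step
#'
#' @param params,grads parallel flat named lists of numeric arrays
#' @param state optimizer state from [adam_init()]
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser
#' @return list(params = updated parameters, state = updated state)
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two parallel gradient lists (NULL-tolerant)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)

## ---- Multi-head self-attention block ---------------------------------------

#' Construct parameters for a multi-head self-attention block
#'
#' Query, key and value maps are 1D convolutions with window one (i.e. a shared
#' position-wise linear map) followed by an ELU activation. An optional table of
#' learned absolute positional embeddings is added to the input before the
#' projections.
#'
#' @param d_in input dimension of each sequence entry
#' @param d output (attention) dimension; must be divisible by `heads`
#' @param heads number of parallel attention heads
#' @param max_len maximum supported sequence length (rows of the positional
#'   table); ignored when `positional = FALSE`
#' @param positional whether to allocate a learned positional-embedding table
#' @param scale attention-score scaling: `"sqrt_d"` divides scores by
#'   `sqrt(d/heads)` per head (Transformer convention, the default) and `"d"`
#'   divides by the full dimension `d`
#' @return an `attention_params` list of weights
#' @export
attention_params <- function(d_in, d, heads = 6L, max_len = 64L,
                             positional = TRUE, scale = c("sqrt_d", "d")) {
  scale <- match.arg(scale)
  if (d %% heads != 0)
    stop("attention dimension d = ", d, " is not divisible by heads = ", heads)
  p <- list(
    Wq = init_mat(d_in, d), bq = init_vec(d),
    Wk = init_mat(d_in, d), bk = init_vec(d),
    Wv = init_mat(d_in, d), bv = init_vec(d)
  )
  if (positional)
    p$P <- matrix(stats::rnorm(max_len * d_in, sd = 0.1), max_len, d_in)
  structure(p, class = "attention_params", heads = as.integer(heads),
            scale = scale, d = as.integer(d), d_in = as.integer(d_in))
}

attn_scale_value <- function(params) {
  h <- attr(params, "heads")
  d <- attr(params, "d")
  if (attr(params, "scale") == "d") d else sqrt(d / h)
}

#' Multi-head self-attention forward pass
#'
#' @param X numeric matrix, one sequence entry per row
#' @param params an [attention_params()] object
#' @param causal if `TRUE`, entry i attends only to entries at positions <= i
#' @return list with `O` (output matrix, rows aligned with `X`), `A` (list of
#'   per-head attention matrices) and a `cache` for the backward pass
#' @export
attention_forward <- function(X, params, causal = FALSE) {
  n <- nrow(X)
  d <- attr(params, "d")
  h <- attr(params, "heads")
  dh <- d %/% h
  if (!is.null(params$P)) {
    if (n > nrow(params$P))
      stop("sequence length ", n, " exceeds positional table (",
           nrow(params$P), " rows)")
    Xp <- X + params$P[seq_len(n), , drop = FALSE]
  } else {
    Xp <- X
  }
  Zq <- sweep(Xp %*% params$Wq, 2L, params$bq, "+")
  Zk <- sweep(Xp %*% params$Wk, 2L, params$bk, "+")
  Zv <- sweep(Xp %*% params$Wv, 2L, params$bv, "+")
  Q <- elu(Zq); K <- elu(Zk); V <- elu(Zv)
  sc <- attn_scale_value(params)
  O <- matrix(0, n, d)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dh + 1L):(i * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sc
    if (causal && n > 1L) S[upper.tri(S)] <- -Inf
    Ai <- softmax_rows(S)
    A[[i]] <- Ai
    O[, idx] <- Ai %*% V[, idx, drop = FALSE]
  }
  list(O = O, A = A,
       cache = list(Xp = Xp, Zq = Zq, Zk = Zk, Zv = Zv,
                    Q = Q, K = K, V = V, A = A, n = n, causal = causal))
}

#' Multi-head self-attention backward pass
#'
#' @param dO gradient of the loss w.r.t. the block output
#' @param cache cache returned by [attention_forward()]
#' @param params the parameters used in the forward pass
#' @return list with `dX` (gradient w.r.t. the input rows) and `grads`
#'   (parameter gradients, including `P` when present)
#' @export
attention_backward <- function(dO, cache, params) {
  d <- attr(params, "d")
  h <- attr(params, "heads")
  dh <- d %/% h
  sc <- attn_scale_value(params)
  n <- cache$n
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dh + 1L):(i * dh)
    Ai <- cache$A[[i]]
    dOi <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOi, cache$V[, idx, drop = FALSE])     # n x n
    dV[, idx] <- crossprod(Ai, dOi)
    dS <- Ai * (dA - rowSums(dA * Ai))                      # softmax jacobian
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sc
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sc
  }
  dZq <- dQ * elu_deriv(cache$Zq)
  dZk <- dK * elu_deriv(cache$Zk)
  dZv <- dV * elu_deriv(cache$Zv)
  Xp <- cache$Xp
  grads <- list(
    Wq = crossprod(Xp, dZq), bq = colSums(dZq),
    Wk = crossprod(Xp, dZk), bk = colSums(dZk),
    Wv = crossprod(Xp, dZv), bv = colSums(dZv)
  )
  dXp <- dZq %*% t(params$Wq) + dZk %*% t(params$Wk) + dZv %*% t(params$Wv)
  if (!is.null(params$P)) {
    dP <- params$P * 0
    dP[seq_len(n), ] <- dXp
    grads$P <- dP
  }
  list(dX = dXp, grads = grads)
}

## ---- attention pooling (sequence -> single vector) -------------------------

# Learned-query attention pooling: weights a = softmax(X u), output t(X) a.
# Used by the hierarchical encoder to pool tokens into a line vector and lines
# into a document vector.
attn_pool_forward <- function(X, u) {
  s <- drop(X %*% u)
  a <- exp(s - max(s)); a <- a / sum(a)
  list(out = drop(crossprod(X, a)), cache = list(X = X, a = a, u = u))
}

attn_pool_backward <- function(dout, cache) {
  X <- cache$X; a <- cache$a; u <- cache$u
  da <- drop(X %*% dout)
  ds <- a * (da - sum(a * da))
  dX <- tcrossprod(a, dout) + tcrossprod(ds, u)
  du <- drop(crossprod(X, ds))
  list(dX = dX, du = du)
}
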