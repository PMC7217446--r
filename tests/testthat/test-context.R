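test_that("GRU with all-zero parameters outputs zeros", {
  set.seed(1)
  p <- gru_params(3L, 4L)
  for (nm in names(p)) p[[nm]][] <- 0
  O <- run_gru(matrix(rnorm(15L), 5L, 3L), p)
  # z = sigmoid(0) = 0.5, c = tanh(0) = 0, h = 0.5 h_prev -> stays at zero
  expect_equal(O, matrix(0, 5L, 4L))
})

test_that("scalar GRU matches a hand-rolled recurrence", {
  p <- gru_params(1L, 1L)
  p$Wz[] <- c(0.5, -0.3); p$bz[] <- 0.1
  p$Wr[] <- c(-0.2, 0.4); p$br[] <- -0.1
  p$Wc[] <- c(0.3, 0.7);  p$bc[] <- 0.2
  x <- c(0.8, -0.5)
  sig <- function(v) 1 / (1 + exp(-v))
  h <- 0
  H <- numeric(2L)
  for (t in 1:2) {
    z <- sig(0.5 * h - 0.3 * x[t] + 0.1)
    r <- sig(-0.2 * h + 0.4 * x[t] - 0.1)
    cc <- tanh(0.3 * (r * h) + 0.7 * x[t] + 0.2)
    h <- (1 - z) * h + z * cc
    H[t] <- h
  }
  O <- run_gru(matrix(x, 2L, 1L), p)
  expect_equal(drop(O), H, tolerance = 1e-12)
})

test_that("unidirectional GRU is bitwise invariant to future perturbations", {
  set.seed(2)
  p <- gru_params(3L, 4L, bidirectional = FALSE)
  E <- matrix(rnorm(18L), 6L, 3L)
  O <- run_gru(E, p)
  for (rep_i in 1:5) {
    j <- sample(2:6, 1L)
    E2 <- E
    E2[j:6, ] <- rnorm(length(E2[j:6, ]))
    O2 <- run_gru(E2, p)
    expect_identical(O2[seq_len(j - 1L), , drop = FALSE],
                     O[seq_len(j - 1L), , drop = FALSE])
  }
  # a bidirectional GRU does depend on the future
  pb <- gru_params(3L, 4L, bidirectional = TRUE)
  Ob <- run_gru(E, pb)
  E3 <- E; E3[6L, ] <- E3[6L, ] + 1
  expect_false(isTRUE(all.equal(run_gru(E3, pb)[1L, ], Ob[1L, ])))
  expect_error(run_gru(matrix(0, 2L, 5L), p), "dimension")
})

test_that("self-attention on a single entry reduces to its value row", {
  set.seed(3)
  p <- attention_params(4L, 4L, heads = 2L, max_len = 8L)
  E <- matrix(rnorm(4L), 1L, 4L)
  fwd <- attention_forward(E, p)
  for (h in 1:2) expect_equal(unname(fwd$A[[h]]), matrix(1, 1L, 1L))
  expect_equal(fwd$O, fwd$cache$V)
})

test_that("self-attention matrix matches a brute-force softmax oracle", {
  # single head, identity projections, no positional table: the attention
  # matrix must equal row-softmax(Q K^T / sqrt(d)) computed directly
  p <- attention_params(2L, 2L, heads = 1L, positional = FALSE)
  p$Wq <- diag(2L); p$Wk <- diag(2L); p$Wv <- diag(2L)
  p$bq[] <- 0; p$bk[] <- 0; p$bv[] <- 0
  X <- matrix(c(0.5, 1.2, 0.3, 0.8, 1.0, 0.1), 3L, 2L)  # positive: ELU = id
  fwd <- attention_forward(X, p)
  S <- X %*% t(X) / sqrt(2)
  A_manual <- exp(S) / rowSums(exp(S))
  expect_equal(fwd$A[[1L]], A_manual, tolerance = 1e-12)
  expect_equal(fwd$O, A_manual %*% X, tolerance = 1e-12)
  # the printed-equation variant scales by d instead of sqrt(d)
  pd <- attention_params(2L, 2L, heads = 1L, positional = FALSE, scale = "d")
  pd$Wq <- diag(2L); pd$Wk <- diag(2L); pd$Wv <- diag(2L)
  fd <- attention_forward(X, pd)
  Sd <- X %*% t(X) / 2
  expect_equal(fd$A[[1L]], exp(Sd) / rowSums(exp(Sd)), tolerance = 1e-12)
})

test_that("attention rows are stochastic, masked rows over allowed positions", {
  set.seed(4)
  p <- attention_params(6L, 6L, heads = 3L, max_len = 16L)
  for (rep_i in 1:10) {
    n <- sample(1:10, 1L)
    E <- matrix(rnorm(n * 6L), n, 6L)
    for (causal in c(FALSE, TRUE)) {
      fwd <- attention_forward(E, p, causal = causal)
      for (A in fwd$A) {
        expect_equal(rowSums(A), rep(1, n), tolerance = 1e-6)
        if (causal && n > 1L)
          expect_true(all(A[upper.tri(A)] == 0))
      }
    }
  }
})

test_that("masked self-attention is bitwise invariant to future perturbations", {
  set.seed(5)
  p <- attention_params(4L, 4L, heads = 2L, max_len = 16L)
  E <- matrix(rnorm(24L), 6L, 4L)
  O <- run_self_attention(E, p, causal = TRUE)
  for (rep_i in 1:5) {
    j <- sample(2:6, 1L)
    E2 <- E
    E2[j:6, ] <- rnorm(length(E2[j:6, ]))
    O2 <- run_self_attention(E2, p, causal = TRUE)
    expect_identical(O2[seq_len(j - 1L), , drop = FALSE],
                     O[seq_len(j - 1L), , drop = FALSE])
  }
  # unmasked attention propagates any change to every output
  Ou <- run_self_attention(E, p, causal = FALSE)
  E3 <- E; E3[6L, ] <- E3[6L, ] + 1
  Ou2 <- run_self_attention(E3, p, causal = FALSE)
  expect_true(all(abs(Ou2[1:5, ] - Ou[1:5, ]) > 0))
})

test_that("with no positional table and no mask, attention is permutation-equivariant", {
  set.seed(6)
  p <- attention_params(4L, 4L, heads = 2L, positional = FALSE)
  E <- matrix(rnorm(20L), 5L, 4L)
  perm <- sample(5L)
  O <- run_self_attention(E, p)
  Op <- run_self_attention(E[perm, ], p)
  expect_equal(Op, O[perm, ], tolerance = 1e-12)
})

test_that("sequences longer than the positional table are rejected", {
  set.seed(7)
  p <- attention_params(3L, 3L, heads = 1L, max_len = 4L)
  expect_error(run_self_attention(matrix(0, 5L, 3L), p), "positional")
})

test_that("attention analytic gradients match finite differences", {
  set.seed(8)
  p <- attention_params(3L, 4L, heads = 2L, max_len = 8L)
  X <- matrix(rnorm(12L), 4L, 3L)
  W <- matrix(rnorm(16L), 4L, 4L)
  for (causal in c(FALSE, TRUE)) {
    fwd <- attention_forward(X, p, causal = causal)
    bk <- attention_backward(W, fwd$cache, p)
    f <- function(v) sum(attention_forward(matrix(v, 4L, 3L), p,
                                           causal = causal)$O * W)
    expect_lt(max(abs(num_grad(f, as.vector(X)) - as.vector(bk$dX))), 1e-6)
    for (nm in c("Wq", "Wk", "Wv", "bv", "P")) {
      fp <- function(v) {
        p2 <- p
        p2[[nm]] <- if (is.matrix(p[[nm]])) matrix(v, nrow(p[[nm]]),
                                                   ncol(p[[nm]])) else v
        sum(attention_forward(X, p2, causal = causal)$O * W)
      }
      expect_lt(max(abs(num_grad(fp, as.vector(p[[nm]])) -
                          as.vector(bk$grads[[nm]]))), 1e-6)
    }
  }
})

test_that("GRU analytic gradients match finite differences", {
  set.seed(9)
  p <- gru_params(3L, 4L, bidirectional = TRUE)
  X <- matrix(rnorm(12L), 4L, 3L)
  W <- matrix(rnorm(32L), 4L, 8L)
  fwd <- casecontext:::gru_forward(X, p)
  bk <- casecontext:::gru_backward(W, fwd$cache, p)
  f <- function(v) sum(casecontext:::gru_forward(matrix(v, 4L, 3L), p)$O * W)
  expect_lt(max(abs(num_grad(f, as.vector(X)) - as.vector(bk$dX))), 1e-6)
  for (nm in c("Wz", "Wr", "Wc", "bz", "Wc_rev", "br_rev")) {
    fp <- function(v) {
      p2 <- p
      p2[[nm]] <- if (is.matrix(p[[nm]])) matrix(v, nrow(p[[nm]]),
                                                 ncol(p[[nm]])) else v
      sum(casecontext:::gru_forward(X, p2)$O * W)
    }
    expect_lt(max(abs(num_grad(fp, as.vector(p[[nm]])) -
                        as.vector(bk$grads[[nm]]))), 1e-6)
  }
})

test_that("case concatenation lengths, separators and label guards", {
  docs <- list(rep("a", 10L), rep("b", 20L), rep("c", 30L))
  all_cat <- concat_case(docs, i = 2L, mode = "all")
  expect_length(all_cat, 62L)                       # 60 tokens + 2 separators
  expect_equal(sum(all_cat == "separatortoken"), 2L)
  prev <- concat_case(docs, i = 2L, mode = "previous")
  expect_length(prev, 31L)                          # docs 1..2 + 1 separator
  first <- concat_case(docs, i = 1L, mode = "previous")
  expect_equal(first, docs[[1L]])                   # empty history
  # all-mode output ignores the target index
  expect_identical(concat_case(docs, i = 1L, mode = "all"),
                   concat_case(docs, i = 3L, mode = "all"))
  expect_error(concat_case(docs, i = 2L, mode = "all",
                           labels = c(1L, 1L, 2L)), "different labels")
  expect_error(concat_case(docs, i = 5L), "out of range")
})
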