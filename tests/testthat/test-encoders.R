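test_that("CNN with zero weights returns the zero embedding", {
  set.seed(1)
  enc <- cnn_encoder(10L, d_w = 4L, feature_maps = 3L)
  for (w in enc$windows) {
    enc$params[[paste0("W", w)]][] <- 0
    enc$params[[paste0("b", w)]][] <- 0
  }
  e <- encode_cnn(c(2L, 3L, 4L, 5L, 6L), enc)
  expect_equal(e, numeric(enc$d))
})

test_that("single-filter CNN response equals the hand-computed window product", {
  set.seed(2)
  enc <- cnn_encoder(8L, d_w = 3L, feature_maps = 1L, windows = 3L)
  doc <- c(2L, 5L, 7L)
  # independent scalar oracle: one window of 3 tokens, ReLU(x . w + b)
  x <- as.vector(t(enc$params$Emb[doc, ]))
  expected <- max(sum(x * enc$params$W3[, 1L]) + enc$params$b3[1L], 0)
  expect_equal(encode_cnn(doc, enc), expected)
})

test_that("CNN output is sensitive to token order within a window", {
  set.seed(3)
  enc <- cnn_encoder(12L, d_w = 5L, feature_maps = 4L)
  doc <- c(4L, 9L, 2L)
  e1 <- encode_cnn(doc, enc)
  e2 <- encode_cnn(rev(doc), enc)
  expect_false(isTRUE(all.equal(e1, e2)))
})

test_that("documents shorter than the largest window are padded, not rejected", {
  set.seed(4)
  enc <- cnn_encoder(10L, d_w = 4L, feature_maps = 2L)
  expect_length(encode_cnn(2L, enc), enc$d)
  expect_error(encode_cnn(integer(0), enc), "at least one token")
})

test_that("CNN analytic gradients match finite differences", {
  set.seed(5)
  enc <- cnn_encoder(12L, d_w = 4L, feature_maps = 3L, windows = c(2L, 3L))
  # move biases off the ReLU kink shared by tied padding windows
  enc$params$b2 <- rnorm(3L, sd = 0.3)
  enc$params$b3 <- rnorm(3L, sd = 0.3)
  docs <- list(c(2L, 5L, 7L, 3L, 9L), c(4L, 4L, 11L))
  W <- matrix(rnorm(2L * enc$d), 2L, enc$d)
  fwd <- casecontext:::cnn_forward_batch(docs, enc)
  gr <- casecontext:::cnn_backward_batch(W, fwd$cache, enc)
  for (nm in c("W2", "W3", "b2", "b3", "Emb")) {
    f <- function(v) {
      e2 <- enc
      p <- enc$params[[nm]]
      e2$params[[nm]] <- if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else v
      sum(casecontext:::cnn_forward_batch(docs, e2)$E * W)
    }
    ng <- num_grad(f, as.vector(enc$params[[nm]]))
    got <- as.vector(gr[[nm]])
    if (nm == "Emb") {
      # the padding row is frozen at zero by design
      ng <- matrix(ng, nrow(enc$params$Emb)); ng[1L, ] <- 0
      ng <- as.vector(ng)
    }
    expect_lt(max(abs(ng - got)), 1e-6)
  }
})

test_that("HiSAN embeds a single-token line deterministically with dim d", {
  set.seed(6)
  enc <- hisan_encoder(10L, d_w = 4L, d = 6L, heads = 2L)
  doc <- list(ids = 3L, lines = cbind(start = 1L, end = 1L))
  e1 <- encode_hisan(doc, enc)
  expect_length(e1, 6L)
  expect_identical(e1, encode_hisan(doc, enc))
})

test_that("HiSAN output dimension is d for documents of 1, 5 and 50 lines", {
  set.seed(7)
  enc <- hisan_encoder(20L, d_w = 4L, d = 6L, heads = 2L, max_lines = 64L)
  for (m in c(1L, 5L, 50L)) {
    ids <- sample(2:20, 3L * m, replace = TRUE)
    lines <- cbind(start = seq(1L, by = 3L, length.out = m),
                   end = seq(3L, by = 3L, length.out = m))
    expect_length(encode_hisan(list(ids = ids, lines = lines), enc), 6L)
  }
  expect_error(encode_hisan(list(ids = 1:3,
                                 lines = matrix(integer(0), 0L, 2L)), enc),
               "line")
})

test_that("duplicating a line changes pooling weights but not line embeddings", {
  set.seed(8)
  enc <- hisan_encoder(15L, d_w = 4L, d = 6L, heads = 2L)
  doc <- list(ids = c(2L, 5L, 7L, 9L, 3L, 4L),
              lines = cbind(start = c(1L, 4L), end = c(3L, 6L)))
  doc_dup <- list(ids = c(doc$ids, 2L, 5L, 7L),
                  lines = cbind(start = c(1L, 4L, 7L), end = c(3L, 6L, 9L)))
  L1 <- casecontext:::hisan_forward(doc, enc)$cache$L
  L2 <- casecontext:::hisan_forward(doc_dup, enc)$cache$L
  expect_equal(L2[1L, ], L1[1L, ])
  expect_equal(L2[2L, ], L1[2L, ])
  expect_equal(L2[3L, ], L2[1L, ])   # the duplicate line embeds identically
})

test_that("HiSAN analytic gradients match finite differences", {
  set.seed(9)
  enc <- hisan_encoder(12L, d_w = 3L, d = 4L, heads = 2L,
                       max_line_tokens = 16L, max_lines = 8L)
  doc <- list(ids = c(2L, 5L, 7L, 3L, 9L, 4L, 11L),
              lines = cbind(start = c(1L, 4L), end = c(3L, 7L)))
  w <- rnorm(4L)
  fwd <- casecontext:::hisan_forward(doc, enc)
  gr <- casecontext:::hisan_backward(w, fwd$cache, enc)
  for (nm in c("tok_Wq", "line_Wv", "u_tok", "u_line", "Emb", "tok_P")) {
    f <- function(v) {
      e2 <- enc
      p <- enc$params[[nm]]
      e2$params[[nm]] <- if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else v
      sum(casecontext:::hisan_forward(doc, e2)$e * w)
    }
    ng <- num_grad(f, as.vector(enc$params[[nm]]))
    got <- as.vector(gr[[nm]])
    if (nm == "Emb") {
      ng <- matrix(ng, nrow(enc$params$Emb)); ng[1L, ] <- 0
      ng <- as.vector(ng)
    }
    expect_lt(max(abs(ng - got)), 1e-6)
  }
})

test_that("extract_embeddings is deterministic and matches standalone encoding", {
  set.seed(10)
  enc <- cnn_encoder(15L, d_w = 4L, feature_maps = 3L)
  docs <- lapply(1:5, function(i) sample(2:15, sample(3:8, 1L), replace = TRUE))
  names(docs) <- paste0("r", 1:5)
  E1 <- extract_embeddings(docs, enc)
  E2 <- extract_embeddings(docs, enc)
  expect_identical(E1, E2)
  expect_equal(dim(E1), c(5L, enc$d))
  expect_equal(rownames(E1), paste0("r", 1:5))
  for (i in 1:5)
    expect_equal(unname(E1[i, ]), encode_cnn(docs[[i]], enc))
  expect_error(extract_embeddings(unname(docs), enc), "named")
})

test_that("embedding stores round-trip bit-exactly through the TSV layout", {
  set.seed(11)
  E <- matrix(rnorm(12L), 4L, 3L)
  rownames(E) <- paste0("r", 1:4)
  f <- tempfile(fileext = ".tsv")
  write_embeddings(E, f)
  back <- read_embeddings(f)
  expect_identical(unname(back), unname(E))
  expect_equal(rownames(back), rownames(E))
})
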