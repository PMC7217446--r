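# Shared test helpers: finite-difference gradients, exhaustive CRF oracles and
# small corpus fixtures built in code.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# brute-force linear-chain CRF: enumerate all K^n label paths
crf_enumerate <- function(E, Tm) {
  n <- nrow(E); K <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(E[cbind(seq_len(n), y)])
    if (n > 1L) s <- s + sum(Tm[cbind(y[-n], y[-1L])])
    s
  })
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       best_path = paths[which.max(scores), ],
       best_score = max(scores),
       paths = paths, scores = scores)
}

# small deterministic report corpus fixture
tiny_reports <- function() {
  as_report_corpus(data.frame(
    report_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    tumor_id = c("tA", "tA", "tA", "tB", "tB", "tC"),
    date = c("2010-03-01", "2009-01-15", "2009-06-30",
             "2012-05-01", "2012-07-01", "2013-01-01"),
    text = c("alpha beta", "gamma delta", "epsilon",
             "zeta eta", "theta", "iota"),
    site = c(1L, 1L, 1L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  ), tasks = "site")
}
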