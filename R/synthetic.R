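# Synthetic case-corpus generator. It emulates the statistical structure that
# makes case-level context necessary in registry pathology-report streams:
# cases of ~3.2 reports on average (minimum 2, matching singleton filtering)
# sharing one aggregate label per task; "addendum" reports carrying no
# label-relevant content; and label evidence optionally split across the
# reports of a case. It makes no attempt to mimic real pathology-report
# language or registry coding semantics.

#' Configuration for the synthetic corpus generator
#'
#' Case lengths follow 2 + Geometric(p) with p chosen so the mean equals
#' `mean_length`. Each class of each task owns a pair of cue tokens unique to
#' that class; a report either carries cue tokens (a signal report) or only
#' background tokens (an addendum). Every case keeps at least one signal
#' report (addendum flags are redrawn while all are set) unless
#' `addendum_rate` is exactly 1. With probability `cue_split_rate` the
#' evidence of a case is split: each signal report carries only one of the two
#' cue tokens, alternating, so no single report shows the full cue pair.
#' Background text is drawn from a Zipf distribution over `background_vocab`
#' token types so that rare types exercise unknown-token mapping.
#'
#' @param num_cases number of cases to generate
#' @param classes classes per task (K)
#' @param mean_length target mean reports per case (default 3.2, minimum 2)
#' @param addendum_rate per-report probability of being an addendum (default 0.3)
#' @param cue_split_rate per-case probability that cue evidence is split across
#'   reports (default 0.5)
#' @param background_vocab background token types (default 2000)
#' @param tokens_per_report background tokens per report (default 30)
#' @param label_noise probability a case's recorded label is flipped to a
#'   random other class (default 0)
#' @param tasks task names to label (default `"site"`)
#' @param year_range calendar years over which case start dates are drawn
#' @param dim,delta,sigma embedding-sequence generator: embedding dimension,
#'   pairwise distance between class centroids, and isotropic noise sd
#' @param seed RNG seed
#' @return a `synth_config` list
#' @export
synth_config <- function(num_cases = 2000L, classes = 4L, mean_length = 3.2,
                         addendum_rate = 0.3, cue_split_rate = 0.5,
                         background_vocab = 2000L, tokens_per_report = 30L,
                         label_noise = 0, tasks = "site",
                         year_range = c(2010L, 2017L),
                         dim = 32L, delta = 4, sigma = 1, seed = 1L) {
  stopifnot(mean_length >= 2, num_cases >= 1L, classes >= 2L,
            addendum_rate >= 0, addendum_rate <= 1,
            cue_split_rate >= 0, cue_split_rate <= 1,
            label_noise >= 0, label_noise <= 1)
  structure(list(num_cases = as.integer(num_cases),
                 classes = as.integer(classes),
                 mean_length = mean_length, addendum_rate = addendum_rate,
                 cue_split_rate = cue_split_rate,
                 background_vocab = as.integer(background_vocab),
                 tokens_per_report = as.integer(tokens_per_report),
                 label_noise = label_noise, tasks = tasks,
                 year_range = as.integer(year_range),
                 dim = as.integer(dim), delta = delta, sigma = sigma,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# geometric success probability giving the target mean case length
synth_geom_p <- function(config) {
  if (config$mean_length == 2) 1 else 1 / (config$mean_length - 1)
}

synth_case_lengths <- function(config) {
  2L + stats::rgeom(config$num_cases, synth_geom_p(config))
}

#' Cue tokens owned by each class of a task
#' @param task task name
#' @param classes number of classes
#' @return character matrix (classes x 2) of cue tokens
#' @export
cue_tokens <- function(task, classes) {
  cbind(sprintf("cue%s%sx", task, letters[seq_len(classes)]),
        sprintf("cue%s%sy", task, letters[seq_len(classes)]))
}

# addendum flags with >= 1 signal report per case (unless rate is exactly 1)
draw_addendum_flags <- function(L, rate) {
  if (rate >= 1) return(rep(TRUE, L))
  repeat {
    fl <- stats::runif(L) < rate
    if (!all(fl)) return(fl)
  }
}

#' Generate a synthetic token-level report corpus with ground truth
#'
#' @param config a [synth_config()]
#' @return list with `reports` (a `report_corpus` data.frame), `truth` (per
#'   report: `signal` flag; per case: label per task) and `config`
#' @export
generate_token_corpus <- function(config) {
  if (config$classes > 26L)
    stop("cue vocabulary supports at most 26 classes per task")
  with_seed(config$seed, {
    K <- config$classes
    cues <- lapply(config$tasks, cue_tokens, classes = K)
    names(cues) <- config$tasks
    zipf_p <- (1 / seq_len(config$background_vocab))
    zipf_p <- zipf_p / sum(zipf_p)
    bg_tokens <- sprintf("bg%04d", seq_len(config$background_vocab))
    lens <- synth_case_lengths(config)
    rows <- vector("list", config$num_cases)
    case_labels <- matrix(0L, config$num_cases, length(config$tasks),
                          dimnames = list(NULL, config$tasks))
    signal_flags <- vector("list", config$num_cases)
    for (ci in seq_len(config$num_cases)) {
      L <- lens[ci]
      tumor_id <- sprintf("T%06d", ci)
      flags <- draw_addendum_flags(L, config$addendum_rate)
      split_case <- stats::runif(1L) < config$cue_split_rate
      y <- vapply(config$tasks, function(t) sample.int(K, 1L), integer(1L))
      recorded <- y
      if (config$label_noise > 0) {
        for (ti in seq_along(recorded)) {
          if (stats::runif(1L) < config$label_noise)
            recorded[ti] <- sample(setdiff(seq_len(K), recorded[ti]), 1L)
        }
      }
      case_labels[ci, ] <- recorded
      signal_flags[[ci]] <- !flags
      start <- as.Date(sprintf("%d-01-01",
                               sample(config$year_range[1L]:config$year_range[2L], 1L))) +
        sample.int(365L, 1L) - 1L
      dates <- start + cumsum(c(0L, sample(10:120, L - 1L, replace = TRUE)))
      sig_idx <- which(!flags)
      cue_side <- integer(L)                 # 0 none, 1 first, 2 second, 3 both
      if (length(sig_idx)) {
        if (split_case && length(sig_idx) >= 2L) {
          cue_side[sig_idx] <- rep(1:2, length.out = length(sig_idx))
        } else {
          cue_side[sig_idx] <- 3L
        }
      }
      texts <- character(L)
      for (ri in seq_len(L)) {
        toks <- sample(bg_tokens, config$tokens_per_report,
                       replace = TRUE, prob = zipf_p)
        if (cue_side[ri] > 0L) {
          for (ti in seq_along(config$tasks)) {
            pair <- cues[[ti]][y[ti], ]
            ins <- switch(cue_side[ri], pair[1L], pair[2L], pair)
            pos <- sample.int(length(toks) + 1L, 1L) - 1L
            toks <- append(toks, ins, after = pos)
          }
        }
        # occasional line structure to exercise hierarchical encoding
        nl <- if (length(toks) > 12L)
          seq(12L, length(toks) - 1L, by = 12L) else integer(0)
        if (length(nl)) for (j in rev(nl)) toks <- append(toks, "\n", after = j)
        texts[ri] <- paste(gsub("^\\n$", "\n", toks), collapse = " ")
      }
      df <- data.frame(
        report_id = sprintf("%s-R%02d", tumor_id, seq_len(L)),
        tumor_id = tumor_id,
        date = as.character(dates),
        text = texts,
        stringsAsFactors = FALSE
      )
      for (ti in seq_along(config$tasks))
        df[[config$tasks[ti]]] <- recorded[ti]
      rows[[ci]] <- df
    }
    reports <- do.call(rbind, rows)
    truth <- list(
      case_labels = data.frame(tumor_id = sprintf("T%06d",
                                                  seq_len(config$num_cases)),
                               case_labels),
      signal = data.frame(report_id = reports$report_id,
                          signal = unlist(signal_flags))
    )
    list(reports = as_report_corpus(reports, config$tasks), truth = truth,
         config = config)
  })
}

#' Generate synthetic document-embedding sequences with labels
#'
#' Bypasses text encoders entirely: signal reports are drawn from their class
#' centroid (centroids at pairwise distance `delta`), addenda from a common
#' background centroid at the origin, both with isotropic Gaussian noise of sd
#' `sigma`.
#'
#' @param config a [synth_config()]
#' @return list with `seqs` (list of n_i x dim matrices), `labels` (list of
#'   integer vectors, constant within a case), `signal` (list of logical
#'   vectors) and `centroids` (K x dim matrix)
#' @export
generate_embedding_sequences <- function(config) {
  with_seed(config$seed, {
    K <- config$classes
    d <- config$dim
    if (K > d) stop("dim must be >= classes for the simplex centroid layout")
    centroids <- matrix(0, K, d)
    for (k in seq_len(K)) centroids[k, k] <- config$delta / sqrt(2)
    lens <- synth_case_lengths(config)
    seqs <- vector("list", config$num_cases)
    labels <- vector("list", config$num_cases)
    signal <- vector("list", config$num_cases)
    for (ci in seq_len(config$num_cases)) {
      L <- lens[ci]
      flags <- draw_addendum_flags(L, config$addendum_rate)
      y <- sample.int(K, 1L)
      E <- matrix(stats::rnorm(L * d, sd = config$sigma), L, d)
      for (ri in seq_len(L))
        if (!flags[ri]) E[ri, ] <- E[ri, ] + centroids[y, ]
      seqs[[ci]] <- E
      labels[[ci]] <- rep(y, L)
      signal[[ci]] <- !flags
    }
    names(seqs) <- names(labels) <- names(signal) <-
      sprintf("T%06d", seq_len(config$num_cases))
    list(seqs = seqs, labels = labels, signal = signal, centroids = centroids)
  })
}

#' Marginal per-report addendum fraction under the generator
#'
#' Accounts for the constraint that every case keeps at least one signal
#' report: for a case of length L the addendum count A is Binomial(L, rate)
#' conditioned on A < L. Returns the report-weighted expectation over the case
#' length distribution.
#'
#' @param config a [synth_config()]
#' @return expected fraction of reports that are addenda
#' @export
addendum_fraction <- function(config) {
  a <- config$addendum_rate
  if (a >= 1) return(1)
  p <- synth_geom_p(config)
  Ls <- 2:200
  pL <- stats::dgeom(Ls - 2L, p)
  eA <- Ls * (a - a^Ls) / (1 - a^Ls)
  sum(pL * eA) / sum(pL * Ls)
}

#' Closed-form per-report accuracy ceiling of a context-free classifier
#'
#' In the well-separated regime (`delta` much larger than `sigma`, or
#' class-unique cue tokens), a per-report classifier can identify every signal
#' report but can do no better than the 1/K prior on addenda, giving
#' (1 - a) + a / K where a is the marginal addendum fraction.
#'
#' @param config a [synth_config()]
#' @return the accuracy ceiling in [0, 1]
#' @export
per_report_ceiling <- function(config) {
  a <- addendum_fraction(config)
  (1 - a) + a / config$classes
}
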