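# Memoised synthetic uplift runs shared across the acceptance checks: the
# seed-101 run also carries the CRF-headed and end-to-end variants so the
# transition-recovery and modular-vs-end-to-end checks reuse its corpus,
# encoder and embeddings instead of retraining from scratch.

.uplift_cache <- new.env(parent = emptyenv())

get_uplift <- function(seed, heavy = FALSE) {
  key <- paste0("s", seed, if (heavy) "_heavy")
  if (!is.null(.uplift_cache[[key]])) return(.uplift_cache[[key]])
  res <- uplift_experiment(seed, include_crf = heavy, include_e2e = heavy)
  .uplift_cache[[key]] <- res
  res
}
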