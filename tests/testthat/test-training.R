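# small shared fixture: an easy embedding-sequence task
make_seq_task <- function(n_cases = 60L, seed = 1L, classes = 3L, dim = 8L) {
  sc <- synth_config(num_cases = n_cases, classes = classes, dim = dim,
                     delta = 4, sigma = 0.5, seed = seed)
  gen <- generate_embedding_sequences(sc)
  n_tr <- floor(0.7 * n_cases)
  list(train = list(seqs = gen$seqs[seq_len(n_tr)],
                    labels = gen$labels[seq_len(n_tr)]),
       val = list(seqs = gen$seqs[-seq_len(n_tr)],
                  labels = gen$labels[-seq_len(n_tr)]),
       classes = classes, dim = dim)
}

test_that("early stopping fires after `patience` flat epochs and restores the best", {
  accs <- c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.9, 0.9)
  epoch <- 0L
  snapshot <- NULL
  fit <- casecontext:::es_fit_loop(
    run_epoch = function() { epoch <<- epoch + 1L; 1 / epoch },
    val_acc = function() accs[epoch],
    get = function() epoch,
    set = function(p) snapshot <<- p,
    train_config(patience = 5L, max_epochs = 50L)
  )
  expect_equal(fit$stop_epoch, 7L)      # epochs 3..7 are five flat epochs
  expect_equal(fit$best_epoch, 2L)
  expect_equal(snapshot, 2L)            # parameters restored from epoch 2
  expect_equal(nrow(fit$log), 7L)
  expect_true(fit$stop_epoch - fit$best_epoch <= 5L)
})

test_that("monotonically improving validation accuracy runs to the epoch cap", {
  epoch <- 0L
  fit <- casecontext:::es_fit_loop(
    run_epoch = function() { epoch <<- epoch + 1L; 0 },
    val_acc = function() epoch / 100,
    get = function() epoch,
    set = function(p) invisible(p),
    train_config(patience = 3L, max_epochs = 12L)
  )
  expect_equal(fit$stop_epoch, 12L)
  expect_equal(fit$best_epoch, 12L)
})

test_that("context training is deterministic given the seed and reduces loss", {
  task <- make_seq_task(n_cases = 80L, seed = 2L)
  cfg <- train_config(batch_size = 16L, lr = 1e-2, patience = 5L,
                      max_epochs = 15L, seed = 11L)
  fit1 <- with_seed(5L, fit_with_early_stopping(
    context_classifier(task$dim, task$classes, context = "gru",
                       head = "softmax", hidden = 8L),
    task$train, task$val, cfg))
  fit2 <- with_seed(5L, fit_with_early_stopping(
    context_classifier(task$dim, task$classes, context = "gru",
                       head = "softmax", hidden = 8L),
    task$train, task$val, cfg))
  expect_identical(fit1$fit$log, fit2$fit$log)
  # loss decreases over the first epochs on this separable task
  expect_lt(fit1$fit$log$train_loss[nrow(fit1$fit$log)],
            fit1$fit$log$train_loss[1L])
  expect_gt(fit1$fit$best_val_acc, 0.5)
})

test_that("CRF-headed context training learns on shared-label sequences", {
  task <- make_seq_task(seed = 3L)
  cfg <- train_config(batch_size = 16L, lr = 1e-2, patience = 3L,
                      max_epochs = 8L, seed = 12L)
  fit <- with_seed(6L, fit_with_early_stopping(
    context_classifier(task$dim, task$classes, context = "attn",
                       head = "crf", heads = 4L, max_len = 64L),
    task$train, task$val, cfg))
  expect_gt(fit$fit$best_val_acc, 0.6)
})

test_that("modular training freezes the encoder in step 2", {
  sc <- synth_config(num_cases = 60L, classes = 3L, tokens_per_report = 10L,
                     background_vocab = 50L, seed = 4L)
  gen <- generate_token_corpus(sc)
  cases <- build_cases(gen$reports)
  split <- split_by_date(cases, seed = 4L)
  toks <- lapply(gen$reports$text, casecontext:::clean_text_lines)
  vocab <- build_vocab(lapply(toks, unlist), min_count = 2L)
  docs <- lapply(toks, function(l) {
    s <- segment_lines(l); s$ids <- encode_tokens(s$tokens, vocab); s
  })
  names(docs) <- gen$reports$report_id
  data <- task_dataset(cases, split, docs, "site")
  cfg <- train_config(batch_size = 16L, lr = 1e-3, patience = 2L,
                      max_epochs = 3L, seed = 13L)
  enc0 <- with_seed(7L, cnn_encoder(length(vocab), d_w = 8L, feature_maps = 4L))
  ctx0 <- with_seed(8L, context_classifier(12L, 3L, context = "attn",
                                           head = "softmax", max_len = 64L))
  pipe <- train_modular(enc0, ctx0, data, cfg)
  # step 1 alone produces the identical encoder: step 2 never touched it
  step1 <- fit_with_early_stopping(
    with_seed(cfg$seed, report_classifier(enc0, 3L)),
    list(docs = data$train$docs, labels = data$train$report_labels),
    list(docs = data$val$docs, labels = data$val$report_labels),
    cfg
  )
  expect_identical(pipe$encoder$params, step1$model$encoder$params)
  expect_identical(casecontext:::param_checksum(pipe$encoder$params),
                   casecontext:::param_checksum(step1$model$encoder$params))

  # step 2 re-run from the saved embedding store reproduces the context model
  f <- tempfile(fileext = ".tsv")
  write_embeddings(pipe$embeddings, f)
  emb2 <- read_embeddings(f)
  seqs <- casecontext:::case_seqs_from_embeddings
  refit <- fit_with_early_stopping(
    with_seed(8L, context_classifier(12L, 3L, context = "attn",
                                     head = "softmax", max_len = 64L)),
    list(seqs = seqs(emb2, data$train$cases), labels = data$train$case_labels),
    list(seqs = seqs(emb2, data$val$cases), labels = data$val$case_labels),
    cfg
  )
  expect_equal(refit$fit$log, pipe$context_fit$log)

  # end-to-end fine-tuning, by contrast, updates the encoder and its
  # word-embedding table
  ctx1 <- with_seed(8L, context_classifier(12L, 3L, context = "attn",
                                           head = "softmax", max_len = 64L))
  e2e <- train_end_to_end(pipe$encoder, ctx1, data,
                          train_config(batch_size = 16L, lr = 1e-3,
                                       patience = 1L, max_epochs = 2L,
                                       seed = 14L))
  expect_false(identical(e2e$encoder$params, pipe$encoder$params))
  emb_delta <- abs(e2e$encoder$params$Emb - pipe$encoder$params$Emb)
  expect_gt(max(emb_delta), 0)          # gradient reached the embedding table
  expect_equal(max(emb_delta[1L, ]), 0) # padding row stays frozen
})
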