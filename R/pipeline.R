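# Experiment pipeline: generate/load -> preprocess -> split -> (pre)train ->
# context-train -> evaluate -> compare. Each stage can persist its artifact in
# an output directory and is resumed from there when re-run, so a run is fully
# reconstructable from its output directory. The thin command-line wrapper in
# inst/cli/casectx maps subcommands onto these stages.

#' Experiment configuration
#'
#' @param task classification task name (a label column of the corpus)
#' @param encoder `"cnn"` or `"hisan"`
#' @param context one of `"none"`, `"concat"`, `"gru"`, `"gru_crf"`, `"attn"`,
#'   `"attn_crf"`
#' @param scenario `"bidirectional"` (offline: all reports of a case visible)
#'   or `"unidirectional"` (online: only previous reports visible)
#' @param regime `"modular"` (two-step: freeze encoder, train context on saved
#'   embeddings) or `"end_to_end"` (joint fine-tuning after encoder pretraining)
#' @param synth a [synth_config()] used when no `corpus_path` is given
#' @param corpus_path optional JSON-Lines corpus to load instead of generating
#' @param d_w,feature_maps,hidden,heads encoder/context dimensions (defaults
#'   match the reference setup: 300-d embeddings, 100 feature maps per window,
#'   GRU hidden 300, 6 attention heads)
#' @param attn_scale attention score scaling (`"sqrt_d"` or `"d"`)
#' @param max_case_len positional-table cap on reports per case; longer cases
#'   are truncated oldest-first with a warning
#' @param min_count vocabulary minimum corpus-wide token count
#' @param cutoff_year first test-set year (default 2016)
#' @param train_frac train fraction of the pre-cutoff cases (default 0.8)
#' @param batch_size,lr,patience,max_epochs training settings (see
#'   [train_config()])
#' @param eval_reps,eval_seed bootstrap settings for the final evaluation
#' @param concat_max_tokens estimated-concatenation-length cap above which
#'   `context = "concat"` with the hierarchical encoder is rejected
#' @param seed master seed for the run
#' @return an `experiment_config` list
#' @export
experiment_config <- function(task = "site",
                              encoder = c("cnn", "hisan"),
                              context = c("none", "concat", "gru", "gru_crf",
                                          "attn", "attn_crf"),
                              scenario = c("bidirectional", "unidirectional"),
                              regime = c("modular", "end_to_end"),
                              synth = synth_config(),
                              corpus_path = NULL,
                              d_w = 300L, feature_maps = 100L, hidden = NULL,
                              heads = 6L, attn_scale = "sqrt_d",
                              max_case_len = 64L, min_count = 5L,
                              cutoff_year = 2016L, train_frac = 0.8,
                              batch_size = 64L, lr = 1e-4, patience = 5L,
                              max_epochs = 100L,
                              eval_reps = 1000L, eval_seed = 1L,
                              concat_max_tokens = 20000L, seed = 1L) {
  cfg <- list(task = task, encoder = match.arg(encoder),
              context = match.arg(context), scenario = match.arg(scenario),
              regime = match.arg(regime), synth = synth,
              corpus_path = corpus_path, d_w = as.integer(d_w),
              feature_maps = as.integer(feature_maps),
              hidden = hidden, heads = as.integer(heads),
              attn_scale = attn_scale, max_case_len = as.integer(max_case_len),
              min_count = as.integer(min_count),
              cutoff_year = as.integer(cutoff_year), train_frac = train_frac,
              batch_size = as.integer(batch_size), lr = lr,
              patience = as.integer(patience),
              max_epochs = as.integer(max_epochs),
              eval_reps = as.integer(eval_reps),
              eval_seed = as.integer(eval_seed),
              concat_max_tokens = as.integer(concat_max_tokens),
              seed = as.integer(seed))
  structure(cfg, class = "experiment_config")
}

config_hash <- function(cfg) {
  r <- serialize(unclass(cfg), NULL)
  sprintf("%08x", sum(as.integer(r[-seq_len(14L)]) * (seq_along(r[-seq_len(14L)]) %% 251)) %%
            .Machine$integer.max)
}

vocab_hash <- function(vocab) {
  sprintf("%08x", (length(vocab) * 7919L +
                     sum(nchar(names(vocab))) %% 1000003L) %% .Machine$integer.max)
}

#' Assemble the per-split task data consumed by the trainers
#'
#' @param cases a `case_set`
#' @param split a `dataset_split`
#' @param docs named list of tokenized documents keyed by report_id
#' @param task label column name
#' @return list with `train`, `val`, `test`, each holding `docs`,
#'   `report_labels`, `cases` (report ids per case, date order) and
#'   `case_labels`
#' @export
task_dataset <- function(cases, split, docs, task) {
  one <- function(ids) {
    cs <- cases$cases[intersect(names(cases$cases), ids)]
    case_rids <- lapply(cs, function(df) df$report_id)
    case_labels <- lapply(cs, function(df) as.integer(df[[task]]))
    rids <- unlist(case_rids, use.names = FALSE)
    list(docs = docs[rids],
         report_labels = unlist(case_labels, use.names = FALSE),
         cases = case_rids,
         case_labels = case_labels)
  }
  list(train = one(split$train), val = one(split$val), test = one(split$test))
}

# truncate cases longer than the positional cap, keeping the newest reports
truncate_cases <- function(data, max_len) {
  for (sp in names(data)) {
    lens <- lengths(data[[sp]]$cases)
    long <- which(lens > max_len)
    if (length(long)) {
      warning(length(long), " case(s) longer than ", max_len,
              " reports truncated oldest-first")
      for (i in long) {
        keep <- (lens[i] - max_len + 1L):lens[i]
        data[[sp]]$cases[[i]] <- data[[sp]]$cases[[i]][keep]
        data[[sp]]$case_labels[[i]] <- data[[sp]]$case_labels[[i]][keep]
      }
    }
  }
  data
}

parse_context <- function(context) {
  list(mech = switch(context, gru = , gru_crf = "gru",
                     attn = , attn_crf = "attn", context),
       head = if (grepl("_crf$", context)) "crf" else "softmax")
}

build_encoder <- function(cfg, vocab_size) {
  if (cfg$encoder == "cnn") {
    cnn_encoder(vocab_size, d_w = cfg$d_w, feature_maps = cfg$feature_maps)
  } else {
    d <- 3L * cfg$feature_maps     # same output dim as the CNN configuration
    hisan_encoder(vocab_size, d_w = cfg$d_w, d = d, heads = cfg$heads)
  }
}

artifact <- function(dir, name) if (is.null(dir)) NULL else file.path(dir, name)

stage_msg <- function(stage, ...) {
  message(sprintf("[casecontext] %s: %s", stage, paste0(...)))
}

#' Run the full experiment pipeline
#'
#' Executes generate/load, preprocess, split, encoder (pre)training, context
#' training and evaluation for one configuration. With an output directory,
#' every stage artifact is written there and reused on re-run; `until` stops
#' the pipeline after the named stage (`"generate"`, `"preprocess"`,
#' `"split"`, `"train-encoder"`, `"embed"`, `"train-context"`,
#' `"evaluate"`).
#'
#' @param cfg an [experiment_config()]
#' @param out_dir optional artifact directory
#' @param until last stage to execute (default `"evaluate"`)
#' @return invisibly for intermediate `until` values; for `"evaluate"`, a
#'   `ctx_run` list with the evaluation report, test predictions, fit logs and
#'   trained models
#' @export
run_experiment <- function(cfg, out_dir = NULL,
                           until = c("evaluate", "generate", "preprocess",
                                     "split", "train-encoder", "embed",
                                     "train-context")) {
  until <- match.arg(until)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  chash <- config_hash(cfg)
  stage_order <- c("generate", "preprocess", "split", "train-encoder",
                   "embed", "train-context", "evaluate")
  want <- function(stage) match(stage, stage_order) <= match(until, stage_order)

  ## generate / load ----------------------------------------------------------
  corpus_file <- artifact(out_dir, "corpus.jsonl")
  if (!is.null(cfg$corpus_path)) {
    reports <- read_report_corpus(cfg$corpus_path, tasks = cfg$task)
    stage_msg("generate", "loaded ", nrow(reports), " reports from ",
              cfg$corpus_path)
  } else if (!is.null(corpus_file) && file.exists(corpus_file)) {
    reports <- read_report_corpus(corpus_file, tasks = cfg$task)
    stage_msg("generate", "reusing ", nrow(reports), " reports from ",
              corpus_file)
  } else {
    synth <- cfg$synth
    synth$seed <- cfg$seed
    gen <- generate_token_corpus(synth)
    reports <- gen$reports
    if (!is.null(corpus_file)) write_report_corpus(reports, corpus_file)
    stage_msg("generate", nrow(reports), " synthetic reports (seed ",
              cfg$seed, ")")
  }
  if (until == "generate") return(invisible(list(reports = reports)))

  ## preprocess ----------------------------------------------------------------
  cases <- build_cases(reports)
  toks <- lapply(reports$text, clean_text_lines)
  vocab_file <- artifact(out_dir, "vocab.tsv")
  if (!is.null(vocab_file) && file.exists(vocab_file)) {
    vocab <- read_vocab(vocab_file)
  } else {
    vocab <- build_vocab(lapply(toks, function(x) unlist(x, use.names = FALSE)),
                         min_count = cfg$min_count)
    if (!is.null(vocab_file)) write_vocab(vocab, vocab_file)
  }
  docs <- lapply(toks, function(lns) {
    seg <- segment_lines(lns)
    seg$ids <- encode_tokens(seg$tokens, vocab)
    seg
  })
  names(docs) <- reports$report_id
  stage_msg("preprocess", length(vocab), " vocabulary ids, ",
            length(docs), " tokenized documents")
  if (until == "preprocess") return(invisible(list(vocab = vocab, docs = docs)))

  ## split ---------------------------------------------------------------------
  split_file <- artifact(out_dir, "split.csv")
  if (!is.null(split_file) && file.exists(split_file)) {
    split <- read_split(split_file)
  } else {
    split <- split_by_date(cases, cutoff_year = cfg$cutoff_year,
                           train_frac = cfg$train_frac, seed = cfg$seed)
    if (!is.null(split_file)) write_split(split, split_file)
  }
  stage_msg("split", length(split$train), " train / ", length(split$val),
            " val / ", length(split$test), " test cases")
  data <- task_dataset(cases, split, docs, cfg$task)
  data <- truncate_cases(data, cfg$max_case_len)
  if (until == "split") return(invisible(list(split = split, data = data)))

  ## concat path (no separate context model) ----------------------------------
  if (cfg$context == "concat") {
    return(run_concat_experiment(cfg, data, vocab, out_dir, chash))
  }

  ## train-encoder -------------------------------------------------------------
  tcfg <- train_config(batch_size = cfg$batch_size, lr = cfg$lr,
                       patience = cfg$patience, max_epochs = cfg$max_epochs,
                       seed = cfg$seed)
  classes <- max(unlist(lapply(data, function(sp) sp$report_labels)),
                 na.rm = TRUE)
  enc_file <- artifact(out_dir, "encoder.rds")
  if (!is.null(enc_file) && file.exists(enc_file)) {
    ck <- readRDS(enc_file)
    enc <- ck$encoder; enc_head <- ck$head; enc_fit <- ck$fit
    stage_msg("train-encoder", "reusing checkpoint ", enc_file)
  } else {
    model0 <- with_seed(cfg$seed,
                        report_classifier(build_encoder(cfg, length(vocab)),
                                          classes))
    st1 <- fit_with_early_stopping(
      model0,
      list(docs = data$train$docs, labels = data$train$report_labels),
      list(docs = data$val$docs, labels = data$val$report_labels),
      tcfg
    )
    enc <- st1$model$encoder; enc_head <- st1$model$head; enc_fit <- st1$fit
    if (!is.null(enc_file))
      saveRDS(list(encoder = enc, head = enc_head, fit = enc_fit,
                   config_hash = chash, vocab_hash = vocab_hash(vocab),
                   seed = cfg$seed), enc_file)
    if (!is.null(out_dir))
      utils::write.csv(enc_fit$log, file.path(out_dir, "encoder_log.csv"),
                       row.names = FALSE)
    stage_msg("train-encoder", "best val acc ",
              sprintf("%.4f", enc_fit$best_val_acc), " at epoch ",
              enc_fit$best_epoch)
  }
  if (until == "train-encoder")
    return(invisible(list(encoder = enc, head = enc_head, fit = enc_fit)))

  ## baseline (context = none) -------------------------------------------------
  if (cfg$context == "none") {
    model <- structure(list(encoder = enc, head = enc_head),
                       class = "report_classifier")
    pred <- predict_reports(model, data$test$docs)
    run <- finish_run(cfg, data, pred$labels, pred$probs,
                      list(encoder_fit = enc_fit), out_dir, chash)
    return(run)
  }

  ## embed ---------------------------------------------------------------------
  emb_file <- artifact(out_dir, "embeddings.tsv")
  if (!is.null(emb_file) && file.exists(emb_file)) {
    emb <- read_embeddings(emb_file)
  } else {
    emb <- extract_embeddings(c(data$train$docs, data$val$docs,
                                data$test$docs), enc)
    if (!is.null(emb_file)) write_embeddings(emb, emb_file)
  }
  stage_msg("embed", nrow(emb), " x ", ncol(emb), " embedding store")
  if (until == "embed") return(invisible(list(embeddings = emb)))

  ## train-context -------------------------------------------------------------
  pc <- parse_context(cfg$context)
  hidden <- cfg$hidden %||% enc$d
  ctx_file <- artifact(out_dir, "context.rds")
  if (!is.null(ctx_file) && file.exists(ctx_file)) {
    ck <- readRDS(ctx_file)
    ctx_model <- ck$model; ctx_fit <- ck$fit; enc_eval <- ck$encoder %||% enc
  } else {
    ctx0 <- with_seed(cfg$seed + 1L, context_classifier(
      d_in = enc$d, classes = classes, context = pc$mech, head = pc$head,
      scenario = cfg$scenario, hidden = hidden, heads = cfg$heads,
      max_len = cfg$max_case_len, attn_scale = cfg$attn_scale))
    if (cfg$regime == "modular") {
      seqs <- function(sp) case_seqs_from_embeddings(emb, data[[sp]]$cases)
      st2 <- fit_with_early_stopping(
        ctx0,
        list(seqs = seqs("train"), labels = data$train$case_labels),
        list(seqs = seqs("val"), labels = data$val$case_labels),
        tcfg
      )
      ctx_model <- st2$model; ctx_fit <- st2$fit; enc_eval <- enc
    } else {
      mkcases <- function(sp) lapply(data[[sp]]$cases,
                                     function(rids) data[[sp]]$docs[rids])
      st2 <- fit_with_early_stopping(
        e2e_classifier(enc, ctx0),
        list(cases = mkcases("train"), labels = data$train$case_labels),
        list(cases = mkcases("val"), labels = data$val$case_labels),
        tcfg
      )
      ctx_model <- st2$model$ctx_model; ctx_fit <- st2$fit
      enc_eval <- st2$model$encoder
    }
    if (!is.null(ctx_file))
      saveRDS(list(model = ctx_model, fit = ctx_fit, encoder = enc_eval,
                   config_hash = chash, vocab_hash = vocab_hash(vocab),
                   seed = cfg$seed), ctx_file)
    if (!is.null(out_dir))
      utils::write.csv(ctx_fit$log, file.path(out_dir, "context_log.csv"),
                       row.names = FALSE)
    stage_msg("train-context", cfg$context, " (", cfg$scenario, ", ",
              cfg$regime, ") best val acc ",
              sprintf("%.4f", ctx_fit$best_val_acc))
  }
  if (until == "train-context")
    return(invisible(list(ctx_model = ctx_model, fit = ctx_fit)))

  ## evaluate ------------------------------------------------------------------
  if (cfg$regime == "modular") {
    test_seqs <- case_seqs_from_embeddings(emb, data$test$cases)
  } else {
    test_seqs <- lapply(data$test$cases, function(rids)
      encoder_embed_batch(enc_eval, data$test$docs[rids])$E)
  }
  preds <- unlist(predict_context(ctx_model, test_seqs), use.names = FALSE)
  finish_run(cfg, data,
             preds, NULL,
             list(encoder_fit = enc_fit, context_fit = ctx_fit,
                  ctx_model = ctx_model, encoder = enc_eval),
             out_dir, chash)
}

# concatenation-strategy experiment: the context is token-level, so the
# per-report classifier itself is trained on concatenated documents
run_concat_experiment <- function(cfg, data, vocab, out_dir, chash) {
  est_doc <- mean(vapply(data$train$docs, function(d) length(d$ids), numeric(1L)))
  est_case <- mean(lengths(data$train$cases))
  est_len <- est_doc * est_case
  if (cfg$encoder == "hisan" && est_len > cfg$concat_max_tokens)
    stop("concat with the hierarchical encoder rejected: estimated ",
         "concatenated length ", round(est_len), " exceeds cap ",
         cfg$concat_max_tokens)
  mode <- if (cfg$scenario == "bidirectional") "all" else "previous"
  sep_id <- unname(vocab[[SEP_TOKEN]])
  concat_ids <- function(docs, upto) {
    ids <- docs[[1L]]$ids
    if (upto > 1L) for (j in 2L:upto) ids <- c(ids, sep_id, docs[[j]]$ids)
    ids
  }
  build <- function(sp) {
    docs <- list(); labels <- integer(0); rid <- character(0)
    for (ci in seq_along(data[[sp]]$cases)) {
      rids <- data[[sp]]$cases[[ci]]
      cdocs <- data[[sp]]$docs[rids]
      labs <- data[[sp]]$case_labels[[ci]]
      if (mode == "all") {
        docs[[length(docs) + 1L]] <- list(ids = concat_ids(cdocs, length(cdocs)))
        labels <- c(labels, labs[1L])
        rid <- c(rid, rids[1L])
      } else {
        for (i in seq_along(rids)) {
          docs[[length(docs) + 1L]] <- list(ids = concat_ids(cdocs, i))
          labels <- c(labels, labs[i])
          rid <- c(rid, rids[i])
        }
      }
    }
    names(docs) <- rid
    list(docs = docs, labels = labels)
  }
  tr <- build("train"); va <- build("val")
  tcfg <- train_config(batch_size = cfg$batch_size, lr = cfg$lr,
                       patience = cfg$patience, max_epochs = cfg$max_epochs,
                       seed = cfg$seed)
  classes <- max(unlist(lapply(data, function(sp) sp$report_labels)),
                 na.rm = TRUE)
  model0 <- with_seed(cfg$seed,
                      report_classifier(build_encoder(cfg, length(vocab)),
                                        classes))
  st <- fit_with_early_stopping(model0,
                                list(docs = tr$docs, labels = tr$labels),
                                list(docs = va$docs, labels = va$labels),
                                tcfg)
  stage_msg("train-encoder", "concat-", mode, " best val acc ",
            sprintf("%.4f", st$fit$best_val_acc))
  # per-report test predictions: in "all" mode every report of a case shares
  # one concatenated input; in "previous" mode each report gets its prefix
  preds <- integer(0)
  for (ci in seq_along(data$test$cases)) {
    rids <- data$test$cases[[ci]]
    cdocs <- data$test$docs[rids]
    if (mode == "all") {
      p <- predict_reports(st$model,
                           list(list(ids = concat_ids(cdocs, length(cdocs)))))
      preds <- c(preds, rep(p$labels, length(rids)))
    } else {
      pdocs <- lapply(seq_along(rids),
                      function(i) list(ids = concat_ids(cdocs, i)))
      preds <- c(preds, predict_reports(st$model, pdocs)$labels)
    }
  }
  finish_run(cfg, data, preds, NULL, list(encoder_fit = st$fit,
                                          model = st$model), out_dir, chash)
}

# evaluation + artifact writing shared by all experiment paths
finish_run <- function(cfg, data, preds, probs, models, out_dir, chash) {
  truth <- unlist(data$test$case_labels, use.names = FALSE)
  rids <- unlist(data$test$cases, use.names = FALSE)
  tids <- rep(names(data$test$cases), lengths(data$test$cases))
  keep <- !is.na(truth)
  report <- evaluate_predictions(truth[keep], preds[keep],
                                 reps = cfg$eval_reps, seed = cfg$eval_seed)
  predictions <- data.frame(
    report_id = rids, tumor_id = tids, task = cfg$task,
    true_label = truth, pred_label = preds, stringsAsFactors = FALSE
  )
  if (!is.null(probs))
    predictions$max_prob <- apply(probs, 1L, max)
  if (!is.null(out_dir)) {
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    out <- c(unclass(report), list(config_hash = chash, seed = cfg$seed,
                                   context = cfg$context,
                                   scenario = cfg$scenario,
                                   regime = cfg$regime, task = cfg$task))
    jsonlite::write_json(out, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  stage_msg("evaluate", "test accuracy ", sprintf("%.4f", report$accuracy),
            ", macro-F ", sprintf("%.4f", report$macro_f))
  structure(list(eval = report, predictions = predictions, models = models,
                 config = cfg, config_hash = chash),
            class = "ctx_run")
}

#' Synthetic uplift experiment: per-report baseline vs case-level context
#'
#' Generates a synthetic token corpus, trains the per-report CNN baseline, and
#' trains bidirectional and unidirectional self-attention context models on
#' the frozen document embeddings (the modular regime). Optionally also trains
#' a CRF-headed context model and an end-to-end counterpart of the
#' bidirectional model. Reports test-set accuracies, the closed-form
#' per-report ceiling, and McNemar's test of the bidirectional context model
#' against the baseline.
#'
#' @param seed seed controlling generation, splitting and training
#' @param num_cases,classes synthetic corpus size and classes per task
#' @param d_w,feature_maps,heads reduced model dimensions (document embeddings
#'   have dimension `3 * feature_maps`)
#' @param include_crf also train self-attention + CRF (bidirectional) and
#'   report the learned transition-matrix diagonal dominance
#' @param include_e2e also fine-tune the bidirectional self-attention model
#'   end-to-end from the pretrained encoder
#' @param max_epochs epoch cap passed to [train_config()]
#' @return list of accuracies and diagnostics
#' @export
uplift_experiment <- function(seed, num_cases = 2000L, classes = 4L,
                              d_w = 32L, feature_maps = 12L, heads = 6L,
                              include_crf = FALSE, include_e2e = FALSE,
                              max_epochs = 100L) {
  sc <- synth_config(num_cases = num_cases, classes = classes, seed = seed)
  gen <- generate_token_corpus(sc)
  cases <- build_cases(gen$reports)
  split <- split_by_date(cases, seed = seed)
  toks <- lapply(gen$reports$text, clean_text_lines)
  vocab <- build_vocab(lapply(toks, function(x) unlist(x, use.names = FALSE)))
  docs <- lapply(toks, function(lns) {
    seg <- segment_lines(lns)
    seg$ids <- encode_tokens(seg$tokens, vocab)
    seg
  })
  names(docs) <- gen$reports$report_id
  data <- task_dataset(cases, split, docs, "site")
  tcfg <- train_config(max_epochs = max_epochs, seed = seed)

  enc0 <- with_seed(seed, report_classifier(
    cnn_encoder(length(vocab), d_w = d_w, feature_maps = feature_maps),
    classes))
  st1 <- fit_with_early_stopping(
    enc0,
    list(docs = data$train$docs, labels = data$train$report_labels),
    list(docs = data$val$docs, labels = data$val$report_labels),
    tcfg
  )
  truth <- unlist(data$test$case_labels, use.names = FALSE)
  base_pred <- predict_reports(st1$model, data$test$docs)$labels
  out <- list(
    seed = seed,
    n_test_reports = length(truth),
    ceiling = per_report_ceiling(sc),
    baseline_acc = accuracy_score(truth, base_pred),
    encoder_fit = st1$fit
  )

  emb <- extract_embeddings(c(data$train$docs, data$val$docs,
                              data$test$docs), st1$model$encoder)
  seqs <- function(sp) case_seqs_from_embeddings(emb, data[[sp]]$cases)
  train_ctx <- function(scenario, head) {
    ctx0 <- with_seed(seed + 1L, context_classifier(
      d_in = ncol(emb), classes = classes, context = "attn", head = head,
      scenario = scenario, heads = heads, max_len = 64L))
    st <- fit_with_early_stopping(
      ctx0,
      list(seqs = seqs("train"), labels = data$train$case_labels),
      list(seqs = seqs("val"), labels = data$val$case_labels),
      tcfg
    )
    pred <- unlist(predict_context(st$model, seqs("test")), use.names = FALSE)
    list(model = st$model, fit = st$fit, pred = pred,
         acc = accuracy_score(truth, pred))
  }
  bi <- train_ctx("bidirectional", "softmax")
  uni <- train_ctx("unidirectional", "softmax")
  out$attn_bi_acc <- bi$acc
  out$attn_uni_acc <- uni$acc
  out$mcnemar_bi_vs_baseline <- mcnemar_compare(bi$pred, base_pred, truth)

  if (include_crf) {
    crf <- train_ctx("bidirectional", "crf")
    Tm <- crf$model$head$T
    out$attn_crf_acc <- crf$acc
    out$crf_transition <- Tm
    out$crf_diag_dominance <- mean(diag(Tm)) -
      mean(Tm[row(Tm) != col(Tm)])
  }
  if (include_e2e) {
    ctx0 <- with_seed(seed + 1L, context_classifier(
      d_in = ncol(emb), classes = classes, context = "attn",
      head = "softmax", scenario = "bidirectional", heads = heads,
      max_len = 64L))
    e2e <- train_end_to_end(st1$model$encoder, ctx0, data, tcfg)
    test_seqs <- lapply(data$test$cases, function(rids)
      encoder_embed_batch(e2e$encoder, data$test$docs[rids])$E)
    pred <- unlist(predict_context(e2e$ctx_model, test_seqs),
                   use.names = FALSE)
    out$e2e_acc <- accuracy_score(truth, pred)
    out$modular_minus_e2e <- out$attn_bi_acc - out$e2e_acc
  }
  out
}

#' Pairwise McNemar comparison matrix across several runs
#'
#' @param runs named list of `ctx_run` objects (or prediction data frames)
#' @param path optional CSV path for the long-format comparison table
#' @return data.frame with one row per ordered model pair: discordant counts,
#'   p-value and method
#' @export
mcnemar_matrix <- function(runs, path = NULL) {
  nms <- names(runs)
  if (is.null(nms)) nms <- paste0("model", seq_along(runs))
  rows <- list()
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (i >= j) next
    res <- compare_runs(runs[[i]], runs[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      model_a = nms[i], model_b = nms[j], b = res$b, c = res$c,
      p_value = res$p_value, method = res$method,
      accuracy_a = res$accuracy_a, accuracy_b = res$accuracy_b,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Compare two runs with McNemar's test
#'
#' Aligns the test predictions of two `ctx_run` objects (or prediction data
#' frames) by report id and applies [mcnemar_compare()].
#'
#' @param runA,runB `ctx_run` objects or their `predictions` data frames
#' @return the [mcnemar_compare()] result plus both accuracies
#' @export
compare_runs <- function(runA, runB) {
  pa <- if (inherits(runA, "ctx_run")) runA$predictions else runA
  pb <- if (inherits(runB, "ctx_run")) runB$predictions else runB
  m <- merge(pa[, c("report_id", "true_label", "pred_label")],
             pb[, c("report_id", "pred_label")],
             by = "report_id", suffixes = c("_a", "_b"))
  res <- mcnemar_compare(m$pred_label_a, m$pred_label_b, m$true_label)
  res$accuracy_a <- accuracy_score(m$true_label, m$pred_label_a)
  res$accuracy_b <- accuracy_score(m$true_label, m$pred_label_b)
  res
}
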