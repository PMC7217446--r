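# Optimization regimes. All models train with Adam (default lr 1e-4) on
# batches of 64 (documents for encoders, case sequences for context models),
# with early stopping on validation accuracy: training stops when validation
# accuracy has not improved for `patience` consecutive epochs and the
# parameters from the best-validation epoch are restored. One model is trained
# per classification task; cross-validation is not used.

#' Training configuration
#'
#' @param batch_size minibatch size (documents or case sequences; default 64)
#' @param lr Adam learning rate (default 1e-4)
#' @param patience epochs without validation-accuracy improvement before
#'   stopping (default 5)
#' @param max_epochs hard cap on epochs (default 100)
#' @param seed RNG seed for shuffling (and any dropout-free stochasticity)
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 64L, lr = 1e-4, patience = 5L,
                         max_epochs = 100L, seed = 1L) {
  stopifnot(batch_size >= 1L, patience >= 1L, max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# shared early-stopping loop. run_epoch() performs one training epoch and
# returns its mean loss; val_acc() scores the current model; get/set snapshot
# parameters. Returns the train log and best/stop epochs, with best parameters
# restored via set().
es_fit_loop <- function(run_epoch, val_acc, get, set, config) {
  best_acc <- -Inf
  best_params <- get()
  best_epoch <- 0L
  streak <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_acc = numeric())
  stop_epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    loss <- run_epoch()
    acc <- val_acc()
    log <- rbind(log, data.frame(epoch = epoch, train_loss = loss,
                                 val_acc = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_params <- get()
      best_epoch <- epoch
      streak <- 0L
    } else {
      streak <- streak + 1L
    }
    stop_epoch <- epoch
    if (streak >= config$patience) break
  }
  set(best_params)
  list(log = log, best_epoch = best_epoch, stop_epoch = stop_epoch,
       best_val_acc = best_acc)
}

batch_indices <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

## ---- per-report encoder classifier -----------------------------------------

#' Couple an encoder with a temporary softmax head for per-report pretraining
#'
#' @param enc a [cnn_encoder()] or [hisan_encoder()]
#' @param classes number of classes of the task
#' @return a `report_classifier` model
#' @export
report_classifier <- function(enc, classes) {
  structure(list(encoder = enc, head = softmax_params(enc$d, classes),
                 classes = as.integer(classes)),
            class = "report_classifier")
}

# batched embedding forward used in both training and inference
encoder_embed_batch <- function(enc, docs) {
  if (inherits(enc, "cnn_encoder")) {
    ids_list <- lapply(docs, function(d) if (is.list(d)) d$ids else d)
    cnn_forward_batch(ids_list, enc)
  } else {
    caches <- lapply(docs, hisan_forward, enc = enc)
    E <- t(vapply(caches, function(fc) fc$e, numeric(enc$d)))
    list(E = E, hisan_caches = caches)
  }
}

encoder_backward_batch <- function(enc, dE, fwd) {
  if (inherits(enc, "cnn_encoder")) {
    cnn_backward_batch(dE, fwd$cache, enc)
  } else {
    grads <- NULL
    for (b in seq_along(fwd$hisan_caches)) {
      g <- hisan_backward(dE[b, ], fwd$hisan_caches[[b]]$cache, enc)
      grads <- grad_add(grads, g)
    }
    grads
  }
}

#' Predict class labels for individual reports
#' @param model a trained `report_classifier`
#' @param docs list of tokenized documents
#' @return list with `labels` (integer) and `probs` (matrix)
#' @export
predict_reports <- function(model, docs) {
  probs <- NULL
  bs <- 256L
  for (ix in split(seq_along(docs), ceiling(seq_along(docs) / bs))) {
    E <- encoder_embed_batch(model$encoder, docs[ix])$E
    probs <- rbind(probs, softmax_predict(E, model$head))
  }
  list(labels = max.col(probs, ties.method = "first"), probs = probs)
}

#' Train a model with Adam and early stopping on validation accuracy
#'
#' Methods exist for per-report encoder classifiers (`report_classifier`,
#' batched over documents), context classifiers over saved embedding sequences
#' (`context_classifier`, batched over cases) and joint encoder+context models
#' (`e2e_classifier`). Training data formats are documented on each method.
#'
#' @param model the model to train
#' @param train_data,val_data task data; disjoint
#' @param config a [train_config()]
#' @return list with the trained `model` and a `fit` record (per-epoch train
#'   loss and validation accuracy, best and stop epoch)
#' @export
fit_with_early_stopping <- function(model, train_data, val_data, config) {
  UseMethod("fit_with_early_stopping")
}

#' @describeIn fit_with_early_stopping `train_data`/`val_data` are lists with
#'   `docs` (list of tokenized documents) and `labels` (integer vector, NA
#'   allowed and excluded from loss and accuracy).
#' @export
fit_with_early_stopping.report_classifier <- function(model, train_data,
                                                      val_data, config) {
  if (length(train_data$docs) == 0L) stop("empty training set")
  set.seed(config$seed)
  opt_enc <- adam_init(model$encoder$params)
  opt_head <- adam_init(model$head)
  run_epoch <- function() {
    tot <- 0; nb <- 0L
    for (ix in batch_indices(length(train_data$docs), config$batch_size)) {
      fwd <- encoder_embed_batch(model$encoder, train_data$docs[ix])
      hl <- softmax_loss_backward(fwd$E, train_data$labels[ix], model$head)
      genc <- encoder_backward_batch(model$encoder, hl$dO, fwd)
      st <- adam_step(model$encoder$params, genc, opt_enc, lr = config$lr)
      model$encoder$params <<- st$params; opt_enc <<- st$state
      st <- adam_step(model$head, hl$grads, opt_head, lr = config$lr)
      model$head[names(st$params)] <<- st$params; opt_head <<- st$state
      tot <- tot + hl$loss; nb <- nb + 1L
    }
    tot / nb
  }
  val_acc <- function() {
    pred <- predict_reports(model, val_data$docs)$labels
    keep <- !is.na(val_data$labels)
    mean(pred[keep] == val_data$labels[keep])
  }
  fit <- es_fit_loop(run_epoch, val_acc,
                     get = function() list(enc = model$encoder$params,
                                           head = model$head),
                     set = function(p) {
                       model$encoder$params <<- p$enc
                       model$head[names(p$head)] <<- p$head
                     },
                     config)
  list(model = model, fit = fit)
}

## ---- context classifier over embedding sequences ---------------------------

#' Construct a case-level context classifier
#'
#' Combines one context mechanism (GRU or multi-head self-attention) with one
#' label head (per-report softmax or linear-chain CRF). The `bidirectional`
#' scenario may use future reports; the `unidirectional` (online) scenario is
#' causally restricted (unidirectional GRU, masked self-attention).
#'
#' @param d_in dimension of the incoming document embeddings
#' @param classes number of classes of the task
#' @param context `"gru"` or `"attn"`
#' @param head `"softmax"` or `"crf"`
#' @param scenario `"bidirectional"` or `"unidirectional"`
#' @param hidden GRU hidden size (default 300)
#' @param heads attention heads (default 6)
#' @param max_len maximum case length supported by the positional table
#' @param attn_scale attention score scaling, `"sqrt_d"` or `"d"`
#' @return a `context_classifier` model
#' @export
context_classifier <- function(d_in, classes, context = c("attn", "gru"),
                               head = c("softmax", "crf"),
                               scenario = c("bidirectional", "unidirectional"),
                               hidden = 300L, heads = 6L, max_len = 64L,
                               attn_scale = c("sqrt_d", "d")) {
  context <- match.arg(context)
  head <- match.arg(head)
  scenario <- match.arg(scenario)
  if (context == "gru") {
    ctx <- gru_params(d_in, hidden = hidden,
                      bidirectional = scenario == "bidirectional")
    d_out <- hidden * (1L + (scenario == "bidirectional"))
  } else {
    ctx <- attention_params(d_in, d_in, heads = heads, max_len = max_len,
                            scale = match.arg(attn_scale))
    d_out <- d_in
  }
  hp <- if (head == "softmax") softmax_params(d_out, classes)
        else crf_params(d_out, classes)
  structure(list(context = context, head_type = head, scenario = scenario,
                 ctx = ctx, head = hp, classes = as.integer(classes),
                 causal = scenario == "unidirectional"),
            class = "context_classifier")
}

context_forward <- function(model, E) {
  if (model$context == "gru") {
    gru_forward(E, model$ctx)
  } else {
    att <- attention_forward(E, model$ctx, causal = model$causal)
    list(O = att$O, cache = att$cache)
  }
}

context_backward <- function(model, dO, cache) {
  if (model$context == "gru") gru_backward(dO, cache, model$ctx)
  else attention_backward(dO, cache, model$ctx)
}

# loss + grads for one case sequence
context_case_backward <- function(model, E, y) {
  fwd <- context_forward(model, E)
  if (model$head_type == "softmax") {
    hl <- softmax_loss_backward(fwd$O, y, model$head)
  } else {
    hl <- crf_loss_backward(fwd$O, y, model$head)
  }
  back <- context_backward(model, hl$dO, fwd$cache)
  list(loss = hl$loss, ctx_grads = back$grads, head_grads = hl$grads,
       dX = back$dX)
}

#' Predict per-report labels for embedding sequences
#' @param model a trained `context_classifier`
#' @param seqs list of embedding matrices (one case per element)
#' @return list of integer label vectors aligned with the rows of each matrix
#' @export
predict_context <- function(model, seqs) {
  lapply(seqs, function(E) {
    O <- context_forward(model, E)$O
    if (model$head_type == "softmax")
      max.col(softmax_predict(O, model$head), ties.method = "first")
    else
      crf_decode(O, model$head)
  })
}

#' @describeIn fit_with_early_stopping `train_data`/`val_data` are lists with
#'   `seqs` (list of embedding matrices, one case per element, reports in date
#'   order) and `labels` (list of integer vectors aligned with the rows).
#'   Cases with missing labels are excluded from the CRF loss; softmax losses
#'   simply skip unlabelled reports.
#' @export
fit_with_early_stopping.context_classifier <- function(model, train_data,
                                                       val_data, config) {
  if (length(train_data$seqs) == 0L) stop("empty training set")
  set.seed(config$seed)
  opt_ctx <- adam_init(model$ctx)
  opt_head <- adam_init(model$head)
  crf <- model$head_type == "crf"
  run_epoch <- function() {
    tot <- 0; nb <- 0L
    for (ix in batch_indices(length(train_data$seqs), config$batch_size)) {
      gc_ctx <- NULL; gc_head <- NULL; bl <- 0; used <- 0L
      for (b in ix) {
        y <- train_data$labels[[b]]
        if (crf && anyNA(y)) next
        cb <- context_case_backward(model, train_data$seqs[[b]], y)
        gc_ctx <- grad_add(gc_ctx, cb$ctx_grads)
        gc_head <- grad_add(gc_head, cb$head_grads)
        bl <- bl + cb$loss; used <- used + 1L
      }
      if (used == 0L) next
      st <- adam_step(model$ctx, grad_scale(gc_ctx, 1 / used), opt_ctx,
                      lr = config$lr)
      model$ctx[names(st$params)] <<- st$params; opt_ctx <<- st$state
      st <- adam_step(model$head, grad_scale(gc_head, 1 / used), opt_head,
                      lr = config$lr)
      model$head[names(st$params)] <<- st$params; opt_head <<- st$state
      tot <- tot + bl / used; nb <- nb + 1L
    }
    if (nb == 0L) 0 else tot / nb
  }
  val_acc <- function() {
    pred <- predict_context(model, val_data$seqs)
    p <- unlist(pred); y <- unlist(val_data$labels)
    keep <- !is.na(y)
    mean(p[keep] == y[keep])
  }
  fit <- es_fit_loop(run_epoch, val_acc,
                     get = function() list(ctx = model$ctx, head = model$head),
                     set = function(p) {
                       model$ctx[names(p$ctx)] <<- p$ctx
                       model$head[names(p$head)] <<- p$head
                     },
                     config)
  list(model = model, fit = fit)
}

## ---- end-to-end (joint) model ----------------------------------------------

#' Construct a joint encoder + context + head model
#'
#' Used for end-to-end training, where the (pre-trained) encoder's parameters
#' keep updating while the context mechanism and head are trained. Batching is
#' per case: all reports of a case go through the encoder in one forward pass.
#'
#' @param enc a (typically pre-trained) encoder
#' @param ctx_model a [context_classifier()] whose `d_in` equals `enc$d`
#' @return an `e2e_classifier` model
#' @export
e2e_classifier <- function(enc, ctx_model) {
  structure(list(encoder = enc, ctx_model = ctx_model),
            class = "e2e_classifier")
}

#' Predict per-report labels for tokenized cases with a joint model
#' @param model an `e2e_classifier`
#' @param cases list of cases, each a list of tokenized documents (date order)
#' @return list of integer label vectors
#' @export
predict_e2e <- function(model, cases) {
  lapply(cases, function(docs) {
    E <- encoder_embed_batch(model$encoder, docs)$E
    predict_context(model$ctx_model, list(E))[[1L]]
  })
}

#' @describeIn fit_with_early_stopping `train_data`/`val_data` are lists with
#'   `cases` (list of cases, each a list of tokenized documents) and `labels`
#'   (list of integer vectors). All parameters, including the word-embedding
#'   table, receive gradient.
#' @export
fit_with_early_stopping.e2e_classifier <- function(model, train_data,
                                                   val_data, config) {
  if (length(train_data$cases) == 0L) stop("empty training set")
  set.seed(config$seed)
  cm <- model$ctx_model
  crf <- cm$head_type == "crf"
  opt_enc <- adam_init(model$encoder$params)
  opt_ctx <- adam_init(cm$ctx)
  opt_head <- adam_init(cm$head)
  run_epoch <- function() {
    tot <- 0; nb <- 0L
    for (ix in batch_indices(length(train_data$cases), config$batch_size)) {
      g_enc <- NULL; g_ctx <- NULL; g_head <- NULL; bl <- 0; used <- 0L
      for (b in ix) {
        y <- train_data$labels[[b]]
        if (crf && anyNA(y)) next
        fwd <- encoder_embed_batch(model$encoder, train_data$cases[[b]])
        cb <- context_case_backward(cm, fwd$E, y)
        ge <- encoder_backward_batch(model$encoder, cb$dX, fwd)
        g_enc <- grad_add(g_enc, ge)
        g_ctx <- grad_add(g_ctx, cb$ctx_grads)
        g_head <- grad_add(g_head, cb$head_grads)
        bl <- bl + cb$loss; used <- used + 1L
      }
      if (used == 0L) next
      st <- adam_step(model$encoder$params, grad_scale(g_enc, 1 / used),
                      opt_enc, lr = config$lr)
      model$encoder$params <<- st$params; opt_enc <<- st$state
      st <- adam_step(cm$ctx, grad_scale(g_ctx, 1 / used), opt_ctx,
                      lr = config$lr)
      cm$ctx[names(st$params)] <<- st$params; opt_ctx <<- st$state
      st <- adam_step(cm$head, grad_scale(g_head, 1 / used), opt_head,
                      lr = config$lr)
      cm$head[names(st$params)] <<- st$params; opt_head <<- st$state
      model$ctx_model <<- cm
      tot <- tot + bl / used; nb <- nb + 1L
    }
    if (nb == 0L) 0 else tot / nb
  }
  val_acc <- function() {
    pred <- predict_e2e(model, val_data$cases)
    p <- unlist(pred); y <- unlist(val_data$labels)
    keep <- !is.na(y)
    mean(p[keep] == y[keep])
  }
  fit <- es_fit_loop(run_epoch, val_acc,
                     get = function() list(enc = model$encoder$params,
                                           ctx = cm$ctx, head = cm$head),
                     set = function(p) {
                       model$encoder$params <<- p$enc
                       cm$ctx[names(p$ctx)] <<- p$ctx
                       cm$head[names(p$head)] <<- p$head
                       model$ctx_model <<- cm
                     },
                     config)
  list(model = model, fit = fit)
}

## ---- regimes ----------------------------------------------------------------

#' Modular two-step training
#'
#' Step 1 trains the encoder on individual reports with a temporary softmax
#' head. Step 2 freezes the encoder, extracts document embeddings for every
#' report, and trains the context classifier on the embedding sequences. The
#' encoder's parameters are bit-identical before and after step 2.
#'
#' @param enc an untrained encoder
#' @param ctx_model an untrained [context_classifier()]
#' @param data a task dataset as produced by [task_dataset()]
#' @param config a [train_config()]
#' @return a `ctx_pipeline`: trained encoder, context model, embeddings and
#'   both fit records
#' @export
train_modular <- function(enc, ctx_model, data, config) {
  model0 <- with_seed(config$seed, report_classifier(enc, ctx_model$classes))
  step1 <- fit_with_early_stopping(
    model0,
    list(docs = data$train$docs, labels = data$train$report_labels),
    list(docs = data$val$docs, labels = data$val$report_labels),
    config
  )
  enc_trained <- step1$model$encoder
  all_docs <- c(data$train$docs, data$val$docs, data$test$docs)
  emb <- extract_embeddings(all_docs, enc_trained)
  seqs <- function(split) case_seqs_from_embeddings(emb, data[[split]]$cases)
  step2 <- fit_with_early_stopping(
    ctx_model,
    list(seqs = seqs("train"), labels = data$train$case_labels),
    list(seqs = seqs("val"), labels = data$val$case_labels),
    config
  )
  structure(list(encoder = enc_trained, encoder_head = step1$model$head,
                 ctx_model = step2$model, embeddings = emb,
                 encoder_fit = step1$fit, context_fit = step2$fit,
                 regime = "modular"),
            class = "ctx_pipeline")
}

# assemble per-case embedding matrices from an embedding store
case_seqs_from_embeddings <- function(emb, cases) {
  lapply(cases, function(rids) emb[rids, , drop = FALSE])
}

#' End-to-end training of a pretrained encoder with a context classifier
#'
#' The encoder is first pretrained on individual reports (or an already
#' trained encoder is supplied), then the whole model - encoder, context
#' mechanism and head - is fine-tuned jointly on case sequences.
#'
#' @param enc a pretrained encoder (e.g. from [train_modular()] step 1)
#' @param ctx_model an untrained [context_classifier()]
#' @param data a task dataset as produced by [task_dataset()]
#' @param config a [train_config()]
#' @return a `ctx_pipeline` with regime `"end_to_end"`
#' @export
train_end_to_end <- function(enc, ctx_model, data, config) {
  mkcases <- function(split) lapply(data[[split]]$cases,
                                    function(rids) data[[split]]$docs[rids])
  fit <- fit_with_early_stopping(
    e2e_classifier(enc, ctx_model),
    list(cases = mkcases("train"), labels = data$train$case_labels),
    list(cases = mkcases("val"), labels = data$val$case_labels),
    config
  )
  structure(list(encoder = fit$model$encoder,
                 ctx_model = fit$model$ctx_model,
                 context_fit = fit$fit, regime = "end_to_end"),
            class = "ctx_pipeline")
}

# stable digest of a parameter list (freeze-contract checks, checkpointing)
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  sum(v) + sum(v * seq_along(v) %% 97)
}
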