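# Per-document baseline encoders. Both map one tokenized report to a document
# embedding e_i (the penultimate-layer representation used for classification):
#   * cnn_encoder   - word-level CNN: learned word embeddings, parallel
#     convolutions over windows of 3/4/5 consecutive words with ReLU, and
#     max-over-time pooling per filter, concatenated.
#   * hisan_encoder - hierarchical self-attention ("HiSAN-lite"): self-attention
#     over the tokens of each line pooled into line embeddings, then
#     self-attention over line embeddings pooled into a document embedding.
#     This is a faithful simplification of the published hierarchical
#     self-attention network, not a line-by-line port.
# Encoders are strictly per-document: no information flows between reports.

PAD_ID <- 1L  # id of "paddingtoken"; its embedding row is zero and frozen

#' Construct a word-level CNN encoder
#'
#' @param vocab_size number of vocabulary ids (embedding rows)
#' @param d_w word-embedding dimension (default 300)
#' @param feature_maps feature maps per window size; the document embedding has
#'   dimension `length(windows) * feature_maps`
#' @param windows convolution window sizes (default 3, 4, 5 consecutive words)
#' @return a `cnn_encoder` object
#' @export
cnn_encoder <- function(vocab_size, d_w = 300L, feature_maps = 100L,
                        windows = c(3L, 4L, 5L)) {
  params <- list(Emb = rbind(numeric(d_w),
                             init_mat(vocab_size - 1L, d_w)))
  for (w in windows) {
    params[[paste0("W", w)]] <- init_mat(w * d_w, feature_maps)
    params[[paste0("b", w)]] <- init_vec(feature_maps)
  }
  structure(list(params = params, d_w = as.integer(d_w),
                 feature_maps = as.integer(feature_maps),
                 windows = as.integer(windows),
                 d = length(windows) * as.integer(feature_maps),
                 vocab_size = as.integer(vocab_size)),
            class = c("cnn_encoder", "encoder"))
}

#' @export
print.cnn_encoder <- function(x, ...) {
  cat("<cnn_encoder> |V| = ", x$vocab_size, ", d_w = ", x$d_w, ", windows ",
      paste(x$windows, collapse = "/"), " x ", x$feature_maps,
      " maps -> d = ", x$d, "\n", sep = "")
  invisible(x)
}

# pad a list of id vectors into a B x Lmax matrix of ids
pad_id_matrix <- function(ids_list, min_len) {
  lens <- lengths(ids_list)
  Lmax <- max(lens, min_len)
  idmat <- matrix(PAD_ID, length(ids_list), Lmax)
  for (b in seq_along(ids_list))
    if (lens[b] > 0L) idmat[b, seq_len(lens[b])] <- ids_list[[b]]
  idmat
}

# batched CNN forward; returns E (B x d) and a cache for the backward pass
cnn_forward_batch <- function(ids_list, enc) {
  p <- enc$params
  B <- length(ids_list)
  idmat <- pad_id_matrix(ids_list, min_len = max(enc$windows))
  Lmax <- ncol(idmat)
  idvec <- as.vector(t(idmat))              # doc-major flattening
  X <- p$Emb[idvec, , drop = FALSE]         # (B*Lmax) x d_w
  d_w <- enc$d_w
  Fm <- enc$feature_maps
  E <- matrix(0, B, enc$d)
  wcache <- list()
  lens <- lengths(ids_list)
  for (wi in seq_along(enc$windows)) {
    w <- enc$windows[wi]
    Lw <- Lmax - w + 1L
    base <- rep((seq_len(B) - 1L) * Lmax, each = Lw) + rep(seq_len(Lw), B)
    Xw <- matrix(0, B * Lw, w * d_w)
    for (k in 0:(w - 1L))
      Xw[, k * d_w + seq_len(d_w)] <- X[base + k, , drop = FALSE]
    S <- sweep(Xw %*% p[[paste0("W", w)]], 2L, p[[paste0("b", w)]], "+")
    Z <- pmax(S, 0)
    # valid windows per document: padding added to reach the batch length
    # must not create extra candidate windows, or embeddings would depend on
    # what else is in the batch
    vw <- pmax(lens, w) - w + 1L
    # max-over-time per document and filter, restricted to valid windows
    M <- matrix(-Inf, B, Fm)
    J <- matrix(1L, B, Fm)
    for (j in seq_len(Lw)) {
      rows <- (seq_len(B) - 1L) * Lw + j
      Zj <- Z[rows, , drop = FALSE]
      upd <- (Zj > M) & (j <= vw)
      J[upd] <- j
      M[upd] <- Zj[upd]
    }
    E[, (wi - 1L) * Fm + seq_len(Fm)] <- M
    wcache[[wi]] <- list(w = w, Lw = Lw, Xw = Xw, S = S, J = J, base = base)
  }
  list(E = E, cache = list(idvec = idvec, idmat = idmat, Lmax = Lmax,
                           wcache = wcache, B = B))
}

# batched CNN backward from dE; returns parameter gradients
cnn_backward_batch <- function(dE, cache, enc) {
  p <- enc$params
  d_w <- enc$d_w
  Fm <- enc$feature_maps
  B <- cache$B
  Lmax <- cache$Lmax
  dX <- matrix(0, B * Lmax, d_w)
  grads <- list()
  for (wi in seq_along(enc$windows)) {
    wc <- cache$wcache[[wi]]
    w <- wc$w; Lw <- wc$Lw
    dM <- dE[, (wi - 1L) * Fm + seq_len(Fm), drop = FALSE]
    dZ <- matrix(0, B * Lw, Fm)
    rows <- (rep(seq_len(B), Fm) - 1L) * Lw + as.vector(wc$J)
    cols <- rep(seq_len(Fm), each = B)
    dZ[cbind(rows, cols)] <- dZ[cbind(rows, cols)] + as.vector(dM)
    dS <- dZ * (wc$S > 0)
    grads[[paste0("W", w)]] <- crossprod(wc$Xw, dS)
    grads[[paste0("b", w)]] <- colSums(dS)
    dXw <- dS %*% t(p[[paste0("W", w)]])
    for (k in 0:(w - 1L)) {
      blk <- dXw[, k * d_w + seq_len(d_w), drop = FALSE]
      tgt <- wc$base + k
      dX[tgt, ] <- dX[tgt, ] + blk
    }
  }
  dEmb <- rowsum(dX, cache$idvec, reorder = FALSE)
  gEmb <- p$Emb * 0
  gEmb[as.integer(rownames(dEmb)), ] <- dEmb
  gEmb[PAD_ID, ] <- 0                        # padding embedding stays zero
  grads$Emb <- gEmb
  grads
}

#' Encode one document with the CNN encoder
#'
#' @param doc an integer vector of token ids, or a [tokenize_report()] result
#'   with an `ids` field; documents shorter than the largest window are
#'   zero-padded up to it
#' @param enc a [cnn_encoder()] object
#' @return numeric document embedding of length `enc$d`
#' @export
encode_cnn <- function(doc, enc) {
  ids <- if (is.list(doc)) doc$ids else doc
  if (length(ids) < 1L) stop("document must contain at least one token")
  drop(cnn_forward_batch(list(as.integer(ids)), enc)$E)
}

## ---- hierarchical self-attention encoder -----------------------------------

#' Construct a hierarchical self-attention encoder (HiSAN-lite)
#'
#' One self-attention layer over the tokens of each line, attention-pooled into
#' a line embedding; one self-attention layer over line embeddings,
#' attention-pooled into the document embedding.
#'
#' @param vocab_size number of vocabulary ids
#' @param d_w word-embedding dimension
#' @param d output (document-embedding) dimension; divisible by `heads`
#' @param heads attention heads per level
#' @param max_line_tokens positional-table size at the token level
#' @param max_lines positional-table size at the line level
#' @return a `hisan_encoder` object
#' @export
hisan_encoder <- function(vocab_size, d_w = 300L, d = 300L, heads = 6L,
                          max_line_tokens = 512L, max_lines = 256L) {
  params <- list(Emb = rbind(numeric(d_w), init_mat(vocab_size - 1L, d_w)),
                 u_tok = stats::rnorm(d, sd = 0.1),
                 u_line = stats::rnorm(d, sd = 0.1))
  tok_att <- attention_params(d_w, d, heads = heads, max_len = max_line_tokens)
  line_att <- attention_params(d, d, heads = heads, max_len = max_lines)
  for (nm in names(tok_att)) params[[paste0("tok_", nm)]] <- tok_att[[nm]]
  for (nm in names(line_att)) params[[paste0("line_", nm)]] <- line_att[[nm]]
  structure(list(params = params, d_w = as.integer(d_w), d = as.integer(d),
                 heads = as.integer(heads), vocab_size = as.integer(vocab_size),
                 tok_attrs = attributes(tok_att),
                 line_attrs = attributes(line_att)),
            class = c("hisan_encoder", "encoder"))
}

#' @export
print.hisan_encoder <- function(x, ...) {
  cat("<hisan_encoder> |V| = ", x$vocab_size, ", d_w = ", x$d_w,
      ", d = ", x$d, ", heads = ", x$heads, "\n", sep = "")
  invisible(x)
}

# view the prefixed flat params as an attention_params object
hisan_att_params <- function(enc, level = c("tok", "line")) {
  level <- match.arg(level)
  nms <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "P")
  p <- enc$params[paste0(level, "_", nms)]
  names(p) <- nms
  p <- p[!vapply(p, is.null, logical(1L))]
  at <- if (level == "tok") enc$tok_attrs else enc$line_attrs
  attributes(p) <- c(attributes(p), at[setdiff(names(at), "names")])
  p
}

hisan_forward <- function(doc, enc) {
  ids <- doc$ids
  lines <- doc$lines
  if (is.null(lines) || nrow(lines) == 0L) stop("document has no line ranges")
  tok_p <- hisan_att_params(enc, "tok")
  line_p <- hisan_att_params(enc, "line")
  m <- nrow(lines)
  L <- matrix(0, m, enc$d)
  lcache <- vector("list", m)
  for (li in seq_len(m)) {
    rng <- lines[li, 1L]:lines[li, 2L]
    Xl <- enc$params$Emb[ids[rng], , drop = FALSE]
    att <- attention_forward(Xl, tok_p, causal = FALSE)
    pool <- attn_pool_forward(att$O, enc$params$u_tok)
    L[li, ] <- pool$out
    lcache[[li]] <- list(rng = rng, att = att, pool = pool)
  }
  latt <- attention_forward(L, line_p, causal = FALSE)
  lpool <- attn_pool_forward(latt$O, enc$params$u_line)
  list(e = lpool$out,
       cache = list(lcache = lcache, L = L, latt = latt, lpool = lpool,
                    ids = ids, tok_p = tok_p, line_p = line_p))
}

hisan_backward <- function(de, cache, enc) {
  grads <- lapply(enc$params, function(p) p * 0)
  lp_back <- attn_pool_backward(de, cache$lpool$cache)
  grads$u_line <- grads$u_line + lp_back$du
  la_back <- attention_backward(lp_back$dX, cache$latt$cache, cache$line_p)
  for (nm in names(la_back$grads))
    grads[[paste0("line_", nm)]] <- grads[[paste0("line_", nm)]] + la_back$grads[[nm]]
  dL <- la_back$dX
  for (li in seq_along(cache$lcache)) {
    lc <- cache$lcache[[li]]
    tp_back <- attn_pool_backward(dL[li, ], lc$pool$cache)
    grads$u_tok <- grads$u_tok + tp_back$du
    ta_back <- attention_backward(tp_back$dX, lc$att$cache, cache$tok_p)
    for (nm in names(ta_back$grads))
      grads[[paste0("tok_", nm)]] <- grads[[paste0("tok_", nm)]] + ta_back$grads[[nm]]
    ids <- cache$ids[lc$rng]
    dEmb <- rowsum(ta_back$dX, ids, reorder = FALSE)
    rows <- as.integer(rownames(dEmb))
    grads$Emb[rows, ] <- grads$Emb[rows, ] + dEmb
  }
  grads$Emb[PAD_ID, ] <- 0
  grads
}

#' Encode one document with the hierarchical self-attention encoder
#'
#' @param doc a [tokenize_report()] result: integer `ids` plus a `lines` range
#'   matrix
#' @param enc a [hisan_encoder()] object
#' @return numeric document embedding of length `enc$d`
#' @export
encode_hisan <- function(doc, enc) {
  hisan_forward(doc, enc)$e
}

#' Encode a whole corpus into a document-embedding matrix
#'
#' Inference is deterministic: running twice yields identical matrices, and
#' each row equals the standalone encoding of that report.
#'
#' @param docs named list of tokenized documents (names are report ids)
#' @param enc a trained encoder
#' @return numeric matrix, one row per report, rownames = report ids
#' @export
extract_embeddings <- function(docs, enc) {
  if (is.null(names(docs)) || any(!nzchar(names(docs))))
    stop("docs must be a named list keyed by report_id")
  if (inherits(enc, "cnn_encoder")) {
    ids_list <- lapply(docs, function(d) if (is.list(d)) d$ids else d)
    E <- cnn_forward_batch(ids_list, enc)$E
  } else {
    E <- t(vapply(docs, function(d) encode_hisan(d, enc), numeric(enc$d)))
  }
  rownames(E) <- names(docs)
  E
}

#' Write / read a document-embedding matrix (TSV: report_id then d columns)
#' @param E embedding matrix with report-id rownames
#' @param path file path
#' @export
write_embeddings <- function(E, path) {
  # full-precision formatting so the store round-trips bit-exactly
  fm <- apply(E, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(report_id = rownames(E), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("report_id", paste0("e", seq_len(ncol(E))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  E <- as.matrix(df[, -1L, drop = FALSE])
  rownames(E) <- df$report_id
  storage.mode(E) <- "double"
  E
}
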