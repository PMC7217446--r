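# Case-level context mechanisms. Each transforms the sequence of per-report
# document embeddings e_0..e_n of one case into context-aware outputs o_0..o_n:
#   * run_gru            - (bi)directional gated recurrent unit
#   * run_self_attention - multi-head self-attention with learned positional
#                          embeddings, optionally causally masked
#   * concat_case        - token-level concatenation of the case's reports
# Unidirectional (online) variants never see future reports.

#' Construct GRU parameters
#'
#' Gates follow the standard formulation: z_t = sigmoid(Wz [h_{t-1}, x_t] + bz),
#' r_t = sigmoid(Wr [h_{t-1}, x_t] + br),
#' c_t = tanh(Wc [r_t * h_{t-1}, x_t] + bc),
#' h_t = (1 - z_t) * h_{t-1} + z_t * c_t, with h_{-1} = 0.
#'
#' @param d_in input dimension
#' @param hidden hidden-state size (default 300)
#' @param bidirectional if `TRUE`, an independent reversed pass is run and its
#'   outputs concatenated, giving outputs of dimension `2 * hidden`
#' @return a `gru_params` list
#' @export
gru_params <- function(d_in, hidden = 300L, bidirectional = FALSE) {
  one_dir <- function() list(
    Wz = init_mat(hidden, hidden + d_in), bz = init_vec(hidden),
    Wr = init_mat(hidden, hidden + d_in), br = init_vec(hidden),
    Wc = init_mat(hidden, hidden + d_in), bc = init_vec(hidden)
  )
  p <- one_dir()
  if (bidirectional) {
    bwd <- one_dir()
    names(bwd) <- paste0(names(bwd), "_rev")
    p <- c(p, bwd)
  }
  structure(p, class = "gru_params", hidden = as.integer(hidden),
            d_in = as.integer(d_in), bidirectional = bidirectional)
}

# single-direction forward over rows of E; returns H (n x hidden) and cache
gru_dir_forward <- function(E, p, suffix = "") {
  g <- function(nm) p[[paste0(nm, suffix)]]
  Wz <- g("Wz"); Wr <- g("Wr"); Wc <- g("Wc")
  bz <- g("bz"); br <- g("br"); bc <- g("bc")
  n <- nrow(E); H <- length(bz)
  out <- matrix(0, n, H)
  steps <- vector("list", n)
  h <- numeric(H)
  for (t in seq_len(n)) {
    x <- E[t, ]
    hx <- c(h, x)
    z <- sigmoid(drop(Wz %*% hx) + bz)
    r <- sigmoid(drop(Wr %*% hx) + br)
    rhx <- c(r * h, x)
    cc <- tanh(drop(Wc %*% rhx) + bc)
    h_new <- (1 - z) * h + z * cc
    steps[[t]] <- list(h_prev = h, x = x, z = z, r = r, cc = cc,
                       hx = hx, rhx = rhx)
    h <- h_new
    out[t, ] <- h
  }
  list(H = out, steps = steps)
}

# BPTT for one direction; dH has one row of output-gradient per step
gru_dir_backward <- function(dH, cache, p, suffix = "") {
  g <- function(nm) p[[paste0(nm, suffix)]]
  Wz <- g("Wz"); Wr <- g("Wr"); Wc <- g("Wc")
  H <- nrow(Wz); din <- ncol(Wz) - H
  n <- nrow(dH)
  gr <- list(Wz = Wz * 0, bz = numeric(H), Wr = Wr * 0, br = numeric(H),
             Wc = Wc * 0, bc = numeric(H))
  dX <- matrix(0, n, din)
  dh_carry <- numeric(H)
  for (t in rev(seq_len(n))) {
    s <- cache$steps[[t]]
    dh <- dH[t, ] + dh_carry
    dz <- dh * (s$cc - s$h_prev)
    dcc <- dh * s$z
    dh_prev <- dh * (1 - s$z)
    # candidate pre-activation
    dcp <- dcc * (1 - s$cc^2)
    gr$Wc <- gr$Wc + tcrossprod(dcp, s$rhx)
    gr$bc <- gr$bc + dcp
    drhx <- drop(crossprod(Wc, dcp))
    dr <- drhx[seq_len(H)] * s$h_prev
    dh_prev <- dh_prev + drhx[seq_len(H)] * s$r
    dx <- drhx[H + seq_len(din)]
    # gates
    dzp <- dz * s$z * (1 - s$z)
    gr$Wz <- gr$Wz + tcrossprod(dzp, s$hx)
    gr$bz <- gr$bz + dzp
    dhx <- drop(crossprod(Wz, dzp))
    drp <- dr * s$r * (1 - s$r)
    gr$Wr <- gr$Wr + tcrossprod(drp, s$hx)
    gr$br <- gr$br + drp
    dhx <- dhx + drop(crossprod(Wr, drp))
    dh_prev <- dh_prev + dhx[seq_len(H)]
    dx <- dx + dhx[H + seq_len(din)]
    dX[t, ] <- dx
    dh_carry <- dh_prev
  }
  names(gr) <- paste0(names(gr), suffix)
  list(dX = dX, grads = gr)
}

gru_forward <- function(E, params) {
  fw <- gru_dir_forward(E, params)
  if (attr(params, "bidirectional")) {
    n <- nrow(E)
    bw <- gru_dir_forward(E[rev(seq_len(n)), , drop = FALSE], params, "_rev")
    O <- cbind(fw$H, bw$H[rev(seq_len(n)), , drop = FALSE])
    list(O = O, cache = list(fw = fw, bw = bw, n = n))
  } else {
    list(O = fw$H, cache = list(fw = fw, n = nrow(E)))
  }
}

gru_backward <- function(dO, cache, params) {
  H <- attr(params, "hidden")
  n <- cache$n
  res_f <- gru_dir_backward(dO[, seq_len(H), drop = FALSE], cache$fw, params)
  if (attr(params, "bidirectional")) {
    dH_rev <- dO[rev(seq_len(n)), H + seq_len(H), drop = FALSE]
    res_b <- gru_dir_backward(dH_rev, cache$bw, params, "_rev")
    list(dX = res_f$dX + res_b$dX[rev(seq_len(n)), , drop = FALSE],
         grads = c(res_f$grads, res_b$grads))
  } else {
    res_f
  }
}

#' Run a (bi)directional GRU over a case's embedding sequence
#'
#' @param E matrix of document embeddings, one report per row (ascending date)
#' @param params a [gru_params()] object whose input dimension matches `ncol(E)`
#' @return matrix of context outputs, one row per report (`hidden` columns, or
#'   `2 * hidden` when bidirectional)
#' @export
run_gru <- function(E, params) {
  if (ncol(E) != attr(params, "d_in"))
    stop("input dimension ", ncol(E), " does not match GRU parameters (",
         attr(params, "d_in"), ")")
  gru_forward(E, params)$O
}

#' Run multi-head self-attention over a case's embedding sequence
#'
#' @param E matrix of document embeddings, one report per row
#' @param params an [attention_params()] object
#' @param causal if `TRUE`, report i attends only to reports at positions <= i
#'   (the online scenario); otherwise attention is unrestricted
#' @return matrix of context outputs aligned with the rows of `E`
#' @export
run_self_attention <- function(E, params, causal = FALSE) {
  attention_forward(E, params, causal = causal)$O
}

#' Concatenate the reports of a case into a single token sequence
#'
#' Valid only when all reports of the case share the same label. In
#' `mode = "all"` every report in the case is concatenated regardless of the
#' target index; in `mode = "previous"` only reports up to and including the
#' target report are used (the online scenario). Documents are joined with a
#' dedicated separator token.
#'
#' @param docs list of token vectors, one per report, in date order
#' @param i target report index (1-based); only used in `"previous"` mode
#' @param mode `"all"` or `"previous"`
#' @param labels optional per-report labels; if supplied and not all equal an
#'   error is raised, since concatenation is invalid when labels differ
#' @param sep separator token inserted between documents
#' @return single token vector
#' @export
concat_case <- function(docs, i = length(docs), mode = c("all", "previous"),
                        labels = NULL, sep = "separatortoken") {
  mode <- match.arg(mode)
  if (!is.null(labels) && length(unique(labels[!is.na(labels)])) > 1L)
    stop("concatenation is invalid when reports of a case carry different labels")
  if (i < 1L || i > length(docs)) stop("target index out of range")
  use <- if (mode == "all") seq_along(docs) else seq_len(i)
  out <- docs[[use[1L]]]
  for (j in use[-1L]) out <- c(out, sep, docs[[j]])
  out
}
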