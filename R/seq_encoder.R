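# Transformer encoder over substructure sequences: token + position
# embedding sum, multi-head scaled dot-product self-attention with padding
# masks, position-wise feed-forward blocks, residual connections with layer
# normalization, and masked mean pooling into a drug sequence embedding.

## ---- tape builders -----------------------------------------------------

# one multi-head self-attention block on rows of X (l x d); mask_row is a
# logical vector of real-token flags (length l)
.tp_mha <- function(tp, X, mask_row, n_heads, prefix, P) {
  l <- nrow(tp_val(tp, X))
  d <- ncol(tp_val(tp, X))
  dh <- d %/% n_heads
  neg <- matrix(0, l, l)
  neg[, !mask_row] <- -1e30
  negid <- tp_const(tp, neg)
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- tp_cols(tp, tp_matmul(tp, X, P(paste0(prefix, "Wq"))), cols)
    K <- tp_cols(tp, tp_matmul(tp, X, P(paste0(prefix, "Wk"))), cols)
    V <- tp_cols(tp, tp_matmul(tp, X, P(paste0(prefix, "Wv"))), cols)
    sc <- tp_scale(tp, tp_matmul(tp, Q, tp_t(tp, K)), 1 / sqrt(dh))
    A <- tp_softmax_rows(tp, tp_add(tp, sc, negid))
    tp_matmul(tp, A, V)
  })
  tp_matmul(tp, tp_concat_cols(tp, heads), P(paste0(prefix, "Wo")))
}

.tp_ffn <- function(tp, X, prefix, P) {
  h <- tp_relu(tp, tp_add(tp, tp_matmul(tp, X, P(paste0(prefix, "W1"))),
                          P(paste0(prefix, "b1"))))
  tp_add(tp, tp_matmul(tp, h, P(paste0(prefix, "W2"))), P(paste0(prefix, "b2")))
}

# full encoder over the real tokens of `seq`; returns id of 1 x d_seq row
.tp_encode_seq <- function(tp, ps, seq, cfg, prefix = "s.") {
  l <- seq$length
  if (l == 0L)
    cdr_stop("degenerate_input_error", "sequence has no real tokens")
  P <- function(nm) tp_param(tp, ps, paste0(prefix, nm))
  # embedding: token row + position row
  X <- tp_add(tp, tp_rows(tp, P("Wc"), seq$token_ids),
              tp_rows(tp, P("Wp"), seq_len(l)))
  mask_row <- rep(TRUE, l)
  for (ly in seq_len(cfg$n_layers)) {
    at <- .tp_mha(tp, X, mask_row, cfg$n_heads, sprintf("l%d.att.", ly), P)
    X <- tp_layernorm_rows(tp, tp_add(tp, X, at))
    ff <- .tp_ffn(tp, X, sprintf("l%d.ffn.", ly), P)
    X <- tp_layernorm_rows(tp, tp_add(tp, X, ff))
  }
  pooled <- tp_colmeans(tp, X)
  tp_add(tp, tp_matmul(tp, pooled, P("out.W")), P("out.b"))
}

## ---- parameters --------------------------------------------------------

#' Initialize sequence-encoder parameters
#'
#' @param vocab_size number of substructure tokens.
#' @param zeta maximum sequence length (size of the position table).
#' @param d model width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param n_layers encoder blocks.
#' @param d_ff feed-forward hidden width.
#' @param d_seq output embedding length.
#' @param seed integer seed.
#' @return named list of parameter matrices plus a `cfg` attribute carrying
#'   the architecture shape.
#' @export
seq_params <- function(vocab_size, zeta = 64L, d = 128L, n_heads = 4L,
                       n_layers = 2L, d_ff = 256L, d_seq = 100L, seed = 1L) {
  if (d %% n_heads != 0L)
    cdr_stop("shape_error", "d (%d) must be divisible by n_heads (%d)",
             d, n_heads)
  with_seed(seed, {
    p <- list(Wc = glorot(vocab_size, d), Wp = glorot(zeta, d))
    for (ly in seq_len(n_layers)) {
      p[[sprintf("l%d.att.Wq", ly)]] <- glorot(d, d)
      p[[sprintf("l%d.att.Wk", ly)]] <- glorot(d, d)
      p[[sprintf("l%d.att.Wv", ly)]] <- glorot(d, d)
      p[[sprintf("l%d.att.Wo", ly)]] <- glorot(d, d)
      p[[sprintf("l%d.ffn.W1", ly)]] <- glorot(d, d_ff)
      p[[sprintf("l%d.ffn.b1", ly)]] <- zeros(1L, d_ff)
      p[[sprintf("l%d.ffn.W2", ly)]] <- glorot(d_ff, d)
      p[[sprintf("l%d.ffn.b2", ly)]] <- zeros(1L, d)
    }
    p[["out.W"]] <- glorot(d, d_seq)
    p[["out.b"]] <- zeros(1L, d_seq)
    attr(p, "cfg") <- list(d = d, n_heads = n_heads, n_layers = n_layers,
                           d_ff = d_ff, d_seq = d_seq, zeta = zeta,
                           vocab_size = vocab_size)
    p
  })
}

## ---- exported op-level functions ---------------------------------------

#' Embed a substructure sequence
#'
#' Row `i` of the result is the sum of the token embedding (row
#' `token_ids[i]` of `Wc`) and the position embedding (row `i` of `Wp`).
#'
#' @param seq a `cdr_substructure_seq`.
#' @param Wc token embedding matrix (`vocab_size x d`).
#' @param Wp position embedding matrix (`zeta x d`).
#' @return matrix `length(seq) x d`.
#' @export
seq_embed <- function(seq, Wc, Wp) {
  stopifnot(inherits(seq, "cdr_substructure_seq"))
  if (any(seq$token_ids > nrow(Wc)))
    cdr_stop("index_error", "token id outside vocabulary")
  Wc[seq$token_ids, , drop = FALSE] + Wp[seq_len(seq$length), , drop = FALSE]
}

#' Masked multi-head scaled dot-product self-attention
#'
#' `softmax((D Wq)(D Wk)' / sqrt(d_head)) (D Wv)` per head, heads
#' concatenated and projected by `Wo`. Padded positions (where `pad_mask`
#' is FALSE) receive a large negative score before the softmax, so no
#' probability mass can attend to them.
#'
#' @param D input matrix (rows = positions).
#' @param Wq,Wk,Wv,Wo projection matrices (`d x d`).
#' @param pad_mask logical vector of real-position flags (default: all
#'   real).
#' @param n_heads number of heads (must divide `ncol(D)`).
#' @return matrix of the same shape as `D`.
#' @export
seq_attend <- function(D, Wq, Wk, Wv, Wo, pad_mask = NULL, n_heads = 1L) {
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, nrow(D))
  ps <- ps_from_list(list(`a.Wq` = Wq, `a.Wk` = Wk, `a.Wv` = Wv, `a.Wo` = Wo))
  tp <- tape_new()
  P <- function(nm) tp_param(tp, ps, nm)
  out <- .tp_mha(tp, tp_const(tp, D), pad_mask, n_heads, "a.", P)
  tp_val(tp, out)
}

#' Position-wise feed-forward block
#'
#' `max(0, Z W1 + b1) W2 + b2` applied row-wise.
#'
#' @param Z input matrix.
#' @param W1,b1,W2,b2 parameters.
#' @return transformed matrix.
#' @export
seq_ffn <- function(Z, W1, b1, W2, b2) {
  h <- pmax(Z %*% W1 + matrix(b1, nrow(Z), length(b1), byrow = TRUE), 0)
  h %*% W2 + matrix(b2, nrow(Z), length(b2), byrow = TRUE)
}

#' Encode a substructure sequence into a drug embedding
#'
#' Applies `n_layers` attention + feed-forward blocks (residual connections
#' with layer normalization) over the real tokens, mean-pools, and maps to
#' `d_seq`. Padding positions cannot influence the result.
#'
#' @param seq a `cdr_substructure_seq` with at least one real token.
#' @param params parameter list from [seq_params()].
#' @return numeric vector of length `d_seq`.
#' @export
encode_drug_sequence <- function(seq, params) {
  stopifnot(inherits(seq, "cdr_substructure_seq"))
  cfg <- attr(params, "cfg")
  ps <- ps_from_list(params)
  tp <- tape_new()
  out <- .tp_encode_seq(tp, ps, seq, cfg, prefix = "")
  as.numeric(tp_val(tp, out))
}
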