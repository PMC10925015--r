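# Edge-collaborative graph convolutional encoder for drug molecules.
#
# The edge tensor is decomposed into per-channel adjacency matrices. Each
# layer sends per-channel messages E_k V W_k, sums them over channels, and
# combines the result with the previous node state. After the first layer
# a relation vector is computed for every bonded pair from the updated node
# embeddings and fused with the incoming edge features (the collaborative
# edge update); the second layer performs node updates only, reading its
# channel adjacencies from a linear projection of the updated edge
# embeddings. Readout is mean-pool plus max-pool over atoms followed by a
# linear map, so the embedding is invariant to atom relabeling.

#' Split an edge tensor into per-channel adjacency matrices
#'
#' @param A numeric array `N x N x C_edge`, symmetric in its first two axes.
#' @return list of `C_edge` matrices, `N x N` each; stacking them along a
#'   third axis reconstructs `A` exactly.
#' @export
channel_decompose <- function(A) {
  stopifnot(is.array(A), length(dim(A)) == 3L)
  lapply(seq_len(dim(A)[3]), function(k) A[, , k])
}

## ---- tape builders (shared by training and the exported wrappers) ------

# messages summed over channels, then combined with the previous state.
# chan_ids: list of node ids for the E_k matrices (N x N each)
.tp_node_update <- function(tp, V, chan_ids, W_ids, b_ids,
                            act = "relu", combine = "learned",
                            Wn = NULL, bn = NULL) {
  msgs <- lapply(seq_along(chan_ids), function(k) {
    m <- tp_matmul(tp, tp_matmul(tp, chan_ids[[k]], V), W_ids[[k]])
    tp_activate(tp, tp_add(tp, m, b_ids[[k]]), act)
  })
  M <- msgs[[1]]
  if (length(msgs) > 1L)
    for (k in 2:length(msgs)) M <- tp_add(tp, M, msgs[[k]])
  if (combine == "sum") {
    tp_add(tp, V, M)
  } else {
    tp_activate(tp, tp_add(tp, tp_matmul(tp, tp_concat_cols(tp, list(V, M)),
                                         Wn), bn), act)
  }
}

# symmetrized relation vectors for all bonds at once; returns B x d_edge
.tp_edge_relation <- function(tp, V, i_idx, j_idx, W_rel, b_rel, act = "relu") {
  raw_ij <- tp_activate(tp, tp_add(tp, tp_matmul(tp, tp_concat_cols(tp, list(
    tp_rows(tp, V, i_idx), tp_rows(tp, V, j_idx))), W_rel), b_rel), act)
  raw_ji <- tp_activate(tp, tp_add(tp, tp_matmul(tp, tp_concat_cols(tp, list(
    tp_rows(tp, V, j_idx), tp_rows(tp, V, i_idx))), W_rel), b_rel), act)
  tp_scale(tp, tp_add(tp, raw_ij, raw_ji), 0.5)
}

.tp_edge_update <- function(tp, E_prev, e_new, act = "relu",
                            combine = "learned", We = NULL, be = NULL) {
  if (combine == "sum") return(tp_add(tp, E_prev, e_new))
  tp_activate(tp, tp_add(tp, tp_matmul(tp, tp_concat_cols(tp, list(E_prev, e_new)),
                                       We), be), act)
}

# full two-layer encoder on the tape; returns the id of a 1 x d_graph row
.tp_encode_graph <- function(tp, ps, graph, prefix = "g.", act = "relu") {
  n <- graph$n_atoms
  c_edge <- dim(graph$edge_tensor)[3]
  V0 <- tp_const(tp, graph$node_features)
  chans <- lapply(channel_decompose(graph$edge_tensor),
                  function(E) tp_const(tp, E))
  P <- function(nm) tp_param(tp, ps, paste0(prefix, nm))
  # layer 1: node update + collaborative edge update
  V1 <- .tp_node_update(tp, V0, chans,
                        lapply(seq_len(c_edge), function(k) P(sprintf("l1.W%d", k))),
                        lapply(seq_len(c_edge), function(k) P(sprintf("l1.b%d", k))),
                        act = act, combine = "learned",
                        Wn = P("l1.Wn"), bn = P("l1.bn"))
  bonds <- which(upper.tri(matrix(TRUE, n, n)) &
                   apply(graph$edge_tensor != 0, c(1, 2), any), arr.ind = TRUE)
  if (nrow(bonds)) {
    i_idx <- bonds[, 1L]; j_idx <- bonds[, 2L]
    e_sym <- .tp_edge_relation(tp, V1, i_idx, j_idx, P("l1.Wrel"),
                               P("l1.brel"), act = act)
    E_prev <- tp_const(tp, t(apply(bonds, 1L, function(b)
      graph$edge_tensor[b[1L], b[2L], ])))
    E1 <- .tp_edge_update(tp, E_prev, e_sym, act = act, combine = "learned",
                          We = P("l1.We"), be = P("l1.be"))
    # layer 2 channels: learned edge embeddings projected to scalar channels
    S <- tp_matmul(tp, E1, P("l2.Wproj"))
    c2 <- ncol(tp_val(tp, S))
    chans2 <- lapply(seq_len(c2), function(k)
      tp_edges_to_adj(tp, S, i_idx, j_idx, n, k))
  } else {
    c2 <- ncol(get(paste0(prefix, "l2.Wproj"), envir = ps))
    chans2 <- lapply(seq_len(c2), function(k) tp_const(tp, matrix(0, n, n)))
  }
  V2 <- .tp_node_update(tp, V1, chans2,
                        lapply(seq_len(c2), function(k) P(sprintf("l2.W%d", k))),
                        lapply(seq_len(c2), function(k) P(sprintf("l2.b%d", k))),
                        act = act, combine = "learned",
                        Wn = P("l2.Wn"), bn = P("l2.bn"))
  pooled <- tp_concat_cols(tp, list(tp_colmeans(tp, V2), tp_colmax(tp, V2)))
  tp_add(tp, tp_matmul(tp, pooled, P("out.W")), P("out.b"))
}

## ---- parameters --------------------------------------------------------

#' Initialize graph-encoder parameters
#'
#' @param schema a `cdr_feature_schema` fixing input channel counts.
#' @param d_node node embedding width per layer.
#' @param d_edge edge embedding width after the collaborative update.
#' @param d_graph output embedding length.
#' @param seed integer seed for the random initialization.
#' @return named list of parameter matrices (prefix-free); see
#'   [encode_drug_graph()].
#' @export
cgcn_params <- function(schema = feature_schema(), d_node = 75L,
                        d_edge = 32L, d_graph = 100L, seed = 1L) {
  c_node <- schema$c_node
  c_edge <- schema$c_edge
  with_seed(seed, {
    p <- list()
    for (k in seq_len(c_edge)) {
      p[[sprintf("l1.W%d", k)]] <- glorot(c_node, d_node)
      p[[sprintf("l1.b%d", k)]] <- zeros(1L, d_node)
    }
    p[["l1.Wn"]] <- glorot(c_node + d_node, d_node)
    p[["l1.bn"]] <- zeros(1L, d_node)
    p[["l1.Wrel"]] <- glorot(2L * d_node, d_edge)
    p[["l1.brel"]] <- zeros(1L, d_edge)
    p[["l1.We"]] <- glorot(c_edge + d_edge, d_edge)
    p[["l1.be"]] <- zeros(1L, d_edge)
    p[["l2.Wproj"]] <- glorot(d_edge, c_edge)
    for (k in seq_len(c_edge)) {
      p[[sprintf("l2.W%d", k)]] <- glorot(d_node, d_node)
      p[[sprintf("l2.b%d", k)]] <- zeros(1L, d_node)
    }
    p[["l2.Wn"]] <- glorot(2L * d_node, d_node)
    p[["l2.bn"]] <- zeros(1L, d_node)
    p[["out.W"]] <- glorot(2L * d_node, d_graph)
    p[["out.b"]] <- zeros(1L, d_graph)
    p
  })
}

## ---- exported op-level functions ---------------------------------------

#' Per-channel node update
#'
#' Computes, for each channel `k`, the message `act(E_k V W_k + b_k)`, sums
#' the messages over channels and combines them with the previous node
#' state: either `V + M` (`combine = "sum"`) or the learned combine
#' `act([V || M] W_n + b_n)`.
#'
#' @param V node matrix `N x d_in`.
#' @param channels list of `N x N` channel adjacency matrices.
#' @param W,b lists of per-channel weight (`d_in x d_out`) and bias
#'   (`1 x d_out`) matrices.
#' @param act activation: `"relu"`, `"tanh"` or `"identity"`.
#' @param combine `"learned"` or `"sum"`.
#' @param W_n,b_n combine parameters (`(d_in + d_out) x d_out`, `1 x d_out`),
#'   required for `combine = "learned"`.
#' @return updated node matrix.
#' @export
cgcn_node_update <- function(V, channels, W, b, act = "relu",
                             combine = c("learned", "sum"),
                             W_n = NULL, b_n = NULL) {
  combine <- match.arg(combine)
  if (!all(vapply(channels, function(E) all(dim(E) == nrow(V)), TRUE)))
    cdr_stop("shape_error", "channel matrices must be N x N with N = nrow(V)")
  if (!all(vapply(W, nrow, 1L) == ncol(V)))
    cdr_stop("shape_error", "W must map d_in -> d_out")
  tp <- tape_new()
  Vid <- tp_const(tp, V)
  out <- .tp_node_update(tp, Vid, lapply(channels, function(E) tp_const(tp, E)),
                         lapply(W, function(w) tp_const(tp, w)),
                         lapply(b, function(x) tp_const(tp, x)),
                         act = act, combine = combine,
                         Wn = if (!is.null(W_n)) tp_const(tp, W_n),
                         bn = if (!is.null(b_n)) tp_const(tp, b_n))
  tp_val(tp, out)
}

#' Relation vector between two bonded atoms
#'
#' `act([V_i || V_j] W_rel + b_rel)`, optionally symmetrized by averaging
#' with the reversed concatenation so that `e_ij == e_ji`.
#'
#' @param V updated node matrix.
#' @param i,j 1-based atom indices, `i != j`.
#' @param W_rel,b_rel relation parameters (`2 d x d_edge`, `1 x d_edge`).
#' @param act activation name.
#' @param symmetrize average over both orientations (default TRUE).
#' @return `1 x d_edge` relation vector.
#' @export
cgcn_edge_relation <- function(V, i, j, W_rel, b_rel, act = "relu",
                               symmetrize = TRUE) {
  n <- nrow(V)
  if (i == j || i < 1L || j < 1L || i > n || j > n)
    cdr_stop("index_error", "need distinct in-range atom indices, got (%d, %d)",
             i, j)
  tp <- tape_new()
  Vid <- tp_const(tp, V)
  Wr <- tp_const(tp, W_rel); br <- tp_const(tp, b_rel)
  out <- if (symmetrize) {
    .tp_edge_relation(tp, Vid, i, j, Wr, br, act = act)
  } else {
    tp_activate(tp, tp_add(tp, tp_matmul(tp, tp_concat_cols(tp, list(
      tp_rows(tp, Vid, i), tp_rows(tp, Vid, j))), Wr), br), act)
  }
  tp_val(tp, out)
}

#' Collaborative edge update
#'
#' Fuses the previous edge feature vector with the new relation vector:
#' `E + e` (`combine = "sum"`) or `act([E || e] W_e + b_e)`.
#'
#' @param E_prev previous edge features (`1 x c` or `B x c`).
#' @param e_new relation vector(s), same number of rows.
#' @param W_e,b_e combine parameters for the learned form.
#' @inheritParams cgcn_node_update
#' @return updated edge feature matrix.
#' @export
cgcn_edge_update <- function(E_prev, e_new, act = "relu",
                             combine = c("learned", "sum"),
                             W_e = NULL, b_e = NULL) {
  combine <- match.arg(combine)
  tp <- tape_new()
  out <- .tp_edge_update(tp, tp_const(tp, E_prev), tp_const(tp, e_new),
                         act = act, combine = combine,
                         We = if (!is.null(W_e)) tp_const(tp, W_e),
                         be = if (!is.null(b_e)) tp_const(tp, b_e))
  tp_val(tp, out)
}

#' Encode a molecular graph into a fixed-length embedding
#'
#' Runs the two-layer encoder: layer 1 updates nodes per edge channel and
#' co-updates the edge features from the new node pair embeddings; layer 2
#' updates nodes only, over channel adjacencies projected from the updated
#' edge embeddings; symmetric mean+max readout gives the drug embedding.
#'
#' @param graph a `cdr_molgraph` from [featurize()].
#' @param params named parameter list from [cgcn_params()].
#' @return numeric vector of length `d_graph`.
#' @export
encode_drug_graph <- function(graph, params) {
  stopifnot(inherits(graph, "cdr_molgraph"))
  ps <- ps_from_list(params)
  tp <- tape_new()
  out <- .tp_encode_graph(tp, ps, graph, prefix = "")
  as.numeric(tp_val(tp, out))
}
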