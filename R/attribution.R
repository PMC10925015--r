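# Gradient-sum gene attribution.
#
# The trained network is a scalar function y of the four omics input
# vectors and the drug; for gene i the attribution score is the sum of the
# absolute partial derivatives of y with respect to that gene's entry in
# each omics layer, taken at the observed input point by reverse-mode
# differentiation. Mutation counts are treated as continuous for the
# purpose of differentiation.

#' Per-gene gradient-sum attribution for one drug-cell-line pair
#'
#' @param model a fitted `cdr_model`.
#' @param drug_id drug identifier present in the model's drug table.
#' @param cell_line_id profiled cell line identifier.
#' @return numeric vector of nonnegative GradSum scores, named by gene id.
#' @export
grad_sum <- function(model, drug_id, cell_line_id) {
  stopifnot(inherits(model, "cdr_model"))
  if (!cell_line_id %in% model$omics$cell_ids)
    cdr_stop("data_error", "unknown cell line '%s'", cell_line_id)
  caches <- .prepare_drugs(drug_id, model$drug_table, model$vocab,
                           model$config, model$schema)
  ps <- ps_from_list(model$params)
  scfg <- c(model$config, .seq_cfg(model$config))
  omics <- model$omics
  tp <- tape_new()
  x_ids <- list(exp = tp_const(tp, matrix(omics$exp[, cell_line_id], 1L)),
                met = tp_const(tp, matrix(omics$meth[, cell_line_id], 1L)),
                mut = tp_const(tp, matrix(omics$mut[, cell_line_id], 1L)),
                copy = tp_const(tp, matrix(omics$copy[, cell_line_id], 1L)))
  gid <- .tp_encode_graph(tp, ps, caches$graphs[[drug_id]], prefix = "g.")
  sid <- .tp_encode_seq(tp, ps, caches$seqs[[drug_id]], scfg, prefix = "s.")
  fused <- .tp_encode_omics(tp, ps, x_ids, prefix = "o.")$fused
  X <- tp_concat_cols(tp, list(gid, sid, fused))
  L <- scfg$d_graph + scfg$d_seq + scfg$d_gene
  y <- .tp_head(tp, ps, X, L, scfg, prefix = "h.")
  grads <- tape_backward(tp, y)
  gs <- numeric(length(omics$gene_ids))
  for (om in names(x_ids)) {
    g <- grads[[x_ids[[om]]]]
    if (!is.null(g)) gs <- gs + abs(as.numeric(g))
  }
  names(gs) <- omics$gene_ids
  gs
}

#' Rank genes by attribution score
#'
#' Sorts genes by GradSum descending; equal scores are broken by gene id in
#' lexicographic order, so the first element attains the maximum score.
#'
#' @param grad_sum numeric vector of scores.
#' @param gene_ids gene identifiers aligned with `grad_sum` (default: its
#'   names).
#' @param k number of genes to return.
#' @return character vector of the top `min(k, n)` gene ids.
#' @export
top_genes <- function(grad_sum, gene_ids = names(grad_sum), k = 5L) {
  if (k < 1L) cdr_stop("data_error", "k must be >= 1")
  ord <- order(-grad_sum, gene_ids, method = "radix")
  gene_ids[ord][seq_len(min(k, length(gene_ids)))]
}

#' Attribution report for one drug-cell-line pair
#'
#' @param model a fitted `cdr_model`.
#' @param drug_id,cell_line_id the pair to explain.
#' @param top_k number of top genes reported.
#' @return Object of class `cdr_attribution`: `drug_id`, `cell_line_id`,
#'   `grad_sum` (named vector), `ranked_genes` (all genes, by descending
#'   score) and `top` (the first `top_k`).
#' @export
attribute_pair <- function(model, drug_id, cell_line_id, top_k = 5L) {
  gs <- grad_sum(model, drug_id, cell_line_id)
  ranked <- top_genes(gs, k = length(gs))
  structure(list(drug_id = drug_id, cell_line_id = cell_line_id,
                 grad_sum = gs, ranked_genes = ranked,
                 top = ranked[seq_len(min(top_k, length(ranked)))],
                 top_k = as.integer(top_k)),
            class = "cdr_attribution")
}

#' @export
print.cdr_attribution <- function(x, ...) {
  cat(sprintf("Gene attribution for %s on %s (top %d of %d genes)\n",
              x$drug_id, x$cell_line_id, length(x$top), length(x$grad_sum)))
  df <- data.frame(gene_id = x$top,
                   grad_sum = unname(x$grad_sum[x$top]),
                   rank = seq_along(x$top))
  print(df, row.names = FALSE)
  invisible(x)
}
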