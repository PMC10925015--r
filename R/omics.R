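# Multi-omics assembly and the attention-fused genomic subnetworks.
#
# Four matrices (genes x cell lines) are intersected on shared genes and
# cells, cleaned by per-gene mean imputation, and transformed:
# expression -> log2(TPM + 1) + quantile normalization across cell lines;
# mutation -> per-gene count of mutated sites (site-level rows sharing a
# gene id are summed); methylation and copy number pass through. Each layer
# is then encoded by its own fully connected subnetwork and the four
# embeddings are fused by single-query additive attention into one gene
# context vector per cell line.

.impute_row_means <- function(m) {
  if (!anyNA(m)) return(m)
  rm <- rowMeans(m, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- rm[idx[, 1L]]
  m
}

.qn <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) return(m)
  limma::normalizeQuantiles(m)
}

#' Assemble per-cell-line omics profiles
#'
#' @param exp expression matrix (genes x cell lines, TPM scale).
#' @param mut mutation matrix; rows may be per-site binary indicators with
#'   duplicated gene row names, which are summed into per-gene mutation
#'   counts.
#' @param meth promoter methylation matrix (genes x cell lines).
#' @param copy copy-number matrix (genes x cell lines).
#' @param gene_list optional character vector restricting the gene space
#'   (e.g. a cancer gene census); default keeps all shared genes.
#' @param exp_scale `"tpm"` (default) applies `log2(x + 1)` before quantile
#'   normalization; `"log"` assumes the matrix is already log-scale.
#' @return Object of class `cdr_omics`: `gene_ids`, `cell_ids` and the four
#'   cleaned matrices (genes x cells, identical dimnames).
#' @export
preprocess_omics <- function(exp, mut, meth, copy, gene_list = NULL,
                             exp_scale = c("tpm", "log")) {
  exp_scale <- match.arg(exp_scale)
  mut <- rowsum(mut, group = rownames(mut), na.rm = FALSE)
  mats <- list(exp = exp, mut = mut, meth = meth, copy = copy)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!is.null(gene_list)) genes <- intersect(genes, gene_list)
  cells <- Reduce(intersect, lapply(mats, colnames))
  if (!length(genes))
    cdr_stop("empty_intersection_error", "no genes shared by all layers")
  if (!length(cells))
    cdr_stop("empty_intersection_error", "no cell lines shared by all layers")
  genes <- sort(genes, method = "radix")
  cells <- sort(cells, method = "radix")
  mats <- lapply(mats, function(m) m[genes, cells, drop = FALSE])
  if (exp_scale == "tpm") mats$exp <- log2(mats$exp + 1)
  mats$exp <- .qn(.impute_row_means(mats$exp))
  dimnames(mats$exp) <- list(genes, cells)
  mats$mut <- round(.impute_row_means(mats$mut))
  mats$meth <- .impute_row_means(mats$meth)
  mats$copy <- .impute_row_means(mats$copy)
  structure(list(gene_ids = genes, cell_ids = cells,
                 exp = mats$exp, mut = mats$mut,
                 meth = mats$meth, copy = mats$copy),
            class = "cdr_omics")
}

#' @export
print.cdr_omics <- function(x, ...) {
  cat(sprintf("<cdr_omics> %d genes x %d cell lines (exp, mut, meth, copy)\n",
              length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

#' Extract one cell line's quadruple gene profile
#'
#' @param omics a `cdr_omics`.
#' @param cell_id cell line identifier.
#' @return Object of class `cdr_omics_profile`: `gene_ids` and four aligned
#'   numeric vectors `exp`, `mut`, `meth`, `copy`.
#' @export
omics_profile <- function(omics, cell_id) {
  stopifnot(inherits(omics, "cdr_omics"))
  if (!cell_id %in% omics$cell_ids)
    cdr_stop("data_error", "unknown cell line '%s'", cell_id)
  structure(list(gene_ids = omics$gene_ids,
                 exp = omics$exp[, cell_id],
                 mut = omics$mut[, cell_id],
                 meth = omics$meth[, cell_id],
                 copy = omics$copy[, cell_id]),
            class = "cdr_omics_profile")
}

## ---- tape builder ------------------------------------------------------

.omics_layers <- c("exp", "met", "mut", "copy")

# x_ids: named list of 1 x n input row nodes (exp/met/mut/copy); returns
# list(y = named list of 1 x d ids, weights_id, fused_id)
.tp_encode_omics <- function(tp, ps, x_ids, prefix = "o.") {
  P <- function(nm) tp_param(tp, ps, paste0(prefix, nm))
  y <- lapply(.omics_layers, function(om) {
    h <- tp_relu(tp, tp_add(tp, tp_matmul(tp, x_ids[[om]],
                                          P(paste0(om, ".W1"))),
                            P(paste0(om, ".b1"))))
    tp_relu(tp, tp_add(tp, tp_matmul(tp, h, P(paste0(om, ".W2"))),
                       P(paste0(om, ".b2"))))
  })
  names(y) <- .omics_layers
  Y <- tp_rbind(tp, y)                                   # 4 x d
  scores <- tp_matmul(tp, tp_tanh(tp, tp_matmul(tp, Y, P("att.U"))),
                      P("att.w"))                        # 4 x 1
  alpha <- tp_softmax_rows(tp, tp_t(tp, scores))         # 1 x 4
  fused <- tp_matmul(tp, alpha, Y)                       # 1 x d
  list(y = y, weights = alpha, fused = fused)
}

# batched variant: encodes many cell lines in one matrix pass.
# x_ids: named list of n x n_genes input nodes (rows = cell lines);
# returns id of the n x d fused embedding matrix
.tp_encode_omics_batch <- function(tp, ps, x_ids, prefix = "o.") {
  P <- function(nm) tp_param(tp, ps, paste0(prefix, nm))
  y <- lapply(.omics_layers, function(om) {
    h <- tp_relu(tp, tp_add(tp, tp_matmul(tp, x_ids[[om]],
                                          P(paste0(om, ".W1"))),
                            P(paste0(om, ".b1"))))
    tp_relu(tp, tp_add(tp, tp_matmul(tp, h, P(paste0(om, ".W2"))),
                       P(paste0(om, ".b2"))))
  })
  names(y) <- .omics_layers
  d <- ncol(tp_val(tp, y[[1]]))
  # per-cell scores for each omics layer -> n x 4 softmax
  scores <- tp_concat_cols(tp, lapply(y, function(ys)
    tp_matmul(tp, tp_tanh(tp, tp_matmul(tp, ys, P("att.U"))), P("att.w"))))
  alpha <- tp_softmax_rows(tp, scores)
  ones <- tp_const(tp, matrix(1, 1L, d))
  fused <- NULL
  for (s in seq_along(y)) {
    term <- tp_mul(tp, tp_matmul(tp, tp_cols(tp, alpha, s), ones), y[[s]])
    fused <- if (is.null(fused)) term else tp_add(tp, fused, term)
  }
  fused
}

#' Initialize omics-encoder parameters
#'
#' Four independent two-hidden-layer fully connected subnetworks (one per
#' omics layer) and a single-query additive attention scorer over their
#' outputs.
#'
#' @param n_genes input length of each omics vector.
#' @param hidden first hidden width.
#' @param d embedding width (second hidden layer output).
#' @param d_att attention scorer width.
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
omics_params <- function(n_genes, hidden = 256L, d = 100L, d_att = 32L,
                         seed = 1L) {
  with_seed(seed, {
    p <- list()
    for (om in .omics_layers) {
      p[[paste0(om, ".W1")]] <- glorot(n_genes, hidden)
      p[[paste0(om, ".b1")]] <- zeros(1L, hidden)
      p[[paste0(om, ".W2")]] <- glorot(hidden, d)
      p[[paste0(om, ".b2")]] <- zeros(1L, d)
    }
    p[["att.U"]] <- glorot(d, d_att)
    p[["att.w"]] <- glorot(d_att, 1L)
    attr(p, "cfg") <- list(n_genes = n_genes, hidden = hidden, d = d,
                           d_att = d_att)
    p
  })
}

#' Encode one omics profile into a fused gene embedding
#'
#' `y_* = f_*(x_*)` through four independent subnetworks; attention weights
#' `softmax(w' tanh(U y_*))` over the four embeddings; the fused embedding
#' is their convex combination.
#'
#' @param profile a `cdr_omics_profile`.
#' @param params parameter list from [omics_params()].
#' @return Object of class `cdr_fused_embedding`: `y_exp`, `y_met`, `y_mut`,
#'   `y_copy` (length-`d` vectors), `attention_weights` (nonnegative,
#'   summing to 1) and `x_gene` (the weighted sum).
#' @export
encode_omics <- function(profile, params) {
  stopifnot(inherits(profile, "cdr_omics_profile"))
  cfg <- attr(params, "cfg")
  if (length(profile$exp) != cfg$n_genes)
    cdr_stop("shape_error", "profile has %d genes, parameters expect %d",
             length(profile$exp), cfg$n_genes)
  ps <- ps_from_list(params)
  tp <- tape_new()
  x_ids <- list(exp = tp_const(tp, matrix(profile$exp, 1L)),
                met = tp_const(tp, matrix(profile$meth, 1L)),
                mut = tp_const(tp, matrix(profile$mut, 1L)),
                copy = tp_const(tp, matrix(profile$copy, 1L)))
  enc <- .tp_encode_omics(tp, ps, x_ids, prefix = "")
  structure(list(y_exp = as.numeric(tp_val(tp, enc$y$exp)),
                 y_met = as.numeric(tp_val(tp, enc$y$met)),
                 y_mut = as.numeric(tp_val(tp, enc$y$mut)),
                 y_copy = as.numeric(tp_val(tp, enc$y$copy)),
                 attention_weights = as.numeric(tp_val(tp, enc$weights)),
                 x_gene = as.numeric(tp_val(tp, enc$fused))),
            class = "cdr_fused_embedding")
}

#' Read the four omics matrices from delimited text files
#'
#' Each file: rows = genes (first column `gene_id`), remaining columns =
#' cell line ids.
#'
#' @param dir directory containing `exp.csv`, `mut.csv`, `meth.csv`,
#'   `copy.csv`.
#' @param gene_list_file optional text file with one gene id per line.
#' @param exp_scale passed to [preprocess_omics()].
#' @return a `cdr_omics` (see [preprocess_omics()]).
#' @export
read_omics_dir <- function(dir, gene_list_file = NULL,
                           exp_scale = c("tpm", "log")) {
  rd <- function(f) {
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  gl <- if (!is.null(gene_list_file)) readLines(gene_list_file)
  preprocess_omics(rd("exp.csv"), rd("mut.csv"), rd("meth.csv"),
                   rd("copy.csv"), gene_list = gl,
                   exp_scale = match.arg(exp_scale))
}
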