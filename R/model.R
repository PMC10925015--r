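# The response model: fuse the two drug embeddings with the omics context
# vector, regress ln IC50 through a 1D convolutional head, train with AdamW
# on mean squared error, and impute unmeasured drug-cell-line pairs.

#' Training and architecture configuration
#'
#' Defaults follow the training recipe (AdamW, learning rate 1e-3, batch
#' size 256, mean-squared-error loss) with CPU-scale encoder widths.
#'
#' @param learning_rate AdamW learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation RMSE (used only
#'   when a VALID split is present).
#' @param seed integer master seed (initialization, shuffling).
#' @param augment_factor SMILES-enumeration multiplicity for the training
#'   split (1 = off).
#' @param weight_decay decoupled weight decay.
#' @param d_node,d_edge,d_graph graph-encoder widths.
#' @param seq_d,seq_heads,seq_layers,seq_ff,d_seq,zeta sequence-encoder
#'   widths and maximum token length.
#' @param espf_mu,espf_delta vocabulary thresholds (minimum merge frequency,
#'   maximum vocabulary size).
#' @param omics_hidden,d_gene,omics_att omics-subnetwork widths.
#' @param conv1,conv2,kernel,dense regression-head shape (channel counts,
#'   kernel width, dense width).
#' @return object of class `cdr_config`.
#' @export
cdr_config <- function(learning_rate = 1e-3, batch_size = 256L,
                       epochs = 100L, patience = 10L, seed = 1L,
                       augment_factor = 1L, weight_decay = 1e-2,
                       d_node = 75L, d_edge = 32L, d_graph = 100L,
                       seq_d = 128L, seq_heads = 4L, seq_layers = 2L,
                       seq_ff = 256L, d_seq = 100L, zeta = 64L,
                       espf_mu = 2L, espf_delta = 2000L,
                       omics_hidden = 256L, d_gene = 100L, omics_att = 32L,
                       conv1 = 40L, conv2 = 10L, kernel = 5L, dense = 128L) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(as.list(environment()), class = "cdr_config")
}

.config_fingerprint <- function(config) {
  s <- paste(names(config), vapply(config, function(x) paste(format(x),
             collapse = ","), ""), sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

## ---- regression head ---------------------------------------------------

head_params <- function(L, config, seed = 1L) {
  k <- config$kernel
  L1 <- L - k + 1L
  P1 <- L1 %/% 2L
  L2 <- P1 - k + 1L
  P2 <- L2 %/% 2L
  if (L2 < 1L || P2 < 1L)
    cdr_stop("shape_error", "embedding length %d too short for the head", L)
  p <- with_seed(seed, list(
    conv1.W = glorot(k, config$conv1), conv1.b = zeros(1L, config$conv1),
    conv2.W = glorot(k * config$conv1, config$conv2),
    conv2.b = zeros(1L, config$conv2),
    dense.W = glorot(P2 * config$conv2, config$dense),
    dense.b = zeros(1L, config$dense),
    out.W = glorot(config$dense, 1L), out.b = zeros(1L, 1L)
  ))
  attr(p, "L") <- L
  attr(p, "config") <- config
  p
}

# X: n x L single-channel signal -> n x 1 predictions
.tp_head <- function(tp, ps, X, L, config, prefix = "h.") {
  P <- function(nm) tp_param(tp, ps, paste0(prefix, nm))
  k <- config$kernel
  c1 <- tp_relu(tp, tp_conv1d(tp, X, P("conv1.W"), P("conv1.b"), L, 1L, k))
  L1 <- L - k + 1L
  p1 <- tp_maxpool2(tp, c1, L1, config$conv1)
  P1 <- L1 %/% 2L
  c2 <- tp_relu(tp, tp_conv1d(tp, p1, P("conv2.W"), P("conv2.b"),
                              P1, config$conv1, k))
  L2 <- P1 - k + 1L
  p2 <- tp_maxpool2(tp, c2, L2, config$conv2)
  h <- tp_relu(tp, tp_add(tp, tp_matmul(tp, p2, P("dense.W")), P("dense.b")))
  tp_add(tp, tp_matmul(tp, h, P("out.W")), P("out.b"))
}

#' Fuse embeddings and predict one response
#'
#' Concatenates the graph, sequence and gene embeddings into one signal and
#' applies the convolutional regression head.
#'
#' @param graph_emb,seq_emb,gene_emb numeric embedding vectors.
#' @param head named list of head parameters ([head_params()]) with a
#'   `config`/`L` attribute, or the `$params`/`$config` of a fitted model.
#' @param config a `cdr_config` (defaulted from the attribute when absent).
#' @return predicted ln IC50 (scalar).
#' @export
fuse_and_predict <- function(graph_emb, seq_emb, gene_emb, head,
                             config = attr(head, "config")) {
  x <- c(graph_emb, seq_emb, gene_emb)
  L <- attr(head, "L") %||% length(x)
  if (length(x) != L)
    cdr_stop("shape_error", "embedding length %d does not match head (%d)",
             length(x), L)
  ps <- ps_from_list(head)
  tp <- tape_new()
  out <- .tp_head(tp, ps, tp_const(tp, matrix(x, 1L)), L, config, prefix = "")
  as.numeric(tp_val(tp, out))
}

## ---- dataset splitting -------------------------------------------------

#' Label records with TRAIN/VALID/TEST splits
#'
#' `random` splits per record; `drug_blind` and `cell_blind` assign whole
#' drugs (cell lines) to one side so no test drug (cell line) is seen in
#' training. An optional validation fraction is carved out of the training
#' records.
#'
#' @param records response data frame (`drug_id`, `cell_line_id`,
#'   `ln_ic50`).
#' @param mode `"random"`, `"drug_blind"` or `"cell_blind"`.
#' @param fraction training fraction of records (0 < fraction < 1).
#' @param seed integer seed.
#' @param valid_fraction fraction of records moved from TRAIN to VALID.
#' @param tol acceptable deviation of the achieved blind-split training
#'   fraction.
#' @return `records` with a `split` column.
#' @export
split_dataset <- function(records, mode = c("random", "drug_blind",
                                            "cell_blind"),
                          fraction = 0.8, seed = 1L, valid_fraction = 0,
                          tol = 0.05) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(records)
  with_seed(seed, {
    if (mode == "random") {
      n_train <- round(fraction * n)
      train_idx <- sample.int(n, n_train)
      is_train <- seq_len(n) %in% train_idx
    } else {
      key <- if (mode == "drug_blind") records$drug_id else records$cell_line_id
      ents <- sample(unique(key))
      counts <- table(key)[ents]
      cum <- cumsum(as.numeric(counts))
      n_ent <- which.min(abs(cum - fraction * n))
      achieved <- cum[n_ent] / n
      if (abs(achieved - fraction) > tol)
        cdr_stop("infeasible_split_error",
                 "blind split reaches %.3f, outside %.2f +/- %.2f",
                 achieved, fraction, tol)
      is_train <- key %in% ents[seq_len(n_ent)]
    }
    records$split <- ifelse(is_train, "TRAIN", "TEST")
    if (valid_fraction > 0) {
      tr <- which(records$split == "TRAIN")
      nv <- round(valid_fraction * n)
      records$split[sample(tr, min(nv, length(tr) - 1L))] <- "VALID"
    }
    records
  })
}

## ---- fitting -----------------------------------------------------------

.check_records <- function(records) {
  need <- c("drug_id", "cell_line_id", "ln_ic50")
  if (!all(need %in% names(records)))
    cdr_stop("data_error", "records need columns %s", paste(need, collapse = ", "))
  if (!"split" %in% names(records)) records$split <- "TRAIN"
  if (any(!is.finite(records$ln_ic50)))
    cdr_stop("data_error", "non-finite ln_ic50 values")
  records
}

# build graph/sequence caches for every drug id used
.prepare_drugs <- function(drug_ids, drug_table, vocab, config, schema) {
  miss <- setdiff(drug_ids, drug_table$drug_id)
  if (length(miss))
    cdr_stop("data_error", "drugs missing from drug table: %s",
             paste(miss, collapse = ", "))
  graphs <- list()
  seqs <- list()
  for (d in drug_ids) {
    smi <- drug_table$smiles[match(d, drug_table$drug_id)]
    graphs[[d]] <- featurize(parse_smiles(smi), schema)
    seqs[[d]] <- espf_tokenize(smi, vocab, config$zeta)
  }
  list(graphs = graphs, seqs = seqs)
}

# tape forward for a set of (drug, cell) pairs; returns prediction node id
.tp_predict_pairs <- function(tp, ps, pairs, caches, omics, config) {
  ud <- unique(pairs$drug_id)
  uc <- unique(pairs$cell_line_id)
  gids <- lapply(ud, function(d)
    .tp_encode_graph(tp, ps, caches$graphs[[d]], prefix = "g."))
  sids <- lapply(ud, function(d)
    .tp_encode_seq(tp, ps, caches$seqs[[d]], config, prefix = "s."))
  x_ids <- list(exp = tp_const(tp, t(omics$exp[, uc, drop = FALSE])),
                met = tp_const(tp, t(omics$meth[, uc, drop = FALSE])),
                mut = tp_const(tp, t(omics$mut[, uc, drop = FALSE])),
                copy = tp_const(tp, t(omics$copy[, uc, drop = FALSE])))
  G <- tp_rbind(tp, gids)
  S <- tp_rbind(tp, sids)
  C <- .tp_encode_omics_batch(tp, ps, x_ids, prefix = "o.")
  di <- match(pairs$drug_id, ud)
  ci <- match(pairs$cell_line_id, uc)
  X <- tp_concat_cols(tp, list(tp_rows(tp, G, di), tp_rows(tp, S, di),
                               tp_rows(tp, C, ci)))
  L <- config$d_graph + config$d_seq + config$d_gene
  .tp_head(tp, ps, X, L, config, prefix = "h.")
}

# sequence-encoder cfg view of a cdr_config
.seq_cfg <- function(config) {
  list(n_layers = config$seq_layers, n_heads = config$seq_heads)
}

#' Fit the drug-response model
#'
#' Builds the substructure vocabulary from the drug table, featurizes every
#' drug as a molecular graph and a token sequence, optionally augments the
#' training split with enumerated SMILES, and minimizes the mean squared
#' error of predicted ln IC50 with AdamW. With a VALID split present,
#' training stops early when validation RMSE has not improved for
#' `config$patience` epochs.
#'
#' @param responses data frame with `drug_id`, `cell_line_id`, `ln_ic50`
#'   and optionally `split` (TRAIN/VALID/TEST; default all TRAIN).
#' @param drugs drug table (`drug_id`, `smiles`).
#' @param omics a `cdr_omics` from [preprocess_omics()].
#' @param config a [cdr_config()].
#' @param verbose print per-epoch loss lines.
#' @return Object of class `cdr_model` with elements `params`, `config`,
#'   `vocab`, `schema`, `drug_table`, `records`, `omics`, `history`,
#'   `fitted` and `fingerprint`. Standard methods are available:
#'   [predict.cdr_model()], `print`, `summary`, `coef`, `residuals`,
#'   `fitted`, `plot`, `simulate`.
#' @export
cdr_fit <- function(responses, drugs, omics, config = cdr_config(),
                    verbose = FALSE) {
  stopifnot(inherits(omics, "cdr_omics"), inherits(config, "cdr_config"))
  records <- .check_records(responses)
  miss_cells <- setdiff(unique(records$cell_line_id), omics$cell_ids)
  if (length(miss_cells))
    cdr_stop("data_error", "cell lines missing from omics: %s",
             paste(miss_cells, collapse = ", "))
  base_drug_ids <- unique(records$drug_id)
  if (config$augment_factor > 1L) {
    aug <- augment_training_set(records, drugs, factor = config$augment_factor,
                                seed = config$seed)
    records_aug <- aug$records
    drug_table <- aug$drug_table
  } else {
    records_aug <- records
    drug_table <- drugs
    if (!"parent_id" %in% names(drug_table))
      drug_table$parent_id <- drug_table$drug_id
  }
  virtual <- setdiff(drug_table$drug_id, drugs$drug_id)
  schema <- feature_schema()
  vocab <- espf_build_vocab(unique(drugs$smiles), mu = config$espf_mu,
                            delta = config$espf_delta)
  # enumerated renderings can contain characters unseen in the base corpus
  extra <- setdiff(unique(unlist(strsplit(drug_table$smiles, ""))),
                   vocab$alphabet)
  if (length(extra)) {
    vocab$alphabet <- sort(c(vocab$alphabet, extra), method = "radix")
    vocab$tokens <- c(vocab$alphabet,
                      paste0(vocab$merges$left, vocab$merges$right))
  }
  caches <- .prepare_drugs(unique(records_aug$drug_id), drug_table,
                           vocab, config, schema)
  n_genes <- length(omics$gene_ids)
  ps <- new.env(parent = emptyenv())
  ps_put(ps, "g.", cgcn_params(schema, config$d_node, config$d_edge,
                               config$d_graph, seed = config$seed))
  ps_put(ps, "s.", seq_params(length(vocab$tokens), config$zeta, config$seq_d,
                              config$seq_heads, config$seq_layers,
                              config$seq_ff, config$d_seq,
                              seed = config$seed + 1L))
  ps_put(ps, "o.", omics_params(n_genes, config$omics_hidden, config$d_gene,
                                config$omics_att, seed = config$seed + 2L))
  ps_put(ps, "h.", head_params(config$d_graph + config$d_seq + config$d_gene,
                               config, seed = config$seed + 3L))
  opt <- adamw_new(ls(ps), lr = config$learning_rate,
                   weight_decay = config$weight_decay)
  fingerprint <- .config_fingerprint(config)
  if (verbose)
    message(sprintf("fit: seed %d, config %s, %d train records",
                    config$seed, fingerprint,
                    sum(records_aug$split == "TRAIN")))
  train <- records_aug[records_aug$split == "TRAIN", , drop = FALSE]
  valid <- records_aug[records_aug$split == "VALID", , drop = FALSE]
  if (!nrow(train)) cdr_stop("data_error", "TRAIN split is empty")
  scfg <- c(config, .seq_cfg(config))
  history <- list(train_mse = numeric(), valid_rmse = numeric())
  best_rmse <- Inf
  best_params <- NULL
  stall <- 0L
  with_seed(config$seed + 10L, {
    for (ep in seq_len(config$epochs)) {
      # leakage guard: virtual drugs must never appear outside TRAIN
      held <- records_aug$split != "TRAIN"
      if (any(records_aug$drug_id[held] %in% virtual))
        cdr_stop("leakage_error", "augmented drug found in VALID/TEST")
      ord <- sample.int(nrow(train))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, nrow(train), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(train))]
        batch <- train[idx, , drop = FALSE]
        tp <- tape_new()
        pred <- .tp_predict_pairs(tp, ps, batch, caches, omics, scfg)
        dif <- tp_sub(tp, pred, tp_const(tp, matrix(batch$ln_ic50, ncol = 1L)))
        loss <- tp_mean(tp, tp_mul(tp, dif, dif))
        grads <- tape_backward(tp, loss)
        adamw_step(opt, ps, param_grads(tp, grads))
        ep_loss <- ep_loss + tp_val(tp, loss)[1L] * nrow(batch)
        nb <- nb + nrow(batch)
      }
      history$train_mse <- c(history$train_mse, ep_loss / nb)
      if (nrow(valid)) {
        vp <- .forward_predict(ps, valid, caches, omics, scfg)
        vr <- sqrt(mean((vp - valid$ln_ic50)^2))
        history$valid_rmse <- c(history$valid_rmse, vr)
        if (vr < best_rmse - 1e-8) {
          best_rmse <- vr
          best_params <- ps_to_list(ps)
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        if (verbose)
          message(sprintf("epoch %3d  train MSE %.5f  valid RMSE %.5f",
                          ep, ep_loss / nb, vr))
        if (stall >= config$patience) break
      } else if (verbose) {
        message(sprintf("epoch %3d  train MSE %.5f", ep, ep_loss / nb))
      }
    }
  })
  if (!is.null(best_params)) ps <- ps_from_list(best_params)
  model <- structure(list(
    params = ps_to_list(ps), config = config, vocab = vocab, schema = schema,
    drug_table = drug_table, records = records_aug, omics = omics,
    history = history, fingerprint = fingerprint
  ), class = "cdr_model")
  model$fitted <- predict(model, records)
  model$base_records <- records
  model
}

# plain forward pass over pairs using current parameters
.forward_predict <- function(ps, pairs, caches, omics, scfg) {
  tp <- tape_new()
  as.numeric(tp_val(tp, .tp_predict_pairs(tp, ps, pairs, caches, omics, scfg)))
}

## ---- S3 methods --------------------------------------------------------

#' Predict ln IC50 for drug-cell-line pairs
#'
#' @param object a fitted `cdr_model`.
#' @param newdata data frame with `drug_id` and `cell_line_id`; defaults to
#'   the (unaugmented) records used in fitting.
#' @param drugs optional drug table supplying SMILES for drugs unseen at
#'   fit time.
#' @param omics optional `cdr_omics` for new cell lines.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cdr_model <- function(object, newdata = NULL, drugs = NULL,
                              omics = NULL, ...) {
  pairs <- newdata %||% object$base_records %||% object$records
  omx <- omics %||% object$omics
  drug_table <- object$drug_table
  if (!is.null(drugs)) {
    drugs$parent_id <- drugs$parent_id %||% drugs$drug_id
    drug_table <- rbind(drug_table,
                        drugs[!drugs$drug_id %in% drug_table$drug_id,
                              c("drug_id", "smiles", "parent_id")])
  }
  miss_cells <- setdiff(unique(pairs$cell_line_id), omx$cell_ids)
  if (length(miss_cells))
    cdr_stop("data_error", "cell lines without omics profile: %s",
             paste(miss_cells, collapse = ", "))
  caches <- .prepare_drugs(unique(pairs$drug_id), drug_table,
                           object$vocab, object$config, object$schema)
  ps <- ps_from_list(object$params)
  scfg <- c(object$config, .seq_cfg(object$config))
  .forward_predict(ps, pairs, caches, omx, scfg)
}

#' @export
print.cdr_model <- function(x, ...) {
  cfg <- x$config
  cat("Drug-response model (graph + sequence + omics fusion)\n")
  cat(sprintf("  drugs: %d (vocab %d tokens) | cell lines: %d | genes: %d\n",
              nrow(x$drug_table), length(x$vocab$tokens),
              length(x$omics$cell_ids), length(x$omics$gene_ids)))
  cat(sprintf("  embeddings: graph %d + seq %d + gene %d -> conv head\n",
              cfg$d_graph, cfg$d_seq, cfg$d_gene))
  ep <- length(x$history$train_mse)
  if (ep)
    cat(sprintf("  trained %d epochs, final train MSE %.5f%s\n", ep,
                x$history$train_mse[ep],
                if (length(x$history$valid_rmse))
                  sprintf(", best valid RMSE %.5f", min(x$history$valid_rmse))
                else ""))
  invisible(x)
}

#' @export
summary.cdr_model <- function(object, ...) {
  recs <- object$base_records %||% object$records
  preds <- object$fitted %||% predict(object)
  out <- list(model = object, metrics = list())
  for (sp in intersect(c("TRAIN", "VALID", "TEST"), unique(recs$split))) {
    sel <- recs$split == sp
    if (sum(sel) >= 2L && max(recs$ln_ic50[sel]) > min(recs$ln_ic50[sel]))
      out$metrics[[sp]] <- evaluate(preds[sel], recs$ln_ic50[sel])
  }
  structure(out, class = "summary.cdr_model")
}

#' @export
print.summary.cdr_model <- function(x, ...) {
  print(x$model)
  for (sp in names(x$metrics)) {
    cat(sprintf("  %-5s ", sp))
    print(x$metrics[[sp]])
  }
  invisible(x)
}

#' @export
coef.cdr_model <- function(object, ...) object$params

#' @export
fitted.cdr_model <- function(object, ...) object$fitted

#' @export
residuals.cdr_model <- function(object, ...) {
  recs <- object$base_records %||% object$records
  recs$ln_ic50 - object$fitted
}

#' @method plot cdr_model
#' @export
plot.cdr_model <- function(x, ...) {
  recs <- x$base_records %||% x$records
  graphics::plot(x$fitted, recs$ln_ic50,
                 col = c(TRAIN = "grey40", VALID = "orange",
                         TEST = "firebrick")[recs$split],
                 xlab = "predicted ln IC50", ylab = "observed ln IC50", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.cdr_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  sdr <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

## ---- checkpointing -----------------------------------------------------

#' Save / load a fitted model
#'
#' The checkpoint carries all module parameters, the vocabulary, the
#' feature schema and the configuration (with its fingerprint), so
#' `cdr_load()` followed by `predict()` reproduces predictions bitwise.
#'
#' @param model a `cdr_model`.
#' @param path file path.
#' @export
cdr_save <- function(model, path) {
  stopifnot(inherits(model, "cdr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname cdr_save
#' @export
cdr_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cdr_model"))
    cdr_stop("data_error", "'%s' is not a saved model", path)
  model
}

## ---- missing-pair imputation -------------------------------------------

#' Grid bookkeeping for a drug-response panel
#'
#' @param n_cells,n_drugs panel dimensions.
#' @param n_observed number of measured pairs.
#' @return list with `total_pairs`, `observed`, `missing` and
#'   `missing_pct` (percent, rounded to 2 decimals).
#' @examples
#' pair_bookkeeping(561, 221, 106496)
#' @export
pair_bookkeeping <- function(n_cells, n_drugs, n_observed) {
  total <- n_cells * n_drugs
  if (n_observed > total)
    cdr_stop("data_error", "observed (%d) exceeds grid size (%d)",
             n_observed, total)
  missing <- total - n_observed
  list(total_pairs = total, observed = n_observed, missing = missing,
       missing_pct = round(100 * missing / total, 2))
}

#' Impute unmeasured drug-cell-line responses and rank drugs
#'
#' Predicts every pair absent from `observed`, then ranks drugs by their
#' mean predicted ln IC50 in ascending order: the head of the ranking is
#' the most sensitive (most potent) drugs, the tail the least effective.
#'
#' @param model a fitted `cdr_model`.
#' @param drugs character vector of drug ids (default: non-virtual drugs in
#'   the model's table).
#' @param cells character vector of cell line ids (default: all profiled).
#' @param observed data frame of measured pairs (default: the fitting
#'   records).
#' @param top_k size of the head/tail lists.
#' @return list with `imputed` (data frame `drug_id`, `cell_line_id`,
#'   `pred_ln_ic50`), `ranking` (per-drug mean over imputed pairs,
#'   ascending), `most_sensitive`, `least_effective` and the bookkeeping
#'   counts.
#' @export
predict_missing <- function(model, drugs = NULL, cells = NULL,
                            observed = NULL, top_k = 10L) {
  stopifnot(inherits(model, "cdr_model"))
  dt <- model$drug_table
  drugs <- drugs %||% unique(dt$drug_id[dt$drug_id == dt$parent_id])
  cells <- cells %||% model$omics$cell_ids
  obs <- observed %||% (model$base_records %||% model$records)
  grid <- expand.grid(drug_id = drugs, cell_line_id = cells,
                      stringsAsFactors = FALSE)
  key <- function(d, cl) paste(d, cl, sep = "\r")
  miss <- grid[!key(grid$drug_id, grid$cell_line_id) %in%
                 key(obs$drug_id, obs$cell_line_id), , drop = FALSE]
  bk <- pair_bookkeeping(length(cells), length(drugs),
                         nrow(grid) - nrow(miss))
  if (nrow(miss)) {
    miss$pred_ln_ic50 <- predict(model, miss)
    means <- tapply(miss$pred_ln_ic50, miss$drug_id, mean)
  } else {
    miss$pred_ln_ic50 <- numeric()
    means <- numeric()
  }
  ranking <- data.frame(drug_id = as.character(names(means) %||% character()),
                        mean_pred_ln_ic50 = as.numeric(means),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$mean_pred_ln_ic50, ranking$drug_id), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  k <- min(top_k, nrow(ranking))
  list(imputed = miss, ranking = ranking,
       most_sensitive = utils::head(ranking, k),
       least_effective = utils::tail(ranking, k),
       bookkeeping = bk)
}
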