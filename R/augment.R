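# SMILES-enumeration data augmentation.
#
# Alternative renderings of a molecule are produced by re-rooting the SMILES
# traversal at another atom (Open Babel's writer, `-xf` option). Augmented
# records are confined to the training split: each virtual drug copies its
# parent's cell line and ln IC50, and validation/test records are never
# touched.

# re-root one SMILES at atom `idx` (1-based); NA on failure
.reroot_smiles <- function(smiles, idx) {
  out <- suppressWarnings(
    system2("obabel", c(shQuote(paste0("-:", smiles)), "-osmi", "-xf", idx),
            stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  if (!length(out)) return(NA_character_)
  sub("\\s+$", "", strsplit(out[1L], "\t", fixed = TRUE)[[1]][1L])
}

#' Enumerate alternative SMILES renderings of one molecule
#'
#' Returns up to `n_variants` strings that differ from the input and from
#' one another as strings while canonicalizing to the same molecule. Small
#' or highly symmetric molecules may admit fewer renderings than requested.
#'
#' @param smiles a valid SMILES string.
#' @param n_variants number of distinct renderings wanted (>= 0).
#' @param seed integer seed controlling the traversal-root sampling.
#' @return character vector of length <= `n_variants`.
#' @examples
#' enumerate_smiles("CCO", 1, seed = 1)
#' @export
enumerate_smiles <- function(smiles, n_variants, seed = 1L) {
  mol <- parse_smiles(smiles)  # propagates parse errors
  if (n_variants <= 0L) return(character())
  n <- nrow(mol$atoms)
  can0 <- canonical_smiles(smiles)
  with_seed(seed, {
    roots <- rep(sample.int(n), length.out = max(10L * n_variants, n))
    out <- character()
    for (r in roots) {
      if (length(out) >= n_variants) break
      v <- .reroot_smiles(smiles, r)
      if (is.na(v) || v == smiles || v %in% out) next
      if (identical(canonical_smiles(v), can0)) out <- c(out, v)
    }
    out
  })
}

#' Expand a training set with enumerated SMILES variants
#'
#' For every record in the augmented split, `factor - 1` additional records
#' are created that reference virtual drugs whose SMILES are enumerated
#' renderings of the parent molecule; each new record keeps the original
#' cell line and ln IC50 so the virtual molecule recombines with the same
#' genomic context. Records outside the augmented split are returned
#' unchanged. Only the training split may be augmented.
#'
#' @param records data frame with columns `drug_id`, `cell_line_id`,
#'   `ln_ic50`, `split` (values TRAIN/VALID/TEST).
#' @param drug_table data frame with columns `drug_id`, `smiles`.
#' @param factor total multiplicity (1 = no augmentation).
#' @param seed integer seed.
#' @param split split label to augment; anything but `"TRAIN"` raises a
#'   leakage error.
#' @return list with `records` (original plus augmented rows) and
#'   `drug_table` (original plus virtual drugs, with a `parent_id` column
#'   mapping every drug to the chemical entity it renders).
#' @export
augment_training_set <- function(records, drug_table, factor = 1L,
                                 seed = 1L, split = "TRAIN") {
  if (!identical(split, "TRAIN"))
    cdr_stop("leakage_error",
             "augmentation of split '%s' would leak into evaluation", split)
  if (!"split" %in% names(records))
    cdr_stop("data_error", "records need a split column")
  if (factor < 1L) cdr_stop("data_error", "factor must be >= 1")
  dt <- drug_table
  if (!"parent_id" %in% names(dt)) dt$parent_id <- dt$drug_id
  if (factor == 1L) return(list(records = records, drug_table = dt))
  train <- records[records$split == "TRAIN", , drop = FALSE]
  drugs <- unique(train$drug_id)
  new_rows <- list()
  new_drugs <- list()
  for (d in drugs) {
    smi <- dt$smiles[match(d, dt$drug_id)]
    if (is.na(smi))
      cdr_stop("data_error", "drug '%s' missing from drug table", d)
    vars <- enumerate_smiles(smi, factor - 1L,
                             seed = seed + match(d, drugs))
    if (!length(vars)) next
    vids <- sprintf("%s_v%d", d, seq_along(vars))
    new_drugs[[d]] <- data.frame(drug_id = vids, smiles = vars,
                                 parent_id = d, stringsAsFactors = FALSE)
    base <- train[train$drug_id == d, , drop = FALSE]
    for (k in seq_along(vids)) {
      add <- base
      add$drug_id <- vids[k]
      new_rows[[paste(d, k)]] <- add
    }
  }
  list(records = rbind(records, do.call(rbind, unname(new_rows))),
       drug_table = rbind(dt, do.call(rbind, unname(new_drugs))))
}
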