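# Seeded synthetic data generators.
#
# These stand-ins emulate the shape of a pharmacogenomic panel -- a drug
# table, four omics matrices and a response table -- with a known generative
# rule (one planted causal gene plus a drug-structure covariate), so
# training, evaluation, imputation and attribution can be exercised and
# verified offline. Distributions are chosen to exercise the code paths,
# not to mimic real marginals.

# built-in pool of drug-like molecules (hard-coded, verified parseable)
.smiles_pool <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "CN1CCC[C@H]1c1cccnc1",             # nicotine
  "Clc1ccccc1C(=O)O",                 # 2-chlorobenzoic acid
  "OC(=O)c1ccccc1O",                  # salicylic acid
  "Nc1ccc(cc1)S(=O)(=O)N",            # sulfanilamide
  "CC(N)Cc1ccccc1",                   # amphetamine
  "NCCc1ccc(O)c(O)c1",                # dopamine
  "OCCc1ccccc1",                      # phenethyl alcohol
  "COc1ccc(CCN)cc1",                  # methoxyphenethylamine
  "CN(C)CCc1ccccc1",                  # dimethylphenethylamine
  "Oc1ccc(cc1)C(=O)OC",               # methyl paraben-like
  "CCOC(=O)c1ccccc1N",                # benzocaine-like
  "CC(C)NCC(O)c1ccc(O)c(O)c1",        # isoprenaline
  "CC(=O)c1ccc(cc1)S(=O)(=O)N",       # sulfacetamide-like
  "c1ccc2c(c1)cccc2O",                # naphthol
  "c1ccc2c(c1)ccc3c2cccc3",           # anthracene
  "O=C(O)Cc1ccccc1",                  # phenylacetic acid
  "O=C(Nc1ccccc1)c1ccccc1",           # benzanilide
  "CCN(CC)CCNC(=O)c1ccc(N)cc1",       # procainamide
  "COc1cc2c(cc1OC)CCN2",              # dimethoxyindoline-like
  "CC1CCCC1C(=O)O",                   # methylcyclopentane acid
  "OC1CCCCC1c1ccccc1",                # phenylcyclohexanol
  "O=C1NC(=O)NC(=O)C1",               # barbituric acid
  "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O",  # penicillin G core
  "Clc1ccc(cc1)C(c1ccccc1)N1CCCC1",   # chlorphen-pyrrolidine
  "CN1CCN(CC1)c1ccccc1",              # phenylpiperazine
  "O=C(c1ccccc1)c1ccccc1",            # benzophenone
  "CC(C)(C)NCC(O)c1ccc(O)cc1",        # salbutamol fragment
  "CCOc1ccccc1OCC",                   # catechol diether
  "Cc1ccc(cc1)S(=O)(=O)Nc1ccccn1",    # sulfapyridine-like
  "OCC(O)c1ccccc1",                   # phenylglycol
  "CC(CS)C(=O)N1CCCC1C(=O)O",         # captopril
  "NC(Cc1ccc(O)cc1)C(=O)O",           # tyrosine
  "NC(Cc1c[nH]c2ccccc12)C(=O)O",      # tryptophan
  "OC(=O)CCc1ccccc1",                 # hydrocinnamic acid
  "COc1ccccc1N1CCNCC1",               # methoxyphenylpiperazine
  "Fc1ccc(cc1)C(=O)CCCN1CCC(O)CC1",   # haloperidol fragment
  "CN(C)C(=O)Oc1cccc(c1)N(C)C",       # physostigmine-like carbamate
  "CCN(CC)C(=O)c1ccccc1N",            # diethyl anthranilamide
  "Cc1ncc(n1C)[N+](=O)[O-]",          # metronidazole core
  "OCc1ccc(O)cc1",                    # hydroxybenzyl alcohol
  "Ic1ccc(cc1)C(=O)O",                # iodobenzoic acid
  "Brc1ccccc1CN",                     # bromobenzylamine
  "CSc1ccccc1N",                      # thioanisidine
  "O=S(=O)(N)c1ccc(N)cc1",            # sulfanilamide isomer
  "CC(O)c1ccccc1",                    # phenylethanol
  "N#Cc1ccc(cc1)C(=O)O",              # cyanobenzoic acid
  "OC(=O)c1ccncc1",                   # isonicotinic acid
  "NC(=O)c1ccncc1",                   # isoniazid fragment
  "Oc1ccc2ccccc2c1",                  # naphthalenol isomer
  "CCOC(=O)CC(C)C",                   # ethyl ester
  "CC(C)OC(=O)c1ccccc1",              # isopropyl benzoate
  "O=C1CCCCC1",                       # cyclohexanone
  "C1CCNCC1",                         # piperidine
  "c1ccc(cc1)N1CCOCC1",               # phenylmorpholine
  "CC(=O)NC1CCCCC1",                  # acetylcyclohexylamine
  "CN1CCCC1=O",                       # methylpyrrolidinone
  "COC(=O)c1ccc(O)cc1",               # methyl hydroxybenzoate
  "OCCN1CCOCC1",                      # hydroxyethylmorpholine
  "Cc1cccc(C)c1NC(=O)CN(CC)CC",       # lidocaine
  "CCCCCC(=O)O"                       # hexanoic acid
)

#' Specification of a synthetic fixture panel
#'
#' The generative rule for responses is
#' `ln_ic50(d, c) = alpha * exp[planted_gene, c] + beta * z(d) + eps`,
#' where `z(d)` is the standardized heavy-atom count of drug `d` and
#' `eps ~ Normal(0, noise_sd)`.
#'
#' @param n_drugs,n_cells,n_genes panel dimensions.
#' @param planted_gene_index index (1-based) of the causal gene.
#' @param alpha planted gene effect size.
#' @param beta drug-structure effect size.
#' @param noise_sd response noise standard deviation.
#' @param missing_fraction fraction of the grid masked as unmeasured.
#' @param seed master seed.
#' @return object of class `cdr_fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 10L, n_cells = 20L, n_genes = 100L,
                         planted_gene_index = 1L, alpha = 1, beta = 1,
                         noise_sd = 0.1, missing_fraction = 0, seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1, noise_sd >= 0,
            planted_gene_index >= 1L, planted_gene_index <= n_genes)
  structure(as.list(environment()), class = "cdr_fixture_spec")
}

#' Sample a drug table from the built-in pool
#'
#' @param n_drugs number of drugs (at most the pool size).
#' @param seed integer seed.
#' @return data frame `drug_id`, `smiles`.
#' @export
make_drug_set <- function(n_drugs, seed = 1L) {
  if (n_drugs < 1L || n_drugs > length(.smiles_pool))
    cdr_stop("pool_exhausted_error", "n_drugs must be in 1..%d",
             length(.smiles_pool))
  with_seed(seed, {
    smi <- sample(.smiles_pool, n_drugs)
    data.frame(drug_id = sprintf("drug_%03d", seq_len(n_drugs)),
               smiles = smi, stringsAsFactors = FALSE)
  })
}

#' Generate the four raw omics matrices
#'
#' Expression entries are standard normal (already log-scale; pass
#' `exp_scale = "log"` to [preprocess_omics()]... see Details), mutation
#' counts Poisson(0.3), methylation Uniform(0, 1), copy number
#' Normal(2, 0.5). A fraction `missing` of entries in each matrix is set to
#' `NA` to exercise mean imputation.
#'
#' @details The expression matrix is generated on the log scale, so
#'   pipelines feeding it to [preprocess_omics()] should use
#'   `exp_scale = "log"` to skip the log2(TPM + 1) transform.
#'
#' @param n_cells,n_genes panel dimensions.
#' @param seed integer seed.
#' @param missing per-entry missingness probability (default 0.02).
#' @return list of matrices `exp`, `mut`, `meth`, `copy`
#'   (genes x cells, dimnames set).
#' @export
make_omics <- function(n_cells, n_genes, seed = 1L, missing = 0.02) {
  stopifnot(n_cells >= 1L, n_genes >= 1L)
  with_seed(seed, {
    dn <- list(sprintf("gene_%04d", seq_len(n_genes)),
               sprintf("cell_%03d", seq_len(n_cells)))
    m <- function(x) matrix(x, n_genes, n_cells, dimnames = dn)
    out <- list(exp = m(stats::rnorm(n_genes * n_cells)),
                mut = m(stats::rpois(n_genes * n_cells, 0.3)),
                meth = m(stats::runif(n_genes * n_cells)),
                copy = m(stats::rnorm(n_genes * n_cells, 2, 0.5)))
    if (missing > 0) {
      for (nm in names(out)) {
        mask <- m(stats::runif(n_genes * n_cells) < missing)
        # keep at least one observed value per gene so means exist
        keep <- apply(mask, 1L, all)
        mask[keep, 1L] <- FALSE
        out[[nm]][mask] <- NA
      }
    }
    out
  })
}

#' Generate responses under the planted rule
#'
#' @param drug_table data frame from [make_drug_set()].
#' @param omics raw matrices from [make_omics()].
#' @param spec a [fixture_spec()].
#' @return list with `responses` (data frame `drug_id`, `cell_line_id`,
#'   `ln_ic50`, full grid) and `truth` (planted gene id, effect sizes,
#'   per-drug covariate `z`).
#' @export
make_responses <- function(drug_table, omics, spec) {
  stopifnot(inherits(spec, "cdr_fixture_spec"))
  ex <- omics$exp
  if (anyNA(ex)) {   # the rule reads the complete (mean-imputed) matrix
    rm <- rowMeans(ex, na.rm = TRUE)
    idx <- which(is.na(ex), arr.ind = TRUE)
    ex[idx] <- rm[idx[, 1L]]
  }
  cells <- colnames(ex)
  gene <- rownames(ex)[spec$planted_gene_index]
  natoms <- vapply(drug_table$smiles,
                   function(s) nrow(parse_smiles(s)$atoms), 1L)
  z <- if (length(natoms) > 1L && stats::sd(natoms) > 0)
    as.numeric(scale(natoms)) else natoms * 0
  names(z) <- drug_table$drug_id
  grid <- expand.grid(drug_id = drug_table$drug_id, cell_line_id = cells,
                      stringsAsFactors = FALSE)
  with_seed(spec$seed + 100L, {
    grid$ln_ic50 <- spec$alpha * ex[gene, grid$cell_line_id] +
      spec$beta * z[grid$drug_id] +
      stats::rnorm(nrow(grid), 0, spec$noise_sd)
  })
  rownames(grid) <- NULL
  list(responses = grid,
       truth = list(planted_gene = gene,
                    planted_gene_index = spec$planted_gene_index,
                    alpha = spec$alpha, beta = spec$beta,
                    noise_sd = spec$noise_sd, z = z))
}

#' Exact-count missingness mask for a response grid
#'
#' Masks exactly `round(missing_fraction * n_drugs * n_cells)` grid entries,
#' uniformly at random.
#'
#' @param n_drugs,n_cells grid dimensions.
#' @param missing_fraction fraction in [0, 1).
#' @param seed integer seed.
#' @return logical matrix `n_drugs x n_cells`; `TRUE` marks missing pairs.
#' @export
make_missing_mask <- function(n_drugs, n_cells, missing_fraction, seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  total <- n_drugs * n_cells
  n_miss <- round(missing_fraction * total)
  mask <- matrix(FALSE, n_drugs, n_cells)
  if (n_miss > 0)
    with_seed(seed, mask[sample.int(total, n_miss)] <- TRUE)
  mask
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper: drug table, raw and preprocessed omics, responses
#' (with the grid mask applied) and the ground-truth rule.
#'
#' @param spec a [fixture_spec()].
#' @return list with `drug_table`, `omics_raw`, `omics` (a `cdr_omics`),
#'   `responses` (observed pairs only), `missing` (masked pairs), `truth`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  drug_table <- make_drug_set(spec$n_drugs, seed = spec$seed)
  omics_raw <- make_omics(spec$n_cells, spec$n_genes, seed = spec$seed + 1L)
  omics <- preprocess_omics(omics_raw$exp, omics_raw$mut, omics_raw$meth,
                            omics_raw$copy, exp_scale = "log")
  resp <- make_responses(drug_table, omics_raw, spec)
  mask <- make_missing_mask(spec$n_drugs, spec$n_cells,
                            spec$missing_fraction, seed = spec$seed + 2L)
  grid <- resp$responses
  di <- match(grid$drug_id, drug_table$drug_id)
  ci <- match(grid$cell_line_id, colnames(omics_raw$exp))
  is_missing <- mask[cbind(di, ci)]
  list(drug_table = drug_table, omics_raw = omics_raw, omics = omics,
       responses = grid[!is_missing, , drop = FALSE],
       missing = grid[is_missing, c("drug_id", "cell_line_id"), drop = FALSE],
       truth = resp$truth)
}
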