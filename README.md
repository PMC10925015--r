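# cdrnet

Predicting cancer drug response (ln IC50) from molecular structure and
multi-omics cell-line profiles, in plain R.

## What it does and for whom

Pharmacogenomic screens measure the half-maximal inhibitory concentration
(IC50) of anticancer compounds against panels of cancer cell lines. For
researchers who want to model such panels — predict unmeasured drug /
cell-line pairs, stress-test protocol choices (drug-blind and cell-blind
splits, training-set augmentation), or ask *which genes drove a
prediction* — `cdrnet` implements an end-to-end regression model plus
seeded synthetic data generators so every stage can be exercised and
verified offline, without downloading public screens.

The model fuses three learned representations of a (drug, cell line) pair:

1. **An edge-collaborative graph encoder.** The molecule is a graph
   $D = (V, A)$ with node features $V \in \mathbb{R}^{N \times C_{node}}$
   and a symmetric edge-channel tensor
   $A \in \mathbb{R}^{N \times N \times C_{edge}}$. Each layer sends
   per-channel messages $\sigma(E_k V W_k + b_k)$ summed over channels
   ($E_k$ the $k$-th channel adjacency), and the first layer co-updates
   every bond's feature vector from its endpoints' new embeddings,
   $e_{ij} = \sigma([V_i \| V_j] W_{ij} + b_{ij})$ (symmetrized), so
   chemical-bond information survives the depth of the network.
2. **A transformer over substructure tokens.** SMILES strings are
   decomposed by frequency-driven pair merging (threshold $\mu$, cap
   $\delta$) into substructure sequences; token + position embeddings
   pass through masked scaled dot-product attention
   $Z = \mathrm{softmax}(QK^\top/\sqrt{d})\,V$ and position-wise
   feed-forward blocks.
3. **Attention-fused omics subnetworks.** Per cell line, four gene
   vectors $[exp, mut, meth, copy]$ are encoded by independent fully
   connected subnetworks $y_* = f_*(x_*)$ and fused as
   $X_{gene} = \sum_s \alpha_s y_s$ with
   $\alpha = \mathrm{softmax}(w^\top \tanh(U y_*))$.

The concatenated embeddings feed a 1D-convolutional head trained with
AdamW (learning rate 1e-3, batch 256) on mean squared error. Training-set
SMILES can be augmented with enumerated alternative renderings of the
same molecules (train split only; leakage is checked every epoch). A
fitted model supports `predict`, `summary`, `residuals`, `plot`,
`simulate`, checkpointing, grid imputation with per-drug sensitivity
ranking, and per-gene **GradSum** attribution
$\mathrm{GradSum}_i = |\partial y/\partial exp_i| + |\partial y/\partial met_i| + |\partial y/\partial mut_i| + |\partial y/\partial copy_i|$.

All differentiable computation runs on a small reverse-mode autodiff tape
implemented in the package and verified against finite differences in the
test suite.

## Worked example

```r
library(cdrnet)

fx <- make_fixture(fixture_spec(n_drugs = 6, n_cells = 20, n_genes = 30,
                                missing_fraction = 0.1, seed = 1))
recs <- split_dataset(fx$responses, mode = "random", fraction = 0.8, seed = 1)
cfg <- cdr_config(epochs = 40, d_node = 16, d_edge = 8, d_graph = 16,
                  seq_d = 16, seq_heads = 2, seq_layers = 1, seq_ff = 24,
                  d_seq = 12, omics_hidden = 32, d_gene = 16, omics_att = 8,
                  conv1 = 6, conv2 = 4, dense = 24, seed = 1)
model <- cdr_fit(recs, fx$drug_table, fx$omics, cfg)
summary(model)
#> Drug-response model (graph + sequence + omics fusion)
#>   drugs: 6 (vocab 26 tokens) | cell lines: 20 | genes: 30
#>   embeddings: graph 16 + seq 12 + gene 16 -> conv head
#>   trained 40 epochs, final train MSE 0.27094
#>   TRAIN RMSE 0.4860 | PCC 0.9600 | SCC 0.9540 (n = 86)
#>   TEST  RMSE 0.5068 | PCC 0.9234 | SCC 0.9345 (n = 22)
```

The TRAIN/TEST lines report root mean square error and the Pearson and
Spearman correlations between predicted and observed ln IC50; a PCC above
0.9 on the held-out pairs means the model recovered most of the planted
gene-plus-structure signal of this synthetic panel. Imputing the 10% of
the grid that was generated as unmeasured, and ranking drugs by mean
predicted ln IC50 (ascending = most potent first):

```r
pm <- predict_missing(model)
nrow(pm$imputed)
#> [1] 12
head(pm$ranking, 3)
#>    drug_id mean_pred_ln_ic50
#> 1 drug_001        -2.1794565
#> 2 drug_004        -1.0357838
#> 3 drug_005        -0.6060786
```

Gene attribution for one pair returns the per-gene GradSum scores and the
ranked top genes:

```r
attribute_pair(model, "drug_001", "cell_001", top_k = 5)
```

A thin command-line front end (`inst/cli/cdrnet`) exposes the same
pipeline as `make-fixtures`, `augment`, `train`, `predict`, `evaluate`,
`impute-missing` and `attribute` subcommands.

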