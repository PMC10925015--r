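mk_mats <- function(n_genes = 8, n_cells = 4, seed = 71) {
  set.seed(seed)
  dn <- list(paste0("G", seq_len(n_genes)), paste0("c", seq_len(n_cells)))
  list(exp = matrix(abs(rnorm(n_genes * n_cells, 5, 2)), n_genes,
                    dimnames = dn),
       mut = matrix(rpois(n_genes * n_cells, 0.4), n_genes, dimnames = dn),
       meth = matrix(runif(n_genes * n_cells), n_genes, dimnames = dn),
       copy = matrix(rnorm(n_genes * n_cells, 2, 0.5), n_genes,
                     dimnames = dn))
}

test_that("missing entries are imputed with the per-gene mean", {
  m <- mk_mats()
  m$meth["G3", ] <- c(1, NA, 3, NA)
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy)
  expect_equal(unname(om$meth["G3", ]), c(1, 2, 3, 2))
})

test_that("site-level mutation rows are summed into per-gene counts", {
  m <- mk_mats(n_genes = 2)
  sites <- matrix(c(1, 0, 1, 0, 0, 0, 0, 1,
                    0, 1, 0, 0, 0, 0, 1, 1), 4, 4, byrow = TRUE,
                  dimnames = list(c("G1", "G1", "G1", "G2"),
                                  colnames(m$exp)))
  om <- preprocess_omics(m$exp[1:2, ], sites, m$meth[1:2, ], m$copy[1:2, ])
  expect_equal(unname(om$mut["G1", ]), c(1, 1, 1, 1))
  expect_equal(unname(om$mut["G2", ]), c(0, 0, 1, 1))
  expect_true(all(om$mut >= 0 & om$mut == round(om$mut)))
})

test_that("quantile normalization equalizes sorted columns and is idempotent", {
  m <- mk_mats(n_genes = 30, n_cells = 5)
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy)
  sv <- apply(om$exp, 2, sort)
  expect_lt(max(apply(sv, 1, function(r) diff(range(r)))), 1e-10)
  twice <- cdrnet:::.qn(om$exp)
  expect_equal(twice, om$exp, tolerance = 1e-12)
})

test_that("gene-list restriction and empty intersections behave", {
  m <- mk_mats()
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy,
                         gene_list = c("G1", "G2", "ZZZ"))
  expect_equal(om$gene_ids, c("G1", "G2"))
  expect_error(preprocess_omics(m$exp, m$mut, m$meth, m$copy,
                                gene_list = "nope"),
               class = "cdrnet_empty_intersection_error")
})

test_that("attention weights are a convex combination over the four layers", {
  m <- mk_mats(n_genes = 10)
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy)
  p <- omics_params(10, hidden = 16, d = 8, d_att = 4, seed = 2)
  fe <- encode_omics(omics_profile(om, "c1"), p)
  expect_true(all(fe$attention_weights >= 0))
  expect_equal(sum(fe$attention_weights), 1, tolerance = 1e-10)
  w <- fe$attention_weights
  expect_equal(fe$x_gene,
               w[1] * fe$y_exp + w[2] * fe$y_met + w[3] * fe$y_mut +
                 w[4] * fe$y_copy,
               tolerance = 1e-10)
  # zeroed scorer gives uniform weights
  p0 <- p
  p0[["att.w"]][] <- 0
  expect_equal(encode_omics(omics_profile(om, "c1"), p0)$attention_weights,
               rep(0.25, 4))
})

test_that("subnetworks are isolated: perturbing one layer leaves the others fixed", {
  m <- mk_mats(n_genes = 10)
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy)
  p <- omics_params(10, hidden = 16, d = 8, d_att = 4, seed = 3)
  pr <- omics_profile(om, "c2")
  base <- encode_omics(pr, p)
  pr2 <- pr
  pr2$exp <- pr$exp + rnorm(10)
  pert <- encode_omics(pr2, p)
  expect_false(isTRUE(all.equal(base$y_exp, pert$y_exp)))
  expect_identical(base$y_met, pert$y_met)
  expect_identical(base$y_mut, pert$y_mut)
  expect_identical(base$y_copy, pert$y_copy)
})

test_that("the methylation embedding has exactly zero gradient to expression input", {
  p <- omics_params(6, hidden = 8, d = 4, d_att = 3, seed = 4)
  ps <- cdrnet:::ps_from_list(p)
  tp <- cdrnet:::tape_new()
  x <- list(exp = cdrnet:::tp_const(tp, matrix(rnorm(6), 1)),
            met = cdrnet:::tp_const(tp, matrix(rnorm(6), 1)),
            mut = cdrnet:::tp_const(tp, matrix(rpois(6, 0.3), 1)),
            copy = cdrnet:::tp_const(tp, matrix(rnorm(6, 2), 1)))
  enc <- cdrnet:::.tp_encode_omics(tp, ps, x, prefix = "")
  loss <- cdrnet:::tp_sum(tp, enc$y$met)
  grads <- cdrnet:::tape_backward(tp, loss)
  expect_null(grads[[x$exp]])       # no path from exp to y_met
  expect_false(is.null(grads[[x$met]]))
})

test_that("batched and single-profile encoders agree", {
  m <- mk_mats(n_genes = 12, n_cells = 5)
  om <- preprocess_omics(m$exp, m$mut, m$meth, m$copy)
  p <- omics_params(12, hidden = 16, d = 8, d_att = 4, seed = 5)
  ps <- cdrnet:::ps_from_list(p)
  tp <- cdrnet:::tape_new()
  x_ids <- list(exp = cdrnet:::tp_const(tp, t(om$exp)),
                met = cdrnet:::tp_const(tp, t(om$meth)),
                mut = cdrnet:::tp_const(tp, t(om$mut)),
                copy = cdrnet:::tp_const(tp, t(om$copy)))
  B <- cdrnet:::tp_val(tp, cdrnet:::.tp_encode_omics_batch(tp, ps, x_ids,
                                                           prefix = ""))
  for (k in seq_along(om$cell_ids)) {
    fe <- encode_omics(omics_profile(om, om$cell_ids[k]), p)
    expect_equal(unname(B[k, ]), fe$x_gene, tolerance = 1e-12)
  }
})
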