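test_that("channel decomposition slices and reconstructs the edge tensor", {
  g <- featurize(parse_smiles("CCO"))
  ch <- channel_decompose(g$edge_tensor)
  expect_length(ch, 6L)
  rebuilt <- array(unlist(ch), dim(g$edge_tensor))
  expect_equal(rebuilt, g$edge_tensor)
  # single-bond channel: 2 bonds x symmetry = 4 nonzero entries
  expect_equal(sum(ch[[1]] != 0), 4L)
  expect_equal(sum(ch[[2]] != 0) + sum(ch[[3]] != 0) + sum(ch[[4]] != 0), 0L)
  zero <- channel_decompose(array(0, c(3, 3, 2)))
  expect_true(all(vapply(zero, function(E) all(E == 0), TRUE)))
})

test_that("node update reproduces the hand-computed path-graph example", {
  V <- rbind(c(1, 0), c(0, 1), c(1, 1))
  E <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  out <- cgcn_node_update(V, list(E), list(diag(2)), list(matrix(0, 1, 2)),
                          act = "identity", combine = "sum")
  expect_equal(out, rbind(c(1, 1), c(2, 2), c(1, 2)))
  # no messages when channels are zero
  out0 <- cgcn_node_update(V, list(E * 0), list(diag(2)),
                           list(matrix(0, 1, 2)),
                           act = "identity", combine = "sum")
  expect_equal(out0, V)
})

test_that("node update is permutation-equivariant", {
  set.seed(51)
  n <- 5
  V <- matrix(rnorm(n * 3), n)
  E <- matrix(0, n, n)
  E[upper.tri(E)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
  E <- E + t(E)
  W <- list(matrix(rnorm(9), 3))
  b <- list(matrix(0, 1, 3))
  Wn <- matrix(rnorm(18), 6)
  bn <- matrix(0, 1, 3)
  base <- cgcn_node_update(V, list(E), W, b, W_n = Wn, b_n = bn)
  for (r in 1:5) {
    pm <- sample(n)
    perm <- cgcn_node_update(V[pm, ], list(E[pm, pm]), W, b, W_n = Wn, b_n = bn)
    expect_equal(perm, base[pm, ], tolerance = 1e-12)
  }
})

test_that("edge relation matches the hand example and is symmetric when averaged", {
  V <- rbind(c(9, 9), c(1, 0), c(0, 1))
  W <- rbind(diag(2), diag(2))
  raw <- cgcn_edge_relation(V, 2, 3, W, matrix(0, 1, 2), act = "identity",
                            symmetrize = FALSE)
  expect_equal(raw, matrix(c(1, 1), 1))
  set.seed(52)
  Vr <- matrix(rnorm(8), 4)
  Wr <- matrix(rnorm(4 * 3), 4)
  br <- matrix(rnorm(3), 1)
  e12 <- cgcn_edge_relation(Vr, 1, 2, Wr, br)
  e21 <- cgcn_edge_relation(Vr, 2, 1, Wr, br)
  expect_equal(e12, e21)
  expect_equal(cgcn_edge_relation(matrix(0, 2, 2), 1, 2,
                                  matrix(1, 4, 2), matrix(0, 1, 2)),
               matrix(0, 1, 2))
  expect_error(cgcn_edge_relation(Vr, 2, 2, Wr, br),
               class = "cdrnet_index_error")
})

test_that("edge update adds under the sum parameterization", {
  expect_equal(cgcn_edge_update(matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                                combine = "sum"),
               matrix(c(1, 1), 1))
  # learned combine with zero relation reduces to a map of E_prev only
  We <- rbind(diag(2), matrix(0, 2, 2))
  out <- cgcn_edge_update(matrix(c(2, 3), 1), matrix(0, 1, 2),
                          act = "identity", W_e = We, b_e = matrix(0, 1, 2))
  expect_equal(out, matrix(c(2, 3), 1))
})

test_that("layer-2 adjacency from edge embeddings is symmetric and bond-sparse", {
  tp <- cdrnet:::tape_new()
  S <- cdrnet:::tp_const(tp, matrix(rnorm(6), 3))
  A <- cdrnet:::tp_val(tp, cdrnet:::tp_edges_to_adj(tp, S, c(1, 2, 3),
                                                    c(2, 3, 4), 4L, 1L))
  expect_equal(A, t(A))
  expect_equal(A[1, 3], 0)
  expect_equal(A[1, 4], 0)
  expect_equal(diag(A), rep(0, 4))
})

test_that("the vectorized layer matches the naive per-edge/per-channel loop oracle", {
  set.seed(53)
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    c_edge <- sample(1:2, 1)
    d_in <- 3; d_out <- 4
    V <- matrix(rnorm(n * d_in), n)
    E_list <- lapply(seq_len(c_edge), function(k) {
      E <- matrix(0, n, n)
      E[upper.tri(E)] <- rbinom(n * (n - 1) / 2, 1, 0.6)
      E + t(E)
    })
    W <- lapply(seq_len(c_edge), function(k) matrix(rnorm(d_in * d_out), d_in))
    b <- lapply(seq_len(c_edge), function(k) matrix(rnorm(d_out), 1))
    Wn <- matrix(rnorm((d_in + d_out) * d_out), d_in + d_out)
    bn <- matrix(rnorm(d_out), 1)
    fast <- cgcn_node_update(V, E_list, W, b, W_n = Wn, b_n = bn)
    slow <- cgcn_layer_oracle(V, E_list, W, b, Wn, bn)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("graph encoding is invariant to atom relabeling and non-degenerate", {
  set.seed(54)
  p <- cgcn_params(d_node = 12, d_edge = 6, d_graph = 10, seed = 3)
  g1 <- featurize(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"))
  g2 <- featurize(parse_smiles("CN1CCC[C@H]1c1cccnc1"))
  e1 <- encode_drug_graph(g1, p)
  e2 <- encode_drug_graph(g2, p)
  expect_length(e1, 10L)
  expect_false(isTRUE(all.equal(e1, e2)))
  for (r in 1:5) {
    pm <- sample(g1$n_atoms)
    expect_lt(max(abs(encode_drug_graph(permute_graph(g1, pm), p) - e1)), 1e-5)
  }
  # edgeless graph runs without edge operations
  e0 <- encode_drug_graph(featurize(parse_smiles("C")), p)
  expect_length(e0, 10L)
})

test_that("gradients reach layer-1 node and edge parameters", {
  p <- cgcn_params(d_node = 8, d_edge = 4, d_graph = 6, seed = 7)
  ps <- cdrnet:::ps_from_list(p)
  tp <- cdrnet:::tape_new()
  g <- featurize(parse_smiles("CCO"))
  emb <- cdrnet:::.tp_encode_graph(tp, ps, g, prefix = "")
  loss <- cdrnet:::tp_sum(tp, emb)
  grads <- cdrnet:::tape_backward(tp, loss)
  pg <- cdrnet:::param_grads(tp, grads)
  expect_gt(max(abs(pg[["l1.W1"]])), 0)
  expect_gt(max(abs(pg[["l1.Wrel"]])), 0)
  expect_gt(max(abs(pg[["l1.We"]])), 0)
})
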