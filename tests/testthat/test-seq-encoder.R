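toy_vocab <- function() espf_build_vocab(c("CCO", "CCO", "CCN", "c1ccccc1"),
                                         mu = 2)

test_that("embedding is the sum of token and position rows", {
  v <- toy_vocab()
  s <- espf_tokenize("CCN", v, 8)
  set.seed(61)
  Wc <- matrix(rnorm(length(v$tokens) * 4), length(v$tokens))
  Wp <- matrix(rnorm(8 * 4), 8)
  E <- seq_embed(s, Wc, Wp)
  expect_equal(E[1, ], Wc[s$token_ids[1], ] + Wp[1, ])
  expect_equal(E[2, ], Wc[s$token_ids[2], ] + Wp[2, ])
  # zero token table leaves the pure position encoding
  expect_equal(seq_embed(s, Wc * 0, Wp), Wp[1:2, ])
})

test_that("attention handles the degenerate identity examples", {
  I4 <- diag(4)
  D1 <- matrix(rnorm(4), 1)
  expect_equal(seq_attend(D1, I4, I4, I4, I4), D1)
  D2 <- rbind(c(1, 2, 0, 0), c(1, 2, 0, 0))
  expect_equal(seq_attend(D2, I4, I4, I4, I4), D2)  # mean of equal rows
})

test_that("attention matches the nested-loop oracle on 3-token toys", {
  set.seed(62)
  for (trial in 1:10) {
    d <- 6
    D <- matrix(rnorm(3 * d), 3)
    Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
    Wv <- matrix(rnorm(d * d), d); Wo <- matrix(rnorm(d * d), d)
    mask <- c(TRUE, TRUE, sample(c(TRUE, FALSE), 1))
    fast <- seq_attend(D, Wq, Wk, Wv, Wo, mask, n_heads = 1)
    slow <- attention_oracle(D, Wq, Wk, Wv, Wo, mask)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("attention rows over unmasked positions sum to one", {
  set.seed(63)
  D <- matrix(rnorm(5 * 4), 5)
  Wq <- matrix(rnorm(16), 4); Wk <- matrix(rnorm(16), 4)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  sc <- (D %*% Wq) %*% t(D %*% Wk) / sqrt(4)
  sc[, !mask] <- -1e30
  A <- exp(sc - apply(sc, 1, max))
  A <- A / rowSums(A)
  expect_equal(rowSums(A[, mask]), rep(1, 5), tolerance = 1e-6)
  expect_equal(max(A[, !mask]), 0, tolerance = 1e-12)
})

test_that("feed-forward block reproduces its closed forms", {
  expect_equal(seq_ffn(matrix(c(1, 2), 1), diag(2), c(0, 0),
                       matrix(1, 2, 1), 0),
               matrix(3, 1))
  expect_equal(seq_ffn(matrix(-1, 1, 1), matrix(1), 0, matrix(1), 0),
               matrix(0, 1))
  Z <- matrix(abs(rnorm(6)), 2)
  expect_equal(seq_ffn(Z, diag(3), rep(0, 3), diag(3), rep(0, 3)), Z)
})

test_that("sequence encoding is deterministic and padding-invariant", {
  v <- toy_vocab()
  p <- seq_params(length(v$tokens), zeta = 16, d = 16, n_heads = 2,
                  n_layers = 2, d_ff = 32, d_seq = 10, seed = 4)
  s <- espf_tokenize("CCOc1ccccc1", v, 16)
  e1 <- encode_drug_sequence(s, p)
  expect_identical(e1, encode_drug_sequence(s, p))
  s_short <- espf_tokenize("CCOc1ccccc1", v, 12)  # less padding, same tokens
  expect_lt(max(abs(encode_drug_sequence(s_short, p) - e1)), 1e-6)
})

test_that("token-disjoint drugs embed differently under random parameters", {
  v <- toy_vocab()
  s1 <- espf_tokenize("CCO", v, 16)
  s2 <- espf_tokenize("c1ccccc1", v, 16)
  expect_length(intersect(s1$tokens, s2$tokens), 0L)
  for (seed in 1:5) {
    p <- seq_params(length(v$tokens), zeta = 16, d = 8, n_heads = 2,
                    n_layers = 1, d_ff = 16, d_seq = 6, seed = seed)
    expect_false(isTRUE(all.equal(encode_drug_sequence(s1, p),
                                  encode_drug_sequence(s2, p))))
  }
})

test_that("an all-padding sequence is rejected", {
  v <- toy_vocab()
  p <- seq_params(length(v$tokens), zeta = 8, d = 8, n_heads = 2,
                  n_layers = 1, d_ff = 16, d_seq = 6, seed = 1)
  empty <- structure(list(tokens = character(), token_ids = integer(),
                          length = 0L, max_len = 8L,
                          pad_mask = rep(FALSE, 8)),
                     class = "cdr_substructure_seq")
  expect_error(encode_drug_sequence(empty, p),
               class = "cdrnet_degenerate_input_error")
})
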