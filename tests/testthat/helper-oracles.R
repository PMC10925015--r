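# Independent brute-force oracles and small shared fixtures.

# heavy-atom count straight from the SMILES text: element tokens outside
# brackets (two-letter organic-subset symbols first), one atom per bracket
# group. Independent of the Open Babel parse used by the package.
count_heavy_atoms_text <- function(smiles) {
  n <- 0L
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    c0 <- chars[i]
    if (c0 == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]*H", inner)) n <- n + 1L   # bracket hydrogens excluded
      i <- j + 1L
      next
    }
    two <- if (i < length(chars)) paste0(c0, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      n <- n + 1L
      i <- i + 2L
      next
    }
    if (c0 %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s")) n <- n + 1L
    i <- i + 1L
  }
  n
}

# from-scratch byte-pair merge oracle: recount all adjacent pairs each
# round using a run-aware tally, pick the winner by (freq desc, left, right)
bpe_oracle <- function(corpus, mu, delta) {
  toks <- strsplit(corpus, "", fixed = TRUE)
  alphabet <- sort(unique(unlist(toks)), method = "radix")
  merges <- list()
  tokens <- alphabet
  repeat {
    if (length(tokens) >= delta) break
    tally <- list()
    for (s in toks) {
      t <- 1L
      while (t < length(s)) {
        if (s[t] == s[t + 1L]) {
          r <- t
          while (r < length(s) && s[r + 1L] == s[t]) r <- r + 1L
          key <- paste(s[t], s[t], sep = "\x01")
          tally[[key]] <- (tally[[key]] %||% 0L) + (r - t + 1L) %/% 2L
          t <- r + 1L
        } else {
          key <- paste(s[t], s[t + 1L], sep = "\x01")
          tally[[key]] <- (tally[[key]] %||% 0L) + 1L
          t <- t + 1L
        }
      }
    }
    if (!length(tally)) break
    keys <- names(tally)
    freqs <- unlist(tally)
    parts <- strsplit(keys, "\x01", fixed = TRUE)
    lefts <- vapply(parts, `[`, "", 1L)
    rights <- vapply(parts, `[`, "", 2L)
    best <- order(-freqs, lefts, rights, method = "radix")[1L]
    if (freqs[best] < mu) break
    a <- lefts[best]; b <- rights[best]
    toks <- lapply(toks, function(s) {
      out <- character(0)
      t <- 1L
      while (t <= length(s)) {
        if (t < length(s) && s[t] == a && s[t + 1L] == b) {
          out <- c(out, paste0(a, b)); t <- t + 2L
        } else {
          out <- c(out, s[t]); t <- t + 1L
        }
      }
      out
    })
    merges[[length(merges) + 1L]] <- c(a, b)
    tokens <- c(tokens, paste0(a, b))
  }
  merges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive per-edge/per-channel message-passing layer (Eqs written as loops):
# messages m_k[i, ] = act(sum_j E_k[i, j] * V[j, ] %*% W_k + b_k), combined
# by the learned form act(cbind(V, sum_k m_k) %*% Wn + bn)
cgcn_layer_oracle <- function(V, E_list, W_list, b_list, Wn, bn,
                              act = function(x) pmax(x, 0)) {
  n <- nrow(V)
  d_out <- ncol(W_list[[1]])
  M <- matrix(0, n, d_out)
  for (k in seq_along(E_list)) {
    mk <- matrix(0, n, d_out)
    for (i in seq_len(n)) {
      acc <- rep(0, ncol(V))
      for (j in seq_len(n)) acc <- acc + E_list[[k]][i, j] * V[j, ]
      mk[i, ] <- act(acc %*% W_list[[k]] + b_list[[k]])
    }
    M <- M + mk
  }
  out <- matrix(0, n, ncol(Wn))
  for (i in seq_len(n)) out[i, ] <- act(c(V[i, ], M[i, ]) %*% Wn + bn)
  out
}

# nested-loop masked single-head attention (softmax over unmasked keys)
attention_oracle <- function(D, Wq, Wk, Wv, Wo, mask) {
  l <- nrow(D); d <- ncol(D)
  Q <- D %*% Wq; K <- D %*% Wk; V <- D %*% Wv
  Z <- matrix(0, l, d)
  for (i in seq_len(l)) {
    sc <- rep(-Inf, l)
    for (j in which(mask)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (j in seq_len(l)) if (mask[j]) Z[i, ] <- Z[i, ] + w[j] * V[j, ]
  }
  Z %*% Wo
}

# compact CPU-scale configuration used by training-based tests
small_config <- function(...) {
  cdr_config(d_node = 16L, d_edge = 8L, d_graph = 16L,
             seq_d = 16L, seq_heads = 2L, seq_layers = 1L, seq_ff = 24L,
             d_seq = 12L, zeta = 48L, omics_hidden = 32L, d_gene = 16L,
             omics_att = 8L, conv1 = 6L, conv2 = 4L, dense = 24L, ...)
}

# permute a molecular graph's atom order (node rows and edge-tensor axes)
permute_graph <- function(g, pm) {
  structure(list(node_features = g$node_features[pm, , drop = FALSE],
                 edge_tensor = g$edge_tensor[pm, pm, , drop = FALSE],
                 n_atoms = g$n_atoms, schema = g$schema),
            class = "cdr_molgraph")
}
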