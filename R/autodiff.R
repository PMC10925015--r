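# Reverse-mode automatic differentiation on a flat tape of matrix nodes.
#
# Every differentiable computation in the package (graph encoder, sequence
# encoder, omics subnetworks, convolutional regression head) is expressed as
# tape operations, so a single backward sweep provides both parameter
# gradients for training and input gradients for gene attribution.
#
# A node holds a numeric matrix value, the ids of its parent nodes, and a
# backward closure mapping the output gradient to one gradient per parent.
# Tapes are rebuilt per forward pass; parameters live in a separate
# environment and are injected once per tape (cached by name).

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$cap <- 256L
  tp$val <- vector("list", 256L)
  tp$par <- vector("list", 256L)
  tp$bk <- vector("list", 256L)
  tp$param_nodes <- new.env(parent = emptyenv())
  tp
}

tp_node <- function(tp, value, parents = integer(), backfn = NULL) {
  n <- tp$n + 1L
  if (n > tp$cap) {
    tp$cap <- tp$cap * 2L
    length(tp$val) <- tp$cap
    length(tp$par) <- tp$cap
    length(tp$bk) <- tp$cap
  }
  tp$n <- n
  tp$val[[n]] <- value
  tp$par[[n]] <- parents
  if (!is.null(backfn)) tp$bk[[n]] <- backfn
  n
}

tp_const <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  tp_node(tp, x)
}

# ps: environment (or list-like env) of name -> matrix
tp_param <- function(tp, ps, name) {
  id <- tp$param_nodes[[name]]
  if (!is.null(id)) return(id)
  v <- get(name, envir = ps)
  id <- tp_node(tp, v)
  tp$param_nodes[[name]] <- id
  id
}

tp_val <- function(tp, id) {
  id <- as.integer(id)
  tp$val[[id]]
}

## ---- elementwise and affine ops ---------------------------------------

# a + b; b may be a 1 x ncol(a) row vector (broadcast over rows) or 1 x 1
tp_add <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  if (identical(dim(va), dim(vb))) {
    tp_node(tp, va + vb, c(a, b), function(g) list(g, g))
  } else if (nrow(vb) == 1L && ncol(vb) == ncol(va)) {
    tp_node(tp, sweep(va, 2L, as.numeric(vb), "+"), c(a, b),
            function(g) list(g, matrix(colSums(g), nrow = 1L)))
  } else if (length(vb) == 1L) {
    tp_node(tp, va + vb[1L], c(a, b),
            function(g) list(g, matrix(sum(g), 1L, 1L)))
  } else stop("tp_add: incompatible shapes")
}

tp_sub <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  stopifnot(identical(dim(va), dim(vb)))
  tp_node(tp, va - vb, c(a, b), function(g) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  stopifnot(identical(dim(va), dim(vb)))
  tp_node(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

tp_scale <- function(tp, a, s) {
  a <- as.integer(a)
  tp_node(tp, tp$val[[a]] * s, a, function(g) list(g * s))
}

tp_matmul <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  tp_node(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), t(va) %*% g))
}

tp_relu <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  m <- va > 0
  tp_node(tp, va * m, a, function(g) list(g * m))
}

tp_tanh <- function(tp, a) {
  a <- as.integer(a)
  y <- tanh(tp$val[[a]])
  tp_node(tp, y, a, function(g) list(g * (1 - y * y)))
}

tp_identity_act <- function(tp, a) a

# activation by name; kept small on purpose
tp_activate <- function(tp, a, act = c("relu", "tanh", "identity")) {
  switch(match.arg(act),
         relu = tp_relu(tp, a),
         tanh = tp_tanh(tp, a),
         identity = a)
}

## ---- softmax / normalization ------------------------------------------

# row-wise softmax; masking is done by adding a large negative const upstream
tp_softmax_rows <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  m <- va - apply(va, 1L, max)
  e <- exp(m)
  y <- e / rowSums(e)
  tp_node(tp, y, a, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# per-row layer normalization: (x - mean) / sqrt(var + eps)
tp_layernorm_rows <- function(tp, a, eps = 1e-5) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  d <- ncol(va)
  mu <- rowMeans(va)
  xc <- va - mu
  v <- rowMeans(xc * xc)
  s <- sqrt(v + eps)
  y <- xc / s
  tp_node(tp, y, a, function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list((g - gm - y * gy) / s)
  })
}

## ---- structural ops ----------------------------------------------------

tp_t <- function(tp, a) {
  a <- as.integer(a)
  tp_node(tp, t(tp$val[[a]]), a, function(g) list(t(g)))
}

tp_concat_cols <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$val[[i]])
  w <- vapply(vals, ncol, 1L)
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

tp_rbind <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$val[[i]])
  h <- vapply(vals, nrow, 1L)
  ends <- cumsum(h)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(tp, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

tp_rows <- function(tp, a, idx) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  nr <- nrow(va)
  idx <- as.integer(idx)
  tp_node(tp, va[idx, , drop = FALSE], a, function(g) {
    gx <- matrix(0, nr, ncol(va))
    for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
    list(gx)
  })
}

tp_cols <- function(tp, a, idx) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  nc <- ncol(va)
  idx <- as.integer(idx)
  tp_node(tp, va[, idx, drop = FALSE], a, function(g) {
    gx <- matrix(0, nrow(va), nc)
    for (k in seq_along(idx)) gx[, idx[k]] <- gx[, idx[k]] + g[, k]
    list(gx)
  })
}

# elementwise max of two same-shape nodes; ties route the gradient to `a`
tp_pmax <- function(tp, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  stopifnot(identical(dim(va), dim(vb)))
  m <- va >= vb
  tp_node(tp, pmax(va, vb), c(a, b),
          function(g) list(g * m, g * !m))
}

## ---- reductions --------------------------------------------------------

tp_sum <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  tp_node(tp, matrix(sum(va), 1L, 1L), a, function(g) {
    list(matrix(g[1L], nrow(va), ncol(va)))
  })
}

tp_mean <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  n <- length(va)
  tp_node(tp, matrix(mean(va), 1L, 1L), a, function(g) {
    list(matrix(g[1L] / n, nrow(va), ncol(va)))
  })
}

# column means over rows -> 1 x d
tp_colmeans <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  n <- nrow(va)
  tp_node(tp, matrix(colMeans(va), 1L), a, function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n, ncol(va)))
  })
}

# column max over rows -> 1 x d (gradient to the first argmax row)
tp_colmax <- function(tp, a) {
  a <- as.integer(a)
  va <- tp$val[[a]]
  w <- apply(va, 2L, which.max)
  tp_node(tp, matrix(apply(va, 2L, max), 1L), a, function(g) {
    gx <- matrix(0, nrow(va), ncol(va))
    gx[cbind(w, seq_along(w))] <- as.numeric(g)
    list(gx)
  })
}

## ---- 1D convolution ----------------------------------------------------

# x: n x (L*Cin), position-major layout (column (p-1)*Cin + c holds channel c
# at position p); w: (k*Cin) x Cout with row (t-1)*Cin + c; b: 1 x Cout.
# Valid convolution, stride 1 -> n x (L2*Cout), L2 = L - k + 1, same layout.
tp_conv1d <- function(tp, x, w, b, L, cin, k) {
  x <- as.integer(x); w <- as.integer(w); b <- as.integer(b)
  vx <- tp$val[[x]]; vw <- tp$val[[w]]; vb <- tp$val[[b]]
  n <- nrow(vx)
  cout <- ncol(vw)
  L2 <- L - k + 1L
  stopifnot(ncol(vx) == L * cin, nrow(vw) == k * cin, ncol(vb) == cout)
  A <- array(vx, c(n, cin, L))                       # A[i, c, p]
  slab <- function(t) {
    At <- A[, , t:(t + L2 - 1L), drop = FALSE]       # n x cin x L2
    matrix(aperm(At, c(1L, 3L, 2L)), n * L2, cin)    # row (j-1)*n+i
  }
  acc <- matrix(rep(as.numeric(vb), each = n * L2), n * L2, cout)
  slabs <- vector("list", k)
  for (t in seq_len(k)) {
    slabs[[t]] <- slab(t)
    rows <- ((t - 1L) * cin + 1L):(t * cin)
    acc <- acc + slabs[[t]] %*% vw[rows, , drop = FALSE]
  }
  out <- matrix(aperm(array(acc, c(n, L2, cout)), c(1L, 3L, 2L)), n, L2 * cout)
  tp_node(tp, out, c(x, w, b), function(g) {
    G <- matrix(aperm(array(g, c(n, cout, L2)), c(1L, 3L, 2L)), n * L2, cout)
    gw <- matrix(0, k * cin, cout)
    gxA <- array(0, c(n, cin, L))
    for (t in seq_len(k)) {
      rows <- ((t - 1L) * cin + 1L):(t * cin)
      gw[rows, ] <- crossprod(slabs[[t]], G)
      GS <- G %*% t(vw[rows, , drop = FALSE])        # (n*L2) x cin
      gxA[, , t:(t + L2 - 1L)] <- gxA[, , t:(t + L2 - 1L), drop = FALSE] +
        aperm(array(GS, c(n, L2, cin)), c(1L, 3L, 2L))
    }
    list(matrix(gxA, n, L * cin), gw, matrix(colSums(G), 1L))
  })
}

# non-overlapping max pool of width 2 along positions for position-major
# layout; odd trailing position dropped
tp_maxpool2 <- function(tp, x, L, cin) {
  L2 <- L %/% 2L
  odd <- as.integer(outer(seq_len(cin), (seq_len(L2) - 1L) * 2L * cin, "+"))
  evn <- odd + cin
  tp_pmax(tp, tp_cols(tp, x, odd), tp_cols(tp, x, evn))
}

# scatter bond scalars into a symmetric N x N adjacency; S is B x C, channel
# k is used; backward accumulates g[i,j] + g[j,i] into S[, k]
tp_edges_to_adj <- function(tp, S, i_idx, j_idx, N, k) {
  S <- as.integer(S)
  vs <- tp$val[[S]]
  A <- matrix(0, N, N)
  A[cbind(i_idx, j_idx)] <- vs[, k]
  A[cbind(j_idx, i_idx)] <- vs[, k]
  tp_node(tp, A, S, function(g) {
    gs <- matrix(0, nrow(vs), ncol(vs))
    gs[, k] <- g[cbind(i_idx, j_idx)] + g[cbind(j_idx, i_idx)]
    list(gs)
  })
}

## ---- backward sweep ----------------------------------------------------

# Returns a list of gradients indexed by node id (NULL where unreachable).
tape_backward <- function(tp, loss_id) {
  n <- tp$n
  grads <- vector("list", n)
  vloss <- tp$val[[loss_id]]
  grads[[loss_id]] <- matrix(1, nrow(vloss), ncol(vloss))
  for (id in seq.int(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bk <- tp$bk[[id]]
    if (is.null(bk)) next
    pg <- bk(g)
    pa <- tp$par[[id]]
    for (k in seq_along(pa)) {
      p <- pa[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# named list of parameter gradients for every parameter injected in the tape
param_grads <- function(tp, grads) {
  out <- list()
  for (nm in ls(tp$param_nodes)) {
    id <- tp$param_nodes[[nm]]
    g <- grads[[id]]
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}
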