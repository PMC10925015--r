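# parameter initialization and the AdamW optimizer

# Glorot-uniform initialization
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

# identity-or-truncated rectangular identity, used by op-level wrappers
eye <- function(nr, nc = nr) {
  m <- matrix(0, nr, nc)
  d <- min(nr, nc)
  m[cbind(seq_len(d), seq_len(d))] <- 1
  m
}

# AdamW: Adam moments with decoupled weight decay.
adamw_new <- function(param_names, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-2) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$wd <- weight_decay; st$t <- 0L
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  st
}

# ps: environment of parameter matrices; grads: named list
adamw_step <- function(st, ps, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- get(nm, envir = ps)
    m <- st$m[[nm]]; if (is.null(m)) m <- p * 0
    v <- st$v[[nm]]; if (is.null(v)) v <- p * 0
    m <- st$b1 * m + (1 - st$b1) * g
    v <- st$b2 * v + (1 - st$b2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + st$eps)
    # decoupled weight decay, biases (single-row) exempt
    if (nrow(p) > 1L) upd <- upd + st$wd * p
    assign(nm, p - st$lr * upd, envir = ps)
  }
  invisible(st)
}

# flatten a named list of matrices into a parameter environment with a prefix
ps_put <- function(ps, prefix, params) {
  for (nm in names(params)) assign(paste0(prefix, nm), params[[nm]], ps)
  invisible(ps)
}

ps_to_list <- function(ps) {
  out <- list()
  for (nm in ls(ps)) out[[nm]] <- get(nm, envir = ps)
  out
}

ps_from_list <- function(lst) {
  ps <- new.env(parent = emptyenv())
  for (nm in names(lst)) assign(nm, lst[[nm]], ps)
  ps
}
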