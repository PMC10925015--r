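# Frequency-merged substructure vocabulary over SMILES strings and the
# matching tokenizer (byte-pair-encoding over single characters).
#
# The base alphabet is the set of characters seen in the corpus; multi-letter
# element symbols ("Cl", "Br") are learned as merges when frequent enough.
# Pair counting is per adjacent occurrence, non-overlapping left-to-right
# within each string; ties in pair frequency are broken lexicographically on
# (left, right) in C locale so the merge list is byte-stable.

# count adjacent pairs across tokenized corpus with non-overlapping
# left-to-right semantics (only pairs with identical halves can overlap:
# a run of r copies contributes floor(r/2))
.count_pairs <- function(toks) {
  env <- new.env(parent = emptyenv())
  bump <- function(key, by) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) by else cur + by
  }
  for (s in toks) {
    len <- length(s)
    if (len < 2L) next
    t <- 1L
    while (t < len) {
      if (s[t] == s[t + 1L]) {
        # maximal run of the repeated token
        r <- t
        while (r < len && s[r + 1L] == s[t]) r <- r + 1L
        bump(paste(s[t], s[t], sep = "\r"), (r - t + 1L) %/% 2L)
        t <- r + 1L
      } else {
        bump(paste(s[t], s[t + 1L], sep = "\r"), 1L)
        t <- t + 1L
      }
    }
  }
  keys <- ls(env, sorted = FALSE)
  if (!length(keys))
    return(data.frame(left = character(), right = character(),
                      freq = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(left = vapply(parts, `[`, "", 1L),
             right = vapply(parts, `[`, "", 2L),
             freq = vapply(keys, function(k) as.integer(env[[k]]), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# greedy left-to-right replacement of the pair (a, b) by the merged token
.apply_merge <- function(s, a, b) {
  len <- length(s)
  if (len < 2L) return(s)
  out <- character(len)
  o <- 0L
  t <- 1L
  ab <- paste0(a, b)
  while (t <= len) {
    if (t < len && s[t] == a && s[t + 1L] == b) {
      o <- o + 1L
      out[o] <- ab
      t <- t + 2L
    } else {
      o <- o + 1L
      out[o] <- s[t]
      t <- t + 1L
    }
  }
  out[seq_len(o)]
}

#' Build a substructure vocabulary from a SMILES corpus
#'
#' Repeatedly merges the most frequent adjacent token pair across the corpus
#' into a new token, until the best pair's frequency drops below `mu` or the
#' vocabulary reaches `delta` tokens. The recorded merge list makes
#' tokenization of unseen strings deterministic.
#'
#' @param corpus character vector of SMILES strings.
#' @param mu minimum pair frequency for a merge (>= 2).
#' @param delta maximum vocabulary size (>= size of the initial alphabet).
#' @return Object of class `cdr_espf_vocab` with fields `alphabet`, `merges`
#'   (data frame `left`, `right`), `tokens` (alphabet then merged tokens, in
#'   merge order), `mu`, `delta`.
#' @examples
#' v <- espf_build_vocab(c("CCO", "CCO", "CCN"), mu = 2)
#' v$merges  # ("C","C") then ("CC","O")
#' @export
espf_build_vocab <- function(corpus, mu = 2L, delta = 2000L) {
  if (!length(corpus) || !all(nzchar(corpus)))
    cdr_stop("data_error", "corpus must be a non-empty set of non-empty strings")
  if (mu < 2L) cdr_stop("data_error", "mu must be >= 2")
  toks <- strsplit(corpus, "", fixed = TRUE)
  alphabet <- sort(unique(unlist(toks)), method = "radix")
  if (delta < length(alphabet))
    cdr_stop("data_error", "delta (%d) below alphabet size (%d)",
             delta, length(alphabet))
  merges <- data.frame(left = character(), right = character(),
                       stringsAsFactors = FALSE)
  tokens <- alphabet
  while (length(tokens) < delta) {
    pc <- .count_pairs(toks)
    if (!nrow(pc)) break
    pc <- pc[order(-pc$freq, pc$left, pc$right, method = "radix"), ]
    if (pc$freq[1L] < mu) break
    a <- pc$left[1L]; b <- pc$right[1L]
    toks <- lapply(toks, .apply_merge, a = a, b = b)
    merges <- rbind(merges, data.frame(left = a, right = b,
                                       stringsAsFactors = FALSE))
    tokens <- c(tokens, paste0(a, b))
  }
  structure(list(alphabet = alphabet, merges = merges, tokens = tokens,
                 mu = as.integer(mu), delta = as.integer(delta)),
            class = "cdr_espf_vocab")
}

#' @export
print.cdr_espf_vocab <- function(x, ...) {
  cat(sprintf("<cdr_espf_vocab> %d tokens (%d alphabet + %d merges), mu=%d, delta=%d\n",
              length(x$tokens), length(x$alphabet), nrow(x$merges),
              x$mu, x$delta))
  invisible(x)
}

#' Tokenize a SMILES string into a substructure sequence
#'
#' Splits into characters, replays the vocabulary's merges in recorded
#' order, maps to token ids, and truncates/pads to `zeta` positions.
#' Concatenating the (pre-truncation) token strings reproduces the input.
#'
#' @param smiles a single SMILES string.
#' @param vocab a `cdr_espf_vocab`.
#' @param zeta maximum sequence length; longer sequences are truncated with
#'   a warning.
#' @return Object of class `cdr_substructure_seq`: `tokens` (character,
#'   truncated), `token_ids` (indices into `vocab$tokens`), `length`,
#'   `max_len` and logical `pad_mask` of length `zeta` (`TRUE` at real-token
#'   positions).
#' @export
espf_tokenize <- function(smiles, vocab, zeta = 64L) {
  stopifnot(inherits(vocab, "cdr_espf_vocab"))
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    cdr_stop("parse_error", "smiles must be a single non-empty string")
  s <- strsplit(smiles, "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(s), vocab$alphabet)
  if (length(unknown))
    cdr_stop("unknown_char_error",
             "character(s) %s not in vocabulary alphabet",
             paste0("'", unknown, "'", collapse = ", "))
  if (nrow(vocab$merges)) {
    for (k in seq_len(nrow(vocab$merges)))
      s <- .apply_merge(s, vocab$merges$left[k], vocab$merges$right[k])
  }
  if (length(s) > zeta) {
    warning(sprintf("sequence of %d tokens truncated to zeta = %d",
                    length(s), zeta))
    s <- s[seq_len(zeta)]
  }
  ids <- match(s, vocab$tokens)
  structure(list(tokens = s, token_ids = ids, length = length(s),
                 max_len = as.integer(zeta),
                 pad_mask = seq_len(zeta) <= length(s)),
            class = "cdr_substructure_seq")
}

#' Write / read a vocabulary as plain text
#'
#' One merge per line (`left<TAB>right`) after comment headers recording
#' `mu`, `delta` and the initial alphabet; round-trips exactly.
#'
#' @param vocab a `cdr_espf_vocab`.
#' @param path file path.
#' @export
write_espf_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "cdr_espf_vocab"))
  hdr <- c(sprintf("# mu=%d", vocab$mu),
           sprintf("# delta=%d", vocab$delta),
           sprintf("# alphabet=%s", paste(vocab$alphabet, collapse = "")))
  body <- if (nrow(vocab$merges))
    paste(vocab$merges$left, vocab$merges$right, sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_espf_vocab
#' @export
read_espf_vocab <- function(path) {
  ln <- readLines(path)
  get_hdr <- function(key) {
    h <- grep(sprintf("^# %s=", key), ln, value = TRUE)[1]
    sub(sprintf("^# %s=", key), "", h)
  }
  mu <- as.integer(get_hdr("mu"))
  delta <- as.integer(get_hdr("delta"))
  alphabet <- strsplit(get_hdr("alphabet"), "", fixed = TRUE)[[1]]
  body <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    merges <- data.frame(left = vapply(parts, `[`, "", 1L),
                         right = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  } else {
    merges <- data.frame(left = character(), right = character(),
                         stringsAsFactors = FALSE)
  }
  structure(list(alphabet = alphabet, merges = merges,
                 tokens = c(alphabet, paste0(merges$left, merges$right)),
                 mu = mu, delta = delta),
            class = "cdr_espf_vocab")
}
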