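# SMILES ingestion and molecular-graph featurization.
#
# Parsing and aromaticity perception are delegated to ChemmineR/Open Babel;
# this file turns the parsed structure into the node feature matrix and the
# symmetric edge-channel adjacency tensor consumed by the graph encoder.

# Characters legal outside bracket atoms in (non-reaction) SMILES.
.smiles_plain_chars <- c(LETTERS, letters, as.character(0:9),
                         "(", ")", "[", "]", "=", "#", "-", "+", "%",
                         "/", "\\", ".", "@", ":", "*")

# Cheap syntactic screen run before handing the string to Open Babel, which
# silently "repairs" some malformed inputs (e.g. dangling branch openers).
validate_smiles_syntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    cdr_stop("parse_error", "SMILES must be a single non-empty string")
  ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), .smiles_plain_chars)
  if (length(bad))
    cdr_stop("parse_error", "illegal character(s) %s in SMILES '%s'",
             paste0("'", bad, "'", collapse = ", "), smiles)
  depth <- 0L
  in_bracket <- FALSE
  ring_open <- character()
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (in_bracket) {
      if (c0 == "]") in_bracket <- FALSE
      if (c0 == "[") cdr_stop("parse_error", "nested '[' in SMILES '%s'", smiles)
      i <- i + 1L
      next
    }
    if (c0 == "[") {
      in_bracket <- TRUE
    } else if (c0 == "]") {
      cdr_stop("parse_error", "unmatched ']' in SMILES '%s'", smiles)
    } else if (c0 == "(") {
      depth <- depth + 1L
    } else if (c0 == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        cdr_stop("parse_error", "unmatched ')' in SMILES '%s'", smiles)
    } else if (c0 == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", ch[i + 1:2])))
        cdr_stop("parse_error", "malformed %% ring label in SMILES '%s'", smiles)
      lab <- paste0(ch[i + 1L], ch[i + 2L])
      ring_open <- if (lab %in% ring_open) setdiff(ring_open, lab)
                   else c(ring_open, lab)
      i <- i + 2L
    } else if (grepl("[0-9]", c0)) {
      ring_open <- if (c0 %in% ring_open) setdiff(ring_open, c0)
                   else c(ring_open, c0)
    }
    i <- i + 1L
  }
  if (in_bracket)
    cdr_stop("parse_error", "unterminated '[' in SMILES '%s'", smiles)
  if (depth != 0L)
    cdr_stop("parse_error", "unbalanced parentheses in SMILES '%s'", smiles)
  if (length(ring_open))
    cdr_stop("parse_error", "unclosed ring bond(s) in SMILES '%s'", smiles)
  invisible(TRUE)
}

# MDL atom-block charge codes: 0 = neutral, 1..3 = +3..+1, 5..7 = -1..-3.
.mdl_charge <- function(code) {
  ifelse(code == 0 | code == 4, 0, 4 - code)
}

#' Parse a SMILES string into a heavy-atom molecule
#'
#' Syntactic validation (balanced branches and ring bonds, legal characters)
#' is performed first; chemical interpretation and aromatic-ring perception
#' are delegated to the Open Babel toolkit through \pkg{ChemmineR}. Hydrogens
#' stay implicit: only heavy atoms become graph vertices.
#'
#' @param smiles a single SMILES string.
#' @return An object of class `cdr_molecule`: a list with `atoms` (data frame
#'   with columns `element`, `degree`, `aromatic`, `charge`, `in_ring`),
#'   `bonds` (data frame with columns `i`, `j`, `kind`, `in_ring`,
#'   `conjugated`; one row per undirected bond, `i < j`, 1-based indices) and
#'   the original `smiles`.
#' @examples
#' m <- parse_smiles("CCO")
#' nrow(m$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(smiles) {
  validate_smiles_syntax(smiles)
  moltxt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                               paste0(smiles, "\n"))),
    error = function(e)
      cdr_stop("parse_error", "toolkit failed to parse SMILES '%s': %s",
               smiles, conditionMessage(e)))
  lines <- strsplit(moltxt, "\n", fixed = TRUE)[[1]]
  cnt <- which(grepl("V2000\\s*$", lines))[1]
  if (is.na(cnt))
    cdr_stop("parse_error", "invalid SMILES '%s'", smiles)
  n <- as.integer(substr(lines[cnt], 1L, 3L))
  nb <- as.integer(substr(lines[cnt], 4L, 6L))
  if (is.na(n) || n == 0L)
    cdr_stop("parse_error", "SMILES '%s' yields no atoms", smiles)
  atom_lines <- lines[cnt + seq_len(n)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  charge <- .mdl_charge(as.integer(substr(atom_lines, 37L, 39L)))
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", cl)),
                             "\\s+")[[1]])
    if (length(f) >= 2L)
      for (k in seq(1L, length(f) - 1L, by = 2L)) charge[f[k]] <- f[k + 1L]
  }
  if (nb == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), kind = character(),
                        in_ring = logical(), conjugated = logical(),
                        stringsAsFactors = FALSE)
  } else {
    bond_lines <- lines[cnt + n + seq_len(nb)]
    b1 <- as.integer(substr(bond_lines, 1L, 3L))
    b2 <- as.integer(substr(bond_lines, 4L, 6L))
    order <- as.integer(substr(bond_lines, 7L, 9L))
    i <- pmin(b1, b2)
    j <- pmax(b1, b2)
    # ring + aromaticity perception via ChemmineR on the same MOL block
    rr <- tryCatch({
      sdfm <- ChemmineR::read.SDFset(lines)[[1]]
      ChemmineR::rings(sdfm, upper = 18, type = "all",
                       arom = TRUE, inner = FALSE)
    }, error = function(e) list(RINGS = list(), AROMATIC = logical()))
    ring_sets <- lapply(rr$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    is_arom <- vapply(rr$AROMATIC, isTRUE, logical(1))
    arom_sets <- ring_sets[which(is_arom)]
    in_same <- function(sets, a, b)
      any(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
    bond_ring <- mapply(function(a, b) in_same(ring_sets, a, b), i, j)
    bond_arom <- mapply(function(a, b) in_same(arom_sets, a, b), i, j)
    kind <- ifelse(bond_arom, "aromatic",
                   c("single", "double", "triple")[pmin(order, 3L)])
    # conjugation: aromatic bonds; single bonds bridging two multiple-bond
    # systems; multiple bonds adjacent to another multiple bond
    mult_b <- kind %in% c("double", "triple", "aromatic")
    n_mult <- tabulate(c(i[mult_b], j[mult_b]), nbins = n)
    conj <- bond_arom |
      (kind == "single" & n_mult[i] >= 1L & n_mult[j] >= 1L) |
      (mult_b & (n_mult[i] >= 2L | n_mult[j] >= 2L))
    bonds <- data.frame(i = as.integer(i), j = as.integer(j), kind = kind,
                        in_ring = as.logical(bond_ring),
                        conjugated = as.logical(conj),
                        stringsAsFactors = FALSE)
    if (any(bonds$i == bonds$j))
      cdr_stop("parse_error", "self-bond in SMILES '%s'", smiles)
  }
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  atom_arom <- logical(n)
  atom_ring <- logical(n)
  if (nrow(bonds)) {
    rr_atoms <- unique(unlist(lapply(seq_len(nrow(bonds)), function(b)
      if (bonds$in_ring[b]) c(bonds$i[b], bonds$j[b]) else integer())))
    atom_ring[rr_atoms] <- TRUE
    ar_atoms <- unique(unlist(lapply(seq_len(nrow(bonds)), function(b)
      if (bonds$kind[b] == "aromatic") c(bonds$i[b], bonds$j[b]) else integer())))
    atom_arom[ar_atoms] <- TRUE
  }
  # crude valence screen for clearly impossible carbons/fluorines, using
  # the toolkit's kekulized bond orders
  vsum <- numeric(n)
  if (nrow(bonds)) {
    o <- pmin(order, 3L)
    for (b in seq_len(nrow(bonds))) {
      vsum[bonds$i[b]] <- vsum[bonds$i[b]] + o[b]
      vsum[bonds$j[b]] <- vsum[bonds$j[b]] + o[b]
    }
  }
  over_c <- element == "C" & vsum - charge > 4.2
  over_f <- element == "F" & vsum > 1
  if (any(over_c | over_f))
    cdr_stop("parse_error", "impossible valence in SMILES '%s'", smiles)
  structure(list(
    atoms = data.frame(element = element, degree = degree,
                       aromatic = atom_arom, charge = as.numeric(charge),
                       in_ring = atom_ring, stringsAsFactors = FALSE),
    bonds = bonds,
    smiles = smiles
  ), class = "cdr_molecule")
}

#' @export
print.cdr_molecule <- function(x, ...) {
  cat(sprintf("<cdr_molecule> %s: %d heavy atoms, %d bonds\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Atom/bond featurization schema
#'
#' Declares the layout of the node feature matrix and the edge-channel
#' tensor. Node features: one-hot element over `elements` (plus an "other"
#' bucket when `other_bucket = TRUE`), one-hot heavy-atom degree `0..max_degree`,
#' an aromatic flag, a ring flag and the formal charge as a signed integer.
#' Edge channels: one-hot bond order (single/double/triple/aromatic), a
#' conjugation flag and an in-ring flag.
#'
#' @param elements character vector of explicitly encoded element symbols.
#' @param other_bucket map unlisted elements to a shared bucket instead of
#'   failing.
#' @param max_degree highest heavy-atom degree with its own indicator.
#' @return Object of class `cdr_feature_schema` with derived channel counts
#'   `c_node` and `c_edge`.
#' @export
feature_schema <- function(elements = c("C", "N", "O", "S", "F", "Cl",
                                        "Br", "I", "P"),
                           other_bucket = TRUE, max_degree = 5L) {
  n_elem <- length(elements) + as.integer(other_bucket)
  structure(list(
    elements = elements, other_bucket = other_bucket,
    max_degree = as.integer(max_degree),
    bond_kinds = c("single", "double", "triple", "aromatic"),
    c_node = n_elem + (max_degree + 1L) + 3L,
    c_edge = 6L
  ), class = "cdr_feature_schema")
}

#' Build the molecular graph tensors for one molecule
#'
#' @param mol a `cdr_molecule` from [parse_smiles()].
#' @param schema a `cdr_feature_schema`; defaults to [feature_schema()].
#' @return Object of class `cdr_molgraph`: `node_features` (N x C_node),
#'   `edge_tensor` (N x N x C_edge, symmetric in its first two axes, all-zero
#'   slices exactly where no bond exists), `n_atoms`, and the `schema`.
#' @examples
#' g <- featurize(parse_smiles("c1ccccc1"))
#' g$n_atoms  # 6
#' @export
featurize <- function(mol, schema = feature_schema()) {
  stopifnot(inherits(mol, "cdr_molecule"), inherits(schema, "cdr_feature_schema"))
  n <- nrow(mol$atoms)
  elems <- schema$elements
  n_elem <- length(elems) + as.integer(schema$other_bucket)
  V <- matrix(0, n, schema$c_node)
  for (a in seq_len(n)) {
    el <- mol$atoms$element[a]
    idx <- match(el, elems)
    if (is.na(idx)) {
      if (!schema$other_bucket)
        cdr_stop("schema_error", "element '%s' not covered by schema", el)
      idx <- n_elem
    }
    V[a, idx] <- 1
    deg <- min(mol$atoms$degree[a], schema$max_degree)
    V[a, n_elem + deg + 1L] <- 1
    off <- n_elem + schema$max_degree + 1L
    V[a, off + 1L] <- as.numeric(mol$atoms$aromatic[a])
    V[a, off + 2L] <- as.numeric(mol$atoms$in_ring[a])
    V[a, off + 3L] <- mol$atoms$charge[a]
  }
  A <- array(0, c(n, n, schema$c_edge))
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
      v <- numeric(schema$c_edge)
      v[match(mol$bonds$kind[b], schema$bond_kinds)] <- 1
      v[5L] <- as.numeric(mol$bonds$conjugated[b])
      v[6L] <- as.numeric(mol$bonds$in_ring[b])
      A[i, j, ] <- v
      A[j, i, ] <- v
    }
  }
  structure(list(node_features = V, edge_tensor = A, n_atoms = n,
                 schema = schema), class = "cdr_molgraph")
}

#' Canonical SMILES via the toolkit
#'
#' Two SMILES strings denote the same molecule exactly when their canonical
#' forms are equal; this is the identity check used by the augmentation
#' module.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  ids <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, `[`, "", 1L)
  names(got) <- vapply(parts, function(p) sub("\\s+$", "", p[2L]), "")
  res <- got[ids]
  if (anyNA(res))
    cdr_stop("parse_error", "canonicalization failed for %d input(s)",
             sum(is.na(res)))
  unname(res)
}

#' Read a drug table
#'
#' Accepts delimited text with a `drug_id,smiles` header, or a `.smi` file
#' with one SMILES per line and an optional second id column (missing ids are
#' auto-numbered).
#'
#' @param path file path.
#' @return data frame with columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(trimws(ln), "[ \t]+")
    smiles <- vapply(parts, `[`, "", 1L)
    ids <- vapply(seq_along(parts), function(k)
      if (length(parts[[k]]) > 1L) parts[[k]][2L] else sprintf("drug_%03d", k),
      "")
    return(data.frame(drug_id = ids, smiles = smiles, stringsAsFactors = FALSE))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(df)))
    cdr_stop("data_error", "drug table needs columns drug_id, smiles")
  df[, c("drug_id", "smiles")]
}
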