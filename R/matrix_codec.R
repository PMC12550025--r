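#' Encode a catalyst molecule as a one-hot matrix triple
#'
#' Maps a molecule onto `M = (T, A, B)`: `T` one-hot of length `S` whose
#' set index equals the atom count (index 0 = empty), `A` the `S x A_t`
#' per-node atom-type one-hot, and `B` the symmetric `S x S x B_t`
#' per-pair bond-type one-hot. Unoccupied nodes are no-atom and all their
#' fibers no-bond. When given SMILES the molecule is canonicalized first,
#' so node order is the toolkit's canonical atom ranking; disconnected
#' fragments occupy consecutive index blocks.
#'
#' @param molecule a [cat_mol] or a single SMILES string.
#' @param vocab a [cat_vocabulary].
#' @return an object of class `catalyst_matrix`: list with elements `T`
#'   (numeric length `S`), `A` (`S x A_t`), `B` (`S x S x B_t`), and `n`
#'   (atom count).
#' @export
encode_catalyst <- function(molecule, vocab) {
  if (is.character(molecule)) {
    can <- canonical_smiles(molecule)
    if (is.na(can)) stop("unparseable SMILES: ", molecule)
    molecule <- parse_smiles(can)[[1]]
    if (is.null(molecule)) stop("unparseable SMILES: ", can)
  }
  stopifnot(inherits(molecule, "cat_mol"), inherits(vocab, "cat_vocabulary"))
  S <- vocab$max_nodes
  At <- length(vocab$atom_types); Bt <- length(vocab$bond_types)
  n <- mol_natoms(molecule)
  if (n > S - 1L) {
    stop(sprintf("molecule has %d atoms; at most %d encodable at S=%d", n, S - 1L, S))
  }
  ai <- match(molecule$atoms, vocab$atom_types)
  if (anyNA(ai)) {
    stop("element(s) outside vocabulary: ",
         paste(unique(molecule$atoms[is.na(ai)]), collapse = ", "))
  }
  Tv <- numeric(S); Tv[n + 1L] <- 1
  A <- matrix(0, S, At); A[, 1L] <- 1
  if (n) {
    A[seq_len(n), 1L] <- 0
    A[cbind(seq_len(n), ai)] <- 1
  }
  B <- array(0, c(S, S, Bt)); B[, , 1L] <- 1
  if (nrow(molecule$bonds)) {
    for (r in seq_len(nrow(molecule$bonds))) {
      i <- molecule$bonds$i[r]; j <- molecule$bonds$j[r]
      ch <- molecule$bonds$order[r] + 1L
      B[i, j, 1L] <- 0; B[i, j, ch] <- 1
      B[j, i, 1L] <- 0; B[j, i, ch] <- 1
    }
  }
  structure(list(T = Tv, A = A, B = B, n = n, charges = molecule$charges),
            class = "catalyst_matrix")
}

#' @export
print.catalyst_matrix <- function(x, ...) {
  cat(sprintf("<catalyst_matrix: %d occupied of %d nodes, %d flat dims>\n",
              x$n, length(x$T), length(matrix_flatten(x))))
  invisible(x)
}

#' Flatten a catalyst matrix to one numeric vector
#' @param m a `catalyst_matrix` (or matrix logits of the same shapes).
#' @return numeric vector of length `S + S*A_t + S*S*B_t`.
#' @export
matrix_flatten <- function(m) c(m$T, as.numeric(m$A), as.numeric(m$B))

# Invariant checks used by tests: one-hot fibers, B symmetry, padding.
validate_matrix <- function(m, vocab) {
  S <- vocab$max_nodes
  ok <- isTRUE(all.equal(sum(m$T), 1)) &&
    all(abs(rowSums(m$A) - 1) < 1e-9) &&
    all(abs(apply(m$B, c(1, 2), sum) - 1) < 1e-9)
  if (!ok) return(FALSE)
  for (ch in seq_along(vocab$bond_types)) {
    if (any(abs(m$B[, , ch] - t(m$B[, , ch])) > 1e-9)) return(FALSE)
  }
  if (any(abs(diag(m$B[, , 1]) - 1) > 1e-9)) return(FALSE)
  n <- which(m$T == 1) - 1L
  if (n < S) {
    pad <- (n + 1L):S
    if (any(m$A[pad, 1] != 1)) return(FALSE)
    if (any(m$B[pad, , 1] != 1) || any(m$B[, pad, 1] != 1)) return(FALSE)
  }
  TRUE
}

# Read the straight argmax structure out of a (one-hot or logit) matrix
# triple; no corrections. Used by the decoder path and round-trip tests.
matrix_to_mol <- function(m, vocab) {
  n <- which.max(m$T) - 1L
  if (n == 0L) return(cat_mol(character()))
  ai <- apply(m$A[seq_len(n), , drop = FALSE], 1, which.max)
  keep <- which(ai != 1L)
  atoms <- vocab$atom_types[ai[keep]]
  remap <- match(seq_len(n), keep)
  bonds <- empty_bonds()
  if (length(keep) >= 2) {
    rows <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      fib <- (m$B[i, j, ] + m$B[j, i, ]) / 2
      ch <- which.max(fib)
      if (ch > 1L && !is.na(remap[i]) && !is.na(remap[j])) {
        rows[[length(rows) + 1L]] <- c(remap[i], remap[j], ch - 1L)
      }
    }
    if (length(rows)) {
      bm <- do.call(rbind, rows)
      bonds <- data.frame(i = bm[, 1], j = bm[, 2], order = bm[, 3])
    }
  }
  charges <- integer(length(keep))
  if (!is.null(m$charges) && length(m$charges) == n) charges <- m$charges[keep]
  cat_mol(atoms, bonds, charges)
}

#' Node-order shuffle augmentation
#'
#' Produces `n_orders` copies of a catalyst matrix whose occupied nodes are
#' simultaneously permuted in the annotation matrix rows and adjacency
#' rows/columns; `T` is unchanged and every copy decodes to the same
#' canonical structure. The first copy uses the identity permutation so the
#' canonical ordering is always present among the augmented set.
#'
#' @param matrix a `catalyst_matrix`.
#' @param n_orders number of orderings to return (the training default is 5).
#' @param seed integer seed making the orderings reproducible.
#' @return list of `catalyst_matrix` objects of length `n_orders`.
#' @export
shuffle_augment <- function(matrix, n_orders = 5L, seed = 1L) {
  stopifnot(inherits(matrix, "catalyst_matrix"), n_orders >= 1L)
  n <- matrix$n
  out <- vector("list", n_orders)
  out[[1L]] <- matrix
  if (n_orders == 1L) return(out)
  rng <- .seeded_rng(seed)
  for (k in 2L:n_orders) {
    if (n <= 1L) { out[[k]] <- matrix; next }
    perm <- rng$sample(n)
    out[[k]] <- .permute_matrix(matrix, perm)
  }
  out
}

.permute_matrix <- function(m, perm) {
  n <- m$n
  A2 <- m$A; A2[seq_len(n), ] <- m$A[perm, , drop = FALSE]
  B2 <- m$B
  B2[seq_len(n), , ] <- m$B[perm, , , drop = FALSE]
  B2[, seq_len(n), ] <- B2[, perm, , drop = FALSE]
  ch2 <- m$charges
  if (!is.null(ch2) && length(ch2) == n) ch2 <- ch2[perm]
  structure(list(T = m$T, A = A2, B = B2, n = n, charges = ch2),
            class = "catalyst_matrix")
}

# Small local RNG wrapper: isolates seeding from the global RNG stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(
    sample = function(n, size = n, replace = FALSE) run(function() sample.int(n, size, replace)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd))
  )
}

#' Attributed molecular graph features
#'
#' Extracts fixed-width node and edge feature vectors for the condition
#' graph encoders. The `"default"` scheme uses element-group one-hots
#' (12), degree one-hots (6) and formal-charge sign (3) per node
#' (width 21), and bond-category one-hots per edge (width 5).
#'
#' @param molecule a [cat_mol] or single SMILES string.
#' @param feature_scheme name of the feature scheme (only `"default"`).
#' @return an object of class `mol_graph`: list with `nodes` (N x 21
#'   matrix), `edges` (data.frame `i`, `j`), `edge_feats` (M x 5 matrix),
#'   `n_nodes`, `n_edges`, and `scheme`.
#' @export
featurize_molecule_graph <- function(molecule, feature_scheme = "default") {
  feature_scheme <- match.arg(feature_scheme)
  if (is.character(molecule)) {
    parsed <- parse_smiles(molecule)[[1]]
    if (is.null(parsed)) stop("unparseable SMILES: ", molecule)
    molecule <- parsed
  }
  sch <- graph_feature_scheme(feature_scheme)
  n <- mol_natoms(molecule)
  nodes <- matrix(0, n, sch$node_width)
  deg <- numeric(n)
  if (nrow(molecule$bonds)) {
    tab <- table(factor(c(molecule$bonds$i, molecule$bonds$j), levels = seq_len(n)))
    deg <- as.numeric(tab)
  }
  for (a in seq_len(n)) {
    sym <- molecule$atoms[a]
    grp <- if (sym %in% sch$element_groups) match(sym, sch$element_groups)
           else if (is_metal(sym)) match("metal", sch$element_groups)
           else match("other", sch$element_groups)
    nodes[a, grp] <- 1
    nodes[a, 12L + min(deg[a], 5) + 1L] <- 1
    nodes[a, 18L + sign(molecule$charges[a]) + 2L] <- 1
  }
  ef <- matrix(0, nrow(molecule$bonds), sch$edge_width)
  if (nrow(molecule$bonds)) {
    ef[cbind(seq_len(nrow(molecule$bonds)), molecule$bonds$order)] <- 1
  }
  structure(list(nodes = nodes, edges = molecule$bonds[, c("i", "j")],
                 edge_feats = ef, n_nodes = n, n_edges = nrow(molecule$bonds),
                 scheme = feature_scheme),
            class = "mol_graph")
}

#' Declared widths of a graph feature scheme
#' @param name scheme name.
#' @return list with `node_width`, `edge_width`, `element_groups`.
#' @export
graph_feature_scheme <- function(name = "default") {
  match.arg(name)
  list(node_width = 21L, edge_width = 5L,
       element_groups = c("C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "H",
                          "metal", "other"))
}

#' One-hot molecular-weight cluster encoding
#'
#' Assigns a molecular weight to one of `length(bin_edges) + 1` half-open
#' bins `[e_k, e_{k+1})` with open outer bins (left-closed convention:
#' a weight equal to an edge falls in the bin to its right).
#'
#' @param molecular_weight non-negative weight in g/mol.
#' @param bin_edges ascending numeric vector of bin boundaries.
#' @return one-hot numeric vector of length `length(bin_edges) + 1`.
#' @export
mw_cluster_onehot <- function(molecular_weight, bin_edges) {
  stopifnot(length(bin_edges) >= 1, !is.unsorted(bin_edges, strictly = TRUE))
  if (molecular_weight < 0) stop("molecular weight must be non-negative")
  k <- findInterval(molecular_weight, bin_edges)
  out <- numeric(length(bin_edges) + 1L)
  out[k + 1L] <- 1
  out
}
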