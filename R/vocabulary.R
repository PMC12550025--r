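#' Atom/bond vocabulary for the catalyst matrix codec
#'
#' The codec maps molecules onto a fixed-size one-hot triple
#' `M = (T, A, B)`: a size indicator `T` (length `S`), an annotation matrix
#' `A` (`S x A_t`, atom type per node) and an adjacency tensor `B`
#' (`S x S x B_t`, bond type per node pair). The vocabulary fixes the three
#' dimensions and the category orderings. Index 1 of `atom_types` is the
#' reserved no-atom entry (`"*"`); index 1 of `bond_types` is no-bond.
#'
#' @param atom_types character vector; first entry must be `"*"` (no-atom).
#' @param bond_types character vector; first entry must be `"none"`.
#' @param max_nodes maximum node count `S` (molecules may use at most
#'   `S - 1` atoms since index 0 of `T` encodes the empty molecule).
#' @return an object of class `cat_vocabulary`.
#' @export
cat_vocabulary <- function(atom_types, bond_types = default_bond_types(),
                           max_nodes = 100L) {
  stopifnot(atom_types[1] == "*", bond_types[1] == "none",
            max_nodes >= 2, !anyDuplicated(atom_types), !anyDuplicated(bond_types))
  structure(list(atom_types = as.character(atom_types),
                 bond_types = as.character(bond_types),
                 max_nodes = as.integer(max_nodes)),
            class = "cat_vocabulary")
}

#' @export
print.cat_vocabulary <- function(x, ...) {
  cat(sprintf("<cat_vocabulary: S=%d, %d atom types, %d bond types, %d flat dims>\n",
              x$max_nodes, length(x$atom_types), length(x$bond_types),
              flatten_dim(x)))
  invisible(x)
}

#' Default bond categories
#'
#' No-bond, the three covalent orders, aromatic, and a catch-all
#' other/coordination category that absorbs dative and unspecified bonds
#' (6 categories in total).
#' @return character vector of length 6.
#' @export
default_bond_types <- function() {
  c("none", "single", "double", "triple", "aromatic", "other")
}

#' Default vocabulary (S = 100, 68 atom types, 6 bond types)
#'
#' The 67 elements cover organic chemistry, main-group elements and the
#' transition metals and lanthanides common in homogeneous catalysis.
#' @return a [cat_vocabulary].
#' @export
default_vocabulary <- function() {
  cat_vocabulary(c("*", .element_table$symbol), default_bond_types(), 100L)
}

#' Build a vocabulary from a training set
#'
#' Observed elements are ordered by frequency (descending, ties broken
#' alphabetically) after the reserved no-atom slot, then padded to
#' `max_atom_types` with curated elements not observed in the data so the
#' channel count stays fixed.
#'
#' @param molecules list of [cat_mol] objects, or character SMILES.
#' @param max_atom_types total atom-type channel count including no-atom.
#' @param max_nodes maximum node count `S`.
#' @param bond_type_policy currently only `"default"` (6 categories).
#' @return a [cat_vocabulary].
#' @export
build_vocabulary <- function(molecules, max_atom_types = 68L,
                             max_nodes = 100L, bond_type_policy = "default") {
  bond_type_policy <- match.arg(bond_type_policy)
  if (is.character(molecules)) molecules <- parse_smiles(molecules)
  counts <- table(unlist(lapply(molecules, function(m) m$atoms)))
  elems <- names(counts)
  if (length(elems) > max_atom_types - 1L) {
    stop(sprintf("%d distinct elements exceed the %d available atom-type slots",
                 length(elems), max_atom_types - 1L))
  }
  observed <- if (length(elems)) elems[order(-as.integer(counts), elems)]
              else character()
  pad <- setdiff(.element_table$symbol, observed)
  atom_types <- c("*", observed, pad)
  if (length(atom_types) < max_atom_types) {
    atom_types <- c(atom_types,
                    sprintf("unused%02d", seq_len(max_atom_types - length(atom_types))))
  }
  cat_vocabulary(atom_types[seq_len(max_atom_types)], default_bond_types(),
                 max_nodes)
}

#' Flattened dimensionality of the matrix representation
#'
#' `S + S*A_t + S*S*B_t`; 66900 for the default vocabulary.
#' @param vocab a [cat_vocabulary].
#' @return integer.
#' @export
flatten_dim <- function(vocab) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types); Bt <- length(vocab$bond_types)
  as.integer(S + S * At + S * S * Bt)
}

#' Serialize / restore a vocabulary as JSON
#' @param vocab a [cat_vocabulary].
#' @param path file path.
#' @return `vocab_to_json` returns the path invisibly; `vocab_from_json`
#'   returns a [cat_vocabulary].
#' @export
vocab_to_json <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname vocab_to_json
#' @export
vocab_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat_vocabulary(x$atom_types, x$bond_types, x$max_nodes)
}
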