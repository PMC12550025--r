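#' Convert decoder logits into a chemically valid molecule
#'
#' Implements the rule-based correction applied to decoded matrix triples:
#' the molecule size is read from the argmax of `T`, atom types from the
#' per-row argmax of `A` over occupied nodes, and candidate bonds (all
#' non-no-bond argmax pairs `i < j`) are added in descending order of their
#' probability. After each addition the two endpoint atoms are checked
#' against the element valence table; a violating bond is removed unless
#' adding a permitted formal charge (+1 on N/P/O, -1 on B; never on carbon)
#' legalizes it. Finalization demotes acyclic aromatic bonds to single,
#' removes unconnected carbon atoms, re-checks valences and round-trips the
#' structure through canonical SMILES; if that fails all aromatic bonds are
#' demoted to single and the round trip retried once.
#'
#' With `correction = FALSE` the raw argmax structure is returned
#' unrepaired (it may be chemically invalid).
#'
#' @param logits list with elements `T` (length `S`), `A` (`S x A_t`) and
#'   `B` (`S x S x B_t`): real-valued scores, probabilities, or a one-hot
#'   `catalyst_matrix`.
#' @param vocab the [cat_vocabulary] the logits are shaped against.
#' @param correction apply the valence-correcting repair (default `TRUE`).
#' @return list with `molecule` (a [cat_mol]; zero atoms when empty),
#'   `smiles` (canonical SMILES or `NA`), and `report` (a
#'   `reconstruction_report` with fields `proposed_bonds`, `rejected_bonds`,
#'   `charged_atoms_added`, `atoms_removed`, `sanitization_passed`,
#'   `empty_output`).
#' @export
reconstruct <- function(logits, vocab, correction = TRUE) {
  S <- vocab$max_nodes
  Bt <- length(vocab$bond_types)
  stopifnot(length(logits$T) == S, all(dim(logits$A) == c(S, length(vocab$atom_types))),
            all(dim(logits$B) == c(S, S, Bt)))
  rep0 <- list(proposed_bonds = 0L, rejected_bonds = 0L, charged_atoms_added = 0L,
               atoms_removed = 0L, sanitization_passed = FALSE, empty_output = TRUE)

  n <- which.max(logits$T) - 1L
  if (n == 0L) {
    return(list(molecule = cat_mol(character()), smiles = NA_character_,
                report = structure(rep0, class = "reconstruction_report")))
  }
  # atom assignment: per-row argmax; rows won by the no-atom channel drop out
  ai <- apply(logits$A[seq_len(n), , drop = FALSE], 1, which.max)
  keep <- which(ai != 1L)
  rep0$atoms_removed <- n - length(keep)
  if (!length(keep)) {
    return(list(molecule = cat_mol(character()), smiles = NA_character_,
                report = structure(rep0, class = "reconstruction_report")))
  }
  atoms <- vocab$atom_types[ai[keep]]
  remap <- match(seq_len(n), keep)

  cand <- .collect_bond_candidates(logits$B, n, keep, remap)
  rep0$proposed_bonds <- nrow(cand)

  if (!correction) {
    bonds <- if (nrow(cand)) data.frame(i = cand$i, j = cand$j, order = cand$channel - 1L)
             else empty_bonds()
    mol <- cat_mol(atoms, bonds)
    smi <- mols_to_smiles(list(mol))
    rep0$empty_output <- FALSE
    rep0$sanitization_passed <- valence_legal(mol) && !is.na(smi)
    return(list(molecule = mol, smiles = smi,
                report = structure(rep0, class = "reconstruction_report")))
  }

  res <- .assign_bonds_with_valence(atoms, cand)
  rep0$rejected_bonds <- res$rejected
  rep0$charged_atoms_added <- res$charged
  mol <- cat_mol(atoms, res$bonds, res$charges)

  mol <- .demote_acyclic_aromatic(mol)
  stripped <- strip_isolated_carbons(mol)
  rep0$atoms_removed <- rep0$atoms_removed + (mol_natoms(mol) - mol_natoms(stripped))
  mol <- stripped
  if (is_empty_mol(mol)) {
    return(list(molecule = mol, smiles = NA_character_,
                report = structure(rep0, class = "reconstruction_report")))
  }

  smi <- .finalize_smiles(mol)
  if (is.na(smi$smiles)) {
    rep0$empty_output <- TRUE
    return(list(molecule = cat_mol(character()), smiles = NA_character_,
                report = structure(rep0, class = "reconstruction_report")))
  }
  rep0$empty_output <- FALSE
  rep0$sanitization_passed <- TRUE
  list(molecule = smi$mol, smiles = smi$smiles,
       report = structure(rep0, class = "reconstruction_report"))
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(paste0("<reconstruction_report: %d proposed, %d rejected, ",
                     "%d charged, %d removed, sane=%s, empty=%s>\n"),
              x$proposed_bonds, x$rejected_bonds, x$charged_atoms_added,
              x$atoms_removed, x$sanitization_passed, x$empty_output))
  invisible(x)
}

# Candidate bonds: symmetric-averaged fiber, normalized to probabilities;
# argmax channel != no-bond becomes a candidate carrying that probability.
# Sorted by probability descending, ties broken lexicographically by
# (i, j, channel).
.collect_bond_candidates <- function(B, n, keep, remap) {
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (is.na(remap[i]) || is.na(remap[j])) next
        fib <- (B[i, j, ] + B[j, i, ]) / 2
        p <- .fiber_probs(fib)
        ch <- which.max(p)
        if (ch > 1L) {
          rows[[length(rows) + 1L]] <- c(remap[i], remap[j], ch, p[ch])
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(), j = integer(), channel = integer(),
                      prob = numeric()))
  }
  m <- do.call(rbind, rows)
  cand <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     channel = as.integer(m[, 3]), prob = m[, 4])
  cand[order(-cand$prob, cand$i, cand$j, cand$channel), , drop = FALSE]
}

# Normalize one fiber to probabilities: nonnegative fibers are scaled by
# their sum, anything else goes through a softmax.
.fiber_probs <- function(fib) {
  if (all(fib >= 0)) {
    s <- sum(fib)
    if (s > 0) return(fib / s)
  }
  e <- exp(fib - max(fib))
  e / sum(e)
}

# Greedy descending-probability assignment with valence checking and the
# permitted formal-charge repairs. Transactional per bond: charges added to
# legalize a bond are reverted when the bond is rejected anyway.
.assign_bonds_with_valence <- function(atoms, cand) {
  n <- length(atoms)
  charges <- integer(n)
  val <- numeric(n)
  rejected <- 0L
  acc <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]; ch <- cand$channel[r]
    bv <- bond_order_value(ch - 1L)
    fix <- .try_endpoint(atoms[i], charges[i], val[i] + bv)
    fix2 <- .try_endpoint(atoms[j], charges[j], val[j] + bv)
    if (fix$ok && fix2$ok) {
      charges[i] <- fix$charge; charges[j] <- fix2$charge
      val[i] <- val[i] + bv; val[j] <- val[j] + bv
      acc[[length(acc) + 1L]] <- c(i, j, ch - 1L)
    } else {
      rejected <- rejected + 1L
    }
  }
  bonds <- if (length(acc)) {
    m <- do.call(rbind, acc)
    data.frame(i = m[, 1], j = m[, 2], order = m[, 3])
  } else empty_bonds()
  list(bonds = bonds, charges = charges, rejected = rejected,
       charged = sum(charges != 0L))
}

# Is `newval` total bond order legal for this atom, possibly after adding a
# permitted formal charge? Carbon is never charged.
.try_endpoint <- function(sym, charge, newval) {
  if (newval <= max_valence(sym, charge) + 1e-9) {
    return(list(ok = TRUE, charge = charge))
  }
  if (charge == 0L) {
    tryc <- switch(sym, N = 1L, P = 1L, O = 1L, B = -1L, NULL)
    if (!is.null(tryc) && newval <= max_valence(sym, tryc) + 1e-9) {
      return(list(ok = TRUE, charge = tryc))
    }
  }
  list(ok = FALSE, charge = charge)
}

# Aromatic bonds that are not part of a cycle within the aromatic-bond
# subgraph cannot belong to an aromatic ring; demote them to single
# (demotion lowers bond-order sums, so valences stay legal).
.demote_acyclic_aromatic <- function(mol) {
  ar <- which(mol$bonds$order == 4L)
  if (!length(ar)) return(mol)
  for (e in ar) {
    sub <- mol$bonds[setdiff(which(mol$bonds$order == 4L), e), , drop = FALSE]
    if (!.connected_in_subgraph(mol$bonds$i[e], mol$bonds$j[e], sub,
                                mol_natoms(mol))) {
      mol$bonds$order[e] <- 1L
    }
  }
  mol
}

.connected_in_subgraph <- function(a, b, edges, n) {
  if (!nrow(edges)) return(FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[a] <- TRUE; queue <- a
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (w == b) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  FALSE
}

# Canonical-SMILES round trip with the aromatic fallback: on failure all
# aromatic bonds become single and the conversion is retried once.
.finalize_smiles <- function(mol) {
  smi <- mols_to_smiles(list(mol))
  if (!is.na(smi) && !is.na(canonical_smiles(smi))) {
    return(list(mol = mol, smiles = smi))
  }
  if (any(mol$bonds$order == 4L)) {
    mol$bonds$order[mol$bonds$order == 4L] <- 1L
    smi <- mols_to_smiles(list(mol))
    if (!is.na(smi) && !is.na(canonical_smiles(smi))) {
      return(list(mol = mol, smiles = smi))
    }
  }
  list(mol = mol, smiles = NA_character_)
}

#' Remove unconnected carbon atoms
#'
#' Deletes fragments that consist of exactly one uncharged carbon atom;
#' every other fragment (single heteroatoms, metals, charged carbons,
#' multi-atom fragments) is retained.
#'
#' @param molecule a [cat_mol].
#' @return a [cat_mol] without isolated neutral carbons (possibly empty).
#' @export
strip_isolated_carbons <- function(molecule) {
  if (is_empty_mol(molecule)) return(molecule)
  frags <- mol_fragments(molecule)
  keep <- vapply(frags, function(f) {
    !(mol_natoms(f) == 1L && f$atoms[1] == "C" && f$charges[1] == 0L)
  }, logical(1))
  frags <- frags[keep]
  if (!length(frags)) return(cat_mol(character()))
  .bind_fragments(frags)
}

.bind_fragments <- function(frags) {
  atoms <- character(); charges <- integer(); bonds <- empty_bonds()
  off <- 0L
  for (f in frags) {
    atoms <- c(atoms, f$atoms); charges <- c(charges, f$charges)
    if (nrow(f$bonds)) {
      b <- f$bonds; b$i <- b$i + off; b$j <- b$j + off
      bonds <- rbind(bonds, b)
    }
    off <- off + mol_natoms(f)
  }
  cat_mol(atoms, bonds, charges)
}
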