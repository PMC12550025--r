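#' Lightweight molecular graph
#'
#' `cat_mol` is the package's internal molecular graph: element symbols,
#' formal charges, and an edge table with integer bond categories
#' (1 = single, 2 = double, 3 = triple, 4 = aromatic, 5 = other/coordination).
#' Hydrogens are implicit; SMILES input is parsed (and output canonicalized)
#' through OpenBabel.
#'
#' @param atoms character vector of element symbols.
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom
#'   indices, `i < j`) and `order` in 1..5; one row per bond.
#' @param charges integer vector of formal charges (default all 0).
#' @return an object of class `cat_mol`.
#' @export
cat_mol <- function(atoms, bonds = empty_bonds(), charges = integer(length(atoms))) {
  atoms <- as.character(atoms)
  charges <- as.integer(charges)
  stopifnot(length(charges) == length(atoms))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$j > length(atoms)) || any(bonds$i < 1L)) {
      stop("bond endpoint outside atom range")
    }
    if (any(bonds$order < 1L | bonds$order > 5L)) stop("bond order must be in 1..5")
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(atoms = atoms, charges = charges,
                 bonds = bonds[, c("i", "j", "order"), drop = FALSE]),
            class = "cat_mol")
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = integer())
}

#' @export
print.cat_mol <- function(x, ...) {
  cat(sprintf("<cat_mol: %d atoms, %d bonds>\n", length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

mol_natoms <- function(mol) length(mol$atoms)

is_empty_mol <- function(mol) length(mol$atoms) == 0L

# Numeric bond-order value used in valence accounting.
bond_order_value <- function(order) {
  c(1, 2, 3, 1.5, 1)[order]
}

# Connected components by BFS; returns integer component label per atom.
mol_components <- function(mol) {
  n <- mol_natoms(mol)
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

# Split a multi-fragment molecule into a list of single-fragment cat_mol,
# fragments ordered by their lowest original atom index.
mol_fragments <- function(mol) {
  comp <- mol_components(mol)
  if (length(comp) == 0L) return(list())
  lapply(seq_len(max(comp)), function(k) {
    keep <- which(comp == k)
    remap <- match(seq_along(comp), keep)
    b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
    if (nrow(b)) { b$i <- remap[b$i]; b$j <- remap[b$j] }
    cat_mol(mol$atoms[keep], b, mol$charges[keep])
  })
}

# Total bond order carried by each atom (aromatic counted 1.5).
mol_valences <- function(mol) {
  v <- numeric(mol_natoms(mol))
  if (nrow(mol$bonds)) {
    val <- bond_order_value(mol$bonds$order)
    for (r in seq_len(nrow(mol$bonds))) {
      v[mol$bonds$i[r]] <- v[mol$bonds$i[r]] + val[r]
      v[mol$bonds$j[r]] <- v[mol$bonds$j[r]] + val[r]
    }
  }
  v
}

#' Molecular weight of a molecular graph
#'
#' Monoisotopic-free standard atomic weights with implicit hydrogens filled
#' to each main-group atom's default valence (charge-adjusted), matching the
#' usual SMILES implicit-hydrogen convention.
#'
#' @param mol a [cat_mol] object.
#' @return molecular weight in g/mol.
#' @export
mol_mw <- function(mol) {
  if (is_empty_mol(mol)) return(0)
  heavy <- sum(element_mass(mol$atoms))
  heavy + 1.008 * sum(mol_implicit_h(mol))
}

# Implicit hydrogen count per atom: fill up to the smallest allowed valence
# that accommodates the current bond-order sum; metals get none.
mol_implicit_h <- function(mol) {
  v <- mol_valences(mol)
  vapply(seq_along(mol$atoms), function(a) {
    sym <- mol$atoms[a]
    if (is_metal(sym) || is.null(.valence_sets[[sym]])) return(0)
    allowed <- .valence_sets[[sym]] + .charge_capacity_shift(sym, mol$charges[a])
    allowed <- allowed[allowed >= v[a] - 1e-9]
    if (!length(allowed)) return(0)
    max(0, floor(min(allowed) - v[a] + 1e-9))
  }, numeric(1))
}

.charge_capacity_shift <- function(sym, charge) {
  if (charge == 0) return(0)
  if (sym %in% c("N", "P") && charge > 0) return(charge)
  if (sym %in% c("O", "S") && charge > 0) return(charge)
  if (sym %in% c("O", "S", "N") && charge < 0) return(charge)
  if (sym == "B" && charge < 0) return(-charge)
  0
}

#' Number of atoms whose element is not carbon or hydrogen
#' @param mol a [cat_mol] object.
#' @return heteroatom count.
#' @export
mol_heteroatoms <- function(mol) sum(!mol$atoms %in% c("C", "H"))

# Cyclomatic number (independent rings) per component, summed.
mol_ring_count <- function(mol) {
  n <- mol_natoms(mol)
  if (n == 0L) return(0L)
  ncomp <- max(mol_components(mol))
  as.integer(nrow(mol$bonds) - n + ncomp)
}

## ---- molfile I/O through OpenBabel -------------------------------------

# V2000 molfile text for one cat_mol. Aromatic bonds are written as type 4,
# "other/coordination" bonds as single. Charges go into M CHG lines.
mol_to_molfile <- function(mol, title = "mol") {
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  lines <- c(title, "  catvae", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  if (n) {
    lines <- c(lines, sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      mol$atoms))
  }
  if (nb) {
    btype <- ifelse(mol$bonds$order == 5L, 1L, mol$bonds$order)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$i, mol$bonds$j, btype))
  }
  chg <- which(mol$charges != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, mol$charges[grp]),
                                      collapse = "")))
    }
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

# Parse V2000 molfile text (possibly several records separated by $$$$)
# into a list of cat_mol. Tolerant of the layout OpenBabel emits.
molfile_to_mols <- function(text) {
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, .parse_one_molfile)
}

.parse_one_molfile <- function(rec) {
  lines <- strsplit(rec, "\n")[[1]]
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- character(n); charges <- integer(n)
  for (a in seq_len(n)) {
    ln <- lines[4 + a]
    atoms[a] <- trimws(substr(ln, 31, 34))
    code <- suppressWarnings(as.integer(trimws(substr(ln, 37, 39))))
    if (!is.na(code) && code > 0L) {
      charges[a] <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[code]
    }
  }
  bonds <- empty_bonds()
  if (nb > 0L) {
    bl <- lines[(4 + n + 1):(4 + n + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
    bonds$order[bonds$order > 4L] <- 1L
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- flds[1]
    for (p in seq_len(k)) charges[flds[2 * p]] <- flds[2 * p + 1]
  }
  cat_mol(atoms, bonds, charges)
}

## ---- SMILES round trips -------------------------------------------------

# Run an OpenBabel conversion keeping per-record alignment via numeric
# titles. A parse error can abort the remainder of a batch, so records
# still missing after the batch pass are retried one by one; entries that
# genuinely fail come back as NA.
.ob_convert_aligned <- function(from, to, payloads, titles) {
  parse_out <- function(out, res) {
    for (ln in strsplit(out, "\n")[[1]]) {
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) >= 2) {
        idx <- match(trimws(parts[2]), titles)
        if (!is.na(idx)) res[idx] <- trimws(parts[1])
      }
    }
    res
  }
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, paste(payloads, collapse = "")),
    error = function(e) ""
  )
  res <- parse_out(out, rep(NA_character_, length(titles)))
  for (k in which(is.na(res))) {
    out1 <- tryCatch(ChemmineOB::convertFormat(from, to, payloads[k]),
                     error = function(e) "")
    res <- parse_out(out1, res)
  }
  res
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings through OpenBabel. Unparseable entries
#' come back as `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  res <- rep(NA_character_, length(smiles))
  usable <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (!length(usable)) return(res)
  titles <- paste0("t", usable)
  payload <- paste0(smiles[usable], " ", titles, "\n")
  res[usable] <- .ob_convert_aligned("SMI", "CAN", payload, titles)
  res
}

#' Canonical SMILES of molecular graphs
#'
#' @param mols a list of [cat_mol] objects (empty molecules give `NA`).
#' @return character vector of canonical SMILES.
#' @export
mols_to_smiles <- function(mols) {
  if (!length(mols)) return(character())
  res <- rep(NA_character_, length(mols))
  nonempty <- which(vapply(mols, Negate(is_empty_mol), logical(1)))
  if (!length(nonempty)) return(res)
  payload <- vapply(seq_along(nonempty), function(k) {
    mol_to_molfile(mols[[nonempty[k]]], title = paste0("t", k))
  }, character(1))
  res[nonempty] <- .ob_convert_aligned("SDF", "CAN", payload,
                                       paste0("t", seq_along(nonempty)))
  res
}

#' Parse SMILES into molecular graphs
#'
#' SMILES are converted to molfile blocks by OpenBabel (which kekulizes
#' aromatic systems) and read into [cat_mol] graphs with formal charges.
#'
#' @param smiles character vector of SMILES.
#' @return a list of [cat_mol]; unparseable entries are `NULL`.
#' @export
parse_smiles <- function(smiles) {
  out <- vector("list", length(smiles))
  usable <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (!length(usable)) return(out)
  titles <- as.character(usable)
  payload <- paste0(smiles[usable], " t", titles, "\n")
  fill_from <- function(sdf, out) {
    recs <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
    recs <- recs[nzchar(trimws(recs))]
    for (rec in recs) {
      title <- trimws(strsplit(rec, "\n")[[1]][1])
      idx <- suppressWarnings(as.integer(sub("^t", "", title)))
      if (!is.na(idx) && idx >= 1L && idx <= length(out)) {
        out[[idx]] <- tryCatch(.parse_one_molfile(rec),
                               error = function(e) NULL)
      }
    }
    out
  }
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste(payload, collapse = "")),
    error = function(e) ""
  )
  out <- fill_from(sdf, out)
  # a parse error can truncate the batch: retry missing entries singly
  for (k in usable[vapply(usable, function(i) is.null(out[[i]]), logical(1))]) {
    one <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF",
                                paste0(smiles[k], " t", k, "\n")),
      error = function(e) ""
    )
    out <- fill_from(one, out)
  }
  out
}

#' Check chemical sanity of a molecular graph
#'
#' A molecule is sane when every atom's total bond order is within its
#' element's allowed valence at its formal charge (metals are treated
#' permissively as coordination centres) and the graph survives a SMILES
#' round trip.
#'
#' @param mol a [cat_mol] object.
#' @param roundtrip also require a successful OpenBabel SMILES round trip.
#' @return `TRUE`/`FALSE`.
#' @export
sanitize_mol <- function(mol, roundtrip = TRUE) {
  if (is_empty_mol(mol)) return(FALSE)
  if (!valence_legal(mol)) return(FALSE)
  if (!roundtrip) return(TRUE)
  smi <- mols_to_smiles(list(mol))
  !is.na(smi) && nzchar(smi)
}

#' Check valence legality of a molecular graph
#'
#' `TRUE` when no atom's total bond order (aromatic counted 1.5) exceeds
#' its element's allowed valence at its formal charge.
#'
#' @param mol a [cat_mol] object.
#' @return `TRUE`/`FALSE`.
#' @export
valence_legal <- function(mol) {
  v <- mol_valences(mol)
  all(vapply(seq_along(mol$atoms), function(a) {
    v[a] <= max_valence(mol$atoms[a], mol$charges[a]) + 1e-9
  }, logical(1)))
}

#' Read molecules from an SDF file
#'
#' Parses a V2000 SD file into molecular graphs (records that fail to
#' parse are dropped with a warning).
#'
#' @param path SDF file path.
#' @return list of [cat_mol] objects.
#' @export
read_sdf <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- lapply(recs, function(rec) {
    tryCatch(.parse_one_molfile(rec), error = function(e) NULL)
  })
  bad <- vapply(out, is.null, logical(1))
  if (any(bad)) warning(sum(bad), " SDF record(s) failed to parse")
  out[!bad]
}

#' Write molecules to an SDF file
#'
#' @param mols a [cat_mol] or list of them (empty molecules are skipped).
#' @param path output path.
#' @param titles optional record titles.
#' @return invisibly, the path.
#' @export
write_sdf <- function(mols, path, titles = NULL) {
  if (inherits(mols, "cat_mol")) mols <- list(mols)
  if (is.null(titles)) titles <- paste0("mol_", seq_along(mols))
  keep <- which(!vapply(mols, is_empty_mol, logical(1)))
  blocks <- vapply(keep, function(k) {
    mol_to_molfile(mols[[k]], title = titles[k])
  }, character(1))
  writeLines(paste(blocks, collapse = ""), path, sep = "")
  invisible(path)
}
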