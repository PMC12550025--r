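#' Specification for synthetic desk-scale reaction fixtures
#'
#' The generator emulates small organic/organometallic reaction records:
#' random valence-legal molecules grown atom-by-atom from an element
#' palette (with occasional double bonds and ring closures), catalysts that
#' are optionally multi-fragment with one lone metal atom, positive
#' reaction times, and a target produced by a declared deterministic
#' function of molecular descriptors plus Gaussian noise:
#' `100 * sigmoid(w . (d - d0) + b) + N(0, sigma)` clipped to `[0, 100]`,
#' where `d = (catalyst MW / 100, heteroatom count, ring count, log time)`.
#' The coefficients `w`, `b` are drawn once from the seed and recorded in
#' the output, so parameter-recovery experiments have a known truth.
#'
#' @param n_records number of reaction records.
#' @param seed integer seed; identical specs give identical datasets.
#' @param max_atoms atom budget per generated molecule (default 12).
#' @param elements palette of heavy elements for organic fragments.
#' @param metal metal used for multi-fragment catalysts.
#' @param multi_fragment_fraction fraction of catalysts built as
#'   ligand--metal(--ligand) multi-fragment complexes.
#' @param noise_sigma Gaussian noise on the target, in target units.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_records = 200L, seed = 1L, max_atoms = 12L,
                         elements = c("C", "C", "C", "C", "N", "O", "P", "S",
                                      "F", "Cl"),
                         metal = "Pd", multi_fragment_fraction = 0.2,
                         noise_sigma = 5) {
  if (max_atoms < 1L) stop("max_atoms must be at least 1")
  stopifnot(n_records >= 1L, multi_fragment_fraction >= 0,
            multi_fragment_fraction <= 1, noise_sigma >= 0)
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 max_atoms = as.integer(max_atoms), elements = elements,
                 metal = metal,
                 multi_fragment_fraction = multi_fragment_fraction,
                 noise_sigma = noise_sigma),
            class = "fixture_spec")
}

# Free-valence budget used while growing fixture molecules.
.grow_valence <- c(C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1, Br = 1,
                   B = 3, Si = 4)

# Grow one random valence-legal molecule of at most n_atoms heavy atoms.
.grow_molecule <- function(rng, n_atoms, elements) {
  pick <- function(k) elements[rng$sample(length(elements), k, replace = TRUE)]
  start <- pick(1)
  guard <- 0L
  while (n_atoms > 1L && .grow_valence[[start]] < 2 && guard < 20L) {
    start <- pick(1); guard <- guard + 1L
  }
  atoms <- start
  free <- .grow_valence[[start]]
  bonds <- empty_bonds()
  while (length(atoms) < n_atoms) {
    host <- which(free >= 1)
    if (!length(host)) break
    h <- host[rng$sample(length(host), 1)]
    el <- pick(1)
    atoms <- c(atoms, el)
    a <- length(atoms)
    free <- c(free, .grow_valence[[el]])
    order <- 1L
    if (free[h] >= 2 && free[a] >= 2 && rng$runif(1) < 0.15) order <- 2L
    bonds <- rbind(bonds, data.frame(i = h, j = a, order = order))
    free[h] <- free[h] - order; free[a] <- free[a] - order
  }
  # occasional ring closure between non-adjacent atoms with spare valence
  if (length(atoms) >= 4L && rng$runif(1) < 0.35) {
    open <- which(free >= 1)
    if (length(open) >= 2L) {
      pr <- open[rng$sample(length(open), 2)]
      adjacent <- any(bonds$i == min(pr) & bonds$j == max(pr))
      if (!adjacent) {
        bonds <- rbind(bonds, data.frame(i = pr[1], j = pr[2], order = 1L))
      }
    }
  }
  cat_mol(atoms, bonds)
}

.fixture_catalyst <- function(rng, spec) {
  lig <- .grow_molecule(rng, 3L + rng$sample(max(1L, spec$max_atoms - 3L), 1),
                        spec$elements)
  if (rng$runif(1) < spec$multi_fragment_fraction) {
    frags <- list(lig, cat_mol(spec$metal))
    if (rng$runif(1) < 0.5) {
      frags <- c(frags, list(.grow_molecule(
        rng, 3L + rng$sample(max(1L, spec$max_atoms - 3L), 1), spec$elements)))
    }
    .bind_fragments(frags)
  } else lig
}

#' Generate a synthetic reaction dataset
#'
#' @param spec a [fixture_spec].
#' @return a reaction-record data frame (see [parse_reaction_table()])
#'   carrying a `target_function` attribute (list with `w`, `b`, `d0`,
#'   `noise_sigma`) and the `spec` itself as an attribute.
#' @export
make_reaction_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- .seeded_rng(spec$seed)
  w <- round(rng$rnorm(4, 0, 1) * c(0.8, 0.5, 0.6, 0.7), 4)
  b <- round(rng$rnorm(1, 0, 0.3), 4)
  d0 <- c(1.0, 2.0, 1.0, 0.0)

  rows <- vector("list", spec$n_records)
  for (r in seq_len(spec$n_records)) {
    n_reac <- 1L + (rng$runif(1) < 0.5)
    reac <- lapply(seq_len(n_reac), function(k) {
      .grow_molecule(rng, 2L + rng$sample(max(1L, spec$max_atoms - 2L), 1),
                     spec$elements)
    })
    prod <- .grow_molecule(rng, 2L + rng$sample(max(1L, spec$max_atoms - 2L), 1),
                           spec$elements)
    regs <- if (rng$runif(1) < 0.5) {
      list(.grow_molecule(rng, 1L + rng$sample(max(1L, spec$max_atoms - 1L), 1),
                          spec$elements))
    } else list()
    cata <- .fixture_catalyst(rng, spec)
    tm <- round(exp(rng$rnorm(1, 0, 0.6)), 3)
    d <- c(mol_mw(cata) / 100, mol_heteroatoms(cata), mol_ring_count(cata),
           log(tm))
    y <- 100 / (1 + exp(-(sum(w * (d - d0)) + b)))
    if (spec$noise_sigma > 0) y <- y + rng$rnorm(1, 0, spec$noise_sigma)
    y <- min(max(y, 0), 100)
    smis <- mols_to_smiles(c(reac, regs, list(prod, cata)))
    rows[[r]] <- new_reaction_record(
      reactants = canonical_smiles(smis[seq_len(n_reac)]),
      product = smis[n_reac + length(regs) + 1L],
      catalyst = smis[n_reac + length(regs) + 2L],
      reagents = if (length(regs)) smis[n_reac + 1L] else character(),
      time_h = tm, target = y, target_kind = "yield",
      catalyst_mw = mol_mw(cata), catalyst_atom_count = mol_natoms(cata))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target_function") <- list(w = w, b = b, d0 = d0,
                                       noise_sigma = spec$noise_sigma)
  attr(out, "spec") <- spec
  out
}

#' Catalyst/time descriptors entering the fixture target function
#'
#' @param records a reaction-record data frame.
#' @return matrix with columns `mw100` (catalyst MW / 100), `hetero`
#'   (catalyst heteroatom count), `rings` (catalyst ring count), `logt`
#'   (log reaction time).
#' @export
reaction_descriptors <- function(records) {
  mols <- parse_smiles(records$catalyst)
  t(vapply(seq_len(nrow(records)), function(r) {
    m <- mols[[r]]
    c(mw100 = records$catalyst_mw[r] / 100,
      hetero = if (is.null(m)) 0 else mol_heteroatoms(m),
      rings = if (is.null(m)) 0 else mol_ring_count(m),
      logt = log(records$time_h[r]))
  }, numeric(4)))
}

#' Fixture dataset with planted duplicates and an outlier
#'
#' Builds a dataset in which `k_groups` records are duplicated with
#' symmetric target jitter (so the post-deduplication mean is known) and
#' one catalyst-MW outlier (a long carbon chain) is planted for the IQR
#' stage. A `manifest` attribute records the expected curation outcome.
#'
#' @param spec a [fixture_spec].
#' @param k_groups number of planted duplicate groups
#'   (`<= n_records / 2`).
#' @return records with planted structure; attribute `manifest` is a list
#'   with `group_keys`, `expected_means`, `outlier_catalyst`,
#'   `n_after_dedup`.
#' @export
make_planted_duplicates <- function(spec, k_groups = 5L) {
  stopifnot(k_groups <= spec$n_records / 2)
  base <- make_reaction_dataset(spec)
  rng <- .seeded_rng(spec$seed + 7777L)
  pick <- rng$sample(nrow(base), k_groups)
  dup <- base[pick, , drop = FALSE]
  jit <- pmin(base$target[pick], 100 - base$target[pick], 5)
  base$target[pick] <- base$target[pick] + jit
  dup$target <- dup$target - jit

  chain <- cat_mol(rep("C", 60L),
                   data.frame(i = 1:59, j = 2:60, order = 1L))
  outlier <- new_reaction_record(
    reactants = base$reactants[[1]], product = base$product[1],
    catalyst = mols_to_smiles(list(chain)), reagents = character(),
    time_h = 1, target = 50, target_kind = "yield",
    catalyst_mw = mol_mw(chain), catalyst_atom_count = 60L)

  out <- rbind(base, dup, outlier)
  rownames(out) <- NULL
  keys <- .record_keys(out)
  manifest <- list(
    group_keys = keys[pick],
    expected_means = (base$target[pick] + dup$target) / 2,
    outlier_catalyst = outlier$catalyst,
    n_after_dedup = nrow(base) + 1L
  )
  attr(out, "manifest") <- manifest
  attr(out, "target_function") <- attr(base, "target_function")
  out
}
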