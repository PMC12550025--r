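#' Latent sampling scheme
#'
#' Three schemes steer catalyst generation: `random_latent_random_condition`
#' draws latents uniformly inside the integer-bounded box of the training
#' latent means and pairs them with a random training condition;
#' `around_sample_random_condition` perturbs an anchor catalyst's latent
#' mean with Gaussian noise under a random training condition;
#' `around_sample_sample_condition` uses the anchor's own condition.
#'
#' @param kind one of the three scheme names.
#' @param noise_scale Gaussian noise scale for around-sample schemes.
#' @param bounds_mode constrain random draws to the training box.
#' @param seed integer seed.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("random_latent_random_condition",
                                     "around_sample_random_condition",
                                     "around_sample_sample_condition"),
                            noise_scale = 0.5, bounds_mode = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(noise_scale >= 0)
  structure(list(kind = kind, noise_scale = noise_scale,
                 bounds_mode = bounds_mode, seed = as.integer(seed)),
            class = "sampling_scheme")
}

#' Latent means and conditions of training records
#'
#' Precomputes what the sampling schemes and optimizers need: the latent
#' mean and condition vector of every training record.
#'
#' @param model a [catvae] model.
#' @param records training reaction records.
#' @return list with `means` (`n x D`), `cond` (`n x D_c`), `records`.
#' @export
model_latents <- function(model, records) {
  mats <- lapply(records$catalyst, encode_catalyst_smiles, model = model)
  cond <- embed_condition(model, records)
  lat <- cvae_encode(model, embed_catalyst(model, mats), cond, sample = FALSE)
  list(means = lat$mean, cond = cond, records = records)
}

# Per-dimension integer-bounded box of training latent means.
latent_box <- function(means) {
  rbind(lower = floor(apply(means, 2, min)),
        upper = ceiling(apply(means, 2, max)))
}

#' Draw one latent/condition pair under a sampling scheme
#'
#' @param scheme a [sampling_scheme].
#' @param model a [catvae] model.
#' @param training output of [model_latents()] on the training set.
#' @param anchor index (into `training$records`) of the anchor catalyst;
#'   required by around-sample schemes.
#' @param rng internal RNG (defaults to a fresh one from the scheme seed).
#' @return list with `z` (length D), `cond` (length D_c), `cond_index`.
#' @export
sample_latent <- function(scheme, model, training, anchor = NULL, rng = NULL) {
  rng <- rng %||% .seeded_rng(scheme$seed)
  D <- ncol(training$means)
  if (scheme$kind == "random_latent_random_condition") {
    box <- latent_box(training$means)
    z <- box[1, ] + rng$runif(D) * (box[2, ] - box[1, ])
    ci <- rng$sample(nrow(training$cond), 1)
    return(list(z = z, cond = training$cond[ci, ], cond_index = ci))
  }
  if (is.null(anchor)) stop("around-sample schemes require an anchor index")
  z <- training$means[anchor, ] + rng$rnorm(D, 0, scheme$noise_scale)
  ci <- if (scheme$kind == "around_sample_sample_condition") anchor
        else rng$sample(nrow(training$cond), 1)
  list(z = z, cond = training$cond[ci, ], cond_index = ci)
}

#' Generate catalysts under a sampling scheme
#'
#' Draws `n` latent/condition pairs, decodes them, and reconstructs
#' molecules (with or without the valence-correcting post-processing).
#' Empty outputs are retained as invalid entries (`NA` SMILES).
#'
#' @param n number of decode attempts.
#' @param scheme a [sampling_scheme].
#' @param model a [catvae] model.
#' @param training output of [model_latents()] on the training set.
#' @param anchor anchor record index for around-sample schemes (a random
#'   training record per draw when `NULL` under an around-sample scheme).
#' @param post_processing apply reconstruction correction (default TRUE).
#' @return list with `smiles` (length `n`, `NA` for empty/invalid),
#'   `molecules`, `reports`, `latents`.
#' @export
generate <- function(n, scheme, model, training, anchor = NULL,
                     post_processing = TRUE) {
  if (n == 0L) {
    return(list(smiles = character(), molecules = list(), reports = list(),
                latents = NULL))
  }
  rng <- .seeded_rng(scheme$seed)
  around <- scheme$kind != "random_latent_random_condition"
  Z <- matrix(0, n, ncol(training$means))
  C <- matrix(0, n, ncol(training$cond))
  for (i in seq_len(n)) {
    anc <- if (around) anchor %||% rng$sample(nrow(training$means), 1) else NULL
    d <- sample_latent(scheme, model, training, anchor = anc, rng = rng)
    Z[i, ] <- d$z; C[i, ] <- d$cond
  }
  logits <- cvae_decode(model, Z, C)
  recs <- lapply(logits, reconstruct, vocab = model$vocab,
                 correction = post_processing)
  list(smiles = vapply(recs, function(r) r$smiles, character(1)),
       molecules = lapply(recs, `[[`, "molecule"),
       reports = lapply(recs, `[[`, "report"),
       latents = Z)
}

#' Score a generated set against a reference set
#'
#' Computes the standard generation metrics, all as fractions of the
#' generated set size so the chain `novel <= unique <= valid` always
#' holds: Valid (chemically sane molecules), Unique (distinct canonical
#' structures among the valid), Novel (distinct valid structures absent
#' from the training set), IntDiv (mean pairwise Tanimoto distance among
#' the distinct valid structures), SNN (mean over valid molecules of the
#' maximum Tanimoto similarity to any training molecule), and Valid(Task)
#' (fraction passing the task rule). Distances use 2048-bit ECFP4.
#'
#' @param generated character SMILES (`NA` = failed decode).
#' @param training_set character SMILES of the reference set.
#' @param task_rule optional rule name (see [task_validity()]) or a
#'   predicate function on a [cat_mol].
#' @param fcd_fn optional plugin: a function
#'   (generated_smiles, training_smiles) -> numeric, reported as `fcd`.
#' @return an object of class `generation_report`.
#' @export
evaluate_generation <- function(generated, training_set, task_rule = NULL,
                                fcd_fn = NULL) {
  stopifnot(length(training_set) >= 1)
  n <- length(generated)
  mols <- parse_smiles(ifelse(is.na(generated), "", generated))
  valid_mask <- vapply(seq_len(n), function(i) {
    !is.na(generated[i]) && !is.null(mols[[i]]) &&
      mol_natoms(mols[[i]]) > 0 && valence_legal(mols[[i]])
  }, logical(1))
  vsmi <- canonical_smiles(generated[valid_mask])
  valid_mask[valid_mask][is.na(vsmi)] <- FALSE
  vsmi <- vsmi[!is.na(vsmi)]
  tcan <- unique(canonical_smiles(training_set))
  tcan <- tcan[!is.na(tcan)]
  usmi <- unique(vsmi)
  nsmi <- setdiff(usmi, tcan)

  intdiv <- 0
  if (length(usmi) >= 2) {
    fp <- ecfp4_fingerprint(usmi)
    sim <- tanimoto_similarity(fp, fp)
    intdiv <- mean(1 - sim[upper.tri(sim)])
  }
  snn <- 0
  if (length(vsmi) >= 1) {
    fpg <- ecfp4_fingerprint(vsmi)
    fpt <- ecfp4_fingerprint(tcan)
    snn <- mean(apply(tanimoto_similarity(fpg, fpt), 1, max))
  }
  vtask <- NA_real_
  if (!is.null(task_rule)) {
    pass <- vapply(seq_len(n), function(i) {
      valid_mask[i] && task_validity(mols[[i]], task_rule)
    }, logical(1))
    vtask <- mean(pass)
  }
  rep <- list(n_requested = n, n_decoded = sum(!is.na(generated)),
              valid = sum(valid_mask) / n,
              valid_task = vtask,
              unique = length(usmi) / n,
              novel = length(nsmi) / n,
              intdiv = intdiv, snn = snn)
  if (!is.null(fcd_fn)) rep$fcd <- fcd_fn(generated, training_set)
  structure(rep, class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf(paste0("<generation_report: n=%d valid=%.3f unique=%.3f ",
                     "novel=%.3f intdiv=%.3f snn=%.3f%s>\n"),
              x$n_requested, x$valid, x$unique, x$novel, x$intdiv, x$snn,
              if (!is.na(x$valid_task %||% NA)) sprintf(" valid_task=%.3f", x$valid_task)
              else ""))
  invisible(x)
}

## ---- task-specific validity --------------------------------------------

.task_rules <- new.env(parent = emptyenv())

#' Task-specific validity predicates
#'
#' Built-in rules: `"single_fragment"` (the catalyst is one connected
#' molecule), `"pd_acetate"` (the fragment multiset contains a palladium
#' acetate complex: a Pd centre plus two acetate groups, as fragments or
#' covalently bound), and `"three_fragment_metal"` (exactly three
#' fragments of which exactly one is a lone metal atom — the L1-M-L2
#' motif). Further rules can be added with [register_task_rule()].
#'
#' @param molecule a [cat_mol] (or single SMILES).
#' @param rule rule name or predicate function.
#' @return `TRUE`/`FALSE`.
#' @export
task_validity <- function(molecule, rule) {
  if (is.character(molecule)) {
    molecule <- parse_smiles(molecule)[[1]]
    if (is.null(molecule)) return(FALSE)
  }
  if (is.function(rule)) return(isTRUE(rule(molecule)))
  fn <- .task_rules[[rule]]
  if (is.null(fn)) stop("unknown task rule: ", rule)
  isTRUE(fn(molecule))
}

#' Register a custom task-validity rule
#' @param name rule name.
#' @param fn predicate: function([cat_mol]) -> logical.
#' @return invisibly, the name.
#' @export
register_task_rule <- function(name, fn) {
  stopifnot(is.function(fn))
  .task_rules[[name]] <- fn
  invisible(name)
}

.init_task_rules <- function() {
  .task_rules[["single_fragment"]] <- function(mol) {
    mol_natoms(mol) > 0 && max(mol_components(mol)) == 1L
  }
  .task_rules[["pd_acetate"]] <- function(mol) {
    frags <- mol_fragments(mol)
    if (!any(vapply(frags, function(f) any(f$atoms == "Pd"), logical(1)))) {
      return(FALSE)
    }
    smis <- mols_to_smiles(frags)
    acet <- canonical_smiles(c("CC(=O)[O-]", "CC(=O)O"))
    n_acetate <- sum(smis %in% acet, na.rm = TRUE)
    if (n_acetate >= 2) return(TRUE)
    # covalently bound variant: a Pd with two O neighbours each part of
    # a C(=O)O acetate motif
    any(vapply(frags, .has_bound_diacetate_pd, logical(1)))
  }
  .task_rules[["three_fragment_metal"]] <- function(mol) {
    frags <- mol_fragments(mol)
    if (length(frags) != 3L) return(FALSE)
    lone_metal <- vapply(frags, function(f) {
      mol_natoms(f) == 1L && is_metal(f$atoms[1])
    }, logical(1))
    sum(lone_metal) == 1L
  }
}

.has_bound_diacetate_pd <- function(f) {
  pd <- which(f$atoms == "Pd")
  if (!length(pd)) return(FALSE)
  for (p in pd) {
    nb <- c(f$bonds$j[f$bonds$i == p], f$bonds$i[f$bonds$j == p])
    o_nb <- nb[f$atoms[nb] == "O"]
    if (length(o_nb) >= 2) {
      good <- vapply(o_nb, function(o) {
        cb <- c(f$bonds$j[f$bonds$i == o], f$bonds$i[f$bonds$j == o])
        any(f$atoms[setdiff(cb, p)] == "C")
      }, logical(1))
      if (sum(good) >= 2) return(TRUE)
    }
  }
  FALSE
}

## ---- ligand filtering ---------------------------------------------------

#' Phosphine/amine ligand filter
#'
#' Chemistry-aware screen for metal-binding ligands: the molecule must
#' contain nitrogen or phosphorus; every phosphorus must carry exactly
#' three covalent bonds (metal-binding phosphines are trivalent); no P-H
#' bond may be present (too reactive to serve as a ligand); and no
#' phosphorus may sit in a three-membered ring (synthetically
#' challenging).
#'
#' @param molecule a [cat_mol] or single SMILES.
#' @param ruleset which rules to apply (default: all four).
#' @return list with `pass` (logical) and `violations` (character vector
#'   drawn from `no_N_or_P`, `P_not_three_bonds`, `P_H_bond`,
#'   `P_in_three_ring`).
#' @export
ligand_filter <- function(molecule,
                          ruleset = c("no_N_or_P", "P_not_three_bonds",
                                      "P_H_bond", "P_in_three_ring")) {
  if (is.character(molecule)) {
    molecule <- parse_smiles(molecule)[[1]]
    if (is.null(molecule)) {
      return(list(pass = FALSE, violations = "unparseable"))
    }
  }
  v <- character()
  pidx <- which(molecule$atoms == "P")
  if ("no_N_or_P" %in% ruleset &&
      !any(molecule$atoms %in% c("N", "P"))) {
    v <- c(v, "no_N_or_P")
  }
  if (length(pidx)) {
    deg <- vapply(pidx, function(p) {
      sum(molecule$bonds$i == p | molecule$bonds$j == p)
    }, integer(1))
    imph <- mol_implicit_h(molecule)[pidx]
    expH <- vapply(pidx, function(p) {
      nb <- c(molecule$bonds$j[molecule$bonds$i == p],
              molecule$bonds$i[molecule$bonds$j == p])
      any(molecule$atoms[nb] == "H")
    }, logical(1))
    if ("P_not_three_bonds" %in% ruleset && any(deg != 3L)) {
      v <- c(v, "P_not_three_bonds")
    }
    if ("P_H_bond" %in% ruleset && any(imph > 0 | expH)) {
      v <- c(v, "P_H_bond")
    }
    if ("P_in_three_ring" %in% ruleset && any(vapply(pidx, function(p) {
      nb <- c(molecule$bonds$j[molecule$bonds$i == p],
              molecule$bonds$i[molecule$bonds$j == p])
      if (length(nb) < 2) return(FALSE)
      prs <- utils::combn(nb, 2)
      any(apply(prs, 2, function(pr) {
        any((molecule$bonds$i == min(pr) & molecule$bonds$j == max(pr)))
      }))
    }, logical(1)))) {
      v <- c(v, "P_in_three_ring")
    }
  }
  list(pass = length(v) == 0L, violations = v)
}
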