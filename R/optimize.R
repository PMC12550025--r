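#' Inverse-design objective specification
#'
#' The objective scored at each latent point: decode the latent under a
#' fixed condition, re-embed and re-encode the resulting catalyst, predict
#' its performance, and combine prediction (`maximize` mode) or negative
#' distance to a target value (`match_value` mode) with reward terms for
#' satisfied predicates, penalty terms for violated constraints, and an
#' optional similarity term pulling candidates toward a reference set.
#'
#' @param target_mode `"maximize"` or `"match_value"`.
#' @param target target value (required for `match_value`; e.g. the
#'   midpoint of a desired binding-energy window).
#' @param penalties list of `list(predicate = function(cat_mol) logical,
#'   magnitude = ...)`; the magnitude is subtracted when the predicate
#'   fires (a violation).
#' @param rewards list of the same shape; added when the predicate holds.
#' @param similarity optional `list(reference = SMILES vector, weight =
#'   w)`: subtracts `w * (1 - max Tanimoto to the reference set)`.
#' @param condition the condition vector the decoder is steered with.
#' @param failure_score score assigned to empty decodes; `NULL` = running
#'   `min(score) - 3 * IQR` floor-capped at -1e6.
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(target_mode = c("maximize", "match_value"),
                           target = NULL, penalties = list(),
                           rewards = list(), similarity = NULL,
                           condition = NULL, failure_score = NULL) {
  target_mode <- match.arg(target_mode)
  if (target_mode == "match_value" && is.null(target)) {
    stop("match_value mode needs a target")
  }
  for (p in c(penalties, rewards)) {
    stopifnot(is.function(p$predicate), p$magnitude >= 0)
  }
  structure(list(target_mode = target_mode, target = target,
                 penalties = penalties, rewards = rewards,
                 similarity = similarity, condition = condition,
                 failure_score = failure_score),
            class = "objective_spec")
}

#' Desired binding-energy window for Suzuki-Miyaura-type cross-coupling
#'
#' The catalyst binding-energy range considered effective for the C-C
#' cross-coupling case study, in kcal/mol; inverse design targets its
#' midpoint.
#' @return `cc_binding_energy_range()` returns `c(-32.1, -23.0)`;
#'   `cc_objective_target()` returns the midpoint.
#' @export
cc_binding_energy_range <- function() c(-32.1, -23.0)

#' @rdname cc_binding_energy_range
#' @export
cc_objective_target <- function() mean(cc_binding_energy_range())

#' Structural penalty predicates for catalyst optimization
#'
#' Named predicates (each `function(cat_mol) -> TRUE` when the constraint
#' is violated) matching the cross-coupling case-study penalties:
#' `wrong_fragment_count` (not the L1-M-L2 three-fragment motif),
#' `missing_key_atoms` (no P, N or O), `bad_heteroatom_bonding`
#' (overcoordinated P/N/O), and `small_ring` (any three- or four-membered
#' ring).
#'
#' @return named list of predicate functions.
#' @export
structural_predicates <- function() {
  list(
    wrong_fragment_count = function(mol) {
      mol_natoms(mol) == 0 || length(mol_fragments(mol)) != 3L
    },
    missing_key_atoms = function(mol) {
      !any(mol$atoms %in% c("P", "N", "O"))
    },
    bad_heteroatom_bonding = function(mol) {
      idx <- which(mol$atoms %in% c("P", "N", "O"))
      if (!length(idx)) return(FALSE)
      v <- mol_valences(mol)
      any(vapply(idx, function(a) {
        v[a] > max_valence(mol$atoms[a], mol$charges[a]) ||
          (mol$atoms[a] == "O" && v[a] > 2) ||
          (mol$atoms[a] == "N" && v[a] > 3) ||
          (mol$atoms[a] == "P" && v[a] > 3)
      }, logical(1)))
    },
    small_ring = function(mol) .has_small_ring(mol, c(3L, 4L))
  )
}

# Any chordless cycle of the given sizes? Checked by bounded DFS.
.has_small_ring <- function(mol, sizes) {
  n <- mol_natoms(mol)
  if (n < 3 || !nrow(mol$bonds)) return(FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  maxlen <- max(sizes)
  found <- FALSE
  walk <- function(start, path) {
    if (found) return()
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3 && length(path) %in% sizes) {
        found <<- TRUE; return()
      }
      if (!(w %in% path) && w > start && length(path) < maxlen) {
        walk(start, c(path, w))
      }
    }
  }
  for (s in seq_len(n)) { walk(s, s); if (found) break }
  found
}

#' Evaluate the inverse-design objective at one latent point
#'
#' @param z latent vector.
#' @param spec an [objective_spec] (with `condition` set).
#' @param model a [catvae] model.
#' @param state internal list carrying running scores (for the adaptive
#'   failure score); optional.
#' @return list with `score`, `smiles` (`NA` for empty decode),
#'   `prediction` (`NA` for empty decode).
#' @export
objective_evaluate <- function(z, spec, model, state = NULL) {
  stopifnot(!is.null(spec$condition))
  cond <- matrix(spec$condition, 1)
  logit <- cvae_decode(model, matrix(z, 1), cond)[[1]]
  rec <- reconstruct(logit, model$vocab)
  if (rec$report$empty_output || is.na(rec$smiles)) {
    fs <- spec$failure_score %||% .adaptive_failure_score(state)
    return(list(score = fs, smiles = NA_character_, prediction = NA_real_))
  }
  mat <- encode_catalyst(rec$molecule, model$vocab)
  x <- embed_catalyst(model, mat)
  lat <- cvae_encode(model, x, cond, sample = FALSE)
  pred <- if (!is.null(model$surrogate)) {
    surrogate_predict(model$surrogate, cbind(lat$mean, cond))
  } else {
    cvae_predict(model, lat$mean, cond)
  }
  base <- if (spec$target_mode == "maximize") pred
          else -abs(pred - spec$target)
  score <- base
  for (p in spec$penalties) {
    if (isTRUE(p$predicate(rec$molecule))) score <- score - p$magnitude
  }
  for (p in spec$rewards) {
    if (isTRUE(p$predicate(rec$molecule))) score <- score + p$magnitude
  }
  if (!is.null(spec$similarity)) {
    fp <- ecfp4_fingerprint(rec$smiles)
    fpr <- ecfp4_fingerprint(spec$similarity$reference)
    maxsim <- max(tanimoto_similarity(fp, fpr))
    score <- score - spec$similarity$weight * (1 - maxsim)
  }
  list(score = score, smiles = rec$smiles, prediction = pred)
}

.adaptive_failure_score <- function(state) {
  if (is.null(state) || !length(state$scores)) return(-1e3)
  q <- stats::quantile(state$scores, c(0.25, 0.75), names = FALSE)
  max(min(state$scores) - 3 * (q[2] - q[1]), -1e6)
}

#' Optimization run settings
#'
#' @param strategy `"random_space"` (search the training-latent integer
#'   box) or `"around_molecule"` (search a ball around an anchor latent).
#' @param rounds optimization rounds (the case-study protocol uses 50).
#' @param calls_per_round objective evaluations per round.
#' @param top_k distinct candidates retained per round (case-study: 10).
#' @param radius search-ball radius for `around_molecule`.
#' @param seed integer seed.
#' @return an object of class `optimization_run`.
#' @export
optimization_run <- function(strategy = c("random_space", "around_molecule"),
                             rounds = 50L, calls_per_round = 20L,
                             top_k = 10L, radius = 3, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(rounds >= 1, calls_per_round >= 1, top_k >= 1, radius > 0)
  structure(list(strategy = strategy, rounds = as.integer(rounds),
                 calls_per_round = as.integer(calls_per_round),
                 top_k = as.integer(top_k), radius = radius,
                 seed = as.integer(seed)),
            class = "optimization_run")
}

#' Bayesian optimization over the latent space
#'
#' Sequential model-based maximization of the inverse-design objective: a
#' Gaussian-process surrogate (RBF kernel) is fitted to all evaluated
#' points and new points are proposed by expected improvement over a
#' random candidate pool inside the search region (pure random search
#' until 10 points are available). Per round, the `top_k` distinct decoded
#' molecules by score are retained; the full trace is returned.
#'
#' @param spec an [objective_spec].
#' @param run an [optimization_run].
#' @param model a [catvae] model.
#' @param training_latents matrix of training latent means (defines the
#'   `random_space` box).
#' @param anchor_latent latent vector at the centre of the
#'   `around_molecule` ball.
#' @param objective optional override: `function(z, state) ->
#'   list(score, smiles, prediction)` (used for mock objectives in
#'   protocol tests).
#' @return an object of class `optimization_result`: list with
#'   `candidates` (data.frame `round`, `smiles`, `score`, `prediction`),
#'   `trace` (every evaluation with the running best), `best`.
#' @export
bayes_optimize <- function(spec, run, model = NULL, training_latents = NULL,
                           anchor_latent = NULL, objective = NULL) {
  if (run$strategy == "random_space") {
    if (is.null(training_latents)) stop("random_space needs training_latents")
    box <- latent_box(training_latents)
    if (all(box[2, ] - box[1, ] <= 0)) stop("degenerate search box")
    D <- ncol(training_latents)
  } else {
    if (is.null(anchor_latent)) stop("around_molecule needs anchor_latent")
    D <- length(anchor_latent)
    box <- rbind(lower = anchor_latent - run$radius,
                 upper = anchor_latent + run$radius)
  }
  if (is.null(objective)) {
    if (is.null(model)) stop("either a model or a mock objective is required")
    objective <- function(z, state) objective_evaluate(z, spec, model, state)
  }
  rng <- .seeded_rng(run$seed)
  draw <- function() {
    if (run$strategy == "around_molecule") {
      # uniform in the L2 ball around the anchor
      dir <- rng$rnorm(D); dir <- dir / sqrt(sum(dir^2))
      anchor_latent + dir * run$radius * rng$runif(1)^(1 / D)
    } else {
      box[1, ] + rng$runif(D) * (box[2, ] - box[1, ])
    }
  }
  X <- NULL; scores <- numeric()
  trace <- list(); cands <- list()
  state <- list(scores = numeric())
  best <- -Inf
  for (round in seq_len(run$rounds)) {
    round_rows <- list()
    for (call in seq_len(run$calls_per_round)) {
      z <- if (length(scores) < 10L) draw() else {
        .propose_ei(X, scores, draw, n_cand = 128L)
      }
      ev <- objective(z, state)
      state$scores <- c(state$scores, ev$score)
      X <- rbind(X, z); scores <- c(scores, ev$score)
      best <- max(best, ev$score)
      trace[[length(trace) + 1L]] <- data.frame(
        round = round, call = call, score = ev$score,
        smiles = ev$smiles %||% NA_character_, best_so_far = best,
        stringsAsFactors = FALSE)
      round_rows[[call]] <- trace[[length(trace)]]
    }
    rr <- do.call(rbind, round_rows)
    rr <- rr[!is.na(rr$smiles), , drop = FALSE]
    if (nrow(rr)) {
      rr <- rr[order(-rr$score), , drop = FALSE]
      rr <- rr[!duplicated(rr$smiles), , drop = FALSE]
      rr <- utils::head(rr, run$top_k)
      cands[[round]] <- data.frame(round = round, smiles = rr$smiles,
                                   score = rr$score, stringsAsFactors = FALSE)
    }
  }
  trace <- do.call(rbind, trace)
  candidates <- if (length(cands)) do.call(rbind, cands)
                else data.frame(round = integer(), smiles = character(),
                                score = numeric())
  structure(list(candidates = candidates, trace = trace,
                 best = trace[which.max(trace$score)[1], ]),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result: %d evaluations, %d candidates, best score %.4f>\n",
              nrow(x$trace), nrow(x$candidates), max(x$trace$score)))
  invisible(x)
}

# Expected-improvement proposal: fit an exact GP to the observed points
# and pick the best of n_cand random candidates.
.propose_ei <- function(X, y, draw, n_cand = 128L) {
  gp <- .gp_fit(X, y)
  cand <- t(vapply(seq_len(n_cand), function(i) draw(), numeric(ncol(X))))
  pr <- .gp_predict(gp, cand)
  fbest <- max(y)
  s <- pmax(pr$sd, 1e-9)
  imp <- pr$mean - fbest
  zq <- imp / s
  ei <- imp * stats::pnorm(zq) + s * stats::dnorm(zq)
  cand[which.max(ei), ]
}

# Exact GP with RBF kernel on inputs scaled to unit box, standardized y.
.gp_fit <- function(X, y, lengthscale = 0.25, noise = 1e-4) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  scale <- pmax(hi - lo, 1e-9)
  Xs <- sweep(sweep(X, 2, lo), 2, scale, `/`)
  mu_y <- mean(y); sd_y <- max(stats::sd(y), 1e-9)
  ys <- (y - mu_y) / sd_y
  K <- .rbf_kernel(Xs, Xs, lengthscale) + diag(noise, nrow(Xs))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(Xs = Xs, lo = lo, scale = scale, L = L, alpha = alpha,
       mu_y = mu_y, sd_y = sd_y, lengthscale = lengthscale)
}

.gp_predict <- function(gp, Xnew) {
  Xs <- sweep(sweep(Xnew, 2, gp$lo), 2, gp$scale, `/`)
  Ks <- .rbf_kernel(Xs, gp$Xs, gp$lengthscale)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(1 - colSums(V^2), 0)
  list(mean = mean_s * gp$sd_y + gp$mu_y, sd = sqrt(var_s) * gp$sd_y)
}

.rbf_kernel <- function(A, B, l) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * l^2))
}
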