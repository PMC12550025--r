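#' Model configuration
#'
#' Hyperparameters of the conditional VAE. Dimensions follow the
#' architecture: catalyst embedding width `d_x`, graph-encoder width
#' `d_graph` per condition role, latent width `d_latent`, hidden widths for
#' the encoder/decoder/adjacency heads, loss weights `alpha` (reconstruction)
#' and `beta` (KL), and the teacher-forcing ratio (default 0.25).
#'
#' @param d_x catalyst embedding width.
#' @param d_graph width of each condition graph embedding.
#' @param d_latent latent dimensionality `D`.
#' @param h_embed,h_enc,h_dec,h_adj hidden-layer widths.
#' @param k_adj width of the annotation-enhancement features whose outer
#'   product seeds the adjacency decoder.
#' @param mw_bins number of catalyst molecular-weight clusters.
#' @param alpha,beta loss weights for reconstruction and KL terms.
#' @param teacher_forcing_ratio probability of feeding a true upstream
#'   block to each decoder stage during training.
#' @param nobond_weight weight of the no-bond channel in the adjacency
#'   cross-entropy; `NULL` = set from the observed no-bond frequency.
#' @param lr,epochs,batch_size Adam learning rate, epoch count, batch size.
#' @param augment_orders node orderings per molecule during training
#'   (1 = no augmentation; the pre-training default is 5).
#' @param seeds integer seeds for repeated training runs.
#' @param surrogate surrogate used at fine-tuning for non-yield targets:
#'   `"none"`, `"random_forest"` or `"gradient_boosting"`.
#' @return a list of class `catvae_config`.
#' @export
catvae_config <- function(d_x = 64L, d_graph = 24L, d_latent = 32L,
                          h_embed = 128L, h_enc = 128L, h_dec = 128L,
                          h_adj = 32L, k_adj = 24L, mw_bins = 8L,
                          alpha = 1, beta = 1e-3,
                          teacher_forcing_ratio = 0.25,
                          nobond_weight = NULL,
                          lr = 1e-3, epochs = 300L, batch_size = 64L,
                          augment_orders = 1L, seeds = c(1L, 2L, 3L),
                          surrogate = c("none", "random_forest",
                                        "gradient_boosting")) {
  stopifnot(alpha >= 0, beta >= 0,
            teacher_forcing_ratio >= 0, teacher_forcing_ratio <= 1)
  structure(list(d_x = d_x, d_graph = d_graph, d_latent = d_latent,
                 h_embed = h_embed, h_enc = h_enc, h_dec = h_dec,
                 h_adj = h_adj, k_adj = k_adj, mw_bins = mw_bins,
                 alpha = alpha, beta = beta,
                 teacher_forcing_ratio = teacher_forcing_ratio,
                 nobond_weight = nobond_weight, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 augment_orders = as.integer(augment_orders),
                 seeds = as.integer(seeds),
                 surrogate = match.arg(surrogate)),
            class = "catvae_config")
}

#' Construct an untrained conditional VAE
#'
#' Initializes all weights from `seed`. The condition graph encoders use
#' fixed seeded weights (deterministic random-feature graph attention);
#' everything else is trained by [catvae_train()].
#'
#' @param vocab a [cat_vocabulary].
#' @param config a [catvae_config].
#' @param seed integer seed for weight initialization.
#' @param mw_edges molecular-weight cluster edges; `NULL` until set from a
#'   training set.
#' @return an object of class `catvae`.
#' @export
catvae <- function(vocab, config = catvae_config(), seed = 1L,
                   mw_edges = NULL) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types)
  Bt <- length(vocab$bond_types)
  cfg <- config
  if (is.null(mw_edges)) mw_edges <- seq(100, 700, length.out = cfg$mw_bins - 1L)
  dc <- 3L * cfg$d_graph + 1L + length(mw_edges) + 1L
  rng <- .seeded_rng(seed)
  sch <- graph_feature_scheme()
  par <- list(
    embT = nn_linear_init(rng, S, cfg$d_x),
    embA1 = nn_linear_init(rng, S * At, cfg$h_embed),
    embA2 = nn_linear_init(rng, cfg$h_embed, cfg$d_x),
    embB1 = nn_linear_init(rng, S * S * Bt, cfg$h_embed),
    embB2 = nn_linear_init(rng, cfg$h_embed, cfg$d_x),
    enc1 = nn_linear_init(rng, cfg$d_x + dc, cfg$h_enc),
    mu = nn_linear_init(rng, cfg$h_enc, cfg$d_latent),
    lv = nn_linear_init(rng, cfg$h_enc, cfg$d_latent),
    decT1 = nn_linear_init(rng, cfg$d_latent + dc, cfg$h_dec),
    decT2 = nn_linear_init(rng, cfg$h_dec, S),
    decA1 = nn_linear_init(rng, cfg$d_latent + dc + S, cfg$h_dec),
    decA2 = nn_linear_init(rng, cfg$h_dec, S * At),
    enh = nn_linear_init(rng, At + S + cfg$d_latent + dc, cfg$k_adj),
    adj1 = nn_linear_init(rng, 2L * cfg$k_adj, cfg$h_adj),
    adj2 = nn_linear_init(rng, cfg$h_adj, Bt),
    pr1 = nn_linear_init(rng, cfg$d_latent + dc, cfg$h_enc),
    pr2 = nn_linear_init(rng, cfg$h_enc, 1L)
  )
  gat <- gat_init(rng, sch$node_width, sch$edge_width, cfg$d_graph)
  structure(list(vocab = vocab, config = cfg, par = par, gat = gat,
                 no_reagent = rng$rnorm(cfg$d_graph, 0, 0.5),
                 mw_edges = mw_edges, d_c = dc, seed = seed,
                 y_center = 0, y_scale = 1, target_kind = "yield",
                 trained_epochs = 0L),
            class = "catvae")
}

#' @export
print.catvae <- function(x, ...) {
  cat(sprintf(paste0("<catvae: S=%d, D_x=%d, D_c=%d, D=%d; %s; ",
                     "%d epochs trained>\n"),
              x$vocab$max_nodes, x$config$d_x, x$d_c, x$config$d_latent,
              x$target_kind, x$trained_epochs))
  invisible(x)
}

## ---- flattening helpers -------------------------------------------------

flatten_A <- function(m) as.numeric(t(m$A))          # node-major, channel fastest
flatten_B <- function(m) as.numeric(aperm(m$B, c(3, 2, 1)))  # i, j, channel fastest

# n x (S*At) -> (n*S) x At with row (s-1)*S + node
to_blocks <- function(M, width) {
  matrix(as.vector(t(M)), ncol = width, byrow = TRUE)
}
from_blocks <- function(R, ncols) {
  matrix(as.vector(t(R)), ncol = ncols, byrow = TRUE)
}

# Stack encoded matrices into the batch design matrices.
batch_matrices <- function(matrices) {
  list(T = do.call(rbind, lapply(matrices, function(m) m$T)),
       A = do.call(rbind, lapply(matrices, flatten_A)),
       B = do.call(rbind, lapply(matrices, flatten_B)))
}

## ---- embeddings ---------------------------------------------------------

#' Embed catalyst matrices
#'
#' Each component of the matrix triple passes through its own network and
#' the three outputs are summed into the catalyst embedding `x`.
#'
#' @param model a [catvae] model.
#' @param matrices one `catalyst_matrix` or a list of them.
#' @return an `n x d_x` matrix of embeddings.
#' @export
embed_catalyst <- function(model, matrices) {
  if (inherits(matrices, "catalyst_matrix")) matrices <- list(matrices)
  bm <- batch_matrices(matrices)
  .embed_fwd(model$par, bm)$x
}

.embed_fwd <- function(par, bm) {
  hA0 <- nn_linear_fwd(par$embA1, bm$A); hA <- nn_relu(hA0)
  hB0 <- nn_linear_fwd(par$embB1, bm$B); hB <- nn_relu(hB0)
  x <- nn_linear_fwd(par$embT, bm$T) + nn_linear_fwd(par$embA2, hA) +
    nn_linear_fwd(par$embB2, hB)
  list(x = x, hA0 = hA0, hA = hA, hB0 = hB0, hB = hB)
}

#' Embed reaction conditions
#'
#' Reactants, reagents and product are embedded independently with the
#' graph attention encoder and mean-pooled within role; absent reagents
#' use the model's learned default (no-reagent) vector. The concatenation
#' with the reaction-time scalar and the molecular-weight cluster one-hot
#' gives the condition vector `c`.
#'
#' @param model a [catvae] model.
#' @param records a reaction-record data frame.
#' @return an `n x D_c` matrix of condition vectors.
#' @export
embed_condition <- function(model, records) {
  smiles <- unique(c(unlist(records$reactants), unlist(records$reagents),
                     records$product))
  mols <- parse_smiles(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) stop("unparseable SMILES in records: ",
                     paste(smiles[bad], collapse = ", "))
  embs <- lapply(mols, function(m) gat_embed(model$gat, m))
  names(embs) <- smiles
  pool <- function(smis) {
    if (!length(smis)) return(NULL)
    rowMeans(do.call(cbind, embs[smis]))
  }
  t(vapply(seq_len(nrow(records)), function(r) {
    rvec <- pool(records$reactants[[r]])
    gvec <- pool(records$reagents[[r]]) %||% model$no_reagent
    pvec <- embs[[records$product[r]]]
    c(rvec, gvec, pvec, records$time_h[r],
      mw_cluster_onehot(records$catalyst_mw[r], model$mw_edges))
  }, numeric(model$d_c)))
}

## ---- encoder / decoder / predictor -------------------------------------

#' Encode catalyst + condition into the latent space
#'
#' @param model a [catvae] model.
#' @param x catalyst embeddings (`n x d_x`).
#' @param cond condition vectors (`n x D_c`).
#' @param sample draw a reparameterized sample (`mean + exp(logvar/2) * eps`)?
#' @param seed seed for `eps` (reproducible sampling).
#' @return a `latent_point`: list with `mean`, `logvar`, `sample`, `eps`
#'   (all `n x D`).
#' @export
cvae_encode <- function(model, x, cond, sample = TRUE, seed = NULL) {
  fw <- .encode_fwd(model$par, x, cond)
  n <- nrow(fw$mu); D <- ncol(fw$mu)
  eps <- matrix(0, n, D)
  if (sample) {
    eps <- if (is.null(seed)) matrix(stats::rnorm(n * D), n, D)
           else matrix(.seeded_rng(seed)$rnorm(n * D), n, D)
  }
  structure(list(mean = fw$mu, logvar = fw$lv,
                 sample = fw$mu + exp(fw$lv / 2) * eps, eps = eps),
            class = "latent_point")
}

.encode_fwd <- function(par, x, cond) {
  X <- cbind(x, cond)
  h0 <- nn_linear_fwd(par$enc1, X); h <- nn_relu(h0)
  mu <- nn_linear_fwd(par$mu, h)
  lv0 <- nn_linear_fwd(par$lv, h)
  lv <- pmin(pmax(lv0, -8), 8)
  list(X = X, h0 = h0, h = h, mu = mu, lv = lv, lv0 = lv0)
}

#' Decode latents into matrix logits
#'
#' Sequential decoding: the size head consumes `(z, c)`; the annotation
#' head consumes `(z, c, T-probabilities)`; the annotation output is
#' enhanced by a linear map whose per-node features form pairwise products
#' (the outer-product initial adjacency) refined by the adjacency head
#' into per-pair bond-type logits (symmetrized). With a `teacher` matrix
#' and `tf_ratio > 0`, each stage independently consumes the true upstream
#' block with probability `tf_ratio`.
#'
#' @param model a [catvae] model.
#' @param z latent vectors (`n x D`).
#' @param cond condition vectors (`n x D_c`).
#' @param teacher optional list of true `catalyst_matrix` objects
#'   (required when `tf_ratio > 0`).
#' @param tf_ratio per-stage teacher-forcing probability.
#' @param seed seed for the forcing draws.
#' @return a list of per-sample `matrix_logits`: each a list with `T`
#'   (length S), `A` (`S x A_t`), `B` (`S x S x B_t`).
#' @export
cvae_decode <- function(model, z, cond, teacher = NULL, tf_ratio = 0,
                        seed = NULL) {
  if (tf_ratio > 0 && is.null(teacher)) {
    stop("teacher matrices are required when tf_ratio > 0")
  }
  bm <- if (!is.null(teacher)) batch_matrices(teacher) else NULL
  rng <- .seeded_rng(seed %||% 1L)
  n <- nrow(z)
  forceT <- if (tf_ratio > 0) rng$runif(n) < tf_ratio else rep(FALSE, n)
  forceA <- if (tf_ratio > 0) rng$runif(n) < tf_ratio else rep(FALSE, n)
  fw <- .decode_fwd(model$par, model$vocab, z, cond, bm, forceT, forceA)
  .split_logits(fw, model$vocab, n)
}

.decode_fwd <- function(par, vocab, z, cond, bm, forceT, forceA) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types)
  Bt <- length(vocab$bond_types)
  n <- nrow(z)
  XT <- cbind(z, cond)
  hT0 <- nn_linear_fwd(par$decT1, XT); hT <- nn_relu(hT0)
  tlog <- nn_linear_fwd(par$decT2, hT)
  tprob <- nn_block_softmax(tlog, S)
  tin <- tprob
  if (any(forceT)) tin[forceT, ] <- bm$T[forceT, , drop = FALSE]

  XA <- cbind(z, cond, tin)
  hA0 <- nn_linear_fwd(par$decA1, XA); hA <- nn_relu(hA0)
  alog <- nn_linear_fwd(par$decA2, hA)
  aprob_blocks <- nn_block_softmax(to_blocks(alog, At), At)
  aprob <- from_blocks(aprob_blocks, S * At)
  ain <- aprob
  if (any(forceA)) ain[forceA, ] <- bm$A[forceA, , drop = FALSE]

  # annotation enhancement: each node row carries its annotation fiber, a
  # positional one-hot, the latent vector and the condition, so the outer
  # product can express node-specific connectivity
  nodeS <- rep(seq_len(n), each = S)
  G <- cbind(to_blocks(ain, At),
             kronecker(rep(1, n), diag(S)),
             z[nodeS, , drop = FALSE],
             cond[nodeS, , drop = FALSE])       # (nS) x (At+S+D+Dc)
  Hn <- nn_linear_fwd(par$enh, G)               # (nS) x k
  sidx <- rep(seq_len(n), each = S * S)
  iidx <- rep(rep(seq_len(S), each = S), n)
  jidx <- rep(seq_len(S), n * S)
  I1 <- (sidx - 1L) * S + iidx
  I2 <- (sidx - 1L) * S + jidx
  swapidx <- (sidx - 1L) * S * S + (jidx - 1L) * S + iidx
  # symmetric pair features: elementwise product and sum of node features
  P <- cbind(Hn[I1, , drop = FALSE] * Hn[I2, , drop = FALSE],
             Hn[I1, , drop = FALSE] + Hn[I2, , drop = FALSE])
  hP0 <- nn_linear_fwd(par$adj1, P); hP <- nn_relu(hP0)
  blog <- nn_linear_fwd(par$adj2, hP)           # (nS^2) x Bt
  bsym <- (blog + blog[swapidx, , drop = FALSE]) / 2
  list(XT = XT, hT0 = hT0, hT = hT, tlog = tlog, tprob = tprob, tin = tin,
       XA = XA, hA0 = hA0, hA = hA, alog = alog, aprob = aprob, ain = ain,
       G = G, Hn = Hn, I1 = I1, I2 = I2, swapidx = swapidx,
       P = P, hP0 = hP0, hP = hP, blog = blog, bsym = bsym,
       forceT = forceT, forceA = forceA, n = n)
}

.split_logits <- function(fw, vocab, n) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types)
  Bt <- length(vocab$bond_types)
  lapply(seq_len(n), function(s) {
    rows <- ((s - 1L) * S * S + 1L):(s * S * S)
    Bs <- aperm(array(t(fw$bsym[rows, , drop = FALSE]), c(Bt, S, S)),
                c(3, 2, 1))
    list(T = as.numeric(fw$tlog[s, ]),
         A = matrix(fw$alog[s, ], S, At, byrow = TRUE),
         B = Bs)
  })
}

#' Predict catalytic performance from the latent mean
#'
#' The predictor consumes the latent mean concatenated with the condition
#' vector and reports on the target scale (percent for yields, clamped to
#' `[0, 100]`).
#'
#' @param model a [catvae] model.
#' @param mu latent means (`n x D`).
#' @param cond condition vectors (`n x D_c`).
#' @return numeric vector of predictions.
#' @export
cvae_predict <- function(model, mu, cond) {
  h <- nn_relu(nn_linear_fwd(model$par$pr1, cbind(mu, cond)))
  yhat <- as.numeric(nn_linear_fwd(model$par$pr2, h))
  y <- yhat * model$y_scale + model$y_center
  if (model$target_kind == "yield") y <- pmin(pmax(y, 0), 100)
  y
}

#' Predict targets for reaction records
#'
#' Full pipeline: encode each record's catalyst, embed its condition, take
#' the latent mean and apply the predictor (or the fitted surrogate when
#' one is attached to the model).
#'
#' @param object a [catvae] model.
#' @param records a reaction-record data frame.
#' @param ... unused.
#' @return numeric vector of predicted targets.
#' @export
predict.catvae <- function(object, records, ...) {
  mats <- lapply(records$catalyst, encode_catalyst_smiles, model = object)
  cond <- embed_condition(object, records)
  x <- embed_catalyst(object, mats)
  lat <- cvae_encode(object, x, cond, sample = FALSE)
  if (!is.null(object$surrogate)) {
    return(surrogate_predict(object$surrogate, cbind(lat$mean, cond)))
  }
  cvae_predict(object, lat$mean, cond)
}

encode_catalyst_smiles <- function(model, smiles) {
  encode_catalyst(smiles, model$vocab)
}

## ---- loss ---------------------------------------------------------------

#' Total training loss and its components
#'
#' `total = alpha * L_recons + beta * L_KL + L_prediction` where
#' `L_recons` sums categorical cross-entropies over the `T`, `A` and `B`
#' fibers, `L_KL` is the closed-form Gaussian KL to the standard normal,
#' and `L_prediction` is the squared error.
#'
#' @param logits per-sample `matrix_logits` (list with `T`, `A`, `B`).
#' @param truth the true `catalyst_matrix`.
#' @param latent a `latent_point` (uses row 1 of `mean`/`logvar`).
#' @param y_hat,y predicted and true target (same scale).
#' @param alpha,beta loss weights (must be non-negative).
#' @param nobond_weight weight of the no-bond channel in the `B`
#'   cross-entropy.
#' @return list with `total`, `recons`, `kl`, `prediction`.
#' @export
loss_total <- function(logits, truth, latent, y_hat, y, alpha = 1, beta = 1,
                       nobond_weight = 1) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  S <- length(truth$T); At <- ncol(truth$A); Bt <- dim(truth$B)[3]
  ceT <- nn_block_ce(matrix(logits$T, 1), matrix(truth$T, 1), S)$loss
  ceA <- nn_block_ce(to_blocks(matrix(flatten_A(logits), 1), At),
                     to_blocks(matrix(flatten_A(truth), 1), At), At)$loss * S
  wb <- c(nobond_weight, rep(1, Bt - 1L))
  ceB <- nn_block_ce(to_blocks(matrix(flatten_B(logits), 1), Bt),
                     to_blocks(matrix(flatten_B(truth), 1), Bt), Bt,
                     w = wb)$loss * S * S
  mu <- latent$mean[1, ]; lv <- latent$logvar[1, ]
  kl <- 0.5 * sum(exp(lv) + mu^2 - 1 - lv)
  pred <- (y_hat - y)^2
  recons <- ceT + ceA + ceB
  list(total = alpha * recons + beta * kl + pred,
       recons = recons, kl = kl, prediction = pred)
}

## ---- training -----------------------------------------------------------

#' Train the conditional VAE
#'
#' Joint training of the reconstruction, KL and prediction objectives with
#' Adam, per-stage teacher forcing, and optional node-shuffle
#' augmentation. Conditions are precomputed once per record.
#'
#' @param model a [catvae] model.
#' @param records reaction records (the training split).
#' @param epochs,batch_size,lr overrides of the model config.
#' @param seed seed controlling batching, sampling noise and forcing.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return the trained model with a `history` element (per-epoch data
#'   frame of loss components).
#' @export
catvae_train <- function(model, records, epochs = NULL, batch_size = NULL,
                         lr = NULL, seed = 1L, verbose = 0L) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- lr %||% cfg$lr
  S <- model$vocab$max_nodes; At <- length(model$vocab$atom_types)
  Bt <- length(model$vocab$bond_types)

  mats <- lapply(records$catalyst, encode_catalyst_smiles, model = model)
  cond0 <- embed_condition(model, records)
  y0 <- records$target
  if (cfg$augment_orders > 1L) {
    aug <- list(); condrows <- integer()
    for (r in seq_along(mats)) {
      aug <- c(aug, shuffle_augment(mats[[r]], cfg$augment_orders,
                                    seed = seed + r))
      condrows <- c(condrows, rep(r, cfg$augment_orders))
    }
    mats <- aug
    cond0 <- cond0[condrows, , drop = FALSE]
    y0 <- y0[condrows]
  }
  model$y_center <- mean(y0); model$y_scale <- max(stats::sd(y0), 1e-6)
  model$target_kind <- records$target_kind[1]
  y <- (y0 - model$y_center) / model$y_scale
  bm <- batch_matrices(mats)

  wb <- cfg$nobond_weight
  if (is.null(wb)) {
    f_nobond <- mean(bm$B[, seq(1, ncol(bm$B), by = Bt)])
    wb <- max((1 - f_nobond) / f_nobond, 0.02)
  }
  wvec <- c(wb, rep(1, Bt - 1L))

  par <- model$par
  st <- adam_init(par)
  rng <- .seeded_rng(seed)
  nall <- nrow(bm$T)
  hist <- vector("list", epochs)
  t_adam <- 0L
  for (ep in seq_len(epochs)) {
    # step decay: full rate for the first 60% of epochs, then 1/3, then 1/10
    lr_ep <- lr * if (ep <= 0.6 * epochs) 1 else if (ep <= 0.85 * epochs) 1 / 3 else 0.1
    ord <- rng$sample(nall)
    comp <- c(total = 0, recons = 0, kl = 0, prediction = 0)
    nb <- 0L
    for (start in seq(1, nall, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, nall)]
      batch <- list(T = bm$T[idx, , drop = FALSE],
                    A = bm$A[idx, , drop = FALSE],
                    B = bm$B[idx, , drop = FALSE])
      step <- .train_step(par, model$vocab, cfg, batch,
                          cond0[idx, , drop = FALSE], y[idx], wvec, rng)
      t_adam <- t_adam + 1L
      upd <- adam_step(par, step$grads, st, lr_ep, t_adam)
      par <- upd$params; st <- upd$state
      comp <- comp + unlist(step$comp)
      nb <- nb + 1L
    }
    hist[[ep]] <- comp / nb
    if (verbose > 0 && (ep %% verbose == 0 || ep == 1L)) {
      message(sprintf("epoch %d: total=%.4f recons=%.4f kl=%.4f pred=%.4f",
                      ep, comp[1] / nb, comp[2] / nb, comp[3] / nb, comp[4] / nb))
    }
  }
  model$par <- par
  model$trained_epochs <- model$trained_epochs + epochs
  model$history <- as.data.frame(do.call(rbind, hist))
  model
}

# One forward/backward pass; returns parameter gradients and the loss
# components averaged over the batch.
.train_step <- function(par, vocab, cfg, bm, cond, y, wvec, rng) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types)
  Bt <- length(vocab$bond_types)
  n <- nrow(bm$T)
  g <- grad_zero_like(par)

  emb <- .embed_fwd(par, bm)
  enc <- .encode_fwd(par, emb$x, cond)
  eps <- matrix(rng$rnorm(n * ncol(enc$mu)), n)
  z <- enc$mu + exp(enc$lv / 2) * eps
  forceT <- rng$runif(n) < cfg$teacher_forcing_ratio
  forceA <- rng$runif(n) < cfg$teacher_forcing_ratio
  dec <- .decode_fwd(par, vocab, z, cond, bm, forceT, forceA)

  hPr0 <- nn_linear_fwd(par$pr1, cbind(enc$mu, cond)); hPr <- nn_relu(hPr0)
  yhat <- as.numeric(nn_linear_fwd(par$pr2, hPr))

  ceT <- nn_block_ce(dec$tlog, bm$T, S)
  ceA <- nn_block_ce(to_blocks(dec$alog, At), to_blocks(bm$A, At), At)
  ceB <- nn_block_ce(dec$bsym, to_blocks(bm$B, Bt), Bt, w = wvec)
  lossT <- ceT$loss; lossA <- ceA$loss * S; lossB <- ceB$loss * S * S
  kl <- 0.5 * sum(exp(enc$lv) + enc$mu^2 - 1 - enc$lv) / n
  lpred <- mean((yhat - y)^2)
  recons <- lossT + lossA + lossB
  total <- cfg$alpha * recons + cfg$beta * kl + lpred

  ## ---- backward ----
  # predictor
  dyhat <- matrix(2 * (yhat - y) / n, ncol = 1)
  bw <- nn_linear_bwd(par$pr2, hPr, dyhat)
  g$pr2$W <- bw$dW; g$pr2$b <- bw$db
  dhPr <- nn_relu_bwd(hPr0, bw$dX)
  bw <- nn_linear_bwd(par$pr1, cbind(enc$mu, cond), dhPr)
  g$pr1$W <- bw$dW; g$pr1$b <- bw$db
  D <- ncol(enc$mu)
  dmu <- bw$dX[, seq_len(D), drop = FALSE]

  # adjacency head
  dbsym <- cfg$alpha * ceB$dlogits * S * S
  dblog <- (dbsym + dbsym[dec$swapidx, , drop = FALSE]) / 2
  bw <- nn_linear_bwd(par$adj2, dec$hP, dblog)
  g$adj2$W <- bw$dW; g$adj2$b <- bw$db
  dhP <- nn_relu_bwd(dec$hP0, bw$dX)
  bw <- nn_linear_bwd(par$adj1, dec$P, dhP)
  g$adj1$W <- bw$dW; g$adj1$b <- bw$db
  k <- ncol(dec$Hn)
  dPprod <- bw$dX[, seq_len(k), drop = FALSE]
  dPsum <- bw$dX[, (k + 1L):(2L * k), drop = FALSE]
  dHn <- rowsum(dPprod * dec$Hn[dec$I2, , drop = FALSE], dec$I1) +
    rowsum(dPprod * dec$Hn[dec$I1, , drop = FALSE], dec$I2) +
    rowsum(dPsum, dec$I1) + rowsum(dPsum, dec$I2)
  bw <- nn_linear_bwd(par$enh, dec$G, dHn)
  g$enh$W <- bw$dW; g$enh$b <- bw$db
  dain <- from_blocks(bw$dX[, seq_len(At), drop = FALSE], S * At)
  D <- ncol(enc$mu)
  nodeS <- rep(seq_len(n), each = S)
  dz_enh <- rowsum(bw$dX[, (At + S + 1L):(At + S + D), drop = FALSE], nodeS)

  # annotation head: gradient reaches alog through the CE and, for
  # non-forced samples, through the downstream use of aprob
  dain[dec$forceA, ] <- 0
  daprob_blocks <- to_blocks(dain, At)
  aprob_blocks <- to_blocks(dec$aprob, At)
  dalog_next <- from_blocks(
    nn_block_softmax_bwd(aprob_blocks, daprob_blocks, At), S * At)
  dalog <- cfg$alpha * S * from_blocks(ceA$dlogits, S * At) + dalog_next
  bw <- nn_linear_bwd(par$decA2, dec$hA, dalog)
  g$decA2$W <- bw$dW; g$decA2$b <- bw$db
  dhA2 <- nn_relu_bwd(dec$hA0, bw$dX)
  bw <- nn_linear_bwd(par$decA1, dec$XA, dhA2)
  g$decA1$W <- bw$dW; g$decA1$b <- bw$db
  dz <- dz_enh + bw$dX[, seq_len(D), drop = FALSE]
  dtin <- bw$dX[, (D + ncol(cond) + 1L):(D + ncol(cond) + S), drop = FALSE]

  # size head
  dtin[dec$forceT, ] <- 0
  dtlog <- cfg$alpha * ceT$dlogits +
    nn_block_softmax_bwd(dec$tprob, dtin, S)
  bw <- nn_linear_bwd(par$decT2, dec$hT, dtlog)
  g$decT2$W <- bw$dW; g$decT2$b <- bw$db
  dhT <- nn_relu_bwd(dec$hT0, bw$dX)
  bw <- nn_linear_bwd(par$decT1, dec$XT, dhT)
  g$decT1$W <- bw$dW; g$decT1$b <- bw$db
  dz <- dz + bw$dX[, seq_len(D), drop = FALSE]

  # latent heads: z = mu + exp(lv/2)*eps; KL terms
  dmu <- dmu + dz + cfg$beta * enc$mu / n
  dlv <- dz * eps * 0.5 * exp(enc$lv / 2) +
    cfg$beta * 0.5 * (exp(enc$lv) - 1) / n
  dlv[enc$lv0 < -8 | enc$lv0 > 8] <- 0
  bw <- nn_linear_bwd(par$mu, enc$h, dmu)
  g$mu$W <- bw$dW; g$mu$b <- bw$db
  dh <- bw$dX
  bw <- nn_linear_bwd(par$lv, enc$h, dlv)
  g$lv$W <- bw$dW; g$lv$b <- bw$db
  dh <- dh + bw$dX
  dh <- nn_relu_bwd(enc$h0, dh)
  bw <- nn_linear_bwd(par$enc1, enc$X, dh)
  g$enc1$W <- bw$dW; g$enc1$b <- bw$db
  dx <- bw$dX[, seq_len(cfg$d_x), drop = FALSE]

  # catalyst embedding
  bw <- nn_linear_bwd(par$embT, bm$T, dx)
  g$embT$W <- bw$dW; g$embT$b <- bw$db
  bw <- nn_linear_bwd(par$embA2, emb$hA, dx)
  g$embA2$W <- bw$dW; g$embA2$b <- bw$db
  dhA <- nn_relu_bwd(emb$hA0, bw$dX)
  bw <- nn_linear_bwd(par$embA1, bm$A, dhA)
  g$embA1$W <- bw$dW; g$embA1$b <- bw$db
  bw <- nn_linear_bwd(par$embB2, emb$hB, dx)
  g$embB2$W <- bw$dW; g$embB2$b <- bw$db
  dhB <- nn_relu_bwd(emb$hB0, bw$dX)
  bw <- nn_linear_bwd(par$embB1, bm$B, dhB)
  g$embB1$W <- bw$dW; g$embB1$b <- bw$db

  list(grads = g,
       comp = list(total = total, recons = recons, kl = kl,
                   prediction = lpred))
}

## ---- evaluation / checkpoints ------------------------------------------

#' Regression metrics of a model on records
#' @param model a [catvae] model (possibly carrying a surrogate).
#' @param records reaction records.
#' @return list with `rmse`, `mae`, `r2`.
#' @export
evaluate_model <- function(model, records) {
  yhat <- predict(model, records)
  y <- records$target
  list(rmse = sqrt(mean((yhat - y)^2)), mae = mean(abs(yhat - y)),
       r2 = 1 - sum((yhat - y)^2) / max(sum((y - mean(y))^2), 1e-12))
}

#' Pre-train a model on a curated reaction dataset
#'
#' Splits the records 90:5:5, trains one model per configured seed on the
#' training split (with node-shuffle augmentation when
#' `config$augment_orders > 1`), evaluates each on the test split, and
#' returns the best model (by validation RMSE) with the per-seed metric
#' report (mean and standard deviation across seeds).
#'
#' @param records curated reaction records.
#' @param config a [catvae_config].
#' @param vocab optional [cat_vocabulary]; built from the catalysts at 68
#'   atom types when omitted.
#' @param split_seed seed of the 90:5:5 split.
#' @return an object of class `catvae_checkpoint`: list with `model`,
#'   `vocab`, `config`, `metrics`, `split`.
#' @export
pretrain <- function(records, config = catvae_config(), vocab = NULL,
                     split_seed = 1L) {
  if (is.null(vocab)) {
    vocab <- build_vocabulary(records$catalyst, max_atom_types = 68L,
                              max_nodes = 100L)
  }
  .check_vocab_coverage(vocab, records)
  sp <- split_dataset(records, c(90, 5, 5), seed = split_seed)
  mw_edges <- unique(stats::quantile(sp$train$catalyst_mw,
                                     probs = seq_len(config$mw_bins - 1L) /
                                       config$mw_bins,
                                     type = 7, names = FALSE))
  per_seed <- list(); best <- NULL; best_val <- Inf
  for (sd in config$seeds) {
    m <- catvae(vocab, config, seed = sd, mw_edges = mw_edges)
    m <- catvae_train(m, sp$train, seed = sd)
    ev <- evaluate_model(m, if (nrow(sp$test)) sp$test else sp$train)
    vl <- if (nrow(sp$validation)) evaluate_model(m, sp$validation)$rmse
          else ev$rmse
    per_seed[[as.character(sd)]] <- ev
    if (vl < best_val) { best_val <- vl; best <- m }
  }
  metrics <- .metric_report(per_seed)
  structure(list(model = best, vocab = vocab, config = config,
                 metrics = metrics, split = sp),
            class = "catvae_checkpoint")
}

#' Fine-tune a pre-trained checkpoint on a downstream dataset
#'
#' Loads the whole pre-trained model (encoder, decoder, predictor) and
#' continues training on the new records. For yield targets the original
#' predictor head is updated; for other target kinds (or when
#' `config$surrogate != "none"`) a surrogate regressor is fitted on the
#' latent-mean + condition features and attached to the model.
#'
#' @param checkpoint a `catvae_checkpoint` from [pretrain()].
#' @param records downstream reaction records.
#' @param config optional [catvae_config] override (defaults to the
#'   checkpoint's).
#' @param seed training seed.
#' @return an updated `catvae_checkpoint`.
#' @export
finetune <- function(checkpoint, records, config = NULL, seed = 1L) {
  cfg <- config %||% checkpoint$config
  model <- checkpoint$model
  model$config <- cfg
  .check_vocab_coverage(model$vocab, records)
  model <- catvae_train(model, records, seed = seed)
  use_surrogate <- cfg$surrogate != "none" || records$target_kind[1] != "yield"
  if (use_surrogate) {
    mats <- lapply(records$catalyst, encode_catalyst_smiles, model = model)
    cond <- embed_condition(model, records)
    lat <- cvae_encode(model, embed_catalyst(model, mats), cond, sample = FALSE)
    kind <- if (cfg$surrogate == "none") "random_forest" else cfg$surrogate
    model$surrogate <- fit_surrogate(cbind(lat$mean, cond), records$target,
                                     model_kind = kind, seed = seed)
  }
  ev <- evaluate_model(model, records)
  structure(list(model = model, vocab = model$vocab, config = cfg,
                 metrics = .metric_report(list(`1` = ev)), split = NULL),
            class = "catvae_checkpoint")
}

.check_vocab_coverage <- function(vocab, records) {
  mols <- parse_smiles(unique(records$catalyst))
  elems <- unique(unlist(lapply(mols, function(m) if (!is.null(m)) m$atoms)))
  missing <- setdiff(elems, vocab$atom_types)
  if (length(missing)) {
    stop("vocabulary does not cover element(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

.metric_report <- function(per_seed) {
  tab <- do.call(rbind, lapply(per_seed, as.data.frame))
  list(per_seed = tab,
       mean = colMeans(tab),
       sd = apply(tab, 2, stats::sd))
}

#' Save / load a model checkpoint directory
#'
#' Weights are stored as RDS; the vocabulary, configuration and metrics as
#' JSON for auditability.
#'
#' @param checkpoint a `catvae_checkpoint`.
#' @param dir directory to create.
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns a `catvae_checkpoint`.
#' @export
save_checkpoint <- function(checkpoint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(checkpoint$model, file.path(dir, "weights.rds"))
  vocab_to_json(checkpoint$vocab, file.path(dir, "vocabulary.json"))
  jsonlite::write_json(unclass(checkpoint$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(checkpoint$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @param dir checkpoint directory.
#' @export
load_checkpoint <- function(dir) {
  model <- readRDS(file.path(dir, "weights.rds"))
  structure(list(model = model,
                 vocab = model$vocab,
                 config = model$config,
                 metrics = jsonlite::read_json(file.path(dir, "metrics.json"),
                                               simplifyVector = TRUE),
                 split = NULL),
            class = "catvae_checkpoint")
}

#' @export
print.catvae_checkpoint <- function(x, ...) {
  cat("<catvae_checkpoint>\n")
  print(x$model)
  if (!is.null(x$metrics$mean)) {
    cat(sprintf("  test metrics (mean over seeds): rmse=%.3f mae=%.3f r2=%.3f\n",
                x$metrics$mean["rmse"], x$metrics$mean["mae"],
                x$metrics$mean["r2"]))
  }
  invisible(x)
}
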