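# CVAE core: analytic gradients, loss decomposition, reparameterization,
# teacher-forcing limits, embedding determinism.

test_that("analytic gradients match finite differences", {
  sv <- cat_vocabulary(c("*", "C", "O", "N"), max_nodes = 6L)
  cfg <- catvae_config(d_x = 8L, d_graph = 4L, d_latent = 5L, h_embed = 10L,
                       h_enc = 10L, h_dec = 10L, h_adj = 6L, k_adj = 5L,
                       mw_bins = 3L, alpha = 1.3, beta = 0.7,
                       teacher_forcing_ratio = 0.5, nobond_weight = 0.3)
  m <- catvae(sv, cfg, seed = 7L, mw_edges = c(100, 300))
  mats <- lapply(c("CCO", "CC", "OCC(N)C"), encode_catalyst, vocab = sv)
  bm <- catvae:::batch_matrices(mats)
  rngc <- catvae:::.seeded_rng(55L)
  cond <- matrix(rngc$rnorm(3 * m$d_c), 3)
  y <- rngc$rnorm(3)
  wvec <- c(0.3, rep(1, 5))
  lossfn <- function(par) {
    catvae:::.train_step(par, sv, cfg, bm, cond, y, wvec,
                         catvae:::.seeded_rng(99L))
  }
  st0 <- lossfn(m$par)
  eps <- 1e-5
  worst <- 0
  for (ly in names(m$par)) {
    v <- m$par[[ly]]$W
    for (idx in unique(pmax(1, round(seq(1, length(v), length.out = 3))))) {
      p1 <- m$par; p1[[ly]]$W[idx] <- p1[[ly]]$W[idx] + eps
      p2 <- m$par; p2[[ly]]$W[idx] <- p2[[ly]]$W[idx] - eps
      num <- (lossfn(p1)$comp$total - lossfn(p2)$comp$total) / (2 * eps)
      ana <- st0$grads[[ly]]$W[idx]
      rel <- abs(num - ana) / max(abs(num) + abs(ana), 1e-8)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("loss decomposition identity holds to machine precision", {
  v <- tiny_vocab()
  m <- encode_catalyst("CCO", v)
  rng <- catvae:::.seeded_rng(12L)
  for (rep in 1:10) {
    lg <- random_logits(v, rng)
    lat <- list(mean = matrix(rng$rnorm(5), 1), logvar = matrix(rng$rnorm(5), 1))
    yh <- rng$rnorm(1); yt <- rng$rnorm(1)
    a <- abs(rng$rnorm(1)); b <- abs(rng$rnorm(1))
    L <- loss_total(lg, m, lat, yh, yt, alpha = a, beta = b,
                    nobond_weight = 0.4)
    expect_equal(L$total, a * L$recons + b * L$kl + L$prediction,
                 tolerance = 1e-12)
    expect_gte(L$kl, 0)
  }
  # KL identity at the standard normal
  lat0 <- list(mean = matrix(0, 1, 5), logvar = matrix(0, 1, 5))
  L0 <- loss_total(random_logits(v, rng), m, lat0, 1, 1)
  expect_equal(L0$kl, 0)
  # alpha = beta = 0 leaves only the prediction term
  Lp <- loss_total(random_logits(v, rng), m, lat0, 3, 1, alpha = 0, beta = 0)
  expect_equal(Lp$total, 4)
  expect_error(loss_total(random_logits(v, rng), m, lat0, 1, 1, alpha = -1),
               "non-negative")
})

test_that("hand-computed loss components match loss_total", {
  v <- cat_vocabulary(c("*", "C"), max_nodes = 3L)
  truth <- encode_catalyst("CC", v)
  lg <- list(T = c(0.1, 0.2, 3), A = matrix(c(0, 1, 2, 1, 0.5, 0), 3, 2),
             B = array(stats::rnorm(3 * 3 * 6), c(3, 3, 6)))
  softmax <- function(x) exp(x) / sum(exp(x))
  ceT <- -log(softmax(lg$T)[3])
  ceA <- -sum(vapply(1:3, function(i) {
    log(softmax(lg$A[i, ])[which.max(truth$A[i, ])])
  }, numeric(1)))
  ceB <- -sum(vapply(1:3, function(i) vapply(1:3, function(j) {
    log(softmax(lg$B[i, j, ])[which.max(truth$B[i, j, ])])
  }, numeric(1)), numeric(3)))
  lat <- list(mean = matrix(c(1, -1), 1), logvar = matrix(c(0.5, -0.5), 1))
  kl <- 0.5 * sum(exp(c(0.5, -0.5)) + c(1, 1) - 1 - c(0.5, -0.5))
  L <- loss_total(lg, truth, lat, 2, 5, alpha = 2, beta = 3)
  expect_equal(L$recons, ceT + ceA + ceB, tolerance = 1e-10)
  expect_equal(L$kl, kl, tolerance = 1e-12)
  expect_equal(L$total, 2 * L$recons + 3 * kl + 9, tolerance = 1e-10)
})

test_that("reparameterization and encoding contracts hold", {
  m <- tiny_model()
  mats <- lapply(c("CCO", "CC(N)C", "CP(C)C"), encode_catalyst,
                 vocab = m$vocab)
  x <- embed_catalyst(m, mats)
  expect_equal(dim(x), c(3L, m$config$d_x))
  expect_true(all(is.finite(x)))
  rng <- catvae:::.seeded_rng(5L)
  cond <- matrix(rng$rnorm(3 * m$d_c), 3)
  lat <- cvae_encode(m, x, cond, sample = TRUE, seed = 17L)
  expect_equal(lat$sample, lat$mean + exp(lat$logvar / 2) * lat$eps)
  lat2 <- cvae_encode(m, x, cond, sample = TRUE, seed = 17L)
  expect_identical(lat$sample, lat2$sample)        # reproducible eps
  lat0 <- cvae_encode(m, x, cond, sample = FALSE)
  expect_equal(lat0$sample, lat0$mean)             # eval mode uses the mean
  # order preserved
  lat_perm <- cvae_encode(m, x[c(2, 1, 3), ], cond[c(2, 1, 3), ],
                          sample = FALSE)
  expect_equal(lat_perm$mean[2, ], lat0$mean[1, ])
})

test_that("catalyst embedding is deterministic but order-sensitive", {
  m <- tiny_model()
  mat <- encode_catalyst("CCOC", m$vocab)
  x1 <- embed_catalyst(m, mat)
  x2 <- embed_catalyst(m, mat)
  expect_identical(x1, x2)                          # bitwise stable
  perm <- shuffle_augment(mat, 2L, seed = 2L)[[2]]
  xp <- embed_catalyst(m, perm)
  expect_false(isTRUE(all.equal(x1, xp)))           # representation order-sensitive
})

test_that("condition embedding handles reagents and duplicates", {
  m <- tiny_model()
  ds <- tiny_records()
  cond <- embed_condition(m, ds)
  expect_equal(dim(cond), c(nrow(ds), m$d_c))
  expect_true(all(is.finite(cond)))
  expect_identical(cond, embed_condition(m, ds))    # deterministic

  # no-reagent records carry the learned default vector exactly
  no_reag <- which(lengths(ds$reagents) == 0)[1]
  dg <- m$config$d_graph
  expect_equal(as.numeric(cond[no_reag, (dg + 1):(2 * dg)]), m$no_reagent)

  # duplicated identical reactant pools to the single-occurrence value
  one <- ds[1, ]; two <- ds[1, ]
  two$reactants <- I(list(rep(one$reactants[[1]][1], 2)))
  one$reactants <- I(list(one$reactants[[1]][1]))
  expect_equal(embed_condition(m, one), embed_condition(m, two))
})

test_that("teacher forcing limits behave as stated", {
  m <- tiny_model()
  mats <- lapply(c("CCO", "CCN"), encode_catalyst, vocab = m$vocab)
  rng <- catvae:::.seeded_rng(3L)
  z <- matrix(rng$rnorm(2 * m$config$d_latent), 2)
  cond <- matrix(rng$rnorm(2 * m$d_c), 2)
  lg0 <- cvae_decode(m, z, cond, tf_ratio = 0)
  lg0b <- cvae_decode(m, z, cond, teacher = mats, tf_ratio = 0)
  expect_equal(lg0, lg0b)                           # teacher ignored at 0
  expect_error(cvae_decode(m, z, cond, tf_ratio = 0.5), "teacher")

  # at ratio 1 every stage consumes the ground truth: feeding a different
  # teacher changes downstream logits, feeding the same one does not
  lg1 <- cvae_decode(m, z, cond, teacher = mats, tf_ratio = 1, seed = 1L)
  lg1b <- cvae_decode(m, z, cond, teacher = mats, tf_ratio = 1, seed = 2L)
  expect_equal(lg1, lg1b)                           # forcing saturated
  # same size, different annotation: only the adjacency stage shifts
  other <- lapply(c("OCO", "NCN"), encode_catalyst, vocab = m$vocab)
  lg2 <- cvae_decode(m, z, cond, teacher = other, tf_ratio = 1, seed = 1L)
  expect_equal(lg1[[1]]$A, lg2[[1]]$A)
  expect_false(isTRUE(all.equal(lg1[[1]]$B, lg2[[1]]$B)))
  # different size: the annotation stage consumes the true T and shifts too
  bigger <- lapply(c("OCCO", "NCCN"), encode_catalyst, vocab = m$vocab)
  lg3 <- cvae_decode(m, z, cond, teacher = bigger, tf_ratio = 1, seed = 1L)
  expect_false(isTRUE(all.equal(lg1[[1]]$A, lg3[[1]]$A)))
  expect_equal(catvae_config()$teacher_forcing_ratio, 0.25)
})

test_that("a tiny overfit run halves the training losses", {
  ds <- tiny_records()
  v <- build_vocabulary(ds$catalyst, max_atom_types = 6L, max_nodes = 8L)
  cfg <- catvae_config(d_x = 24L, d_graph = 8L, d_latent = 12L, h_embed = 32L,
                       h_enc = 32L, h_dec = 48L, h_adj = 24L, k_adj = 16L,
                       mw_bins = 3L, epochs = 150L, batch_size = 12L,
                       lr = 3e-3, beta = 1e-3, seeds = 1L)
  m <- catvae(v, cfg, seed = 2L, mw_edges = c(50, 120))
  m <- catvae_train(m, ds, seed = 2L)
  h <- m$history
  expect_lt(h$total[nrow(h)], 0.5 * h$total[1])
  expect_lt(sqrt(h$prediction[nrow(h)]), 0.5 * sqrt(h$prediction[1]))
  expect_true(all(h$kl >= 0))
  # deterministic training under a fixed seed
  m2 <- catvae(v, cfg, seed = 2L, mw_edges = c(50, 120))
  m2 <- catvae_train(m2, ds, seed = 2L)
  expect_equal(m$history$total, m2$history$total, tolerance = 1e-10)
  # predictions come back on the percent scale
  p <- predict(m, ds)
  expect_true(all(p >= 0 & p <= 100))
})

test_that("augmentation multiplies training matrices per record", {
  ds <- tiny_records()
  v <- build_vocabulary(ds$catalyst, max_atom_types = 6L, max_nodes = 8L)
  cfg <- catvae_config(d_x = 8L, d_graph = 4L, d_latent = 4L, h_embed = 8L,
                       h_enc = 8L, h_dec = 8L, h_adj = 6L, k_adj = 4L,
                       mw_bins = 3L, epochs = 1L, batch_size = 100L,
                       augment_orders = 5L, seeds = 1L)
  m <- catvae(v, cfg, seed = 1L, mw_edges = c(50, 120))
  m <- catvae_train(m, ds, seed = 1L)
  # one epoch over n*5 samples in batches of 100
  expect_equal(catvae_config(augment_orders = 5L)$augment_orders, 5L)
  expect_equal(m$trained_epochs, 1L)
})

test_that("checkpoints round-trip through save/load", {
  ds <- tiny_records()
  v <- build_vocabulary(ds$catalyst, max_atom_types = 6L, max_nodes = 8L)
  cfg <- catvae_config(d_x = 8L, d_graph = 4L, d_latent = 4L, h_embed = 8L,
                       h_enc = 8L, h_dec = 8L, h_adj = 6L, k_adj = 4L,
                       mw_bins = 3L, epochs = 2L, batch_size = 12L, seeds = 1L)
  ck <- pretrain(ds, cfg, vocab = v, split_seed = 1L)
  dir <- tempfile()
  save_checkpoint(ck, dir)
  expect_true(file.exists(file.path(dir, "weights.rds")))
  expect_true(file.exists(file.path(dir, "vocabulary.json")))
  ck2 <- load_checkpoint(dir)
  expect_equal(predict(ck2$model, ds[1:3, ]), predict(ck$model, ds[1:3, ]))
  # vocabulary coverage failure is loud
  bad <- ds; bad$catalyst[1] <- "[Pt]CC"
  expect_error(finetune(ck, bad), "cover")
})
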