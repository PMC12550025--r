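# Shared fixtures, memoised per test session so expensive objects (the
# 1000-record curation fixture, the trained desk-scale model) are built
# once and reused across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

tiny_vocab <- function(S = 8L) {
  cat_vocabulary(c("*", "C", "O", "N", "P", "S", "Cl", "Pd"),
                 max_nodes = S)
}

# One-hot logits for a hand-built molecule under a vocabulary.
onehot_logits <- function(smiles, vocab) {
  unclass(encode_catalyst(smiles, vocab))
}

# Random matrix logits: random declared size, N(0,1) atom/bond scores.
random_logits <- function(vocab, rng) {
  S <- vocab$max_nodes; At <- length(vocab$atom_types)
  Bt <- length(vocab$bond_types)
  Tv <- numeric(S); Tv[1L + rng$sample(S - 1L, 1)] <- 1
  B <- array(rng$rnorm(S * S * Bt), c(S, S, Bt))
  list(T = Tv, A = matrix(rng$rnorm(S * At), S, At), B = B)
}

fixture_records_1000 <- function() {
  memo("records1000", function() {
    make_reaction_dataset(fixture_spec(n_records = 1000L, seed = 101L,
                                       max_atoms = 12L))
  })
}

fixture_records_small <- function() {
  memo("records_small", function() {
    make_reaction_dataset(fixture_spec(n_records = 60L, seed = 5L,
                                       max_atoms = 10L))
  })
}

# Desk-scale study conditions: 200 single-fragment records of <= 12 atoms,
# noise sigma 5. Trained once; reused by the learning-sanity, sampling and
# generation tests.
desk_training <- function() {
  memo("desk", function() {
    spec <- fixture_spec(n_records = 200L, seed = 11L, max_atoms = 12L,
                         noise_sigma = 5, multi_fragment_fraction = 0)
    records <- make_reaction_dataset(spec)
    vocab <- build_vocabulary(records$catalyst, max_atom_types = 12L,
                              max_nodes = max(records$catalyst_atom_count) + 2L)
    cfg <- catvae_config(d_latent = 32L, k_adj = 40L, h_adj = 64L,
                         epochs = 800L, batch_size = 64L, lr = 3e-3,
                         alpha = 1, beta = 1e-3, seeds = 1L)
    model <- catvae(vocab, cfg, seed = 1L,
                    mw_edges = stats::quantile(records$catalyst_mw, 1:7 / 8,
                                               names = FALSE))
    model <- catvae_train(model, records, seed = 1L)
    list(records = records, vocab = vocab, model = model,
         truth = canonical_smiles(records$catalyst))
  })
}

# A small untrained model over the tiny vocabulary, for contract tests
# that do not need learned weights.
tiny_model <- function() {
  memo("tiny_model", function() {
    catvae(tiny_vocab(), catvae_config(d_x = 16L, d_graph = 8L,
                                       d_latent = 8L, h_embed = 24L,
                                       h_enc = 24L, h_dec = 24L,
                                       h_adj = 12L, k_adj = 10L,
                                       mw_bins = 3L),
           seed = 42L, mw_edges = c(100, 300))
  })
}

tiny_records <- function(n = 12L) {
  memo(paste0("tiny_records", n), function() {
    make_reaction_dataset(fixture_spec(n_records = n, seed = 21L,
                                       max_atoms = 6L,
                                       elements = c("C", "C", "N", "O"),
                                       multi_fragment_fraction = 0))
  })
}
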