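# catvae

A reaction-conditioned conditional variational autoencoder (CVAE) for
homogeneous catalyst design in R. The package is aimed at computational and
synthetic chemists who want, from a table of reaction records, a single
model that both **predicts a catalytic endpoint** (percent yield, binding
energy, ΔΔG‡) and **generates candidate catalysts** appropriate to a given
reaction context, with Bayesian optimization over the latent space for
inverse design.

## The model

A catalyst is a one-hot matrix triple **M** = (*T*, *A*, *B*): a size
indicator *T* ∈ {0,1}^S, a node annotation matrix *A* ∈ {0,1}^(S×Aₜ) and a
symmetric bond tensor *B* ∈ {0,1}^(S×S×Bₜ). At the defaults
(S = 100, Aₜ = 68 atom types including no-atom, Bₜ = 6 bond types including
no-bond) the representation flattens to 100 + 100·68 + 100·100·6 = **66 900**
dimensions.

The surrounding reaction enters as a condition vector **c**: graph-attention
embeddings of reactants, reagents (a learned default vector when absent) and
product, the reaction time, and a one-hot molecular-weight cluster of the
catalyst. A joint CVAE learns

- an encoder *Q*(**z** | **x**, **c**) over the catalyst embedding **x**,
- a three-stage sequential decoder *P*(**M** | **z**, **c**) (size →
  annotation → outer-product-seeded adjacency) with teacher forcing at
  ratio 0.25,
- a predictor *f*(**z**, **c**) on the latent mean,

under the loss **L** = α·L_recons + β·L_KL + L_prediction. Decoded matrices
become valid molecules through a rule-based correction: bonds are assigned
in descending probability order with valence checking after each addition
(formal charges are added where that legalizes the local valence; carbon is
never charged), followed by aromatic clearance, sanitization, and removal of
unconnected carbon atoms.

Generated sets are scored with the standard metrics (Valid, Valid(Task),
Unique, Novel, IntDiv, SNN) on 2048-bit ECFP4 Tanimoto distances, and
inverse design runs Gaussian-process Bayesian optimization over the latent
box with chemistry-aware penalty/reward terms.

Everything is exercisable offline: a fixture module generates desk-scale
synthetic reaction datasets whose target is a recorded deterministic
function of molecular descriptors plus noise, so curation, training,
generation and optimization all have recoverable ground truth.

## Worked example

```r
library(catvae)

# 1. synthetic desk-scale reaction data with a known target function
spec <- fixture_spec(n_records = 120, seed = 7, max_atoms = 10,
                     multi_fragment_fraction = 0, noise_sigma = 5)
reactions <- make_reaction_dataset(spec)
reactions <- curate_reactions(reactions, seed = 7)

# 2. vocabulary sized from the data, then the model
vocab <- build_vocabulary(reactions$catalyst, max_atom_types = 12,
                          max_nodes = max(reactions$catalyst_atom_count) + 2)
print(vocab)
#> <cat_vocabulary: S=12, 12 atom types, 6 bond types, 1020 flat dims>

config <- catvae_config(d_latent = 32, k_adj = 40, h_adj = 64,
                        epochs = 400, lr = 3e-3, beta = 1e-3, seeds = 1)
model <- catvae(vocab, config, seed = 1,
                mw_edges = quantile(reactions$catalyst_mw, 1:7/8, names = FALSE))
model <- catvae_train(model, reactions, seed = 1)   # ~3 min on one CPU

# 3. prediction quality and exact-reconstruction rate on the training set
round(unlist(evaluate_model(model, reactions)), 3)
#>  rmse   mae    r2
#> 0.151 0.117 1.000

training <- model_latents(model, reactions)
logits <- cvae_decode(model, training$means, training$cond)
recon <- vapply(logits, function(l) reconstruct(l, vocab)$smiles, character(1))
mean(recon == canonical_smiles(reactions$catalyst), na.rm = TRUE)
#> [1] 0.625

# 4. generate 200 catalysts and score them
scheme <- sampling_scheme("random_latent_random_condition", seed = 2)
gen <- generate(200, scheme, model, training)
evaluate_generation(gen$smiles, reactions$catalyst, task_rule = "single_fragment")
#> <generation_report: n=200 valid=0.510 unique=0.500 novel=0.500
#>                     intdiv=0.866 snn=0.113 valid_task=0.120>

# 5. inverse design around a known catalyst
spec_obj <- objective_spec("maximize", condition = training$cond[1, ])
run <- optimization_run("around_molecule", rounds = 5, calls_per_round = 8,
                        top_k = 5, radius = 2, seed = 3)
result <- bayes_optimize(spec_obj, run, model,
                         anchor_latent = training$means[1, ])
print(result)
#> <optimization_result: 40 evaluations, 22 candidates, best score 75.7814>
head(result$candidates, 3)
#>   round           smiles    score
#> 1     1 CCC1SC2(C1P2)C.O 75.78137
#> 2     1   CCCSC1(C)CP1.O 73.26781
#> 3     1     CCCSC1(O)CP1 68.80322
```

Reading the numbers: the predictor essentially memorizes the 120-record
training set (RMSE 0.15 percent-yield units); 62.5% of training catalysts
decode back to their exact canonical structure after 400 epochs (longer
desk-scale runs reach ~100%, see the methods vignette); random-box sampling
produces 51% chemically valid molecules, nearly all distinct and novel, with
high internal diversity (0.87) and low nearest-neighbour similarity to the
tiny training set (0.11); and the optimizer's candidates are ranked by the
predicted yield under the chosen reaction condition.

A command-line entry point wrapping the same pipeline stages
(`fixtures`, `curate`, `pretrain`, `finetune`, `generate`, `evaluate`,
`optimize`) ships as `inst/cli/catvae.R`:

```sh
Rscript inst/cli/catvae.R fixtures --out_dir out/fx --seed 5 --n_records 200
Rscript inst/cli/catvae.R curate   --out_dir out/cur --input out/fx/reactions.csv
```

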