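# Graph attention encoder for condition molecules (reactants, reagents,
# product). Two attention layers with mean pooling produce a fixed-width
# embedding per molecule. The weights are drawn once from the model seed
# and held fixed (a deterministic random-feature graph encoder); the
# trainable encoder/decoder/predictor adapt to this embedding. See the
# methods vignette for the rationale.

gat_init <- function(rng, node_width, edge_width, dg) {
  list(
    l1 = list(W = matrix(rng$rnorm(node_width * dg, 0, sqrt(2 / (node_width + dg))),
                         node_width, dg),
              a_src = rng$rnorm(dg, 0, 0.5), a_dst = rng$rnorm(dg, 0, 0.5),
              a_edge = rng$rnorm(edge_width, 0, 0.5)),
    l2 = list(W = matrix(rng$rnorm(dg * dg, 0, sqrt(1 / dg)), dg, dg),
              a_src = rng$rnorm(dg, 0, 0.5), a_dst = rng$rnorm(dg, 0, 0.5),
              a_edge = rng$rnorm(edge_width, 0, 0.5)),
    dg = dg
  )
}

.leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# One attention layer over an undirected graph with self-loops.
.gat_layer <- function(layer, H, edges, edge_feats) {
  n <- nrow(H)
  Hw <- H %*% layer$W
  src <- as.numeric(Hw %*% layer$a_src)
  dst <- as.numeric(Hw %*% layer$a_dst)
  # neighbour lists including self-loop (zero edge features)
  out <- matrix(0, n, ncol(Hw))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- list(j = i, e = 0)
  if (nrow(edges)) {
    escore <- as.numeric(edge_feats %*% layer$a_edge)
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]
      nb[[i]]$j <- c(nb[[i]]$j, j); nb[[i]]$e <- c(nb[[i]]$e, escore[r])
      nb[[j]]$j <- c(nb[[j]]$j, i); nb[[j]]$e <- c(nb[[j]]$e, escore[r])
    }
  }
  for (i in seq_len(n)) {
    js <- nb[[i]]$j
    logit <- .leaky(src[i] + dst[js] + nb[[i]]$e)
    al <- exp(logit - max(logit)); al <- al / sum(al)
    out[i, ] <- as.numeric(al %*% Hw[js, , drop = FALSE])
  }
  tanh(out)
}

# Embed one molecule (cat_mol or mol_graph) to a length-dg vector.
gat_embed <- function(gat, molecule) {
  g <- if (inherits(molecule, "mol_graph")) molecule
       else featurize_molecule_graph(molecule)
  if (g$n_nodes == 0L) return(numeric(gat$dg))
  H <- .gat_layer(gat$l1, g$nodes, g$edges, g$edge_feats)
  H <- .gat_layer(gat$l2, H, g$edges, g$edge_feats)
  colMeans(H)
}
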