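# Independent oracles used across the suite.  These deliberately avoid the
# package's pruning/fitting code paths: enumeration, direct arithmetic, or
# third-party references (ape, Matrix) only.

# Exhaustive likelihood: sum over all internal-node state assignments and
# mixture categories, with transition matrices from transition_matrix()
# (itself cross-checked against Matrix::expm elsewhere).
oracle_loglik <- function(tree, aln, model) {
  rm <- clockshift:::model_q(model)
  rw <- clockshift:::model_rates(model)
  ns <- length(rm$labels)
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_along(rw$rates), function(k)
    lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(rm, tree$edge.length[e] * rw$rates[k])))
  part <- clockshift:::IUPAC_PARTIALS
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), tree$Nnode)))
  for (col in seq_len(ncol(aln))) {
    Lmix <- 0
    for (k in seq_along(rw$rates)) {
      s <- 0
      for (g in seq_len(nrow(grid))) {
        statevec <- integer(nn)
        statevec[(ntip + 1L):nn] <- grid[g, ]
        lik <- rm$pi[[statevec[root_node(tree)]]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          if (ch <= ntip) {
            tipp <- part[aln[ch, col], ]
            lik <- lik * sum(P[[k]][[e]][statevec[p], ] * tipp)
          } else {
            lik <- lik * P[[k]][[e]][statevec[p], statevec[ch]]
          }
        }
        s <- s + lik
      }
      Lmix <- Lmix + rw$weights[k] * s
    }
    total <- total + log(Lmix)
  }
  total
}

# Exhaustive parsimony: minimum changes over every internal-state assignment.
oracle_fitch <- function(tree, tip_states) {
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  lev <- sort(unique(as.character(tip_states)))
  grid <- as.matrix(expand.grid(rep(list(lev), tree$Nnode)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- c(as.character(tip_states), grid[g, ])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Random bifurcating tree via ape, converted through Newick text.
random_tree <- function(ntips, seed) {
  set.seed(seed)
  parse_newick(ape::write.tree(ape::rtree(ntips)))
}

random_alignment <- function(ntips, nsites, seed, taxa) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), ntips * nsites, replace = TRUE),
              nrow = ntips, dimnames = list(taxa, NULL))
  clockshift:::new_alignment(m)
}

# small rooted ultrametric tree (depth 0.1) with a class-1 focal branch
small_clock_tree <- function() {
  parse_newick(paste0("((A:0.04,B:0.04):0.06,((C:0.05,D:0.05)#1:0.03,",
                      "(E:0.06,F:0.06):0.02):0.02);"))
}
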