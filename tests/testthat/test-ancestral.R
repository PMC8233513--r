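test_that("zero-length branches pin the ancestral state", {
  tr <- parse_newick("((A:0,B:0):0.1,C:0.4);")
  m <- matrix(c("A", "A", "G"), ncol = 1, dimnames = list(c("A", "B", "C"), NULL))
  post <- marginal_reconstruction(tr, clockshift:::new_alignment(m),
                                  hky_params(kappa = 2, pi = rep(.25, 4)))
  anc_ab <- which(post$node_names == paste0("node", mrca_node(tr, c("A", "B"))))
  expect_equal(unname(post$prob[anc_ab, 1, "A"]), 1, tolerance = 1e-9)
})

test_that("marginal posteriors match brute-force joint enumeration", {
  tr <- parse_newick("((A:0.15,B:0.34):0.12,C:0.4);")
  mod <- hky_params(kappa = 3, pi = c(.35, .2, .15, .3), alpha = .6, ncat = 2)
  m <- matrix(c("A", "C", "A",
                "G", "G", "T"), nrow = 3,
              dimnames = list(c("A", "B", "C"), NULL))
  aln <- clockshift:::new_alignment(m)
  post <- marginal_reconstruction(tr, aln, mod)

  # oracle: joint likelihood over (root, internal) states, marginalized by hand
  rm <- hky_q(mod); rw <- clockshift:::model_rates(mod)
  ntip <- 3L
  for (col in 1:2) {
    for (node in 4:5) {
      marg <- numeric(4)
      for (k in seq_along(rw$rates)) {
        P <- lapply(seq_len(nrow(tr$edge)), function(e)
          transition_matrix(rm, tr$edge.length[e] * rw$rates[k]))
        for (s4 in 1:4) for (s5 in 1:4) {
          st <- c(match(m[, col], clockshift:::NUC), s4, s5)
          lik <- rm$pi[[st[4]]]
          for (e in seq_len(nrow(tr$edge))) {
            lik <- lik * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
          }
          marg[st[node]] <- marg[st[node]] + rw$weights[k] * lik
        }
      }
      marg <- marg / sum(marg)
      expect_equal(unname(post$prob[node - ntip, col, ]), marg,
                   tolerance = 1e-10)
    }
  }
})

test_that("posteriors sum to one and rooting does not change them", {
  tr <- fixture_primate_tree()
  mod <- hky_params(kappa = 4, pi = c(.3, .2, .2, .3), alpha = .8, ncat = 5)
  aln <- simulate_alignment(tr, mod, 120, c(1, 0.5, 0.35), seed = 31)
  post <- marginal_reconstruction(tr, aln, mod)
  expect_lt(max(abs(apply(post$prob, c(1, 2), sum) - 1)), 1e-10)

  # unrooted evaluation at the matching node gives identical posteriors
  # (reversible model: reconstruction is invariant to root placement)
  tru <- unroot_tree(tr)
  post_u <- marginal_reconstruction(tru, aln, mod)
  nm <- paste0("node", mrca_node(tru, c("Human", "Gibbon")))
  nm_r <- paste0("node", mrca_node(tr, c("Human", "Gibbon")))
  expect_equal(unname(post_u$prob[nm, , ]), unname(post$prob[nm_r, , ]),
               tolerance = 1e-8)
})

test_that("a clade-shared variant is reconstructed at the clade ancestor", {
  tr <- fixture_primate_tree()
  owm <- c("Rhesus_macaque", "Crab_eating_macaque", "Baboon", "Green_monkey")
  m <- matrix("A", n_tips(tr), 3, dimnames = list(tr$tip.label, NULL))
  m[owm, 2] <- "T"  # derived variant shared by all Old World monkeys
  post <- marginal_reconstruction(tr, clockshift:::new_alignment(m),
                                  hky_params(kappa = 4, pi = rep(.25, 4)))
  anc <- paste0("node", mrca_node(tr, owm))
  expect_equal(unname(post$map[anc, 2]), "T")
  expect_equal(unname(post$map[anc, 1]), "A")
})

test_that("extract_sites returns a tidy 1-based table matching the posterior", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 2, pi = rep(.25, 4))
  aln <- simulate_alignment(tr, mod, 20, seed = 8)
  post <- marginal_reconstruction(tr, aln, mod)
  tab <- extract_sites(post)
  expect_equal(nrow(tab), length(post$node_names) * 20L)
  i <- which(tab$node == post$node_names[2] & tab$column == 7L)
  expect_equal(tab$prob[i], unname(post$map_prob[2, 7]))
  expect_equal(tab$map_state[i], unname(post$map[2, 7]))
  expect_equal(tab$p_A[i] + tab$p_C[i] + tab$p_G[i] + tab$p_T[i], 1,
               tolerance = 1e-9)
  expect_error(extract_sites(post, nodes = "nope"), "unknown node")
  expect_error(extract_sites(post, columns = 999), "out of range")
})

test_that("Fitch: trivial, hand-checked, and exhaustive-oracle cases", {
  tr4 <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_min_changes(tr4, c(A = 1, B = 1, C = 1, D = 1))$changes, 0L)
  expect_equal(fitch_min_changes(tr4, c(A = 0, B = 1, C = 0, D = 1))$changes, 2L)

  for (seed in 1:12) {
    tr <- random_tree(8, seed + 300)
    set.seed(seed)
    states <- setNames(sample(0:1, 8, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) states[1] <- 1L - states[1]
    got <- fitch_min_changes(tr, states)
    expect_equal(got$changes, oracle_fitch(tr, states[tr$tip.label]))
    # the returned assignment realizes the optimal count
    st <- got$states
    expect_equal(sum(st[tr$edge[, 1]] != st[tr$edge[, 2]]), got$changes)
  }
})

test_that("Fitch count is invariant under 0/1 relabeling; wildcards work", {
  tr <- random_tree(7, 42)
  set.seed(2)
  states <- setNames(sample(0:1, 7, replace = TRUE), tr$tip.label)
  flipped <- setNames(1L - states, names(states))
  expect_equal(fitch_min_changes(tr, states)$changes,
               fitch_min_changes(tr, flipped)$changes)
  states[2] <- NA
  expect_lte(fitch_min_changes(tr, states)$changes,
             fitch_min_changes(tr, flipped)$changes)
  expect_error(fitch_min_changes(tr, states, missing = "error"), "missing state")
})
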