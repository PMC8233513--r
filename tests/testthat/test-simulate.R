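test_that("zero branch lengths give identical sequences; seeds reproduce", {
  tr <- small_clock_tree()
  tr$edge.length[] <- 0
  mod <- hky_params(kappa = 2, pi = c(.3, .2, .2, .3))
  aln <- simulate_alignment(tr, mod, 100, seed = 5)
  expect_true(all(apply(unclass(aln), 2, function(col) all(col == col[1]))))

  tr2 <- small_clock_tree()
  a1 <- simulate_alignment(tr2, mod, 500, seed = 9)
  a2 <- simulate_alignment(tr2, mod, 500, seed = 9)
  expect_identical(unclass(a1), unclass(a2))
  a3 <- simulate_alignment(tr2, mod, 500, seed = 10)
  expect_false(identical(unclass(a1), unclass(a3)))
})

test_that("simulated base composition follows the stationary frequencies", {
  tr <- parse_newick("(x:0.05,y:0.05);")
  pi <- c(.4, .25, .15, .2)
  aln <- simulate_alignment(tr, hky_params(kappa = 3, pi = pi), 40000, seed = 2)
  obs <- base_frequencies(aln)
  # multinomial sampling error at n = 80k characters
  expect_lt(max(abs(obs - pi)), 4 * sqrt(max(pi * (1 - pi)) / 80000))
})

test_that("pairwise distance re-estimation inverts the simulation", {
  tr <- parse_newick("(x:0.1,y:0.1);")   # total separation 0.2
  mod <- hky_params(kappa = 2, pi = rep(.25, 4))
  aln <- simulate_alignment(tr, mod, 20000, seed = 13)
  nll <- function(t) {
    tt <- tr; tt$edge.length <- c(t / 2, t / 2)
    -log_likelihood(tt, aln, mod)$lnL
  }
  t_hat <- optimize(nll, c(0.01, 1))$minimum
  # curvature-based SE of the distance estimate
  h <- 1e-4
  se <- 1 / sqrt((nll(t_hat + h) - 2 * nll(t_hat) + nll(t_hat - h)) / h^2)
  expect_lt(abs(t_hat - 0.2), 3 * se)
})

test_that("omega = 0 forbids nonsynonymous change; determinism holds", {
  tr <- small_clock_tree()
  tr$edge.length <- tr$edge.length * 4
  mod0 <- m0_params(kappa = 2, omega = 0, freq_mode = "equal")
  aln <- simulate_codon_alignment(tr, mod0, 150, seed = 3)
  gc <- clockshift:::genetic_code_tables()
  aa <- apply(unclass(aln), 1, function(ch) {
    cods <- clockshift:::codon_strings(ch)
    gc$aa[match(cods, gc$codons)]
  })
  expect_true(all(apply(aa, 1, function(z) length(unique(z)) == 1L)))
  b1 <- simulate_codon_alignment(tr, mod0, 80, seed = 4)
  b2 <- simulate_codon_alignment(tr, mod0, 80, seed = 4)
  expect_identical(unclass(b1), unclass(b2))
})

test_that("neutral M0 produces no stop codons and plausible divergence", {
  tr <- small_clock_tree()
  mod <- m0_params(kappa = 1, omega = 1, freq_mode = "equal")
  aln <- simulate_codon_alignment(tr, mod, 400, seed = 6)
  expect_silent(clockshift:::check_stop_codons(aln))
  # neutral, symmetric: nonsyn/syn substitution counts should be near the
  # genetic-code expectation (~2.8 single-step nonsyn per syn opportunity)
  gc <- clockshift:::genetic_code_tables()
  x <- clockshift:::codon_strings(unclass(aln)["C", ])
  y <- clockshift:::codon_strings(unclass(aln)["D", ])
  d <- which(x != y)
  one_step <- d[gc$ndiff[cbind(match(x[d], gc$codons),
                               match(y[d], gc$codons))] == 1L]
  aa_diff <- gc$aa[match(x[one_step], gc$codons)] !=
    gc$aa[match(y[one_step], gc$codons)]
  frac_nonsyn <- mean(aa_diff)
  # code-wide fraction of single-step changes that are nonsynonymous
  single <- gc$ndiff == 1L
  nonsyn <- outer(gc$aa, gc$aa, "!=")
  expected <- sum(single & nonsyn) / sum(single)
  expect_lt(abs(frac_nonsyn - expected), 0.12)
})

test_that("binary-trait simulator: iid limit and covariate dominance", {
  tr <- fixture_mammal_tree()
  n <- n_tips(tr)
  X <- cbind(rep(0, n))
  # decay huge -> independent; beta 0 -> Bernoulli(1/2)
  y <- unlist(lapply(1:40, function(i)
    simulate_binary_trait(tr, decay = 1e6, beta = 0, X, seed = i)))
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / length(y)))

  set.seed(1)
  x <- rnorm(n)
  y2 <- simulate_binary_trait(tr, decay = 1e6, beta = 50,
                              cbind(x), seed = 2)
  expect_true(all(y2[x > 0.2] == 1L) && all(y2[x < -0.2] == 0L))
})

test_that("tip-state correlation decays with patristic distance", {
  tr <- fixture_mammal_tree()
  D <- tip_distances(tr)
  near <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  X <- cbind(rep(0, n_tips(tr)))
  draws <- vapply(1:300, function(i)
    simulate_binary_trait(tr, decay = 0.02, beta = 0, X, seed = 7000 + i),
    integer(n_tips(tr)))
  agree_near <- mean(draws[near[1], ] == draws[near[2], ])
  agree_far <- mean(draws[far[1], ] == draws[far[2], ])
  expect_gt(agree_near, agree_far)
})

test_that("fixtures have the documented structure", {
  pr <- fixture_primate_tree()
  expect_equal(n_tips(pr), 13L)
  expect_equal(sum(pr$edge.class == 1L), 1L)
  stem <- which(pr$edge.class == 1L)
  owm <- c("Rhesus_macaque", "Crab_eating_macaque", "Baboon", "Green_monkey")
  expect_equal(pr$edge[stem, 2], mrca_node(pr, owm))
  hom <- resolve_branches(pr, list(mrca = c("Gibbon", "Human")))
  expect_true(all(pr$edge.class[hom] == 2L))
  expect_equal(sum(pr$edge.class == 2L), length(hom))
  # stem excluded by default; included on request
  pr2 <- fixture_primate_tree(include_hominoid_stem = TRUE)
  expect_equal(sum(pr2$edge.class == 2L), length(hom) + 1L)
  depths <- node_depths(pr)[seq_len(13)]
  expect_lt(diff(range(depths)), 1e-9)

  mm <- fixture_mammal_tree()
  expect_equal(n_tips(mm), 29L)
  dm <- node_depths(mm)[seq_len(29)]
  expect_lt(diff(range(dm)), 1e-9)
  expect_true(is_rooted_tree(mm))
})
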