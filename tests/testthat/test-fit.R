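# Recovery tests run at desk scale: shorter alignments and fewer replicates
# than a production validation, with tolerances widened accordingly.

test_that("free-branch fit recovers simulated branch lengths", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 3, pi = c(.3, .2, .2, .3), alpha = 0.8, ncat = 5)
  aln <- simulate_alignment(tr, mod, 8000, seed = 21)
  fit <- fit_free_branches(tr, aln, restarts = 0L)
  expect_true(fit$converged)
  expect_true(fit$lnL > -Inf)
  truth <- unroot_tree(tr)
  # compare split-by-split: both trees share the topology
  expect_equal(sum(fit$tree$edge.length), sum(truth$edge.length),
               tolerance = 0.06)
  expect_equal(fit$kappa, 3, tolerance = 0.15)
  expect_equal(fit$alpha, 0.8, tolerance = 0.35)
})

test_that("doubling true branch lengths doubles the estimated tree length", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 2, pi = rep(0.25, 4))
  aln1 <- simulate_alignment(tr, mod, 6000, seed = 31)
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  aln2 <- simulate_alignment(tr2, mod, 6000, seed = 32)
  f1 <- fit_free_branches(tr, aln1, ncat = 1L, restarts = 0L)
  f2 <- fit_free_branches(tr2, aln2, ncat = 1L, restarts = 0L)
  expect_equal(sum(f2$tree$edge.length) / sum(f1$tree$edge.length), 2,
               tolerance = 0.1)
})

test_that("identical sequences drive lengths to the zero boundary, flagged", {
  tr <- small_clock_tree()
  m <- matrix("A", 6, 40, dimnames = list(tr$tip.label, NULL))
  m[, 1:10] <- "C"  # avoid degenerate all-one-base frequencies
  aln <- clockshift:::new_alignment(m)
  fit <- fit_free_branches(tr, aln, ncat = 1L, restarts = 0L)
  expect_true(all(fit$tree$edge.length < 1e-6))
  expect_true(fit$boundary)
})

test_that("local clock under a strict-clock truth recovers r = 1", {
  tr <- fixture_primate_tree()
  mod <- hky_params(kappa = 4, pi = c(.3, .2, .2, .3), alpha = 0.8, ncat = 5)
  aln <- simulate_alignment(tr, mod, 6000, class_rates = c(1, 1, 1), seed = 41)
  fit <- fit_local_clock(tr, aln, restarts = 0L)
  se <- parameter_ses(fit, c("r1", "r2"))
  expect_true(fit$converged)
  expect_lt(abs(fit$rates[2] - 1), 3 * se$se[["r1"]])
  expect_lt(abs(fit$rates[3] - 1), 3 * se$se[["r2"]])
})

test_that("local clock recovers a fast focal branch and a slow clade", {
  tr <- fixture_primate_tree()
  mod <- hky_params(kappa = 4, pi = c(.3, .2, .2, .3), alpha = 0.8, ncat = 5)
  aln <- simulate_alignment(tr, mod, 10000, class_rates = c(1, 2, 0.35),
                            seed = 43)
  fit <- fit_local_clock(tr, aln, restarts = 0L)
  se <- parameter_ses(fit, c("r1", "r2"))
  expect_lt(abs(fit$rates[2] - 2), 3 * se$se[["r1"]])
  expect_lt(abs(fit$rates[3] - 0.35), 3 * se$se[["r2"]])
})

test_that("unidentifiable labelling is rejected", {
  tr <- small_clock_tree()
  tr$edge.class <- rep(1L, nrow(tr$edge))  # no background branch left
  aln <- random_alignment(6, 50, 3, tr$tip.label)
  expect_error(fit_local_clock(tr, aln), "unidentifiable")
})

test_that("nested models respect the likelihood ordering", {
  tr <- fixture_primate_tree()
  mod <- hky_params(kappa = 4, pi = c(.3, .2, .2, .3), alpha = 0.8, ncat = 5)
  aln <- simulate_alignment(tr, mod, 2000, class_rates = c(1, 2, 0.5),
                            seed = 45)
  strict_tree <- tr; strict_tree$edge.class <- rep(0L, nrow(tr$edge))
  ll_strict <- fit_local_clock(strict_tree, aln, restarts = 0L)$lnL
  ll_local <- fit_local_clock(tr, aln, restarts = 0L)$lnL
  ll_free <- fit_free_branches(tr, aln, restarts = 0L)$lnL
  tol <- 0.05  # optimizer slack
  expect_lte(ll_strict, ll_local + tol)
  expect_lte(ll_local, ll_free + tol)
})

test_that("rate-multiplier recovery is unbiased across a grid (desk scale)", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 2, pi = rep(.25, 4))
  for (r1 in c(0.3, 1, 2)) {
    ests <- vapply(1:8, function(i) {
      aln <- simulate_alignment(tr, mod, 2500, class_rates = c(1, r1),
                                seed = 1000 * r1 + i)
      fit_local_clock(tr, aln, ncat = 1L, restarts = 0L)$rates[2]
    }, numeric(1))
    mc_se <- sd(ests) / sqrt(length(ests))
    # desk-scale version of the bias check: mean within ~3 MC SEs
    expect_lt(abs(mean(ests) - r1), 3 * mc_se + 0.02)
  }
})

test_that("curvature SEs track the Monte-Carlo spread of r1", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 2, pi = rep(.25, 4))
  res <- t(vapply(1:24, function(i) {
    aln <- simulate_alignment(tr, mod, 8000, class_rates = c(1, 1.5),
                              seed = 500 + i)
    fit <- fit_local_clock(tr, aln, ncat = 1L, restarts = 0L)
    c(est = fit$rates[2], se = parameter_ses(fit, "r1")$se[["r1"]])
  }, numeric(2)))
  # desk scale (24 reps, 8 kb): 25% agreement in place of 20% at 200 reps
  expect_lt(abs(median(res[, "se"]) - sd(res[, "est"])) / sd(res[, "est"]),
            0.25)
})

test_that("quadratic synthetic likelihood yields the exact analytic SE", {
  # -lnL = 0.5 * (x - x0)^2 / v in log coordinates; SE(exp(x)) = exp(x0)*sqrt(v)
  x0 <- log(1.7); v <- 0.04
  fake <- structure(list(
    par_trans = x0,
    negll_trans = function(x) 0.5 * (x - x0)^2 / v,
    par_names = "r1"), class = "local_clock_fit")
  se <- parameter_ses(fake, "r1")
  expect_equal(unname(se$se), exp(x0) * sqrt(v), tolerance = 1e-6)
  # oracle route: numDeriv Hessian agrees with the internal differences
  H <- numDeriv::hessian(fake$negll_trans, x0)
  expect_equal(clockshift:::num_hessian(fake$negll_trans, x0)[1, 1],
               H[1, 1], tolerance = 1e-6)
})

test_that("covariance matrices are symmetric and PSD-flagged", {
  tr <- small_clock_tree()
  mod <- hky_params(kappa = 2, pi = rep(.25, 4), alpha = 1, ncat = 3)
  aln <- simulate_alignment(tr, mod, 2000, class_rates = c(1, 1.4), seed = 77)
  fit <- fit_local_clock(tr, aln, ncat = 3L, restarts = 0L)
  se <- parameter_ses(fit)
  expect_equal(se$cov, t(se$cov), tolerance = 1e-10)
  expect_true(is.logical(se$psd))
  expect_true(all(eigen(se$cov, symmetric = TRUE)$values > -1e-8))
})

test_that("M0 fit recovers neutral omega within 3 SEs", {
  tr <- random_tree(8, 3)
  tr$edge.length <- tr$edge.length * 0.15
  mod <- m0_params(kappa = 2, omega = 1, freq_mode = "equal")
  aln <- simulate_codon_alignment(tr, mod, 300, seed = 55)
  fit <- fit_m0(aln, tr, freq_mode = "equal", restarts = 0L)
  se <- parameter_ses(fit, c("kappa", "omega"))
  expect_true(fit$converged)
  expect_lt(abs(fit$omega - 1), 3 * se$se[["omega"]])
})

test_that("all-synonymous data drive omega to the zero boundary, flagged", {
  tr <- random_tree(6, 9)
  tr$edge.length <- tr$edge.length * 0.3
  mod <- m0_params(kappa = 2, omega = 0, freq_mode = "equal")
  aln <- simulate_codon_alignment(tr, mod, 200, seed = 66)
  fit <- fit_m0(aln, tr, freq_mode = "equal", restarts = 0L)
  expect_lt(fit$omega, 1e-4)
  expect_true(fit$boundary)
})
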