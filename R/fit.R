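# Maximum-likelihood fitting: free branch lengths, local clocks with labelled
# rate classes, and the M0 codon model.
#
# All optimizations run in transformed coordinates (log for rates/lengths/
# kappa/alpha/root age, logit for nested age proportions) with L-BFGS-B.
# Standard errors come from a central-difference Hessian of the negative
# log-likelihood at the optimum, back-transformed by the delta rule.

OPT_CONTROL <- list(maxit = 1000L, factr = 1e7)

#' Central-difference Hessian
#' @keywords internal
num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  hh <- h * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < p) for (j in (i + 1L):p) {
      ej <- rep(0, p); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

# invert an observed-information matrix, falling back to a pseudo-inverse
# (flagged) when it is not positive definite
safe_cov <- function(H) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  psd <- all(e$values > 1e-10 * max(abs(e$values)))
  if (psd) {
    cov <- e$vectors %*% diag(1 / e$values, length(e$values)) %*% t(e$vectors)
  } else {
    warning("observed information is not positive definite; using pseudo-inverse")
    vals <- ifelse(abs(e$values) > 1e-10 * max(abs(e$values)), 1 / e$values, 0)
    cov <- e$vectors %*% diag(pmax(vals, 0), length(vals)) %*% t(e$vectors)
  }
  list(cov = (cov + t(cov)) / 2, psd = psd)
}

run_optim <- function(par, fn, lower, upper, restarts = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # forward-difference gradient: p+1 objective calls instead of optim's 2p
  gr <- function(p) {
    f0 <- fn(p)
    h <- 1e-6 * pmax(1, abs(p))
    vapply(seq_along(p), function(i) {
      pi2 <- p; pi2[i] <- p[i] + h[i]
      (fn(pi2) - f0) / h[i]
    }, numeric(1))
  }
  best <- stats::optim(par, fn, gr, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = OPT_CONTROL)
  for (r in seq_len(restarts)) {
    par2 <- pmin(pmax(par + stats::rnorm(length(par), 0, 0.5), lower), upper)
    cand <- tryCatch(
      stats::optim(par2, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = OPT_CONTROL),
      error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value - 1e-9) best <- cand
  }
  best
}

# quick moment-style initial kappa: observed transition vs transversion
# mismatches over sequence pairs (expectation ts/tv = kappa/2 at low
# divergence under equal frequencies); only an optimizer warm start
init_kappa <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  pairs <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  ts <- tv <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- m[pairs[r, 1], ]; b <- m[pairs[r, 2], ]
    ok <- a %in% NUC & b %in% NUC & a != b
    pur <- c("A", "G")
    is_ts <- (a %in% pur) == (b %in% pur)
    ts <- ts + sum(ok & is_ts)
    tv <- tv + sum(ok & !is_ts)
  }
  if (tv == 0L) return(2)
  min(max(2 * ts / tv, 0.2), 50)
}

# ---- free branch lengths ----------------------------------------------

#' Fit branch lengths and HKY(+gamma) parameters without a clock
#'
#' Joint ML over all branch lengths, kappa and (if `ncat > 1`) the gamma
#' shape; base frequencies are the observed alignment frequencies.  Rooted
#' input is unrooted first (the two root branches are not separately
#' identifiable under a reversible model).
#'
#' @param tree tree topology (branch lengths, if present, seed the optimizer).
#' @param aln nucleotide `seq_alignment`.
#' @param ncat discrete gamma categories (1 = rate homogeneity).
#' @param gap gap policy, see [compress_patterns()].
#' @param restarts extra random restarts of the optimizer.
#' @param seed seed for restart jitter.
#' @return an object of class `free_branch_fit`.
#' @export
fit_free_branches <- function(tree, aln, ncat = 5L, gap = "missing",
                              restarts = 1L, seed = 1L) {
  if (n_tips(tree) < 3L) stop("need at least 3 taxa")
  tree <- unroot_tree(tree)
  patterns <- compress_patterns(aln, gap)
  pi <- base_frequencies(aln)
  tp <- tip_partials(patterns, tree$tip.label)
  ord <- postorder_edges(tree)
  edge_post <- tree$edge[ord, , drop = FALSE]
  nnode <- n_tips(tree) + tree$Nnode
  root <- root_node(tree)
  nb <- nrow(tree$edge)
  use_gamma <- ncat > 1L

  init_len <- if (!is.null(tree$edge.length) && !anyNA(tree$edge.length))
    pmax(tree$edge.length, 1e-4) else rep(0.1, nb)
  par0 <- c(log(init_len), log(init_kappa(aln)), if (use_gamma) log(1))
  lower <- c(rep(log(1e-9), nb), log(0.01), if (use_gamma) log(0.02))
  upper <- c(rep(log(20), nb), log(200), if (use_gamma) log(100))

  negll <- function(par) {
    blen <- exp(par[seq_len(nb)])
    kappa <- exp(par[nb + 1L])
    alpha <- if (use_gamma) exp(par[nb + 2L]) else NULL
    mod <- hky_params(kappa = kappa, pi = pi, alpha = alpha, ncat = ncat)
    eg <- rate_matrix_eigen(hky_q(mod))
    rw <- model_rates(mod)
    site <- pruning_site_loglik_raw(edge_post, blen[ord], eg, tp, nnode, root,
                                    rw$rates, rw$weights)
    -sum(site * patterns$counts)
  }

  opt <- run_optim(par0, negll, lower, upper, restarts, seed)
  blen <- exp(opt$par[seq_len(nb)])
  tree$edge.length <- blen
  boundary <- any(blen <= 1.5e-9) || any(blen >= 19)
  structure(list(tree = tree,
                 kappa = exp(opt$par[nb + 1L]),
                 alpha = if (use_gamma) exp(opt$par[nb + 2L]) else NULL,
                 ncat = as.integer(ncat), pi = pi,
                 lnL = -opt$value,
                 converged = opt$convergence == 0L,
                 boundary = boundary,
                 par_trans = opt$par, negll_trans = negll,
                 par_names = c(paste0("blen", seq_len(nb)), "kappa",
                               if (use_gamma) "alpha")),
            class = "free_branch_fit")
}

# ---- local clock -------------------------------------------------------

# layout of the transformed parameter vector for a local-clock model
clock_layout <- function(tree) {
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  root <- root_node(tree)
  internal <- (ntip + 1L):nn
  pre_nodes <- unique(tree$edge[rev(postorder_edges(tree)), 2])
  pre_int <- pre_nodes[pre_nodes > ntip]        # internal non-root, preorder
  cls <- edge_classes(tree)
  nclass <- max(cls) + 1L
  list(ntip = ntip, nn = nn, root = root, pre_int = pre_int,
       nclass = nclass, cls = cls)
}

clock_branch_lengths <- function(tree, ages, rates_by_class) {
  cls <- edge_classes(tree)
  (ages[tree$edge[, 1]] - ages[tree$edge[, 2]]) * rates_by_class[cls + 1L]
}

#' Fit a local-clock model with labelled branch rate classes
#'
#' Node ages (tips at age 0, units of expected class-0 substitutions per
#' site) and per-class rate multipliers are estimated jointly with kappa and
#' the gamma shape.  The background class 0 is fixed at rate 1; labelled
#' classes get free multipliers.  The covariance of the free parameters is
#' available through [parameter_ses()].
#'
#' @param tree rooted tree carrying `edge.class` labels (see
#'   [label_branches()]); existing branch lengths seed the age initialisation.
#' @param aln nucleotide `seq_alignment`.
#' @param ncat discrete gamma categories.
#' @param gap gap policy.
#' @param restarts extra random optimizer restarts.
#' @param seed seed for restart jitter.
#' @return an object of class `local_clock_fit` with elements `rates`
#'   (multiplier per class, class 0 first), `ages`, `kappa`, `alpha`, `lnL`,
#'   `tree` (fitted branch lengths), convergence and boundary flags.
#' @export
fit_local_clock <- function(tree, aln, ncat = 5L, gap = "missing",
                            restarts = 1L, seed = 1L) {
  if (!is_rooted_tree(tree)) stop("local-clock fitting needs a rooted tree")
  tree <- normalize_classes(tree)
  lay <- clock_layout(tree)
  if (lay$nclass < 1L || !any(lay$cls == 0L))
    stop("unidentifiable labelling: no background (class 0) branches remain")
  # under a reversible model only the sum of the two root-adjacent branch
  # lengths is observable, so a rate class confined to a root edge rides a
  # likelihood ridge against the root age
  root_edges <- which(tree$edge[, 1] == root_node(tree))
  ridge <- lay$cls[root_edges] != 0L &
    !(lay$cls[root_edges] %in% lay$cls[-root_edges])
  if (any(ridge))
    warning("rate class found only on a root-adjacent branch; ",
            "it is confounded with the root age (reversible model)")
  patterns <- compress_patterns(aln, gap)
  pi <- base_frequencies(aln)
  tp <- tip_partials(patterns, tree$tip.label)
  ord <- postorder_edges(tree)
  edge_post <- tree$edge[ord, , drop = FALSE]
  use_gamma <- ncat > 1L
  nprop <- length(lay$pre_int)
  nrate <- lay$nclass - 1L
  parent <- node_parents(tree)

  ages_from_par <- function(par) {
    ages <- numeric(lay$nn)
    ages[lay$root] <- exp(par[1L])
    if (nprop > 0L) {
      p <- stats::plogis(par[1L + seq_len(nprop)])
      for (i in seq_len(nprop)) {
        nd <- lay$pre_int[i]
        ages[nd] <- p[i] * ages[parent[nd]]
      }
    }
    ages
  }

  negll <- function(par) {
    ages <- ages_from_par(par)
    rates_cls <- c(1, exp(par[1L + nprop + seq_len(nrate)]))
    blen <- clock_branch_lengths(tree, ages, rates_cls)
    kappa <- exp(par[1L + nprop + nrate + 1L])
    alpha <- if (use_gamma) exp(par[1L + nprop + nrate + 2L]) else NULL
    mod <- hky_params(kappa = kappa, pi = pi, alpha = alpha, ncat = ncat)
    eg <- rate_matrix_eigen(hky_q(mod))
    rw <- model_rates(mod)
    site <- pruning_site_loglik_raw(edge_post, blen[ord], eg, tp, lay$nn,
                                    lay$root, rw$rates, rw$weights)
    -sum(site * patterns$counts)
  }

  # initialise ages from input branch lengths when available
  if (!is.null(tree$edge.length) && !anyNA(tree$edge.length)) {
    depth <- node_depths(tree)
    tipd <- depth[seq_len(lay$ntip)]
    h0 <- max(mean(tipd), 1e-3)
    ages0 <- pmax(h0 - node_ages_proxy(tree, depth), 1e-5)
  } else {
    h0 <- 0.1
    ages0 <- NULL
  }
  par0 <- c(log(h0), rep(0, nprop), rep(0, nrate), log(init_kappa(aln)),
            if (use_gamma) log(1))
  if (!is.null(ages0)) {
    for (i in seq_len(nprop)) {
      nd <- lay$pre_int[i]
      pr <- min(max(ages0[nd] / max(ages0[parent[nd]], 1e-8), 0.02), 0.98)
      par0[1L + i] <- stats::qlogis(pr)
    }
  }
  lower <- c(log(1e-6), rep(-12, nprop), rep(log(1e-4), nrate), log(0.01),
             if (use_gamma) log(0.02))
  upper <- c(log(10), rep(12, nprop), rep(log(1e4), nrate), log(200),
             if (use_gamma) log(100))

  opt <- run_optim(par0, negll, lower, upper, restarts, seed)
  ages <- ages_from_par(opt$par)
  rates_cls <- c(1, exp(opt$par[1L + nprop + seq_len(nrate)]))
  tree_fit <- tree
  tree_fit$edge.length <- clock_branch_lengths(tree, ages, rates_cls)
  boundary <- nrate > 0L &&
    (any(rates_cls[-1] <= 1.2e-4) || any(rates_cls[-1] >= 0.9e4))
  par_names <- c("root_age",
                 if (nprop) paste0("prop", seq_len(nprop)),
                 if (nrate) paste0("r", seq_len(nrate)),
                 "kappa", if (use_gamma) "alpha")
  structure(list(rates = rates_cls, ages = ages,
                 kappa = exp(opt$par[1L + nprop + nrate + 1L]),
                 alpha = if (use_gamma)
                   exp(opt$par[1L + nprop + nrate + 2L]) else NULL,
                 ncat = as.integer(ncat), pi = pi,
                 lnL = -opt$value, tree = tree_fit,
                 converged = opt$convergence == 0L, boundary = boundary,
                 par_trans = opt$par, negll_trans = negll,
                 par_names = par_names),
            class = "local_clock_fit")
}

# proxy node "ages" from branch lengths: mean root-to-node depth subtracted
# from mean tip depth; only used to initialise the optimizer
node_ages_proxy <- function(tree, depth) {
  d <- depth
  d[seq_len(n_tips(tree))] <- mean(depth[seq_len(n_tips(tree))])
  d
}

# ---- M0 codon model ----------------------------------------------------

#' Fit the M0 codon model (single dN/dS ratio)
#'
#' Joint ML over branch lengths, kappa and omega with fixed codon
#' frequencies (F3x4 from the data by default).  Standard errors for kappa
#' and omega come from the observed information via [parameter_ses()].
#'
#' @param aln codon `seq_alignment` without in-frame stops.
#' @param tree tree topology (rooted input is unrooted).
#' @param freq_mode `"F3x4"` or `"equal"`.
#' @param gap gap policy.
#' @param restarts extra random optimizer restarts.
#' @param seed seed for restart jitter.
#' @return object of class `m0_fit` with `kappa`, `omega`, `lnL`, `tree`,
#'   `codon_freqs` and optimizer metadata.
#' @export
fit_m0 <- function(aln, tree, freq_mode = c("F3x4", "equal"),
                   gap = "missing", restarts = 1L, seed = 1L) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(aln_alphabet(aln) == "codon")
  if (n_tips(tree) < 3L) stop("need at least 3 taxa")
  tree <- unroot_tree(tree)
  patterns <- compress_patterns(aln, gap)
  freqs <- if (freq_mode == "F3x4") f3x4_freqs(aln) else rep(1 / 61, 61)
  tp <- tip_partials(patterns, tree$tip.label)
  ord <- postorder_edges(tree)
  edge_post <- tree$edge[ord, , drop = FALSE]
  nnode <- n_tips(tree) + tree$Nnode
  root <- root_node(tree)
  nb <- nrow(tree$edge)

  init_len <- if (!is.null(tree$edge.length) && !anyNA(tree$edge.length))
    pmax(tree$edge.length, 1e-4) else rep(0.1, nb)
  par0 <- c(log(init_len), log(2), log(0.2))
  lower <- c(rep(log(1e-9), nb), log(0.01), log(1e-6))
  upper <- c(rep(log(20), nb), log(200), log(50))

  # most optimizer steps only move branch lengths, so cache the 61x61
  # eigendecomposition on (kappa, omega)
  eig_cache <- new.env(parent = emptyenv())
  negll <- function(par) {
    blen <- exp(par[seq_len(nb)])
    kappa <- exp(par[nb + 1L]); omega <- exp(par[nb + 2L])
    key <- paste(format(kappa, digits = 17), format(omega, digits = 17))
    eg <- eig_cache[[key]]
    if (is.null(eg)) {
      mod <- m0_params(kappa = kappa, omega = omega, codon_freqs = freqs)
      eg <- rate_matrix_eigen(m0_q(mod))
      rm(list = ls(eig_cache), envir = eig_cache)  # keep one entry
      eig_cache[[key]] <- eg
    }
    site <- pruning_site_loglik_raw(edge_post, blen[ord], eg, tp, nnode, root,
                                    1, 1)
    -sum(site * patterns$counts)
  }

  opt <- run_optim(par0, negll, lower, upper, restarts, seed)
  blen <- exp(opt$par[seq_len(nb)])
  tree$edge.length <- blen
  omega <- exp(opt$par[nb + 2L])
  structure(list(kappa = exp(opt$par[nb + 1L]), omega = omega,
                 codon_freqs = freqs, freq_mode = freq_mode,
                 lnL = -opt$value, tree = tree,
                 converged = opt$convergence == 0L,
                 boundary = omega <= 1.5e-6 || any(blen <= 1.5e-9),
                 par_trans = opt$par, negll_trans = negll,
                 par_names = c(paste0("blen", seq_len(nb)), "kappa", "omega")),
            class = "m0_fit")
}

# ---- standard errors ---------------------------------------------------

#' Delta-rule standard errors from the observed information
#'
#' Computes a central-difference Hessian of the negative log-likelihood at
#' the optimum in the transformed coordinates used by the optimizer, inverts
#' it, and back-transforms the requested parameters to their natural scale.
#' Works for all fit classes in this package.
#'
#' @param fit a `free_branch_fit`, `local_clock_fit` or `m0_fit`.
#' @param which parameter names (see `fit$par_names`); default: all
#'   non-nuisance parameters (rates, kappa, alpha, omega, root_age).
#' @param h relative step for the finite differences.
#' @return list with `se` (named), `cov` (natural scale), `psd` flag.
#' @export
parameter_ses <- function(fit, which = NULL, h = 1e-4) {
  nm <- fit$par_names
  if (is.null(which))
    which <- nm[grepl("^(r[0-9]+|kappa|alpha|omega|root_age)$", nm)]
  idx <- match(which, nm)
  if (anyNA(idx)) stop(sprintf("unknown parameter(s): %s",
                               paste(which[is.na(idx)], collapse = ", ")))
  H <- num_hessian(fit$negll_trans, fit$par_trans, h = h)
  sc <- safe_cov(H)
  cov_t <- sc$cov[idx, idx, drop = FALSE]
  # all reported parameters are log-transformed: d(natural)/d(trans) = natural
  natural <- exp(fit$par_trans[idx])
  # proportions are never in `which`, so the Jacobian is diagonal
  J <- diag(natural, length(natural))
  cov_n <- J %*% cov_t %*% J
  dimnames(cov_n) <- list(which, which)
  se <- sqrt(pmax(diag(cov_n), 0))
  list(se = stats::setNames(se, which), cov = cov_n, psd = sc$psd)
}
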