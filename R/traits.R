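# Binary expression state vs life-history covariates: phylogenetic logistic
# regression (GEE with exponentially decaying working correlation on
# patristic distances), plain log-scale correlations, and a genome-wide
# expression-trait correlation screen.

#' Read a species trait table
#'
#' Tab-separated with a header; must contain a `species` column.  Typical
#' columns: `fpkm` (cardiac expression), `body_mass_g`, `heart_rate_bpm`,
#' `bmr` (mass-specific basal metabolic rate).
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table")
  df
}

#' Dichotomize expression into high/low states
#'
#' @param table data.frame with `species` and an expression column.
#' @param threshold expression cut-off; state 1 iff value >= threshold.
#' @param column expression column name (default `"fpkm"`).
#' @return named integer vector of 0/1 states with attributes `threshold`
#'   and `column`; species with missing values are dropped with a warning.
#' @export
binarize_expression <- function(table, threshold = 1, column = "fpkm") {
  if (!column %in% names(table))
    stop(sprintf("column '%s' not in trait table", column))
  v <- table[[column]]
  keep <- !is.na(v)
  if (any(!keep))
    warning(sprintf("dropping %d species with missing %s",
                    sum(!keep), column))
  out <- stats::setNames(as.integer(v[keep] >= threshold),
                         table$species[keep])
  attr(out, "threshold") <- threshold
  attr(out, "column") <- column
  out
}

#' Phylogenetic logistic regression of a binary trait
#'
#' Generalized estimating equations for a logistic mean model with a working
#' correlation among species decaying exponentially in patristic distance,
#' `corr(i, j) = exp(-decay * d_ij)`.  The decay rate is profiled by a
#' Gaussian pseudo-likelihood of the Pearson residuals; as the fitted decay
#' grows large the estimator reduces to ordinary logistic regression.
#'
#' @param tree tree with branch lengths; tips must cover `names(y)`.
#' @param y named binary (0/1) response per species.
#' @param X covariate matrix or data.frame (no intercept column; one is
#'   added), rownames matching species.
#' @param decay_grid candidate decay rates for the profile (scaled by the
#'   mean patristic distance); `Inf` (independence) is always included.
#' @param max_iter,tol Fisher-scoring controls.
#' @param ridge small L2 penalty applied only if separation is detected.
#' @return object of class `phylo_logistic_fit`: `coef`, `se`, `vcov`,
#'   `decay`, `converged`, `separation`, `n`.
#' @export
phylo_logistic_fit <- function(tree, y, X,
                               decay_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, 32),
                               max_iter = 50L, tol = 1e-10, ridge = 1e-3) {
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species")
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss))
    stop(sprintf("species not in tree: %s", paste(miss, collapse = ", ")))
  if (length(unique(y)) < 2L) stop("response is constant")
  X <- as.matrix(X)
  if (!is.null(rownames(X))) X <- X[sp, , drop = FALSE]
  if (nrow(X) != length(y)) stop("X rows must match y")
  Xd <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (n < 10L) stop("need at least 10 species")

  D <- tip_distances(tree)[sp, sp]
  dbar <- mean(D[upper.tri(D)])
  grid <- c(decay_grid / dbar, Inf)

  fit_beta <- function(Rinv, lambda = 0) {
    beta <- rep(0, ncol(Xd))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- as.vector(Xd %*% beta)
      mu <- stats::plogis(eta)
      A <- mu * (1 - mu)
      sA <- sqrt(pmax(A, 1e-12))
      # U = X' A^{1/2} Rinv A^{-1/2} (y - mu);  J = X' A^{1/2} Rinv A^{1/2} X
      W1 <- Xd * sA
      U <- crossprod(W1, Rinv %*% ((y - mu) / sA)) - lambda * beta
      J <- crossprod(W1, Rinv %*% W1) + diag(lambda, ncol(Xd))
      step <- tryCatch(solve(J, U), error = function(e) NULL)
      if (is.null(step)) break
      # dampen huge steps to keep the scoring stable
      if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
      beta <- beta + as.vector(step)
      if (max(abs(step)) < tol) { ok <- TRUE; break }
    }
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    A <- pmax(mu * (1 - mu), 1e-12)
    W1 <- Xd * sqrt(A)
    J <- crossprod(W1, Rinv %*% W1) + diag(lambda, ncol(Xd))
    vcov <- tryCatch(solve(J), error = function(e) matrix(NA, ncol(Xd), ncol(Xd)))
    list(beta = beta, mu = mu, A = A, vcov = vcov, converged = ok)
  }

  profile_obj <- function(delta, fit) {
    R <- if (is.finite(delta)) exp(-delta * D) else diag(n)
    diag(R) <- 1
    R <- R + diag(1e-8, n)
    e <- (y - fit$mu) / sqrt(fit$A)
    ch <- tryCatch(chol(R), error = function(e2) NULL)
    if (is.null(ch)) return(Inf)
    z <- backsolve(ch, e, transpose = TRUE)
    sum(log(diag(ch))) + 0.5 * sum(z^2)
  }

  # alternate: fit beta under each candidate working correlation, score the
  # standardized residuals, keep the best decay
  best <- NULL
  for (delta in grid) {
    R <- if (is.finite(delta)) exp(-delta * D) else diag(n)
    diag(R) <- 1
    Rinv <- tryCatch(solve(R + diag(1e-8, n)), error = function(e) NULL)
    if (is.null(Rinv)) next
    f <- fit_beta(Rinv)
    sep <- any(f$mu > 1 - 1e-6 | f$mu < 1e-6) || any(abs(f$beta) > 15) ||
      !f$converged
    if (sep) f <- fit_beta(Rinv, lambda = ridge)
    crit <- profile_obj(delta, f)
    if (is.null(best) || crit < best$crit)
      best <- list(delta = delta, fit = f, crit = crit, separation = sep)
  }
  if (is.null(best)) stop("phylogenetic logistic fit failed for every decay value")
  f <- best$fit
  se <- sqrt(pmax(diag(f$vcov), 0))
  structure(list(coef = stats::setNames(f$beta, colnames(Xd)),
                 se = stats::setNames(se, colnames(Xd)),
                 vcov = f$vcov,
                 decay = best$delta,
                 mean_distance = dbar,
                 converged = f$converged,
                 separation = best$separation,
                 n = n),
            class = "phylo_logistic_fit")
}

#' @export
print.phylo_logistic_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic logistic regression (n = %d)\n", x$n))
  tab <- cbind(estimate = x$coef, se = x$se, z = x$coef / x$se)
  print(round(tab, 4))
  cat(sprintf("working-correlation decay: %s per unit distance\n",
              format(x$decay, digits = 4)))
  if (x$separation) cat("note: separation detected; ridge fallback used\n")
  invisible(x)
}

#' Correlation between two species-level variables
#'
#' Pearson correlation with a two-sided t-test, optionally on log10 scales.
#'
#' @param x,y numeric vectors.
#' @param transform `"log10"` (both variables; requires positive values) or
#'   `"none"`.
#' @return list of class `correlation_result`: `r`, `p`, `n`, `transform`.
#' @export
loglog_correlation <- function(x, y, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (transform == "log10") {
    if (any(x <= 0) || any(y <= 0))
      stop("log10 transform requires positive values")
    x <- log10(x); y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 transform = transform),
            class = "correlation_result")
}

#' Genome-wide expression-trait correlation screen
#'
#' Correlates each gene's expression across species with a trait vector and
#' ranks genes by absolute correlation, with a multiplicity adjustment
#' across genes (Benjamini-Hochberg by default).
#'
#' @param expr genes x species matrix with rownames (genes) and colnames
#'   (species).
#' @param trait named trait vector over (a subset of) the species.
#' @param transform applied to the trait: `"log10"` or `"none"`; expression
#'   is left on its input scale.
#' @param adjust a method for [stats::p.adjust()].
#' @return data.frame ranked by `|r|`: gene, r, p, p_adj, n; all-zero genes
#'   are dropped (count reported via the `dropped` attribute).
#' @export
correlation_screen <- function(expr, trait, transform = c("log10", "none"),
                               adjust = "BH") {
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  sp <- intersect(colnames(expr), names(trait))
  if (length(sp) < 3L) stop("need at least 3 species shared by expr and trait")
  expr <- expr[, sp, drop = FALSE]
  tv <- trait[sp]
  if (transform == "log10") {
    if (any(tv <= 0)) stop("log10 transform requires positive trait values")
    tv <- log10(tv)
  }
  zero <- apply(expr, 1, function(v) all(v == 0) || stats::sd(v) == 0)
  nd <- sum(zero)
  expr <- expr[!zero, , drop = FALSE]
  if (nrow(expr) == 0L) stop("no genes with variable expression")
  res <- t(apply(expr, 1, function(v) {
    ct <- stats::cor.test(v, tv)
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
  out <- data.frame(gene = rownames(expr), r = res[, "r"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = adjust),
                    n = length(sp), row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- nd
  attr(out, "adjust") <- adjust
  out
}
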