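# Substitution models: HKY nucleotide, M0 codon, discrete-gamma rates.

#' HKY model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi base frequencies over (A, C, G, T), summing to 1.
#' @param alpha gamma shape for among-site rate variation, or `NULL` for
#'   rate homogeneity.
#' @param ncat number of discrete gamma categories (default 5).
#' @export
hky_params <- function(kappa = 2, pi = rep(0.25, 4), alpha = NULL, ncat = 5L) {
  stopifnot(kappa > 0, length(pi) == 4, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-12) stop("base frequencies must sum to 1")
  if (!is.null(alpha) && alpha <= 0) stop("gamma shape must be positive")
  structure(list(kappa = kappa, pi = stats::setNames(as.numeric(pi), NUC),
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "hky_params")
}

#' M0 codon model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_freqs frequencies over the 61 sense codons (universal code),
#'   or `NULL` to use the mode given by `freq_mode`.
#' @param freq_mode `"equal"` or `"F3x4"`; `"F3x4"` requires frequencies to
#'   be supplied later from data via [f3x4_freqs()].
#' @export
m0_params <- function(kappa = 2, omega = 0.2, codon_freqs = NULL,
                      freq_mode = c("equal", "F3x4")) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(kappa > 0, omega >= 0)
  if (is.null(codon_freqs) && freq_mode == "equal")
    codon_freqs <- rep(1 / 61, 61)
  if (!is.null(codon_freqs)) {
    stopifnot(length(codon_freqs) == 61, all(codon_freqs >= 0))
    if (abs(sum(codon_freqs) - 1) > 1e-9)
      stop("codon frequencies must sum to 1")
  }
  structure(list(kappa = kappa, omega = omega,
                 codon_freqs = codon_freqs, freq_mode = freq_mode),
            class = "m0_params")
}

# ---- genetic code ------------------------------------------------------

#' The 61 sense codons of the universal code, with translations
#' @keywords internal
genetic_code_tables <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- names(gc)[gc != "*"]
      aa <- unname(gc[gc != "*"])
      # precompute single-step structure
      n <- length(codons)
      cm <- do.call(rbind, strsplit(codons, ""))
      is_ts <- function(x, y) {
        (x %in% c("A", "G") && y %in% c("A", "G")) ||
          (x %in% c("C", "T") && y %in% c("C", "T"))
      }
      diff_pos <- matrix(0L, n, n)
      transition <- matrix(FALSE, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        d <- which(cm[i, ] != cm[j, ])
        diff_pos[i, j] <- length(d)
        if (length(d) == 1L)
          transition[i, j] <- is_ts(cm[i, d], cm[j, d])
      }
      tab <<- list(codons = codons, aa = aa, chars = cm,
                   ndiff = diff_pos, transition = transition)
    }
    tab
  }
})

#' Sense codons of the universal genetic code
#' @export
sense_codons <- function() genetic_code_tables()$codons

# ---- rate matrices -----------------------------------------------------

new_rate_matrix <- function(Q, pi, labels) {
  dimnames(Q) <- list(labels, labels)
  structure(list(Q = Q, pi = stats::setNames(pi, labels), labels = labels),
            class = "rate_matrix")
}

#' HKY instantaneous rate matrix
#'
#' Reversible 4x4 generator with transitions scaled by kappa, normalized so
#' the mean substitution rate at stationarity is 1.
#'
#' @param params an [hky_params()] object.
#' @return a `rate_matrix`.
#' @export
hky_q <- function(params) {
  stopifnot(inherits(params, "hky_params"))
  pi <- params$pi
  Q <- matrix(0, 4, 4)
  transitions <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    mult <- if (any(transitions[, 1] == i & transitions[, 2] == j))
      params$kappa else 1
    Q[i, j] <- mult * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  new_rate_matrix(Q, pi, NUC)
}

#' M0 codon instantaneous rate matrix
#'
#' 61x61 generator over the sense codons of the universal code.  Codon pairs
#' differing at more than one position have rate 0; single-step rates are
#' multiplied by kappa for transitions and by omega for nonsynonymous
#' changes, and weighted by the target codon frequency.  Normalized to mean
#' rate 1 at stationarity.
#'
#' @param params an [m0_params()] object with codon frequencies set.
#' @return a `rate_matrix`.
#' @export
m0_q <- function(params) {
  stopifnot(inherits(params, "m0_params"))
  gc <- genetic_code_tables()
  pi <- params$codon_freqs
  if (is.null(pi)) stop("codon frequencies are not set (use f3x4_freqs or equal mode)")
  n <- 61L
  base <- ifelse(gc$ndiff == 1L, 1, 0)
  base <- base * ifelse(gc$transition, params$kappa, 1)
  nonsyn <- outer(gc$aa, gc$aa, "!=")
  base <- base * ifelse(nonsyn, params$omega, 1)
  Q <- base * matrix(pi, n, n, byrow = TRUE)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate M0 rate matrix (zero total rate)")
  Q <- Q / scale
  new_rate_matrix(Q, pi, gc$codons)
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Products of position-specific nucleotide frequencies, with stop codons
#' removed and the remainder renormalized.
#'
#' @param aln a codon `seq_alignment`.
#' @return numeric vector of 61 sense-codon frequencies.
#' @export
f3x4_freqs <- function(aln) {
  stopifnot(aln_alphabet(aln) == "codon")
  if (ncol(aln) == 0L) stop("empty alignment")
  pos <- (seq_len(ncol(aln)) - 1L) %% 3L + 1L
  fpos <- sapply(1:3, function(p) {
    chars <- unclass(aln)[, pos == p, drop = FALSE]
    chars <- chars[chars %in% NUC]
    tab <- table(factor(chars, levels = NUC))
    as.numeric(tab) / sum(tab)
  })  # 4 x 3
  gc <- genetic_code_tables()
  f <- apply(gc$chars, 1, function(cd) {
    fpos[match(cd[1], NUC), 1] * fpos[match(cd[2], NUC), 2] *
      fpos[match(cd[3], NUC), 3]
  })
  if (sum(f) <= 0) stop("degenerate position-specific frequencies")
  f / sum(f)
}

# ---- transition probabilities ------------------------------------------

#' Eigendecomposition of a reversible rate matrix
#'
#' Decomposes the pi-symmetrized generator; used by the pruning core and by
#' [transition_matrix()].
#' @keywords internal
rate_matrix_eigen <- function(rm) {
  pi <- as.numeric(rm$pi)
  sqp <- sqrt(pi)
  B <- diag(sqp) %*% rm$Q %*% diag(1 / sqp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, pi = pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by spectral decomposition of the symmetrized reversible
#' generator; falls back to scaling-and-squaring if the reconstruction is
#' ill-conditioned.
#'
#' @param rm a `rate_matrix`.
#' @param t branch length (>= 0).
#' @export
transition_matrix <- function(rm, t) {
  if (t < 0) stop("branch length must be >= 0")
  eg <- rate_matrix_eigen(rm)
  sqp <- sqrt(eg$pi)
  P <- (eg$vectors %*% diag(exp(eg$values * t), length(eg$values)) %*%
          t(eg$vectors))
  P <- P * outer(1 / sqp, sqp)
  if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-8) {
    P <- expm_ss(rm$Q * t)
  }
  P[P < 0] <- 0
  dimnames(P) <- list(rm$labels, rm$labels)
  P
}

# scaling-and-squaring matrix exponential (Taylor core); fallback only
expm_ss <- function(A, order = 12L) {
  nrm <- max(abs(A))
  k <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 2L)
  As <- A / 2^k
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (m in seq_len(order)) {
    term <- term %*% As / m
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

#' Discrete-gamma category rates
#'
#' Mean rates of K equal-probability classes of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretization for among-site rate
#' variation.  The returned rates are renormalized to mean exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories (>= 1).
#' @return numeric vector of K increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, K) {
  if (alpha <= 0) stop("gamma shape must be positive")
  K <- as.integer(K)
  if (K < 1L) stop("need at least one category")
  if (K == 1L) return(1)
  b <- stats::qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  # mean within each class via the Gamma(alpha+1, alpha) cdf identity
  cum <- c(0, stats::pgamma(b, shape = alpha + 1, rate = alpha), 1)
  r <- K * diff(cum)
  r / mean(r)
}

#' Category rates and weights for a model (1 category if no gamma)
#' @keywords internal
model_rates <- function(params) {
  if (inherits(params, "hky_params") && !is.null(params$alpha)) {
    r <- discrete_gamma_rates(params$alpha, params$ncat)
    list(rates = r, weights = rep(1 / length(r), length(r)))
  } else {
    list(rates = 1, weights = 1)
  }
}

#' Rate matrix for either model family
#' @keywords internal
model_q <- function(params) {
  if (inherits(params, "hky_params")) hky_q(params)
  else if (inherits(params, "m0_params")) m0_q(params)
  else stop("unknown model parameter class")
}
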