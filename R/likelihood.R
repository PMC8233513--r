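# Phylogenetic likelihood by pruning (C++ core) and helpers shared by the
# fitting routines.

#' Tip partial-likelihood cube for a set of site patterns
#'
#' @param patterns result of [compress_patterns()].
#' @param taxa_order character vector giving the slice order (tree tip order).
#' @return array nstates x npatterns x ntips.
#' @keywords internal
tip_partials <- function(patterns, taxa_order) {
  idx <- match(taxa_order, patterns$taxa)
  if (anyNA(idx))
    stop(sprintf("taxa in tree but not in alignment: %s",
                 paste(taxa_order[is.na(idx)], collapse = ", ")))
  pat <- patterns$patterns[idx, , drop = FALSE]
  npat <- ncol(pat)
  if (patterns$alphabet == "nucleotide") {
    out <- array(0, c(4, npat, length(taxa_order)))
    for (i in seq_along(taxa_order)) {
      chars <- pat[i, ]
      chars[!(chars %in% rownames(IUPAC_PARTIALS))] <- "N"
      out[, , i] <- t(IUPAC_PARTIALS[chars, , drop = FALSE])
    }
  } else {
    gc <- genetic_code_tables()
    out <- array(0, c(61, npat, length(taxa_order)))
    codon_partial <- function(cod) {
      ch <- strsplit(cod, "")[[1]]
      ch[!(ch %in% rownames(IUPAC_PARTIALS))] <- "N"
      p1 <- IUPAC_PARTIALS[ch[1], ]; p2 <- IUPAC_PARTIALS[ch[2], ]
      p3 <- IUPAC_PARTIALS[ch[3], ]
      p1[match(gc$chars[, 1], NUC)] * p2[match(gc$chars[, 2], NUC)] *
        p3[match(gc$chars[, 3], NUC)]
    }
    u <- unique(as.vector(pat))
    lut <- vapply(u, codon_partial, numeric(61))
    for (i in seq_along(taxa_order))
      out[, , i] <- lut[, match(pat[i, ], u)]
  }
  out
}

#' Phylogenetic log-likelihood under HKY(+gamma) or M0
#'
#' Felsenstein pruning over compressed site patterns, mixing over discrete
#' gamma categories with equal weights when the model carries a gamma shape.
#'
#' @param tree tree with branch lengths on every edge.
#' @param x a `seq_alignment` or the result of [compress_patterns()].
#' @param model [hky_params()] or [m0_params()].
#' @param gap gap policy forwarded to [compress_patterns()].
#' @return list with `lnL`, per-pattern `site_lnl`, `counts`.
#' @export
log_likelihood <- function(tree, x, model, gap = c("missing", "strict")) {
  gap <- match.arg(gap)
  patterns <- if (inherits(x, "seq_alignment")) compress_patterns(x, gap) else x
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has unset branch lengths")
  rm <- model_q(model)
  eg <- rate_matrix_eigen(rm)
  rw <- model_rates(model)
  site <- pruning_site_loglik(tree, patterns, eg, rw$rates, rw$weights)
  list(lnL = sum(site * patterns$counts), site_lnl = site,
       counts = patterns$counts)
}

# low-level entry used inside optimizers: eigendecomposition and partials
# are supplied by the caller so they can be cached
pruning_site_loglik_raw <- function(edge_post, elen_post, eg, tp, nnode, root,
                                    rates, weights) {
  cpp_mixture_loglik(edge_post, elen_post, eg$values, eg$vectors, eg$pi,
                     tp, rates, weights, nnode, root)
}

pruning_site_loglik <- function(tree, patterns, eg, rates, weights) {
  ord <- postorder_edges(tree)
  tp <- tip_partials(patterns, tree$tip.label)
  nnode <- n_tips(tree) + tree$Nnode
  pruning_site_loglik_raw(tree$edge[ord, , drop = FALSE],
                          tree$edge.length[ord], eg, tp, nnode,
                          root_node(tree), rates, weights)
}
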