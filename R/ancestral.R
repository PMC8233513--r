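# Marginal (empirical-Bayes) ancestral sequence reconstruction and Fitch
# parsimony counting of discrete trait changes.

#' Marginal ancestral state posteriors under HKY(+gamma)
#'
#' For each internal node and alignment column, the posterior probability of
#' each nucleotide given all tip data, computed by combining downward
#' partial likelihoods with the "flow" from the rest of the tree, and
#' averaging over gamma categories weighted by their per-site posterior
#' probability (set `category_weights = "equal"` for plain 1/K weights).
#'
#' @param tree tree with fitted branch lengths (rooted or unrooted; under a
#'   reversible model the reconstruction does not depend on root placement).
#' @param aln nucleotide `seq_alignment`.
#' @param model fitted [hky_params()].
#' @param gap gap policy.
#' @param category_weights `"posterior"` (default) or `"equal"`.
#' @return an `ancestral_posterior` object: `prob` (array internal-node x
#'   column x state), `map` (character matrix), `map_prob`, `tied` (logical
#'   matrix; ties broken by A<C<G<T order), `node_names`.
#' @export
marginal_reconstruction <- function(tree, aln, model, gap = "missing",
                                    category_weights = c("posterior", "equal")) {
  category_weights <- match.arg(category_weights)
  patterns <- compress_patterns(aln, gap)
  if (patterns$alphabet != "nucleotide")
    stop("ancestral reconstruction supports nucleotide alignments")
  rm <- hky_q(model)
  rw <- model_rates(model)
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  root <- root_node(tree)
  npat <- length(patterns$counts)
  tp <- tip_partials(patterns, tree$tip.label)
  ord <- postorder_edges(tree)
  kids <- children_list(tree)
  parent <- node_parents(tree)
  edge_of_child <- integer(nn)
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  K <- length(rw$rates)

  post_k <- vector("list", K)
  sitelik_k <- matrix(0, npat, K)
  for (k in seq_len(K)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(rm, tree$edge.length[e] * rw$rates[k]))
    # downward pass
    down <- vector("list", nn)
    for (i in seq_len(ntip)) down[[i]] <- tp[, , i, drop = TRUE]
    for (i in (ntip + 1L):nn) down[[i]] <- matrix(1, 4, npat)
    for (e in ord) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      down[[p]] <- down[[p]] * (P[[e]] %*% down[[ch]])
    }
    sitelik_k[, k] <- as.vector(rm$pi %*% down[[root]])
    # upward pass ("flow" from the rest of the tree)
    flow <- vector("list", nn)
    flow[[root]] <- matrix(rm$pi, 4, npat)
    for (e in rev(ord)) {   # preorder: parents before children
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip) next
      sib_prod <- matrix(1, 4, npat)
      for (s in setdiff(kids[[p]], ch)) {
        es <- edge_of_child[s]
        sib_prod <- sib_prod * (P[[es]] %*% down[[s]])
      }
      flow[[ch]] <- t(P[[e]]) %*% (flow[[p]] * sib_prod)
    }
    pk <- array(0, c(tree$Nnode, npat, 4))
    for (v in (ntip + 1L):nn) {
      raw <- t(flow[[v]] * down[[v]])  # npat x 4
      pk[v - ntip, , ] <- raw / rowSums(raw)
    }
    post_k[[k]] <- pk
  }

  w <- if (category_weights == "posterior") {
    wk <- sweep(sitelik_k, 2, rw$weights, "*")
    wk / rowSums(wk)
  } else {
    matrix(1 / K, npat, K)
  }
  prob_pat <- array(0, c(tree$Nnode, npat, 4))
  for (k in seq_len(K))
    prob_pat <- prob_pat + post_k[[k]] * rep(w[, k], each = tree$Nnode)

  # expand patterns back to alignment columns
  prob <- prob_pat[, patterns$index, , drop = FALSE]
  map_idx <- apply(prob, c(1, 2), which.max)
  mx <- apply(prob, c(1, 2), max)
  tied <- apply(prob, c(1, 2), function(p) sum(abs(p - max(p)) < 1e-12) > 1L)
  node_names <- internal_node_names(tree)
  dimnames(prob) <- list(node_names, NULL, NUC)
  structure(list(prob = prob,
                 map = matrix(NUC[map_idx], tree$Nnode,
                              dimnames = list(node_names, NULL)),
                 map_prob = mx, tied = tied,
                 node_names = node_names,
                 method = "marginal (empirical Bayes)",
                 category_weights = category_weights),
            class = "ancestral_posterior")
}

internal_node_names <- function(tree) {
  ntip <- n_tips(tree)
  nm <- paste0("node", (ntip + 1L):(ntip + tree$Nnode))
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    ok <- !is.na(lab) & nzchar(lab)
    nm[ok] <- lab[ok]
  }
  nm
}

#' Extract MAP states and probabilities at chosen nodes and columns
#'
#' @param post an `ancestral_posterior`.
#' @param nodes internal node names (default all).
#' @param columns 1-based alignment columns (default all).
#' @return data.frame with node, column (1-based), MAP state, its
#'   probability, a tie flag, and the four posterior probabilities.
#' @export
extract_sites <- function(post, nodes = NULL, columns = NULL) {
  if (is.null(nodes)) nodes <- post$node_names
  if (is.null(columns)) columns <- seq_len(ncol(post$map))
  ni <- match(nodes, post$node_names)
  if (anyNA(ni))
    stop(sprintf("unknown node name(s): %s",
                 paste(nodes[is.na(ni)], collapse = ", ")))
  if (any(columns < 1L | columns > ncol(post$map)))
    stop("column index out of range")
  grid <- expand.grid(node = ni, column = columns)
  out <- data.frame(
    node = post$node_names[grid$node],
    column = grid$column,
    map_state = post$map[cbind(grid$node, grid$column)],
    prob = post$map_prob[cbind(grid$node, grid$column)],
    tied = post$tied[cbind(grid$node, grid$column)],
    stringsAsFactors = FALSE)
  for (s in NUC)
    out[[paste0("p_", s)]] <- post$prob[cbind(grid$node, grid$column,
                                              match(s, NUC))]
  out
}

#' Write MAP ancestral sequences to FASTA
#' @export
write_ancestral_fasta <- function(post, path, nodes = NULL) {
  if (is.null(nodes)) nodes <- post$node_names
  ni <- match(nodes, post$node_names)
  seqs <- apply(post$map[ni, , drop = FALSE], 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", nodes), seqs)), path)
  invisible(path)
}

# ---- Fitch parsimony ---------------------------------------------------

#' Minimum number of discrete state changes on a tree (Fitch parsimony)
#'
#' Bottom-up set intersections/unions count the forced changes; a top-down
#' pass returns one optimal assignment of internal states.  Children at a
#' polytomy are combined sequentially, which equals an arbitrary resolution
#' of the polytomy (a warning is issued).
#'
#' @param tree a tree (branch lengths not used).
#' @param tip_states named vector of states (coerced to character) per tip;
#'   `NA` handling per `missing`.
#' @param missing `"wildcard"` treats missing tips as compatible with every
#'   state; `"error"` refuses them.
#' @return list with `changes` (integer) and `states` (one optimal
#'   assignment, named by tip and internal node).
#' @export
fitch_min_changes <- function(tree, tip_states,
                              missing = c("wildcard", "error")) {
  missing <- match.arg(missing)
  ntip <- n_tips(tree)
  kids <- children_list(tree)
  deg <- lengths(kids)
  if (any(deg > 2L & seq_along(deg) != root_node(tree)) ||
      (is_rooted_tree(tree) && deg[root_node(tree)] > 2L) ||
      deg[root_node(tree)] > 3L)
    warning("polytomies resolved arbitrarily for Fitch counting")
  if (is.null(names(tip_states))) {
    if (length(tip_states) != ntip)
      stop("unnamed tip_states must have one entry per tip")
    x <- tip_states
  } else {
    x <- tip_states[tree$tip.label]
  }
  if (anyNA(x) && missing == "error") {
    bad <- tree$tip.label[is.na(x)]
    stop(sprintf("missing state for tip(s): %s", paste(bad, collapse = ", ")))
  }
  lev <- sort(unique(as.character(x[!is.na(x)])))
  if (length(lev) == 0L) stop("all tip states are missing")
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip))
    sets[[i]] <- if (is.na(x[i])) lev else as.character(x[i])
  changes <- 0L
  ord <- postorder_edges(tree)
  done <- logical(nn)
  for (e in ord) {
    p <- tree$edge[e, 1]
    if (done[p]) next
    ch <- kids[[p]]
    s <- sets[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(s, sets[[c2]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[c2]]); changes <- changes + 1L }
    }
    sets[[p]] <- s
    done[p] <- TRUE
  }
  # top-down: one optimal assignment
  states <- character(nn)
  root <- root_node(tree)
  states[root] <- sort(sets[[root]])[1]
  for (e in rev(ord)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    states[ch] <- if (states[p] %in% sets[[ch]]) states[p]
    else sort(sets[[ch]])[1]
  }
  names(states) <- c(tree$tip.label, internal_node_names(tree))
  list(changes = changes, states = states)
}
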