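# Trees with per-branch rate classes.
#
# The tree container is an ape-compatible "phylo" (edge matrix, edge.length,
# tip.label, Nnode) extended with `edge.class`, an integer rate-class label
# per branch (0 = background).  Class marks follow the PAML convention:
# "#k" labels a single branch, "$k" labels a branch and its whole subtree.

#' Parse a Newick string into a rate-class labelled tree
#'
#' Accepts standard Newick with optional branch lengths and node labels, plus
#' PAML-style rate-class marks: `#k` after a tip or clade labels that single
#' branch with class `k`; `$k` labels the branch and every branch descending
#' from it.  Unmarked branches carry class 0 (the background class).
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an object of class `c("clock_tree", "phylo")` with elements
#'   `edge`, `edge.length`, `tip.label`, `Nnode`, `node.label` and
#'   `edge.class` (integer per edge row).
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[ \t\r\n]+", "", text)
  if (!nzchar(s)) stop("empty Newick string")
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))

  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$s <- s
  env$n <- nchar(s)

  peek <- function() if (env$i > env$n) "" else substr(env$s, env$i, env$i)
  advance <- function() env$i <- env$i + 1L

  read_label <- function() {
    start <- env$i
    while (env$i <= env$n && !substr(env$s, env$i, env$i) %in%
           c("(", ")", ",", ":", ";", "#", "$")) {
      advance()
    }
    substr(env$s, start, env$i - 1L)
  }
  read_number <- function(what) {
    start <- env$i
    while (env$i <= env$n && grepl("[-+0-9.eE]", substr(env$s, env$i, env$i)))
      advance()
    tok <- substr(env$s, start, env$i - 1L)
    x <- suppressWarnings(as.numeric(tok))
    if (is.na(x)) stop(sprintf("expected %s, got '%s' at position %d",
                               what, tok, start))
    x
  }
  read_annotations <- function(node) {
    repeat {
      ch <- peek()
      if (ch == "#" || ch == "$") {
        advance()
        k <- read_number("rate-class integer")
        if (k != round(k) || k < 0)
          stop(sprintf("rate-class mark must be a non-negative integer, got %s", k))
        node$mark <- as.integer(k)
        node$mark_clade <- (ch == "$")
      } else if (ch == ":") {
        advance()
        len <- read_number("branch length")
        if (len < 0)
          stop(sprintf("negative branch length '%s' at position %d",
                       format(len), env$i))
        node$len <- len
      } else {
        break
      }
    }
    node
  }
  parse_subtree <- function() {
    node <- list(children = list(), label = "", len = NA_real_,
                 mark = NA_integer_, mark_clade = FALSE)
    if (peek() == "(") {
      advance()
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_subtree()
        ch <- peek()
        if (ch == ",") { advance(); next }
        if (ch == ")") { advance(); break }
        stop(sprintf("unexpected token '%s' at position %d", ch, env$i))
      }
      node$label <- read_label()
    } else {
      node$label <- read_label()
      if (!nzchar(node$label))
        stop(sprintf("expected tip label at position %d", env$i))
    }
    read_annotations(node)
  }

  root <- parse_subtree()
  if (peek() != ";")
    stop(sprintf("expected ';' at position %d, got '%s'", env$i, peek()))
  if (length(root$children) == 0L) stop("tree must have at least 2 tips")

  # flatten: tips numbered in order of appearance, internals in preorder
  tips <- character(0)
  count_tips <- function(nd) {
    if (length(nd$children) == 0L) tips[[length(tips) + 1L]] <<- nd$label
    else for (ch in nd$children) count_tips(ch)
  }
  count_tips(root)
  ntip <- length(tips)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tips))
    stop(sprintf("duplicate tip name(s): %s",
                 paste(unique(tips[duplicated(tips)]), collapse = ", ")))

  edge_p <- integer(0); edge_c <- integer(0)
  edge_len <- numeric(0); edge_cls <- integer(0)
  node_lab <- character(0)
  tip_i <- 0L; int_i <- ntip

  assign_ids <- function(nd, parent_id, inherited_class) {
    cls <- if (!is.na(nd$mark)) nd$mark else inherited_class
    if (length(nd$children) == 0L) {
      tip_i <<- tip_i + 1L
      id <- tip_i
    } else {
      int_i <<- int_i + 1L
      id <- int_i
      node_lab[[id - ntip]] <<- nd$label
    }
    if (!is.na(parent_id)) {
      edge_p <<- c(edge_p, parent_id)
      edge_c <<- c(edge_c, id)
      edge_len <<- c(edge_len, nd$len)
      edge_cls <<- c(edge_cls, cls)
    }
    # "#k" marks only this branch; "$k" propagates to the subtree
    down_class <- if (!is.na(nd$mark) && nd$mark_clade) nd$mark else inherited_class
    if (length(nd$children) > 0L)
      for (ch in nd$children) assign_ids(ch, id, down_class)
    invisible(NULL)
  }
  assign_ids(root, NA_integer_, 0L)

  tr <- list(edge = cbind(edge_p, edge_c, deparse.level = 0),
             edge.length = edge_len,
             tip.label = tips,
             Nnode = int_i - ntip,
             node.label = node_lab,
             edge.class = as.integer(edge_cls))
  if (all(is.na(tr$edge.length))) tr$edge.length <- NULL
  class(tr) <- c("clock_tree", "phylo")
  tr
}

#' Serialize a labelled tree to Newick
#'
#' Non-zero branch classes are written as per-branch `#k` marks, which
#' `parse_newick()` reads back to an identical labelling.
#'
#' @param tree a `clock_tree`/`phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ntip <- n_tips(tree)
  kids <- children_list(tree)
  cls <- edge_classes(tree)
  has_len <- !is.null(tree$edge.length)
  edge_of <- integer(ntip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  fmt <- function(node) {
    if (node <= ntip) {
      out <- tree$tip.label[node]
    } else {
      lab <- if (!is.null(tree$node.label) && node - ntip <= length(tree$node.label))
        tree$node.label[node - ntip] else ""
      if (is.na(lab)) lab <- ""
      out <- paste0("(", paste(vapply(kids[[node]], fmt, ""), collapse = ","),
                    ")", lab)
    }
    e <- edge_of[node]
    if (node != root_node(tree) && e > 0L) {
      if (cls[e] != 0L) out <- paste0(out, " #", cls[e])
      if (has_len) out <- paste0(out, ":", format(tree$edge.length[e],
                                                  digits = digits))
    }
    out
  }
  paste0(fmt(root_node(tree)), ";")
}

# ---- small structural helpers ------------------------------------------

#' @export
n_tips <- function(tree) length(tree$tip.label)

#' @export
root_node <- function(tree) n_tips(tree) + 1L

#' Children of every node, as a list indexed by node id
#' @keywords internal
children_list <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

#' Edge classes, defaulting to all-background
#' @keywords internal
edge_classes <- function(tree) {
  if (is.null(tree$edge.class)) rep(0L, nrow(tree$edge)) else tree$edge.class
}

#' Is the tree rooted (root has exactly two children)?
#' @export
is_rooted_tree <- function(tree) {
  sum(tree$edge[, 1] == root_node(tree)) == 2L
}

#' Postorder permutation of edge rows (children before parents)
#' @keywords internal
postorder_edges <- function(tree) {
  # edges are stored in DFS preorder by the parser; recompute to be safe
  nn <- n_tips(tree) + tree$Nnode
  edge_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  order <- integer(0)
  stack <- root_node(tree)
  pre <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    es <- edge_of[[as.character(nd)]]
    if (!is.null(es)) {
      pre <- c(pre, es)
      stack <- c(stack, tree$edge[es, 2])
    }
  }
  rev(pre)
}

#' Depth (distance from the root) of every node
#' @keywords internal
node_depths <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  depth <- numeric(nn)
  ord <- rev(postorder_edges(tree))  # preorder: parents before children
  for (e in ord)
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
  depth
}

#' Parent of every node (0 for the root)
#' @keywords internal
node_parents <- function(tree) {
  par <- integer(n_tips(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

#' Pairwise patristic distances between tips
#'
#' @param tree a tree with branch lengths.
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
tip_distances <- function(tree) {
  ntip <- n_tips(tree)
  depth <- node_depths(tree)
  par <- node_parents(tree)
  anc <- function(i) {
    out <- i
    while (par[i] != 0L) { i <- par[i]; out <- c(out, i) }
    out
  }
  ancs <- lapply(seq_len(ntip), anc)
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) for (j in (i + 1L):ntip) {
    m <- intersect(ancs[[i]], ancs[[j]])[1L]  # ancestors listed tipward-first
    d[i, j] <- d[j, i] <- depth[i] + depth[j] - 2 * depth[m]
  }
  d
}

#' Most recent common ancestor of a set of tip names
#' @export
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop(sprintf("unknown tip(s): %s", paste(tips[is.na(idx)], collapse = ", ")))
  if (length(idx) == 1L) return(idx)
  par <- node_parents(tree)
  anc <- function(i) {
    out <- i
    while (par[i] != 0L) { i <- par[i]; out <- c(out, i) }
    out
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[1L]
}

#' Edge indices in the subtree below a node (optionally plus the stem edge)
#' @keywords internal
clade_edges <- function(tree, node, include_stem = FALSE) {
  edge_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    es <- edge_of[[as.character(nd)]]
    if (!is.null(es)) {
      out <- c(out, es)
      stack <- c(stack, tree$edge[es, 2])
    }
  }
  if (include_stem) {
    stem <- which(tree$edge[, 2] == node)
    out <- c(stem, out)
  }
  sort(out)
}

#' Resolve a branch selector to edge indices
#'
#' Selectors: an integer vector of edge indices; `list(tip = "name")` for the
#' terminal branch above a tip; `list(mrca = c(...), stem_only = TRUE)` for
#' the stem branch of the clade spanned by the named tips;
#' `list(mrca = c(...), include_stem = FALSE)` for all branches inside that
#' clade (crown), with `include_stem = TRUE` adding the stem.
#' @export
resolve_branches <- function(tree, selector) {
  if (is.numeric(selector)) {
    idx <- as.integer(selector)
    if (any(idx < 1L | idx > nrow(tree$edge)))
      stop("edge index out of range")
    return(idx)
  }
  if (!is.list(selector)) stop("selector must be an edge index vector or a list")
  if (!is.null(selector$tip)) {
    i <- match(selector$tip, tree$tip.label)
    if (is.na(i)) stop(sprintf("unknown tip '%s'", selector$tip))
    return(which(tree$edge[, 2] == i))
  }
  if (!is.null(selector$mrca)) {
    node <- mrca_node(tree, selector$mrca)
    if (isTRUE(selector$stem_only)) {
      stem <- which(tree$edge[, 2] == node)
      if (length(stem) == 0L)
        stop("clade stem selector resolves to the root; no stem branch exists")
      return(stem)
    }
    return(clade_edges(tree, node, include_stem = isTRUE(selector$include_stem)))
  }
  stop("selector must contain 'tip' or 'mrca'")
}

#' Assign rate classes to branches from a list of selectors
#'
#' @param tree a tree.
#' @param labeling a list of entries, each `list(class = k, ...)` where the
#'   remaining fields form a selector understood by [resolve_branches()].
#'   Selected branch sets must be disjoint; unselected branches get class 0.
#' @return the tree with `edge.class` set.
#' @export
label_branches <- function(tree, labeling) {
  cls <- rep(0L, nrow(tree$edge))
  taken <- rep(FALSE, nrow(tree$edge))
  for (entry in labeling) {
    if (is.null(entry$class)) stop("each labeling entry needs a 'class'")
    k <- as.integer(entry$class)
    sel <- entry[setdiff(names(entry), "class")]
    idx <- resolve_branches(tree, sel)
    if (any(taken[idx]))
      stop("branch selectors overlap: a branch was assigned two classes")
    taken[idx] <- TRUE
    cls[idx] <- k
  }
  tree$edge.class <- cls
  tree
}

#' Read a branch labelling from a YAML file
#'
#' The file holds a list of blocks, e.g.
#' `- {class: 1, mrca: [A, B], stem_only: true}`.
#' @export
read_branch_labels <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.list(spec)) stop("labeling YAML must be a list of selector blocks")
  lapply(spec, function(b) {
    if (!is.null(b$mrca)) b$mrca <- as.character(unlist(b$mrca))
    b
  })
}

#' Normalize rate classes to a contiguous set 0..C-1
#'
#' Class 0 stays 0; other classes are renumbered in increasing order.
#' @export
normalize_classes <- function(tree) {
  cls <- edge_classes(tree)
  u <- sort(unique(cls[cls != 0L]))
  tree$edge.class <- ifelse(cls == 0L, 0L, match(cls, u))
  tree$edge.class <- as.integer(tree$edge.class)
  tree
}

#' Remove the root by merging its two child branches
#' @export
unroot_tree <- function(tree) {
  if (!is_rooted_tree(tree)) return(tree)
  ntip <- n_tips(tree)
  root <- root_node(tree)
  es <- which(tree$edge[, 1] == root)
  c1 <- tree$edge[es[1], 2]; c2 <- tree$edge[es[2], 2]
  cls <- edge_classes(tree)
  # attach child c2 (or c1 if c2 is a tip) under the other child
  keep <- if (c2 > ntip) c2 else c1
  move <- if (keep == c2) c1 else c2
  ek <- es[which(tree$edge[es, 2] == keep)]
  em <- es[which(tree$edge[es, 2] == move)]
  if (keep <= ntip) stop("cannot unroot a 2-tip tree")
  newlen <- tree$edge.length[ek] + tree$edge.length[em]
  newcls <- max(cls[ek], cls[em])
  # rebuild: drop root, make `keep` the new basal node
  edge <- tree$edge; len <- tree$edge.length
  edge[em, 1] <- keep
  len[em] <- newlen
  cls[em] <- newcls
  drop <- ek
  edge <- edge[-drop, , drop = FALSE]
  len <- len[-drop]; cls <- cls[-drop]
  # renumber: nodes > root shift down by one
  edge[edge > root] <- edge[edge > root] - 1L
  tree$edge <- edge
  tree$edge.length <- len
  tree$edge.class <- as.integer(cls)
  tree$Nnode <- tree$Nnode - 1L
  if (!is.null(tree$node.label)) tree$node.label <- tree$node.label[-1L]
  tree <- renumber_preorder(tree)
  tree
}

#' Re-root a tree on a chosen branch
#'
#' A new root node is inserted on the selected branch at `position` times the
#' branch length away from the child end.  Patristic distances between tips
#' are unchanged; branch classes stay attached to their (undirected) branches,
#' the split branch keeping its class on both halves.
#'
#' @param tree tree (rooted trees are unrooted first).
#' @param selector a branch selector ([resolve_branches()]) resolving to one branch.
#' @param position fraction in `[0, 1]`, measured from the child end.
#' @export
root_on_edge <- function(tree, selector, position = 0.5) {
  stopifnot(position >= 0, position <= 1)
  tree <- unroot_tree(tree)
  idx <- resolve_branches(tree, selector)
  if (length(idx) != 1L)
    stop(sprintf("selector resolves to %d branches; need exactly 1", length(idx)))
  ntip <- n_tips(tree)
  cls <- edge_classes(tree)
  p <- tree$edge[idx, 1]; ch <- tree$edge[idx, 2]
  L <- tree$edge.length[idx]; k <- cls[idx]

  # new node ids: everything >= ntip+1 shifts by one, new root = ntip+1
  edge <- tree$edge; len <- tree$edge.length
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  p2 <- if (p > ntip) p + 1L else p
  ch2 <- if (ch > ntip) ch + 1L else ch
  newroot <- ntip + 1L
  edge <- edge[-idx, , drop = FALSE]
  len <- len[-idx]; cls2 <- cls[-idx]
  edge <- rbind(c(newroot, ch2), c(newroot, p2), edge)
  len <- c(position * L, (1 - position) * L, len)
  cls2 <- c(k, k, cls2)

  # flip edges on the path from p2 up to the old basal node (skipping the
  # edge flipped in the previous step, whose child is now p2 again)
  prev <- integer(0)
  repeat {
    up <- setdiff(which(edge[, 2] == p2), c(1:2, prev))
    if (length(up) == 0L) break
    edge[up, ] <- edge[up, 2:1]
    prev <- up
    p2 <- edge[up, 2]
  }
  tree$edge <- edge
  tree$edge.length <- len
  tree$edge.class <- as.integer(cls2)
  tree$Nnode <- tree$Nnode + 1L
  tree$node.label <- NULL
  renumber_preorder(tree)
}

# Renumber internal nodes so they follow preorder from the basal node and the
# edge rows are in DFS preorder (the format the rest of the package assumes).
#' @keywords internal
renumber_preorder <- function(tree) {
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  # basal node: internal node that never appears as a child
  internal <- (ntip + 1L):nn
  basal <- setdiff(internal, tree$edge[, 2])
  if (length(basal) != 1L) stop("malformed tree: no unique basal node")
  edge_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  newid <- integer(nn)
  newid[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip
  order_edges <- integer(0)
  stack <- basal
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd > ntip) { nxt <- nxt + 1L; newid[nd] <- nxt }
    es <- edge_of[[as.character(nd)]]
    if (!is.null(es)) {
      es <- rev(es)  # preserve child order when using a LIFO stack
      order_edges <- c(order_edges, rev(es))
      stack <- c(stack, tree$edge[es, 2])
    }
  }
  lab <- tree$node.label
  tree$edge <- cbind(newid[tree$edge[order_edges, 1]],
                     newid[tree$edge[order_edges, 2]], deparse.level = 0)
  tree$edge.length <- tree$edge.length[order_edges]
  if (!is.null(tree$edge.class))
    tree$edge.class <- tree$edge.class[order_edges]
  if (!is.null(lab)) {
    newlab <- rep(NA_character_, tree$Nnode)
    old_int <- which(newid > ntip)
    for (o in seq_along(newid)) {
      if (o > ntip && o - ntip <= length(lab))
        newlab[newid[o] - ntip] <- lab[o - ntip]
    }
    tree$node.label <- newlab
  }
  tree
}
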