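# Seeded simulators: sequences along trees (HKY+gamma, M0 codon), binary
# traits with phylogenetic signal, and the bundled fixture trees.

sim_states_along_tree <- function(tree, rm, nsite, rates, weights,
                                  class_rates) {
  ns <- length(rm$labels)
  cls <- edge_classes(tree)
  cat_of_site <- sample.int(length(rates), nsite, replace = TRUE,
                            prob = weights)
  nn <- n_tips(tree) + tree$Nnode
  states <- matrix(0L, nn, nsite)
  root <- root_node(tree)
  states[root, ] <- sample.int(ns, nsite, replace = TRUE, prob = rm$pi)
  ord <- rev(postorder_edges(tree))  # preorder: parents before children
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_eff <- tree$edge.length[e] * class_rates[cls[e] + 1L]
    for (k in seq_along(rates)) {
      P <- transition_matrix(rm, t_eff * rates[k])
      for (s in unique(states[p, cat_of_site == k])) {
        idx <- which(states[p, ] == s & cat_of_site == k)
        states[ch, idx] <- sample.int(ns, length(idx), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  states[seq_len(n_tips(tree)), , drop = FALSE]
}

#' Simulate a nucleotide alignment along a tree
#'
#' Root states are drawn from the stationary frequencies and evolved down
#' the tree under HKY(+discrete gamma); per-branch rate-class multipliers
#' scale the branch lengths.  Site-wise gamma categories are drawn from the
#' same K discrete categories used in inference, so simulation and fitting
#' share one model.
#'
#' @param tree tree with branch lengths (and optionally `edge.class`).
#' @param model an [hky_params()] object.
#' @param nsites number of sites.
#' @param class_rates multiplier per rate class (class 0 first); default all 1.
#' @param seed RNG seed (recorded in the result's attributes).
#' @return a `seq_alignment` with a `seed` attribute.
#' @export
simulate_alignment <- function(tree, model, nsites, class_rates = NULL,
                               seed = 1L) {
  stopifnot(inherits(model, "hky_params"), nsites >= 1)
  nclass <- max(edge_classes(tree)) + 1L
  if (is.null(class_rates)) class_rates <- rep(1, nclass)
  stopifnot(length(class_rates) >= nclass, all(class_rates > 0))
  set.seed(seed)
  rm <- hky_q(model)
  rw <- model_rates(model)
  tips <- sim_states_along_tree(tree, rm, nsites, rw$rates, rw$weights,
                                class_rates)
  mat <- matrix(NUC[tips], nrow = nrow(tips),
                dimnames = list(tree$tip.label, NULL))
  out <- new_alignment(mat, "nucleotide")
  attr(out, "seed") <- seed
  out
}

#' Simulate a codon alignment under the M0 model
#'
#' @param tree tree with branch lengths (and optionally `edge.class`).
#' @param model an [m0_params()] object with codon frequencies set.
#' @param ncodons number of codons.
#' @param class_rates multiplier per rate class; default all 1.
#' @param seed RNG seed.
#' @return a codon `seq_alignment` (no stop codons by construction).
#' @export
simulate_codon_alignment <- function(tree, model, ncodons, class_rates = NULL,
                                     seed = 1L) {
  stopifnot(inherits(model, "m0_params"), ncodons >= 1)
  nclass <- max(edge_classes(tree)) + 1L
  if (is.null(class_rates)) class_rates <- rep(1, nclass)
  set.seed(seed)
  rm <- m0_q(model)
  tips <- sim_states_along_tree(tree, rm, ncodons, 1, 1, class_rates)
  codons <- sense_codons()
  chars <- matrix("", nrow(tips), 3L * ncodons,
                  dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(nrow(tips))) {
    chars[i, ] <- unlist(strsplit(codons[tips[i, ]], ""))
  }
  out <- new_alignment(chars, "codon")
  attr(out, "seed") <- seed
  out
}

#' Simulate a binary trait with phylogenetic signal
#'
#' Latent threshold model: tip liabilities are multivariate normal with
#' correlation `exp(-decay * d_ij)` on patristic distances, shifted by the
#' linear predictor `X %*% beta`, and thresholded at zero.
#'
#' @param tree tree with branch lengths.
#' @param decay correlation decay rate per unit patristic distance (>= 0).
#' @param beta coefficient vector (include an intercept column in `X` if
#'   wanted).
#' @param X covariate matrix, rows in tree tip order.
#' @param seed RNG seed.
#' @return integer vector of 0/1 states named by tip.
#' @export
simulate_binary_trait <- function(tree, decay, beta, X, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == n_tips(tree), length(beta) == ncol(X),
            all(is.finite(X)), decay >= 0)
  set.seed(seed)
  D <- tip_distances(tree)
  Sigma <- exp(-decay * D)
  diag(Sigma) <- 1
  L <- chol(Sigma + diag(1e-8, nrow(Sigma)))
  z <- as.vector(t(L) %*% stats::rnorm(nrow(Sigma)))
  liab <- as.vector(X %*% beta) + z
  stats::setNames(as.integer(liab > 0), tree$tip.label)
}

# ---- fixture trees -----------------------------------------------------

# build an ultrametric Newick string from a nested (age, children) spec
ultrametric_nwk <- function(node, parent_age = NULL) {
  if (is.character(node)) {
    paste0(node, ":", format(parent_age, digits = 12))
  } else {
    inner <- paste(vapply(node$children, ultrametric_nwk, "",
                          parent_age = node$age), collapse = ",")
    if (is.null(parent_age)) paste0("(", inner, ");")
    else paste0("(", inner, "):", format(parent_age - node$age, digits = 12))
  }
}

nd <- function(age, ...) list(age = age, children = list(...))

#' Bundled 13-taxon primate tree fixture
#'
#' A rooted ultrametric tree of 13 primates (mouse-lemur rooting) with
#' plausible depths in expected class-0 substitutions per site.  The stem
#' branch of the Old World monkeys (Cercopithecidae) carries rate class 1
#' (the focal branch of the acceleration test) and the hominoid crown clade
#' carries class 2; these branch lengths are synthetic fixtures, not
#' estimates from any real alignment.
#'
#' @param include_hominoid_stem also put the hominoid stem branch in class 2.
#' @return a `clock_tree` with `edge.class` set.
#' @export
fixture_primate_tree <- function(include_hominoid_stem = FALSE) {
  spec <- nd(0.10,
    "Mouse_lemur",
    nd(0.085,
      "Tarsier",
      nd(0.055,
        nd(0.025, "Marmoset", "Squirrel_monkey"),
        nd(0.035,
          nd(0.016,
            nd(0.006, "Rhesus_macaque", "Crab_eating_macaque"),
            nd(0.010, "Baboon", "Green_monkey")),
          nd(0.028,
            "Gibbon",
            nd(0.020,
              "Orangutan",
              nd(0.012, "Gorilla", nd(0.008, "Human", "Chimpanzee"))))))))
  tr <- parse_newick(ultrametric_nwk(spec))
  label_branches(tr, list(
    list(class = 1L, mrca = c("Rhesus_macaque", "Green_monkey"),
         stem_only = TRUE),
    list(class = 2L, mrca = c("Gibbon", "Human"),
         include_stem = include_hominoid_stem)))
}

#' Bundled 29-taxon mammal chronogram fixture
#'
#' A rooted ultrametric tree of 29 mammals with plausible divergence times
#' in million years (synthetic fixture loosely following consensus mammal
#' timetrees; not data from any specific study).
#'
#' @return a `clock_tree`.
#' @export
fixture_mammal_tree <- function() {
  spec <- nd(160,
    "Opossum",
    nd(100,
      nd(90,
        "Armadillo",
        nd(65, "Elephant", "Hyrax")),
      nd(95,
        nd(88,  # Euarchontoglires
          nd(80,  # Glires
            nd(50, "Rabbit", "Pika"),
            nd(72,
              "Squirrel",
              nd(70, "Guinea_pig", nd(20, "Mouse", "Rat")))),
          nd(74,  # primates
            "Mouse_lemur",
            nd(43,
              "Marmoset",
              nd(29,
                "Rhesus_macaque",
                nd(9, "Gorilla", nd(7, "Human", "Chimpanzee")))))),
        nd(85,  # Laurasiatheria
          nd(65, "Hedgehog", "Shrew"),
          nd(80,
            nd(58, "Microbat", "Megabat"),
            nd(78,
              nd(62,
                "Pig",
                nd(25, "Cow", nd(10, "Sheep", "Goat"))),
              nd(74,
                "Horse",
                nd(55,
                  "Cat",
                  nd(45, "Dog", nd(40, "Ferret", "Panda"))))))))))
  parse_newick(ultrametric_nwk(spec))
}
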