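test_that("parse_newick reads topology, lengths and rate-class marks", {
  tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
  expect_equal(n_tips(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  internal_edge <- which(tr$edge[, 2] > n_tips(tr))
  expect_equal(tr$edge.length[internal_edge], 0.5)

  tr2 <- parse_newick("((A,B)#1,C);")
  mark <- which(tr2$edge[, 2] == mrca_node(tr2, c("A", "B")))
  expect_equal(tr2$edge.class[mark], 1L)
  expect_true(all(tr2$edge.class[-mark] == 0L))

  tr3 <- parse_newick("((A:1,B:2)$3:0.5,C:1);")
  clade <- resolve_branches(tr3, list(mrca = c("A", "B"), include_stem = TRUE))
  expect_true(all(tr3$edge.class[clade] == 3L))
})

test_that("parse errors name the offending token", {
  expect_error(parse_newick("((A,B),C;"), "unbalanced")
  expect_error(parse_newick("((A,B),A);"), "duplicate tip")
  expect_error(parse_newick("((A:-0.5,B:1),C:1);"), "negative branch length")
})

test_that("Newick round trip is an isomorphism on topology, lengths, labels", {
  for (seed in 1:5) {
    tr <- random_tree(8, seed)
    tr$edge.class <- sample(0:2, nrow(tr$edge), replace = TRUE)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    d1 <- tip_distances(tr); d2 <- tip_distances(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
    # classes survive: compare per-branch classes via the split each edge makes
    key <- function(t) {
      sapply(seq_len(nrow(t$edge)), function(e) {
        below <- clockshift:::clade_edges(t, t$edge[e, 2], include_stem = FALSE)
        tips <- sort(t$tip.label[intersect(t$edge[below, 2],
                                           seq_len(n_tips(t)))])
        if (t$edge[e, 2] <= n_tips(t)) tips <- t$tip.label[t$edge[e, 2]]
        paste(tips, collapse = "|")
      })
    }
    k1 <- key(tr); k2 <- key(tr2)
    expect_equal(tr2$edge.class[match(k1, k2)], tr$edge.class)
  }
})

test_that("clade selectors are invariant to child rotation", {
  a <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  b <- parse_newick("((D:1,C:1):1,(B:1,A:1):1);")
  sel <- list(mrca = c("C", "D"), include_stem = FALSE)
  tips_of <- function(t, idx) sort(t$tip.label[t$edge[idx, 2][t$edge[idx, 2] <= n_tips(t)]])
  expect_equal(tips_of(a, resolve_branches(a, sel)),
               tips_of(b, resolve_branches(b, sel)))
})

test_that("root_on_edge preserves pairwise patristic distances", {
  # tip case with explicit arithmetic
  star <- parse_newick("(A:1,B:1,C:1.5);")
  rooted <- root_on_edge(star, list(tip = "C"), position = 0.5)
  expect_true(is_rooted_tree(rooted))
  d <- tip_distances(rooted)
  expect_equal(d["C", "A"], 2.5)

  for (seed in 1:50) {
    tr <- unroot_tree(random_tree(8, seed))
    d0 <- tip_distances(tr)
    edge_pick <- 1L + (seed %% nrow(tr$edge))
    r <- root_on_edge(tr, edge_pick, position = 0.3)
    d1 <- tip_distances(r)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-9)
    # oracle route: ape computes the same matrix
    d_ape <- ape::cophenetic.phylo(r)[rownames(d0), colnames(d0)]
    expect_equal(d_ape, d0, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("rooting then unrooting recovers the unrooted metric", {
  tr <- random_tree(7, 99)
  r <- root_on_edge(tr, 3L, position = 0.25)
  u <- unroot_tree(r)
  expect_false(is_rooted_tree(u))
  expect_equal(tip_distances(u)[tr$tip.label, tr$tip.label],
               tip_distances(tr), tolerance = 1e-9)
})

test_that("alignment readers parse FASTA and PHYLIP to equal matrices", {
  fa <- tempfile(fileext = ".fa"); ph <- tempfile(fileext = ".phy")
  writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
  writeLines(c("2 4", "s1  ACGT", "s2  ACGA"), ph)
  a1 <- read_alignment(fa, "fasta")
  a2 <- read_alignment(ph, "phylip")
  expect_equal(dim(a1), c(2L, 4L))
  expect_equal(unclass(a1), unclass(a2), ignore_attr = TRUE)

  # unknown characters become fully ambiguous; case-insensitive
  writeLines(c(">s1", "acgz"), fa)
  a3 <- read_alignment(fa, "fasta")
  expect_equal(unname(unclass(a3)[1, 4]), "N")
})

test_that("codon mode rejects in-frame stops with a position report", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATGTAACCC", ">s2", "ATGAAACCC"), fa)
  expect_error(read_alignment(fa, "fasta", "codon"), "s1.*codon 2")
  writeLines(c(">s1", "ATGAAACC"), fa)
  expect_error(read_alignment(fa, "fasta", "codon"), "divisible by 3")
})

test_that("pattern compression preserves counts and likelihood", {
  m <- matrix(c("A", "A", "C",
                "A", "A", "G"), nrow = 2, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  pats <- compress_patterns(clockshift:::new_alignment(m))
  expect_equal(length(pats$counts), 2L)
  expect_equal(sum(pats$counts), 3L)
  expect_equal(sort(pats$counts), c(1L, 2L))

  tr <- random_tree(5, 11)
  aln <- random_alignment(5, 200, 12, tr$tip.label)
  mod <- hky_params(kappa = 3, pi = c(.3, .2, .2, .3), alpha = .6, ncat = 3)
  ll_pat <- log_likelihood(tr, aln, mod)
  # column-by-column evaluation (no compression benefit)
  ll_cols <- sum(vapply(seq_len(ncol(aln)), function(j) {
    one <- clockshift:::new_alignment(aln[, j, drop = FALSE])
    log_likelihood(tr, one, mod)$lnL
  }, numeric(1)))
  expect_equal(ll_pat$lnL, ll_cols, tolerance = 1e-10)
})

test_that("strict gap policy drops gapped columns", {
  m <- matrix(c("A", "-", "C",
                "A", "A", "C"), nrow = 2, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  aln <- clockshift:::new_alignment(m)
  expect_equal(sum(compress_patterns(aln, "strict")$counts), 2L)
  expect_equal(sum(compress_patterns(aln, "missing")$counts), 3L)
})

test_that("branch labelling from YAML resolves and rejects overlap", {
  tr <- fixture_primate_tree()
  yml <- tempfile(fileext = ".yaml")
  writeLines(paste(
    "- class: 1",
    "  mrca: [Rhesus_macaque, Green_monkey]",
    "  stem_only: true",
    "- class: 2",
    "  mrca: [Gibbon, Human]",
    "  include_stem: false", sep = "\n"), yml)
  tr2 <- label_branches(tr, read_branch_labels(yml))
  expect_equal(tr2$edge.class, tr$edge.class)
  expect_error(label_branches(tr, list(
    list(class = 1, mrca = c("Human", "Chimpanzee")),
    list(class = 2, mrca = c("Gorilla", "Human")))), "overlap")
})

test_that("class normalization yields contiguous labels with 0 preserved", {
  tr <- parse_newick("((A:1,B:1)#5:1,(C:1,D:1)#2:1);")
  trn <- normalize_classes(tr)
  expect_setequal(unique(trn$edge.class), c(0L, 1L, 2L))
  expect_equal(trn$edge.class[tr$edge.class == 0L],
               rep(0L, sum(tr$edge.class == 0L)))
  expect_true(all(trn$edge.class[tr$edge.class == 5L] == 2L))
})
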