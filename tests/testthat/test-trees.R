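test_that("Newick reading validates rootedness and round-trips topology", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)

  expect_error(read_newick("((a:1,b:1):1,c:1,d:1);"), "basal polytomy|unrooted")
  expect_error(read_newick(text = "((a:1,b:1):1;", file = "x"), "exactly one")

  # round trip on a random 50-leaf tree: identical bipartitions and lengths
  tr50 <- generate_toy_tree(50, seed = 7, depth = 0.4)
  tr50b <- read_newick(write_newick(tr50))
  pp_a <- ape::prop.part(tr50)
  pp_b <- ape::prop.part(tr50b)
  set_of <- function(pp, tr) {
    labs <- attr(pp, "labels")
    sort(vapply(pp, function(i) paste(sort(labs[i]), collapse = "|"), ""))
  }
  expect_identical(set_of(pp_a, tr50), set_of(pp_b, tr50b))
  d <- ape::cophenetic.phylo(tr50)
  expect_equal(ape::cophenetic.phylo(tr50b)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
})

test_that("eligible_nodes matches a brute-force clade-size scan", {
  tr8 <- balanced_tree(8)
  el <- eligible_nodes(tr8, 4)
  # a balanced 8-leaf tree has exactly two non-root internal nodes with 4 tips
  sizes <- vapply(el, function(nd) length(unlist(
    phangorn::Descendants(tr8, nd, "tips"))), integer(1))
  expect_equal(length(el), 2)
  expect_true(all(sizes == 4))

  tr <- generate_toy_tree(20, seed = 3)
  for (m in c(2, 4, 7)) {
    el <- eligible_nodes(tr, m)
    root <- ape::Ntip(tr) + 1L
    all_int <- root + seq_len(tr$Nnode) - 1L
    brute <- all_int[vapply(all_int, function(nd)
      nd != root && length(unlist(phangorn::Descendants(tr, nd, "tips"))) >= m,
      logical(1))]
    expect_setequal(el, brute)
  }
  # m = 2 returns every non-root internal node of a bifurcating tree
  expect_equal(length(eligible_nodes(tr, 2)), tr$Nnode - 1L)
})

test_that("regime painting follows nearest ancestor-or-self shift, any input order", {
  tr <- balanced_tree(8)
  ntip <- ape::Ntip(tr)
  expect_true(all(paint_regimes(tr, integer(0))$node_regime == 0))

  el <- eligible_nodes(tr, 2)
  s_outer <- el[length(el)]            # deepest eligible: largest clade
  kids <- tr$edge[tr$edge[, 1] == s_outer, 2]
  s_inner <- kids[kids > ntip][1]
  pa <- paint_regimes(tr, c(s_outer, s_inner))
  # brute force: walk ancestors for every node
  shift_of <- c(1L, 2L)
  names(shift_of) <- c(s_outer, s_inner)
  for (nd in seq_len(ntip + tr$Nnode)) {
    cur <- nd; reg <- 0L
    repeat {
      if (as.character(cur) %in% names(shift_of)) { reg <- shift_of[[as.character(cur)]]; break }
      e <- which(tr$edge[, 2] == cur)
      if (!length(e)) break
      cur <- tr$edge[e, 1]
    }
    expect_identical(pa$node_regime[nd], reg)
  }
  # idempotent under input order; regime ids follow given order
  pb <- paint_regimes(tr, c(s_inner, s_outer))
  expect_equal(sort(unique(pb$node_regime)), 0:2)
  expect_equal(which(pa$node_regime == 0), which(pb$node_regime == 0))

  expect_error(paint_regimes(tr, ntip + 1L), "root")
  expect_error(paint_regimes(tr, c(s_outer, s_outer)), "duplicate")

  # stem-edge vs crown convention differ exactly on the stem branch
  one <- paint_regimes(tr, s_outer)
  crown <- paint_regimes(tr, s_outer, stem_edge = FALSE)
  po <- ape::reorder.phylo(tr, "postorder")
  stem <- which(po$edge[, 2] == s_outer)
  expect_equal(one$edge_regime[stem], 1L)
  expect_equal(crown$edge_regime[stem], 0L)
  expect_equal(one$edge_regime[-stem], crown$edge_regime[-stem])
})

test_that("canonical leafset ids survive tree rewriting", {
  tr <- generate_toy_tree(12, seed = 5)
  nd <- eligible_nodes(tr, 4)[1]
  id <- node_leafset(tr, nd)
  tr2 <- read_newick(write_newick(tr))
  expect_equal(sort(unlist(strsplit(node_leafset(tr2, node_from_leafset(tr2, id)), "\\|"))),
               sort(unlist(strsplit(id, "\\|"))))
  expect_true(is.na(node_from_leafset(tr, "not|a|clade")))
})

test_that("pattern compression conserves site counts and handles missing taxa", {
  tr <- fx_tree16()
  aln <- simulate_alignment(tr, freqs = list(c(0.3, 0.2, 0.2, 0.3)),
                            length = 500, seed = 11)
  pat <- compress_patterns(aln)
  expect_equal(sum(attr(pat, "weight")), 500)
  expect_error(compress_patterns(aln, c(tr$tip.label, "missing_taxon")),
               "absent")
  # identical sequences give a single-taxon view with few patterns
  m <- matrix("a", 2, 2, dimnames = list(c("x", "y"), NULL))
  p2 <- compress_patterns(ape::as.DNAbin(m))
  expect_equal(length(attr(p2, "weight")), 1)
  expect_equal(sum(attr(p2, "weight")), 2)
})

test_that("empirical frequencies match a direct tally and skip ambiguity", {
  m <- matrix(c("a", "c", "g", "t",
                "a", "a", "-", "n"), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  f <- empirical_frequencies(ape::as.DNAbin(m), eps = 0)
  expect_equal(as.numeric(f), c(3, 1, 1, 1) / 6)
  tr <- fx_tree16()
  aln <- simulate_alignment(tr, freqs = list(c(0.1, 0.2, 0.3, 0.4)),
                            length = 300, seed = 2)
  chars <- tolower(as.character(as.matrix(aln)))
  tab <- table(factor(chars, levels = c("a", "c", "g", "t")))
  expect_equal(as.numeric(empirical_frequencies(aln, eps = 0)),
               as.numeric(tab / sum(tab)))
})

test_that("relaxed PHYLIP alignments and NHX-commented Newick are read", {
  tr <- fx_tree16()
  aln <- simulate_alignment(tr, freqs = list(rep(0.25, 4)), length = 120,
                            seed = 12)
  tmp <- tempfile(fileext = ".phy")
  ape::write.dna(as.matrix(aln), tmp, format = "sequential", colsep = "")
  back <- read_alignment(tmp, format = "phylip")
  expect_identical(as.character(back)[tr$tip.label, ],
                   as.character(as.matrix(aln))[tr$tip.label, ])

  nwk <- "((a:1,b:1)[&&NHX:regime=1]:1,(c:1,d:1)95:1);"
  tr2 <- read_newick(nwk)
  expect_equal(ape::Ntip(tr2), 4)
  expect_true("95" %in% tr2$node.label)
})
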