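test_that("Dirichlet compositions have the right moments and are reproducible", {
  draws <- sample_compositions(20000, seed = 4)
  mat <- do.call(rbind, draws)
  # uniform Dirichlet: marginal mean 1/4, var 3/80
  se <- sqrt(3 / 80 / nrow(mat))
  expect_true(all(abs(colMeans(mat) - 0.25) < 4 * se))
  expect_true(all(abs(apply(mat, 2, var) - 3 / 80) < 0.002))
  expect_identical(sample_compositions(3, seed = 11),
                   sample_compositions(3, seed = 11))
  # concentrated prior collapses toward the center
  tight <- do.call(rbind, sample_compositions(2000, concentration = 100,
                                              seed = 5))
  expect_true(all(apply(tight, 2, var) < 0.001))
})

test_that("shift-node sampling honors clade-size, buffer and lineage rules", {
  expect_identical(sample_shift_nodes(fx_tree16(), 0), integer(0))

  tr <- balanced_tree(16)
  D <- node_path_distances(tr)
  sizes <- function(nds) vapply(nds, function(nd)
    length(unlist(phangorn::Descendants(tr, nd, "tips"))), integer(1))
  # brute-force enumeration of valid independent pairs
  elig <- eligible_nodes(tr, 4)
  elig <- elig[sizes(elig) <= 12]
  lineage <- function(nd) {
    anc <- integer(0); p <- nd
    repeat {
      e <- which(tr$edge[, 2] == p); if (!length(e)) break
      p <- tr$edge[e, 1]; anc <- c(anc, p)
    }
    c(nd, anc, unlist(phangorn::Descendants(tr, nd, "all")))
  }
  valid_pair <- function(a, b)
    !(b %in% lineage(a)) && !(a %in% lineage(b)) && D[a, b] >= 2
  pairs <- expand.grid(a = elig, b = elig)
  pairs <- pairs[pairs$a != pairs$b, ]
  ok <- pairs[mapply(valid_pair, pairs$a, pairs$b), ]
  for (seed in 1:20) {
    got <- sample_shift_nodes(tr, 2, min_clade = 4, max_clade = 12,
                              buffer = 2, seed = seed)
    expect_true(any(ok$a == got[1] & ok$b == got[2]))
  }
  # nested mode keeps draws on one lineage with the buffer respected
  tr64 <- fx_tree64()
  for (seed in 1:10) {
    got <- sample_shift_nodes(tr64, 2, min_clade = 4, buffer = 2,
                              nested = TRUE, seed = seed)
    D64 <- node_path_distances(tr64)
    expect_gte(D64[got[1], got[2]], 2)
    lin <- lineage <- c(got[1],
      unlist(phangorn::Descendants(tr64, got[1], "all")),
      ape::nodepath(tr64, ape::Ntip(tr64) + 1L, got[1]))
    expect_true(got[2] %in% lin)
  }
  expect_error(sample_shift_nodes(balanced_tree(8), 5, min_clade = 4,
                                  max_restarts = 5), "restarts|clade-size")
})

test_that("sequence simulation hits degenerate contracts and stationarity", {
  tr <- fx_tree16()
  aln0 <- simulate_alignment(tr, freqs = list(rep(0.25, 4)), length = 0)
  expect_equal(dim(as.matrix(aln0))[2], 0)

  tr_zero <- tr; tr_zero$edge.length[] <- 0
  aln <- simulate_alignment(tr_zero, freqs = list(c(0.2, 0.3, 0.3, 0.2)),
                            length = 50, seed = 6)
  chars <- as.character(as.matrix(aln))
  expect_true(all(apply(chars, 2, function(col) length(unique(col)) == 1)))

  # long-branch star tree: tip composition converges to the regime frequencies
  star <- ape::stree(40, type = "star")
  star$edge.length <- rep(10, nrow(star$edge))
  pi <- c(0.1, 0.45, 0.15, 0.3)
  aln_s <- simulate_alignment(star, freqs = list(pi), length = 2000, seed = 14)
  counts <- table(factor(tolower(as.character(as.matrix(aln_s))),
                         levels = c("a", "c", "g", "t")))
  expect_gt(chisq.test(counts, p = pi)$p.value, 0.01)
})

test_that("simulated datasets carry a faithful truth sidecar and annotations", {
  tr <- fx_tree64()
  ds <- simulate_dataset(tr, "independent", n_shifts = 2, length = 100,
                         seed = 77)
  expect_equal(length(ds$freqs), 3)
  expect_equal(ncol(as.matrix(ds$alignment)), 100)
  # repainting from the recorded shift nodes reproduces the painting
  repaint <- paint_regimes(tr, node_from_leafset(tr, ds$leafsets))
  expect_identical(repaint$node_regime, ds$painting$node_regime)
  # model annotations: one per regime (root annotation included)
  expect_equal(lengths(regmatches(ds$annotated_newick,
    gregexpr("&model=HKY", ds$annotated_newick))), 3, ignore_attr = TRUE)
  ds0 <- simulate_dataset(tr, "none", length = 50, seed = 1)
  expect_equal(lengths(regmatches(ds0$annotated_newick,
    gregexpr("&model=HKY", ds0$annotated_newick))), 1, ignore_attr = TRUE)
  # determinism under the seed
  ds2 <- simulate_dataset(tr, "independent", n_shifts = 2, length = 100,
                          seed = 77)
  expect_identical(as.character(ds$alignment), as.character(ds2$alignment))
  expect_identical(ds$shift_nodes, ds2$shift_nodes)

  # round trip through files
  tmp <- tempfile()
  paths <- write_sim_dataset(ds, tmp)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::fromJSON(paths["truth"])
  expect_identical(sort(truth$leafsets), sort(ds$leafsets))
  aln_back <- read_alignment(paths["fasta"])
  expect_identical(as.character(aln_back)[tr$tip.label, ],
                   as.character(as.matrix(ds$alignment))[tr$tip.label, ])
})

test_that("toy trees are reproducible pure-birth trees; burst mode compresses the base", {
  tr3 <- generate_toy_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr3), 3)
  expect_identical(write_newick(generate_toy_tree(25, seed = 9)),
                   write_newick(generate_toy_tree(25, seed = 9)))
  tr250 <- generate_toy_tree(250, seed = 2)
  expect_equal(ape::Ntip(tr250), 250)
  expect_true(all(tr250$edge.length > 0))
  expect_equal(max(ape::node.depth.edgelength(tr250)), 0.5, tolerance = 1e-6)
  # burst: the oldest internal nodes sit within the top 5% of depth
  trb <- generate_toy_tree(100, seed = 3, burst = TRUE, depth = 1)
  depth <- ape::node.depth.edgelength(trb)
  ages <- max(depth) - depth
  int_ages <- sort(ages[101 + seq_len(trb$Nnode) - 1], decreasing = TRUE)
  expect_gt(int_ages[ceiling(0.2 * trb$Nnode)], 0.94)
})
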