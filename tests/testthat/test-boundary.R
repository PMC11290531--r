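test_that("grafting adds one epsilon tip per internal node and is invertible", {
  tr4 <- balanced_tree(4, bl = 1)
  g4 <- graft_internal_terminals(tr4)
  expect_equal(ape::Ntip(g4$tree), 4 + 3)
  expect_equal(nrow(g4$map), 3)

  chron <- generate_toy_tree(32, seed = 6, depth = 80)  # "Ma" scale
  g <- graft_internal_terminals(chron, eps = 1e-6)
  expect_equal(ape::Ntip(g$tree), 32 + 31)
  grafted_edges <- g$tree$edge.length[match(match(g$map$tip, g$tree$tip.label),
                                            g$tree$edge[, 2])]
  expect_true(all(abs(grafted_edges - 1e-6) < 1e-12))
  back <- ungraft(g)
  pp <- function(tr) {
    p <- ape::prop.part(tr)
    sort(vapply(p, function(i) paste(sort(attr(p, "labels")[i]), collapse = "|"), ""))
  }
  expect_identical(pp(back), pp(chron))
  expect_warning(graft_internal_terminals(fx_tree16()
    |> (\(t) { t$edge.length[1] <- t$edge.length[1] * 3; t })()),
    "ultrametric")
})

test_that("proximity predictor evaluates its closed forms", {
  expect_equal(proximity_predictor(67), 0)
  expect_equal(proximity_predictor(66), log(1e-3))
  expect_equal(proximity_predictor(76), log(10), tolerance = 1e-12)
  expect_equal(proximity_predictor(56), log(10), tolerance = 1e-12)
  expect_error(proximity_predictor(-1), "stem_age")
})

test_that("node ages give stem ages from the parent branch point", {
  tr <- read_newick("((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  ages <- node_ages(tr)
  root_age <- 2
  expect_equal(ages$age[1], root_age)
  expect_equal(ages$stem_age[1], root_age)  # root: own age by convention
  expect_equal(sort(ages$age[-1]), c(1, 1.5))
  expect_equal(ages$stem_age[-1], c(2, 2))
})

test_that("gene-tree discordance classifies conflicts and collapses weak support", {
  ref <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  gt_same <- ape::read.tree(text = "((a:1,b:1)100:1,(c:1,d:1)100:1);")
  gt_conf <- ape::read.tree(text = "((a:1,c:1)100:1,(b:1,d:1)100:1);")
  gt_weak <- ape::read.tree(text = "((a:1,c:1)50:1,(b:1,d:1)50:1);")

  d0 <- gene_tree_discordance(list(gt_same, gt_same, gt_same), ref)
  expect_equal(d0$p, c(NA, 0, 0))  # root bipartition is trivial
  expect_equal(d0$asin_sqrt_p[-1], c(0, 0))

  d1 <- gene_tree_discordance(list(gt_same, gt_same, gt_conf), ref)
  expect_equal(d1$p[-1], c(1 / 3, 1 / 3))
  expect_equal(d1$asin_sqrt_p[-1], rep(asin(sqrt(1 / 3)), 2),
               tolerance = 1e-9)

  # full conflict maps to the transform's upper bound pi/2
  dfull <- gene_tree_discordance(list(gt_conf), ref)
  expect_equal(dfull$asin_sqrt_p[-1], rep(pi / 2, 2), tolerance = 1e-9)

  # collapsing sub-cutoff support makes the conflicting tree non-decisive
  d2 <- gene_tree_discordance(list(gt_same, gt_weak), ref, support_cut = 95)
  expect_equal(d2$n_decisive[-1], c(1, 1))
  expect_equal(d2$p[-1], c(0, 0))

  # partial taxon overlap: restriction to shared taxa
  gt_sub <- ape::read.tree(text = "((a:1,c:1)100:1,d:1);")
  d3 <- gene_tree_discordance(list(gt_sub), ref)
  expect_equal(d3$n_decisive, c(0, 0, 0))  # 3-taxon restriction is trivial
})

test_that("phylogenetic logistic regression reduces to glm when the signal vanishes", {
  tr <- generate_toy_tree(60, seed = 15, depth = 100)
  set.seed(2)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(-0.5 + 1.2 * x))
  dat <- data.frame(shift = y, proximity = x, tip = tr$tip.label)
  fit <- fit_phylo_logistic(tr, dat, shift ~ proximity, alpha = Inf, nboot = 0)
  ref <- glm(y ~ x, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-4)
  expect_equal(as.numeric(fit$naive), as.numeric(coef(ref)), tolerance = 1e-6)
})

test_that("phylo-logistic bookkeeping: exclusions, errors, bootstrap, invariance", {
  chron <- generate_toy_tree(24, seed = 8, depth = 100)
  g <- graft_internal_terminals(chron)
  ages <- node_ages(chron)
  covs <- data.frame(tip = g$map$tip,
                     proximity = proximity_predictor(ages$stem_age, 50),
                     shift = 0L)
  set.seed(5)
  covs$shift <- rbinom(nrow(covs), 1, plogis(-0.3 - 0.8 * covs$proximity))
  if (all(covs$shift == 0)) covs$shift[1:3] <- 1L
  expect_error(fit_phylo_logistic(g$tree, transform(covs, shift = 0L),
                                  shift ~ proximity), "positive and negative")
  fit <- fit_phylo_logistic(g$tree, covs, shift ~ proximity, nboot = 50,
                            seed = 9)
  expect_true(is.finite(fit$alpha) || is.infinite(fit$alpha))
  expect_equal(dim(fit$boot), c(50, 2))
  # bootstrap SD exists and the point estimate sits inside a wide interval
  qs <- quantile(fit$boot[, 2], c(0.005, 0.995), na.rm = TRUE)
  expect_true(fit$coefficients[2] >= qs[1] && fit$coefficients[2] <= qs[2])
  # invariance to observation order
  perm <- sample(nrow(covs))
  fit_p <- fit_phylo_logistic(g$tree, covs[perm, ], shift ~ proximity,
                              alpha = fit$alpha, nboot = 0)
  fit_o <- fit_phylo_logistic(g$tree, covs, shift ~ proximity,
                              alpha = fit$alpha, nboot = 0)
  expect_equal(fit_p$coefficients, fit_o$coefficients, tolerance = 1e-8)
})

test_that("discordance-level predictions use mean plus/minus one standard deviation", {
  covs <- data.frame(proximity = rnorm(30), discordance = runif(30, 0, 1.2))
  fit <- structure(list(coefficients = c("(Intercept)" = -1,
                                         proximity = -0.5,
                                         discordance = 0.8),
                        formula = shift ~ proximity + discordance),
                   class = "phylo_glm")
  pr <- predict_discordance_levels(fit, covs, proximity = c(0, 1))
  expect_equal(nrow(pr), 6)
  m <- mean(covs$discordance); s <- sd(covs$discordance)
  lo <- plogis(-1 - 0.5 * 0 + 0.8 * (m - s))
  expect_equal(pr$prob[pr$level == "low" & pr$proximity == 0], lo,
               tolerance = 1e-12)
})

test_that("node covariates combine shift indicators, proximity, and discordance", {
  chron <- generate_toy_tree(16, seed = 44, depth = 90)
  shift_nodes <- eligible_nodes(chron, 4)[1:2]
  covs <- node_covariates(chron, node_leafset(chron, shift_nodes),
                          boundary = 60)
  expect_equal(sum(covs$shift), 2)
  expect_setequal(covs$node[covs$shift == 1], shift_nodes)
  expect_equal(covs$proximity,
               proximity_predictor(covs$stem_age, 60))
  disc <- data.frame(node = covs$node,
                     asin_sqrt_p = seq(0, 1, length.out = nrow(covs)))
  covs2 <- node_covariates(chron, character(0), discordance = disc)
  expect_equal(covs2$discordance, disc$asin_sqrt_p)
  expect_equal(sum(covs2$shift), 0)
})
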