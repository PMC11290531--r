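# Independent oracles used across the suite. These deliberately avoid the
# package's pruning machinery: likelihoods are computed by exhaustive
# marginalization over internal states, and Jukes-Cantor quantities come from
# their closed forms.

# exhaustive-likelihood oracle for a (possibly regime-painted) HKY model;
# feasible for <= 5 taxa
brute_force_lnl <- function(tree, model, aln) {
  chars <- tolower(as.character(as.matrix(aln)))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  regime <- model$painting$node_regime
  Plist <- lapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    r <- regime[ch]
    Q <- build_rate_matrix(model$exch, model$freqs[[r + 1]])
    transition_probs(Q, tree$edge.length[e])[[1]]
  })
  code <- c(a = 1, c = 2, g = 3, t = 4)
  grid <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
  total <- 0
  for (site in seq_len(ncol(chars))) {
    obs <- code[chars[tree$tip.label, site]]
    lik <- 0
    for (gi in seq_len(nrow(grid))) {
      st <- c(obs, grid[gi, ])
      p <- model$freqs[[1]][st[root]]
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Plist[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      lik <- lik + p
    }
    total <- total + log(unname(lik))
  }
  total
}

jc_p_same <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)
jc_p_diff <- function(t) 0.25 - 0.25 * exp(-4 * t / 3)

# closed-form two-taxon Jukes-Cantor log-likelihood for an alignment with
# n_match identical and n_diff differing sites over total path length t
jc_pair_lnl <- function(t, n_match, n_diff) {
  n_match * log(0.25 * jc_p_same(t)) + n_diff * log(0.25 * jc_p_diff(t))
}

jc_model <- function(tree, n_regimes = 1) {
  painting <- paint_regimes(tree, integer(0))
  regime_model(painting, list(rep(0.25, 4)), hky_exchangeabilities(1))
}

# reference Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
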