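# Likelihood engine: a mutable environment holding the postorder tree
# indexing, compressed site patterns, per-edge transition matrices and cached
# partial likelihoods. Refitting one regime's composition only recomputes the
# nodes whose subtree intersects that regime's edges, which is what makes the
# greedy search affordable on hundreds of candidate clades.

softmax4 <- function(theta) {
  e <- exp(c(theta, 0) - max(theta, 0))
  e / sum(e)
}

theta_of <- function(freq) log(freq[1:3] / freq[4])

node_postorder <- function(edge, ntip, nnode) {
  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1]
    kids[[pa]] <- c(kids[[pa]], edge[e, 2])
  }
  root <- ntip + 1L
  out <- integer(nnode); k <- 0L
  stack <- root
  state <- integer(ntip + nnode)
  while (length(stack)) {
    nd <- stack[length(stack)]
    if (state[nd] == 0L) {
      state[nd] <- 1L
      ch <- kids[[nd]]
      stack <- c(stack, ch[ch > ntip])
    } else {
      stack <- stack[-length(stack)]
      if (state[nd] == 1L) { k <- k + 1L; out[k] <- nd; state[nd] <- 2L }
    }
  }
  out
}

#' Build a likelihood engine for a tree and alignment patterns
#'
#' Mostly internal; exposed so that repeated fits against the same data can
#' share indexing and cached partials.
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param patterns a `phyDat` from [compress_patterns()] covering all tree
#'   tips.
#' @param ncat number of gamma rate categories the engine must accommodate.
#' @return an environment of class `ll_engine`.
#' @export
ll_engine <- function(tree, patterns, ncat = 1) {
  validate_tree(tree, require_binary_root = FALSE)
  stopifnot(ncat >= 1, ncat <= 16)
  miss <- setdiff(tree$tip.label, names(patterns))
  if (length(miss)) stop("tree tips absent from patterns: ",
                         paste(head(miss, 5), collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po); nint <- po$Nnode; root <- ntip + 1L
  edge <- po$edge; nedge <- nrow(edge)
  weights <- as.numeric(attr(patterns, "weight"))
  npat <- length(weights)
  contrast <- attr(patterns, "contrast")
  tipdata <- matrix(0L, npat, ntip)  # patterns x tips: contiguous per tip
  for (i in seq_len(ntip)) tipdata[, i] <- as.integer(patterns[[po$tip.label[i]]])
  # weighted A/C/G/T counts per tip (ambiguity spread via the contrast rows);
  # used for cheap empirical starting compositions of clade fits
  tip_counts <- t(vapply(seq_len(ntip), function(i)
    colSums(weights * contrast[tipdata[, i], , drop = FALSE]),
    numeric(4)))

  parent_of <- integer(ntip + nint)
  edge_of_node <- integer(ntip + nint)
  for (e in seq_len(nedge)) {
    parent_of[edge[e, 2]] <- edge[e, 1]
    edge_of_node[edge[e, 2]] <- e
  }
  po_int <- node_postorder(edge, ntip, nint)
  rank <- integer(ntip + nint); rank[po_int] <- seq_along(po_int)
  kids_edges <- split(seq_len(nedge) - 1L, edge[, 1])  # 0-based for C

  eng <- new.env(parent = emptyenv())
  eng$tree <- po; eng$ntip <- ntip; eng$nint <- nint; eng$root <- root
  eng$edge_child <- as.integer(edge[, 2]); eng$edge_parent <- as.integer(edge[, 1])
  eng$elen <- po$edge.length; eng$nedge <- nedge
  eng$parent_of <- parent_of; eng$edge_of_node <- edge_of_node
  eng$po_int <- po_int; eng$rank <- rank; eng$kids_edges <- kids_edges
  eng$tipdata <- tipdata; eng$contrast <- contrast; eng$weights <- weights
  eng$tip_counts <- tip_counts
  eng$npat <- npat; eng$ncat <- as.integer(ncat)
  eng$n_sites <- sum(weights)
  eng$P <- array(0, c(16, nedge, ncat))
  eng$partials <- numeric(4 * npat * nint * ncat)
  eng$scalelog <- numeric(npat * nint * ncat)
  eng$clade_edges_cache <- vector("list", ntip + nint)
  eng$sub_cache <- list()
  class(eng) <- "ll_engine"
  eng
}

# edges of the clade rooted at `node`, including the stem edge
engine_clade_edges <- function(eng, node) {
  ce <- eng$clade_edges_cache[[node]]
  if (!is.null(ce)) return(ce)
  desc <- unlist(phangorn::Descendants(eng$tree, node, type = "all"))
  ce <- eng$edge_of_node[c(node, desc)]
  ce <- ce[ce > 0L]
  eng$clade_edges_cache[[node]] <- ce
  ce
}

# regime id per postorder edge under the painting's conventions
engine_edge_regime <- function(eng, painting) {
  er <- painting$node_regime[eng$edge_child]
  if (!painting$stem_edge && length(painting$shift_nodes)) {
    idx <- match(painting$shift_nodes, eng$edge_child)
    er[idx] <- painting$node_regime[eng$edge_parent[idx]]
  }
  er
}

# internal nodes (postorder-sorted) whose partials depend on the given edges
dirty_nodes <- function(eng, eidx) {
  nodes <- unique(eng$edge_parent[eidx])
  seen <- logical(eng$ntip + eng$nint)
  seen[nodes] <- TRUE
  for (nd in nodes) {
    p <- eng$parent_of[nd]
    while (p != 0L && !seen[p]) { seen[p] <- TRUE; p <- eng$parent_of[p] }
  }
  out <- which(seen)
  out[order(eng$rank[out])]
}

todo_structures <- function(eng, nodes) {
  ke <- eng$kids_edges[as.character(nodes)]
  lens <- lengths(ke)
  list(nodes = as.integer(nodes),
       ptr = as.integer(c(0L, cumsum(lens))),
       edges = as.integer(unlist(ke, use.names = FALSE)))
}

engine_set_P <- function(eng, eidx, eig, rates) {
  for (c in seq_along(rates))
    eng$P[, eidx, c] <- pmat_block(eig, eng$elen[eidx] * rates[c])
  invisible(eng)
}

engine_prune <- function(eng, rootfreq, nodes = eng$po_int) {
  td <- todo_structures(eng, nodes)
  C_prune(eng$edge_child, eng$edge_parent, eng$P, eng$tipdata, eng$contrast,
          eng$weights, as.numeric(rootfreq), eng$ntip, eng$root, eng$ncat,
          td$nodes, td$ptr, td$edges, eng$partials, eng$scalelog)
}

# install a full model (all regimes' P matrices) and recompute all partials
engine_eval_full <- function(eng, model) {
  er <- engine_edge_regime(eng, model$painting)
  rates <- model_rates(model)
  for (r in sort(unique(er))) {
    eidx <- which(er == r)
    Q <- build_rate_matrix(model$exch, model$freqs[[r + 1]])
    engine_set_P(eng, eidx, rev_eigen(Q), rates)
  }
  engine_prune(eng, model$freqs[[1]])
}

# maximize lnL over one regime's composition, all else fixed; the engine must
# be consistent with `model` on entry and is left consistent with the fit.
engine_refit_regime <- function(eng, model, r, factr = 1e4, maxit = 200,
                                start = NULL) {
  if (r > 0 && model$painting$stem_edge &&
      length(clade_tips(eng$tree, model$painting$shift_nodes[r])) <= eng$ntip / 2)
    return(engine_refit_anchored(eng, model, r, factr = factr, maxit = maxit,
                                 start = start))
  er <- engine_edge_regime(eng, model$painting)
  eidx <- which(er == r)
  rates <- model_rates(model)
  dirty <- if (length(eidx)) dirty_nodes(eng, eidx) else eng$root
  td <- todo_structures(eng, dirty)
  if (is.null(start)) start <- model$freqs[[r + 1]]
  rf_fixed <- as.numeric(model$freqs[[1]])
  obj <- function(theta) {
    pi <- softmax4(theta)
    if (any(pi < 1e-10)) return(-1e10)
    Q <- build_rate_matrix(model$exch, pi)
    if (length(eidx)) engine_set_P(eng, eidx, rev_eigen(Q), rates)
    rf <- if (r == 0) pi else rf_fixed
    C_prune(eng$edge_child, eng$edge_parent, eng$P, eng$tipdata, eng$contrast,
            eng$weights, rf, eng$ntip, eng$root, eng$ncat,
            td$nodes, td$ptr, td$edges, eng$partials, eng$scalelog)
  }
  opt <- optim(theta_of(as.numeric(start)), obj, method = "L-BFGS-B",
               control = list(fnscale = -1, factr = factr, maxit = maxit))
  lnl <- obj(opt$par)  # leave engine state at the optimum
  model$freqs[[r + 1]] <- base_frequencies(softmax4(opt$par))
  list(model = model, lnl = lnl, converged = opt$convergence == 0L)
}

# coordinate ascent over all regime compositions (newest regime first, the
# ancestral regime last); stops when a sweep improves lnL by less than `tol`.
engine_fit_all <- function(eng, model, sweeps = 5, tol = 1e-6,
                           refresh = TRUE) {
  lnl <- if (refresh) engine_eval_full(eng, model) else engine_prune(eng, model$freqs[[1]])
  R <- length(model$freqs)
  order_r <- c(rev(seq_len(R - 1)), 0L)
  converged <- TRUE
  for (s in seq_len(sweeps)) {
    for (r in order_r) {
      res <- engine_refit_regime(eng, model, r)
      model <- res$model
      converged <- converged && res$converged
      new_lnl <- res$lnl
    }
    if (new_lnl - lnl < tol) { lnl <- max(lnl, new_lnl); break }
    lnl <- new_lnl
  }
  list(model = model, lnl = lnl, converged = converged)
}

#' Log-likelihood of a regime model on a painted tree
#'
#' Felsenstein pruning in which the branch into node `x` uses the rate matrix
#' of `regime_of(x)` (stem-edge convention), root partials are weighted by the
#' ancestral regime's frequencies, and gamma categories are averaged with
#' equal weights.
#'
#' @param tree rooted `phylo` (branch lengths in substitutions/site).
#' @param model a `regime_model` whose painting refers to `tree`.
#' @param patterns `phyDat` patterns covering the tree tips.
#' @return total log-likelihood in nats.
#' @export
log_likelihood <- function(tree, model, patterns) {
  eng <- ll_engine(tree, patterns, ncat = model$ncat)
  lnl <- engine_eval_full(eng, model)
  if (!is.finite(lnl)) stop("non-finite log-likelihood (zero-probability pattern?)")
  lnl
}

#' Maximum-likelihood equilibrium frequencies for selected regimes
#'
#' Optimizes the composition of the target regimes over the 3-simplex
#' (softmax parameterization, bounded quasi-Newton), holding exchangeabilities,
#' gamma shape, branch lengths, and the other regimes fixed. With several
#' target regimes a coordinate ascent is used. Optional random restarts guard
#' against local optima.
#'
#' @param tree rooted `phylo`.
#' @param model starting `regime_model`.
#' @param patterns `phyDat` patterns.
#' @param regimes regime ids to fit (default: all).
#' @param sweeps,tol coordinate-ascent controls.
#' @param n_starts number of optimization starts (first start is the model's
#'   own frequencies; extras are uniform-Dirichlet draws).
#' @param seed RNG seed for the extra starts.
#' @param refit_exch also re-estimate the shared exchangeabilities (and gamma
#'   shape) at this regime configuration, alternating with the composition
#'   sweeps. Compositions estimated under a homogeneous-fit kappa carry a
#'   small but systematic bias on strongly shifted data; this removes it.
#' @return list with `model`, `lnl`, and `converged`.
#' @export
fit_frequencies <- function(tree, model, patterns, regimes = NULL,
                            sweeps = 5, tol = 1e-6, n_starts = 1, seed = NULL,
                            refit_exch = FALSE) {
  eng <- ll_engine(tree, patterns, ncat = model$ncat)
  all_r <- seq_len(length(model$freqs)) - 1L
  if (is.null(regimes)) regimes <- all_r
  stopifnot(all(regimes %in% all_r))
  run_one_pass <- function(m0) {
    if (setequal(regimes, all_r)) return(engine_fit_all(eng, m0, sweeps, tol))
    lnl <- engine_eval_full(eng, m0)
    conv <- TRUE
    for (s in seq_len(sweeps)) {
      for (r in regimes) {
        res <- engine_refit_regime(eng, m0, r)
        m0 <- res$model; conv <- conv && res$converged; new_lnl <- res$lnl
      }
      if (new_lnl - lnl < tol) { lnl <- max(lnl, new_lnl); break }
      lnl <- new_lnl
    }
    list(model = m0, lnl = lnl, converged = conv)
  }
  run_once <- function(m0) {
    res <- run_one_pass(m0)
    if (!refit_exch) return(res)
    for (round in 1:4) {
      prev <- res$lnl
      ex <- engine_refit_exch(eng, res$model)
      res <- run_one_pass(ex$model)
      res$converged <- res$converged && ex$converged
      if (res$lnl - prev < tol) break
    }
    res
  }
  best <- run_once(model)
  if (n_starts > 1) {
    starts <- with_seed(seed, replicate(n_starts - 1, sample_compositions(
      length(regimes)), simplify = FALSE))
    for (st in starts) {
      m0 <- model
      for (i in seq_along(regimes)) m0$freqs[[regimes[i] + 1]] <- st[[i]]
      cand <- run_once(m0)
      if (cand$lnl > best$lnl) best <- cand
    }
  }
  best
}

#' Joint ML of the homogeneous nuisance model
#'
#' Fits the root composition together with the exchangeability parameters
#' (kappa for HKY, five free rates for GTR) and, when `gamma_categories > 1`,
#' the gamma shape, under a single-regime model. These nuisance values are
#' held fixed during the shift search.
#'
#' @param tree rooted `phylo`.
#' @param patterns `phyDat` patterns.
#' @param family `"HKY"` or `"GTR"`.
#' @param gamma_categories number of discrete-gamma categories (1 = uniform
#'   rates, no shape parameter).
#' @param engine optional pre-built [ll_engine()].
#' @return list with `exch`, `gamma_shape`, `root_freq`, `lnl`, `n_params`,
#'   and `converged`.
#' @export
fit_global_nuisance <- function(tree, patterns, family = c("HKY", "GTR"),
                                gamma_categories = 1, engine = NULL) {
  family <- match.arg(family)
  ncat <- as.integer(gamma_categories)
  eng <- if (is.null(engine)) ll_engine(tree, patterns, ncat = max(ncat, 1)) else engine
  painting <- paint_regimes(tree, integer(0))
  f0 <- pmax(as.numeric(phangorn::baseFreq(patterns)), 1e-4)
  f0 <- f0 / sum(f0)
  n_ex <- if (family == "HKY") 1L else 5L
  par0 <- c(theta_of(f0),
            if (family == "HKY") log(2) else rep(0, 5),
            if (ncat > 1) log(1) else NULL)
  todo <- todo_structures(eng, eng$po_int)
  obj <- function(par) {
    pi <- softmax4(par[1:3])
    if (any(pi < 1e-10)) return(-1e10)
    exch <- if (family == "HKY") hky_exchangeabilities(exp(par[4]))
            else gtr_exchangeabilities(c(exp(par[4:8]), 1))
    shape <- if (ncat > 1) exp(par[3 + n_ex + 1]) else NULL
    rates <- if (ncat > 1) gamma_rates(shape, ncat) else 1
    eig <- rev_eigen(build_rate_matrix(exch, pi))
    engine_set_P(eng, seq_len(eng$nedge), eig, rates)
    C_prune(eng$edge_child, eng$edge_parent, eng$P, eng$tipdata, eng$contrast,
            eng$weights, pi, eng$ntip, eng$root, eng$ncat,
            todo$nodes, todo$ptr, todo$edges, eng$partials, eng$scalelog)
  }
  opt <- optim(par0, obj, method = "L-BFGS-B",
               control = list(fnscale = -1, factr = 1e8, maxit = 500))
  lnl <- obj(opt$par)
  pi <- base_frequencies(softmax4(opt$par[1:3]))
  exch <- if (family == "HKY") hky_exchangeabilities(exp(opt$par[4]))
          else gtr_exchangeabilities(c(exp(opt$par[4:8]), 1))
  shape <- if (ncat > 1) exp(opt$par[3 + n_ex + 1]) else NULL
  list(exch = exch, gamma_shape = shape, gamma_categories = ncat,
       root_freq = pi, lnl = lnl,
       n_params = n_exch_params(exch, ncat),
       converged = opt$convergence == 0L)
}

# ---- anchored refit of a non-ancestral regime -------------------------------
# All edges of a derived regime lie inside the clade of its shift node `s`
# (stem edge included). During a refit of that regime everything outside the
# clade is fixed, so the likelihood factorizes through the stem:
#   lnL_p = log sum_y W_p(y) * sum_x P_stem[y, x] * L_clade,p(x)
# with W the outside likelihood at parent(s) (fixed) and L_clade the inside
# partial at s. The inside part only depends on the pattern restricted to the
# clade's tips, which deduplicates heavily for small clades; each optimizer
# evaluation then costs a clade-sized pruning plus one pass over patterns.

engine_sub_structure <- function(eng, s) {
  key <- as.character(s)
  cached <- eng$sub_cache[[key]]
  if (!is.null(cached)) return(cached)
  tips_glob <- clade_tips(eng$tree, s)
  desc_all <- c(s, unlist(phangorn::Descendants(eng$tree, s, type = "all")))
  ints_glob <- desc_all[desc_all > eng$ntip]
  ints_glob <- ints_glob[order(eng$rank[ints_glob])]  # postorder
  k <- length(tips_glob)
  tip_id <- stats::setNames(seq_len(k), tips_glob)
  int_id <- stats::setNames(k + seq_along(ints_glob), ints_glob)
  node_id <- function(nd) ifelse(nd <= eng$ntip, tip_id[as.character(nd)],
                                 int_id[as.character(nd)])
  glob_edges <- setdiff(eng$edge_of_node[desc_all], eng$edge_of_node[s])
  glob_edges <- glob_edges[glob_edges > 0L]
  edge_child <- as.integer(node_id(eng$edge_child[glob_edges]))
  edge_parent <- as.integer(node_id(eng$edge_parent[glob_edges]))
  sp <- C_subpatterns(eng$tipdata, as.integer(tips_glob))
  nsub <- nrow(sp$sub)
  kid_groups <- split(seq_along(glob_edges) - 1L, edge_parent)
  ord <- match(as.integer(int_id), as.integer(names(kid_groups)) )
  kid_groups <- kid_groups[ord]
  sub <- list(
    s = s, tips_glob = tips_glob, ints_glob = ints_glob,
    glob_edges = glob_edges,
    edge_child = edge_child, edge_parent = edge_parent,
    elen = eng$elen[glob_edges],
    stem_edge = eng$edge_of_node[s],
    map = sp$map, tipdata = sp$sub, nsub = nsub,
    ntip_sub = k, nint_sub = length(ints_glob),
    root_sub = as.integer(int_id[as.character(s)]),
    todo_nodes = as.integer(int_id),
    todo_ptr = as.integer(c(0L, cumsum(lengths(kid_groups)))),
    todo_edges = as.integer(unlist(kid_groups, use.names = FALSE)),
    weights0 = numeric(nsub),
    partials = numeric(4 * nsub * length(ints_glob) * eng$ncat),
    scalelog = numeric(nsub * length(ints_glob) * eng$ncat),
    P = array(0, c(16, length(glob_edges), eng$ncat)))
  eng$sub_cache[[key]] <- sub
  sub
}

# outside likelihood W at parent(s) per gamma category: list of 4 x npat
# matrices plus per-pattern log scales; requires engine partials consistent
# with the current model.
engine_outside_W <- function(eng, s, rootfreq) {
  path <- integer(0)
  p <- eng$parent_of[s]
  while (p != 0L) { path <- c(p, path); p <- eng$parent_of[p] }  # root..pa(s)
  npat <- eng$npat
  lapply(seq_len(eng$ncat), function(cc) {
    O <- matrix(rootfreq, 4, npat)
    ls <- numeric(npat)
    child_inl <- function(e) {
      # [4, npat] matrix of sum_z P_e[y, z] L_child(z) over parent states y
      ch <- eng$edge_child[e]
      M <- matrix(eng$P[, e, cc], 4, 4)
      if (ch <= eng$ntip) {
        L <- t(eng$contrast[eng$tipdata[, ch], , drop = FALSE])
      } else {
        ii <- ch - eng$ntip - 1L
        off <- ((cc - 1L) * eng$nint + ii) * 4L * npat
        L <- matrix(eng$partials[off + seq_len(4L * npat)], 4, npat)
        ls <<- ls + eng$scalelog[((cc - 1L) * eng$nint + ii) * npat +
                                   seq_len(npat)]
      }
      M %*% L
    }
    for (j in seq_along(path)) {
      u <- path[j]
      nxt <- if (j < length(path)) path[j + 1] else s
      kids <- eng$kids_edges[[as.character(u)]] + 1L
      for (e in kids) {
        if (eng$edge_child[e] == nxt) next
        O <- O * child_inl(e)
      }
      if (nxt != s) {
        M <- matrix(eng$P[, eng$edge_of_node[nxt], cc], 4, 4)
        O <- crossprod(M, O)  # O_v(x) = sum_y O_u(y) P[y, x]
      }
      m <- pmax(O[1, ], O[2, ], O[3, ], O[4, ])
      ls <- ls + log(m)
      O <- O / rep(m, each = 4)
    }
    list(W = O, ls = ls)
  })
}

# refit one derived regime through the anchored factorization; leaves the
# engine consistent with the fitted model and returns the full-tree lnL.
engine_refit_anchored <- function(eng, model, r, factr = 1e4, maxit = 200,
                                  start = NULL) {
  s <- model$painting$shift_nodes[r]
  sub <- engine_sub_structure(eng, s)
  er <- engine_edge_regime(eng, model$painting)
  eidx <- which(er == r)                      # includes the stem edge
  rates <- model_rates(model)
  ncat <- eng$ncat
  # fixed transition matrices inside the clade (nested regimes) copied over
  sub$P[, , ] <- eng$P[, sub$glob_edges, , drop = FALSE]
  ve_glob <- setdiff(eidx, sub$stem_edge)
  ve_sub <- match(ve_glob, sub$glob_edges)
  stem_len <- eng$elen[sub$stem_edge]
  outside <- engine_outside_W(eng, s, as.numeric(model$freqs[[1]]))
  W <- array(0, c(4, eng$npat, ncat))
  lsW <- matrix(0, eng$npat, ncat)
  for (cc in seq_len(ncat)) {
    W[, , cc] <- outside[[cc]]$W
    lsW[, cc] <- outside[[cc]]$ls
  }
  if (is.null(start)) start <- model$freqs[[r + 1]]
  Pstem <- matrix(0, 16, ncat)
  obj <- function(theta) {
    pi <- softmax4(theta)
    if (any(pi < 1e-10)) return(-1e10)
    eig <- rev_eigen(build_rate_matrix(model$exch, pi))
    for (cc in seq_len(ncat)) {
      if (length(ve_sub))
        sub$P[, ve_sub, cc] <- pmat_block(eig, sub$elen[ve_sub] * rates[cc])
      Pstem[, cc] <<- pmat_block(eig, stem_len * rates[cc])[, 1]
    }
    C_prune(sub$edge_child, sub$edge_parent, sub$P, sub$tipdata, eng$contrast,
            sub$weights0, pi, sub$ntip_sub, sub$root_sub, ncat,
            sub$todo_nodes, sub$todo_ptr, sub$todo_edges,
            sub$partials, sub$scalelog)
    C_anchor_lnl(W, lsW, Pstem, sub$partials, sub$scalelog,
                 sub$root_sub - sub$ntip_sub - 1L, sub$nint_sub, sub$nsub,
                 ncat, sub$map, eng$weights)
  }
  opt <- optim(theta_of(as.numeric(start)), obj, method = "L-BFGS-B",
               control = list(fnscale = -1, factr = factr, maxit = maxit))
  pi_hat <- base_frequencies(softmax4(opt$par))
  model$freqs[[r + 1]] <- pi_hat
  # re-install globally and recompute the touched partials
  eig <- rev_eigen(build_rate_matrix(model$exch, pi_hat))
  engine_set_P(eng, eidx, eig, rates)
  lnl <- engine_prune(eng, model$freqs[[1]], dirty_nodes(eng, eidx))
  list(model = model, lnl = lnl, converged = opt$convergence == 0L)
}

# refit shared exchangeabilities (and gamma shape) given current compositions;
# leaves the engine consistent and returns the updated model pieces
engine_refit_exch <- function(eng, model, factr = 1e7) {
  er <- engine_edge_regime(eng, model$painting)
  regimes <- sort(unique(er))
  family <- model$exch$family
  n_ex <- if (family == "HKY") 1L else 5L
  ncat <- eng$ncat
  par0 <- c(if (family == "HKY") log(model$exch$kappa)
            else log(model$exch$rates[1:5]),
            if (ncat > 1) log(model$gamma_shape) else NULL)
  obj <- function(par) {
    exch <- if (family == "HKY") hky_exchangeabilities(exp(par[1]))
            else gtr_exchangeabilities(c(exp(par[1:5]), 1))
    shape <- if (ncat > 1) exp(par[n_ex + 1]) else NULL
    rates <- if (ncat > 1) gamma_rates(shape, ncat) else 1
    for (r in regimes) {
      eidx <- which(er == r)
      eig <- rev_eigen(build_rate_matrix(exch, model$freqs[[r + 1]]))
      engine_set_P(eng, eidx, eig, rates)
    }
    engine_prune(eng, model$freqs[[1]])
  }
  opt <- optim(par0, obj, method = "L-BFGS-B",
               control = list(fnscale = -1, factr = factr, maxit = 200))
  lnl <- obj(opt$par)
  exch <- if (family == "HKY") hky_exchangeabilities(exp(opt$par[1]))
          else gtr_exchangeabilities(c(exp(opt$par[1:5]), 1))
  model$exch <- exch
  if (ncat > 1) model$gamma_shape <- exp(opt$par[n_ex + 1])
  list(model = model, lnl = lnl, converged = opt$convergence == 0L)
}
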