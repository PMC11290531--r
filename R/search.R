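#' Bayesian Information Criterion
#'
#' @param lnl log-likelihood in nats.
#' @param k number of free parameters.
#' @param n sample size (alignment sites by default elsewhere).
#' @return `k * log(n) - 2 * lnl`.
#' @export
bic <- function(lnl, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * lnl
}

# free parameters of a configuration: 3 per regime plus shared nuisance
config_k <- function(n_regimes, nuisance) 3L * n_regimes + nuisance$n_params

make_model <- function(painting, freqs, nuisance) {
  regime_model(painting, freqs, exch = nuisance$exch,
               gamma_shape = nuisance$gamma_shape,
               gamma_categories = nuisance$gamma_categories)
}

#' Score every eligible clade as a single-shift candidate
#'
#' For each eligible node, fits the clade's equilibrium composition with the
#' remainder of the tree held at the nuisance root composition, and scores the
#' two-regime model by BIC. Candidates are returned sorted by ascending BIC,
#' ties broken by postorder index.
#'
#' @param tree rooted `phylo`.
#' @param patterns `phyDat` patterns.
#' @param nuisance output of [fit_global_nuisance()].
#' @param min_clade minimum clade size for eligibility.
#' @param stem_edge shift-placement convention (see [paint_regimes()]).
#' @param bic_n `"sites"` (conventional) or `"patterns"` for the BIC sample
#'   size.
#' @param engine optional shared [ll_engine()].
#' @return data.frame of candidates (node, leafset, lnl, bic, delta_bic vs the
#'   root-only model) with fitted frequencies in `attr(, "freqs")`.
#' @export
score_candidates <- function(tree, patterns, nuisance, min_clade = 4,
                             stem_edge = TRUE, bic_n = c("sites", "patterns"),
                             engine = NULL) {
  bic_n <- match.arg(bic_n)
  eng <- if (is.null(engine)) ll_engine(tree, patterns, nuisance$gamma_categories) else engine
  n <- if (bic_n == "sites") eng$n_sites else eng$npat
  elig <- eligible_nodes(tree, min_clade)
  model0 <- make_model(paint_regimes(tree, integer(0)), list(nuisance$root_freq),
                       nuisance)
  lnl0 <- engine_eval_full(eng, model0)
  bic0 <- bic(lnl0, config_k(1L, nuisance), n)
  rates <- model_rates(model0)
  eig0 <- rev_eigen(build_rate_matrix(nuisance$exch, nuisance$root_freq))
  k2 <- config_k(2L, nuisance)
  out <- vector("list", length(elig))
  for (i in seq_along(elig)) {
    nd <- elig[i]
    painting <- paint_regimes(tree, nd, stem_edge = stem_edge)
    tips <- clade_tips(eng$tree, nd)
    start <- colSums(eng$tip_counts[tips, , drop = FALSE])
    start <- pmax(start / sum(start), 1e-4)
    m1 <- make_model(painting, list(nuisance$root_freq, start / sum(start)),
                     nuisance)
    res <- engine_refit_regime(eng, m1, 1L, factr = 1e8,
                               start = start / sum(start))
    out[[i]] <- list(node = nd, lnl = res$lnl,
                     bic = bic(res$lnl, k2, n),
                     freq = res$model$freqs[[2]])
    # restore the root-only transition matrices on the candidate's edges
    er <- engine_edge_regime(eng, painting)
    eidx <- which(er == 1L)
    if (length(eidx)) {
      engine_set_P(eng, eidx, eig0, rates)
      engine_prune(eng, nuisance$root_freq, dirty_nodes(eng, eidx))
    }
  }
  df <- data.frame(node = vapply(out, `[[`, 0, "node"),
                   lnl = vapply(out, `[[`, 0, "lnl"),
                   bic = vapply(out, `[[`, 0, "bic"))
  df$delta_bic <- df$bic - bic0
  df$leafset <- node_leafset(tree, df$node)
  ord <- order(df$bic, seq_len(nrow(df)))
  freqs <- lapply(out, `[[`, "freq")[ord]
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "freqs") <- freqs
  attr(df, "root_bic") <- bic0
  attr(df, "root_lnl") <- lnl0
  df
}

#' Greedy stepwise search for composition shifts
#'
#' Starting from the root-only model, candidates are visited in ascending-BIC
#' order; each is tentatively added, compositions are re-estimated according
#' to `refit`, and the shift is kept only if the updated BIC is strictly
#' lower.
#'
#' The `refit` modes trade fidelity against cost: `"all"` re-optimizes every
#' regime jointly at each trial (coordinate ascent over regimes); `"new"`
#' re-estimates only the candidate regime's composition against the current
#' configuration during a trial and re-optimizes all regimes jointly once a
#' shift is accepted, so the configuration entering every comparison is
#' jointly fitted while trials stay cheap (the trial likelihood is a lower
#' bound of its joint counterpart, making acceptance conservative); `"none"`
#' keeps the candidate's single-shift scoring estimate verbatim (the literal
#' stepwise rule). `"none"` is cheap but lets stale compositions mimic
#' improvement once a true shift is in the configuration.
#'
#' @inheritParams score_candidates
#' @param refit composition re-estimation at each trial: `"all"`, `"new"`,
#'   or `"none"` (see Details).
#' @param frozen convenience alias: `TRUE` forces `refit = "none"`.
#' @param final_refit jointly re-optimize all compositions once after the
#'   last acceptance (recommended unless `refit = "all"` already ran).
#' @param sweeps,tol coordinate-ascent controls for the joint refit.
#' @param candidates optional precomputed [score_candidates()] output.
#' @return a `shift_config`: accepted `shift_nodes` (in acceptance order),
#'   `leafsets`, final `model`, `lnl`, `bic`, the strictly decreasing
#'   `bic_trajectory`, the per-candidate `decisions` log, and bookkeeping
#'   (`n`, `k`, `nuisance`, `min_clade`).
#' @export
greedy_search <- function(tree, patterns, nuisance, min_clade = 4,
                          stem_edge = TRUE, refit = c("all", "new", "none"),
                          frozen = FALSE, final_refit = TRUE,
                          sweeps = 5, tol = 1e-6,
                          bic_n = c("sites", "patterns"),
                          candidates = NULL, engine = NULL) {
  refit <- if (frozen) "none" else match.arg(refit)
  bic_n <- match.arg(bic_n)
  eng <- if (is.null(engine)) ll_engine(tree, patterns, nuisance$gamma_categories) else engine
  n <- if (bic_n == "sites") eng$n_sites else eng$npat
  if (is.null(candidates))
    candidates <- score_candidates(tree, patterns, nuisance, min_clade,
                                   stem_edge, bic_n, engine = eng)
  cand_freqs <- attr(candidates, "freqs")
  shifts <- integer(0)
  model <- make_model(paint_regimes(tree, integer(0)),
                      list(nuisance$root_freq), nuisance)
  lnl_cur <- engine_eval_full(eng, model)
  bic_cur <- bic(lnl_cur, config_k(1L, nuisance), n)
  trajectory <- bic_cur
  decisions <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    nd <- candidates$node[i]
    if (nd %in% shifts) next
    trial_shifts <- c(shifts, nd)
    painting_t <- paint_regimes(tree, trial_shifts, stem_edge = stem_edge)
    freqs_t <- c(model$freqs, cand_freqs[i])
    model_t <- make_model(painting_t, freqs_t, nuisance)
    if (refit == "none") {
      lnl_t <- engine_eval_full(eng, model_t)
      fit <- list(model = model_t, lnl = lnl_t)
    } else if (refit == "new") {
      if (!length(shifts)) {
        # against the root-only background the trial objective is the scoring
        # objective, so the scored fit is already the trial optimum
        fit <- list(model = model_t, lnl = candidates$lnl[i])
      } else {
        engine_eval_full(eng, model_t)
        fit <- engine_refit_regime(eng, model_t, length(trial_shifts),
                                   factr = 1e7)
      }
    } else {
      fit <- engine_fit_all(eng, model_t, sweeps = sweeps, tol = tol)
    }
    bic_t <- bic(fit$lnl, config_k(length(trial_shifts) + 1L, nuisance), n)
    accept <- bic_t < bic_cur
    decisions[[i]] <- data.frame(node = nd, leafset = candidates$leafset[i],
                                 bic_trial = bic_t, bic_current = bic_cur,
                                 accepted = accept)
    if (accept) {
      shifts <- trial_shifts
      if (refit == "new") {
        # re-optimize the whole accepted configuration before moving on
        fit <- engine_fit_all(eng, fit$model, sweeps = sweeps, tol = tol)
        bic_t <- min(bic_t,
                     bic(fit$lnl, config_k(length(shifts) + 1L, nuisance), n))
      }
      model <- fit$model
      lnl_cur <- fit$lnl
      bic_cur <- bic_t
      trajectory <- c(trajectory, bic_t)
    } else if (!(refit == "new" && !length(shifts))) {
      engine_eval_full(eng, model)  # restore accepted configuration
    }
  }
  if (final_refit && refit != "all" && length(shifts)) {
    # polish all regime compositions jointly at the accepted configuration
    fit <- engine_fit_all(eng, model, sweeps = sweeps, tol = tol)
    model <- fit$model
    lnl_cur <- fit$lnl
    bic_cur <- min(bic_cur, bic(lnl_cur, config_k(length(shifts) + 1L, nuisance), n))
  }
  structure(list(shift_nodes = shifts,
                 leafsets = node_leafset(tree, shifts),
                 model = model, lnl = lnl_cur, bic = bic_cur,
                 bic_trajectory = trajectory,
                 decisions = do.call(rbind, decisions),
                 nuisance = nuisance, n = n,
                 k = config_k(length(shifts) + 1L, nuisance),
                 min_clade = min_clade, stem_edge = stem_edge,
                 tree = tree),
            class = "shift_config")
}

#' @export
print.shift_config <- function(x, ...) {
  cat("Shift configuration:", length(x$shift_nodes), "accepted shift(s)\n")
  cat(sprintf("  lnL = %.3f, BIC = %.3f (root-only BIC = %.3f)\n",
              x$lnl, x$bic, x$bic_trajectory[1]))
  if (length(x$shift_nodes)) {
    for (i in seq_along(x$shift_nodes)) {
      gc_ <- equilibrium_gc(x$model$freqs[[i + 1]])
      cat(sprintf("  shift %d at node %d (clade of %d tips), eq GC = %.3f\n",
                  i, x$shift_nodes[i],
                  length(clade_tips(x$tree, x$shift_nodes[i])), gc_))
    }
  }
  if (!is.null(x$existence))
    cat("  existence weights:",
        paste(sprintf("%.4f", x$existence), collapse = " "), "\n")
  invisible(x)
}

bic_weight_pair <- function(bic_a, bic_b) {
  # weight of model a against model b
  d <- c(bic_a, bic_b) - min(bic_a, bic_b)
  w <- exp(-0.5 * d)
  w[1] / sum(w)
}

refit_configuration <- function(eng, tree, shifts, config, sweeps = 5,
                                tol = 1e-6) {
  painting <- paint_regimes(tree, shifts, stem_edge = config$stem_edge)
  # warm start: retained regimes keep their fitted compositions
  freqs <- c(config$model$freqs[1],
             config$model$freqs[match(shifts, config$shift_nodes) + 1])
  freqs[vapply(freqs, is.null, TRUE)] <- config$model$freqs[1]
  model <- make_model(painting, freqs, config$nuisance)
  fit <- engine_fit_all(eng, model, sweeps = sweeps, tol = tol)
  list(model = fit$model, lnl = fit$lnl,
       bic = bic(fit$lnl, config_k(length(shifts) + 1L, config$nuisance),
                 config$n))
}

#' BIC weights for the existence of each accepted shift
#'
#' Compares the final configuration against the configuration with one shift
#' removed (all compositions re-optimized); the weight is
#' `exp(-0.5 dBIC_with) / (exp(-0.5 dBIC_with) + exp(-0.5 dBIC_without))`.
#'
#' @param config a `shift_config`.
#' @param patterns the `phyDat` patterns the configuration was fit to.
#' @param engine optional shared engine.
#' @return named numeric vector of weights between 0 and 1, one per accepted shift.
#' @export
existence_weights <- function(config, patterns, engine = NULL) {
  stopifnot(inherits(config, "shift_config"))
  if (!length(config$shift_nodes)) return(numeric(0))
  tree <- config$tree
  eng <- if (is.null(engine)) ll_engine(tree, patterns, config$nuisance$gamma_categories) else engine
  w <- numeric(length(config$shift_nodes))
  for (i in seq_along(config$shift_nodes)) {
    without <- setdiff(config$shift_nodes, config$shift_nodes[i])
    alt <- refit_configuration(eng, tree, without, config)
    w[i] <- bic_weight_pair(config$bic, alt$bic)
  }
  engine_eval_full(eng, config$model)
  names(w) <- config$leafsets
  w
}

#' BIC weights for the location of each accepted shift
#'
#' Re-places each accepted shift at its focal node and at each internal
#' daughter, refits the configuration, and normalizes BIC weights over the
#' placements. Leaf daughters cannot host a clade shift and are excluded,
#' with the weights renormalized over the remaining placements; when both
#' daughters are leaves the focal node receives weight 1.
#'
#' @inheritParams existence_weights
#' @return list (one element per shift) of named weight vectors over
#'   `c("focal", "child1", "child2")` restricted to internal placements.
#' @export
location_weights <- function(config, patterns, engine = NULL) {
  stopifnot(inherits(config, "shift_config"))
  if (!length(config$shift_nodes)) return(list())
  tree <- config$tree
  ntip <- ape::Ntip(tree)
  eng <- if (is.null(engine)) ll_engine(tree, patterns, config$nuisance$gamma_categories) else engine
  out <- vector("list", length(config$shift_nodes))
  for (i in seq_along(config$shift_nodes)) {
    s <- config$shift_nodes[i]
    kids <- tree$edge[tree$edge[, 1] == s, 2]
    placements <- c(focal = s,
                    stats::setNames(kids, paste0("child", seq_along(kids))))
    internal <- placements > ntip
    internal["focal"] <- TRUE
    placements <- placements[internal]
    # a placement that collides with another accepted shift is not available
    placements <- placements[!(placements %in% setdiff(config$shift_nodes, s))]
    if (length(placements) == 1L) {
      out[[i]] <- c(focal = 1)
      next
    }
    bics <- vapply(placements, function(p) {
      if (p == s) return(config$bic)
      shifts_p <- replace(config$shift_nodes, i, p)
      refit_configuration(eng, tree, shifts_p, config)$bic
    }, 0)
    d <- bics - min(bics)
    w <- exp(-0.5 * d)
    out[[i]] <- w / sum(w)
  }
  engine_eval_full(eng, config$model)
  names(out) <- config$leafsets
  out
}

#' Detect equilibrium base-composition shifts on a rooted phylogram
#'
#' Full pipeline: compress patterns, fit the homogeneous nuisance model,
#' score eligible clades, run the greedy BIC search, and (optionally)
#' compute existence and location BIC weights for the accepted shifts.
#'
#' @param tree rooted `phylo`, branch lengths in substitutions/site.
#' @param aln `DNAbin` alignment (or `phyDat`) covering the tree tips.
#' @param min_clade minimum clade size for an eligible shift node.
#' @param family exchangeability family, `"HKY"` or `"GTR"`.
#' @param gamma_categories discrete-gamma categories for site-rate
#'   heterogeneity; 0 or 1 disables.
#' @param existence,location compute the corresponding BIC weights.
#' @param refit trial-step composition re-estimation mode (see
#'   [greedy_search()]).
#' @param frozen alias: `TRUE` forces `refit = "none"` (the literal stepwise
#'   rule).
#' @param final_refit jointly re-optimize compositions at the accepted
#'   configuration.
#' @param prune_below drop accepted shifts whose existence weight falls below
#'   this value and refit (off by default: weights are reported, not used to
#'   delete shifts).
#' @param refit_nuisance re-estimate the shared exchangeabilities (and gamma
#'   shape) jointly with the compositions at the final accepted
#'   configuration.
#' @param stem_edge shift-placement convention (see [paint_regimes()]).
#' @param bic_n BIC sample size: `"sites"` or `"patterns"`.
#' @param sweeps,tol joint-refit controls.
#' @return a `shift_config` with `existence` and `location` entries when
#'   requested.
#' @export
detect_shifts <- function(tree, aln, min_clade = 4,
                          family = c("HKY", "GTR"), gamma_categories = 4,
                          existence = TRUE, location = TRUE,
                          refit = c("all", "new", "none"),
                          frozen = FALSE, final_refit = TRUE,
                          refit_nuisance = FALSE, prune_below = NULL,
                          stem_edge = TRUE, bic_n = c("sites", "patterns"),
                          sweeps = 5, tol = 1e-6) {
  family <- match.arg(family)
  bic_n <- match.arg(bic_n)
  validate_tree(tree)
  patterns <- if (inherits(aln, "phyDat")) aln else compress_patterns(aln, tree$tip.label)
  ncat <- max(1L, as.integer(gamma_categories))
  eng <- ll_engine(tree, patterns, ncat = ncat)
  nuisance <- fit_global_nuisance(tree, patterns, family = family,
                                  gamma_categories = ncat, engine = eng)
  config <- greedy_search(tree, patterns, nuisance, min_clade = min_clade,
                          stem_edge = stem_edge, refit = refit, frozen = frozen,
                          final_refit = final_refit,
                          sweeps = sweeps, tol = tol, bic_n = bic_n,
                          engine = eng)
  if (refit_nuisance) {
    fit <- fit_frequencies(tree, config$model, patterns, refit_exch = TRUE)
    config$model <- fit$model
    config$lnl <- fit$lnl
    config$nuisance$exch <- fit$model$exch
    config$nuisance$gamma_shape <- fit$model$gamma_shape
    config$bic <- min(config$bic, bic(fit$lnl, config$k, config$n))
  }
  if (existence && length(config$shift_nodes)) {
    config$existence <- existence_weights(config, patterns, engine = eng)
    if (!is.null(prune_below) && any(config$existence < prune_below)) {
      keep <- config$shift_nodes[config$existence >= prune_below]
      refit <- refit_configuration(eng, tree, keep, config)
      config$shift_nodes <- keep
      config$leafsets <- node_leafset(tree, keep)
      config$model <- refit$model
      config$lnl <- refit$lnl
      config$bic <- refit$bic
      config$existence <- existence_weights(config, patterns, engine = eng)
    }
  }
  if (location && length(config$shift_nodes))
    config$location <- location_weights(config, patterns, engine = eng)
  config
}

#' Tabular summary of a shift configuration
#'
#' @param object a `shift_config`.
#' @param ... unused.
#' @return data.frame with one row per accepted shift: node, clade size,
#'   fitted equilibrium frequencies, equilibrium GC, and support weights when
#'   available.
#' @export
summary.shift_config <- function(object, ...) {
  s <- object$shift_nodes
  if (!length(s)) {
    return(data.frame(node = integer(0), clade_size = integer(0)))
  }
  fr <- do.call(rbind, object$model$freqs[-1])
  colnames(fr) <- c("pi_A", "pi_C", "pi_G", "pi_T")
  df <- data.frame(node = s,
                   leafset_hash = substr(object$leafsets, 1, 40),
                   clade_size = vapply(s, function(nd)
                     length(clade_tips(object$tree, nd)), integer(1)),
                   fr,
                   eq_gc = vapply(object$model$freqs[-1], equilibrium_gc, 0))
  if (!is.null(object$existence)) df$existence_weight <- as.numeric(object$existence)
  if (!is.null(object$location))
    df$focal_location_weight <- vapply(object$location, function(w)
      as.numeric(w["focal"]), 0)
  df
}

#' Annotated Newick with regime ids as NHX comments
#'
#' @param tree the tree the painting refers to.
#' @param painting a `regime_painting`.
#' @return Newick string in which every branch carries
#'   `[&&NHX:regime=<id>]`.
#' @export
annotated_newick <- function(tree, painting) {
  build <- function(nd) {
    ntip <- ape::Ntip(tree)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    lab <- if (nd <= ntip) tree$tip.label[nd]
           else paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
    e <- which(tree$edge[, 2] == nd)
    if (!length(e)) return(lab)  # root
    sprintf("%s:%.10g[&&NHX:regime=%d]", lab, tree$edge.length[e],
            painting$node_regime[nd])
  }
  paste0(build(ape::Ntip(tree) + 1L), ";")
}
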