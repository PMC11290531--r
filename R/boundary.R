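# Boundary-proximity analysis: shift presence at internal nodes modeled
# against temporal distance to a geological boundary (default: the K-Pg
# horizon at 66 Ma) with phylogeny-aware logistic regression. Internal nodes
# become observations by grafting a negligible-length terminal onto each one,
# which makes the shared-path-length covariance of a standard phylogenetic
# regression well defined for node-level states.

#' Graft a negligible-length terminal onto every internal node
#'
#' @param chronogram ultrametric `phylo` with branch lengths in Ma (a warning,
#'   not an error, is raised for non-ultrametric input).
#' @param eps branch length of the grafted tips, in Ma.
#' @return a `grafted_tree`: list with the grafted `tree`, a `map` data.frame
#'   (original internal node id, its leafset, grafted tip label), and `eps`.
#' @export
graft_internal_terminals <- function(chronogram, eps = 1e-6) {
  validate_tree(chronogram, require_binary_root = FALSE)
  if (!ape::is.ultrametric(chronogram, tol = 1e-6))
    warning("chronogram is not ultrametric; grafted-tip ages will be uneven")
  ntip <- ape::Ntip(chronogram)
  internal <- ntip + seq_len(chronogram$Nnode)
  leafsets <- node_leafset(chronogram, internal)
  labels <- paste0("node_", internal)
  tr <- chronogram
  for (i in seq_along(internal)) {
    where <- node_from_leafset(tr, leafsets[i])
    tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = labels[i], edge.length = eps,
                          Nnode = 1L), class = "phylo")
    tr <- ape::bind.tree(tr, tip, where = where)
  }
  structure(list(tree = tr,
                 map = data.frame(node = internal, leafset = leafsets,
                                  tip = labels),
                 eps = eps),
            class = "grafted_tree")
}

#' Remove the grafted terminals again
#'
#' Inverse of [graft_internal_terminals()]; useful to verify the graft left
#' the original topology untouched.
#'
#' @param grafted a `grafted_tree`.
#' @return `phylo` without the grafted tips.
#' @export
ungraft <- function(grafted) {
  ape::drop.tip(grafted$tree, grafted$map$tip)
}

#' Log-proportional proximity to a temporal boundary
#'
#' `log(max(|stem_age - boundary|, floor))`: distances enter the logistic
#' model proportionally, and the floor guards nodes that sit exactly on the
#' boundary.
#'
#' @param stem_age node stem age(s) in Ma.
#' @param boundary boundary age in Ma (66 for the K-Pg horizon).
#' @param floor smallest distance, in Ma, before the log.
#' @return numeric predictor value(s).
#' @export
proximity_predictor <- function(stem_age, boundary = 66, floor = 1e-3) {
  stopifnot(all(stem_age >= 0))
  log(pmax(abs(stem_age - boundary), floor))
}

#' Node ages and stem ages of a chronogram
#'
#' @param chronogram ultrametric `phylo`.
#' @return data.frame per internal node: node id, leafset, crown `age`, and
#'   `stem_age` (the age of the subtending branch point; for the root, its own
#'   age).
#' @export
node_ages <- function(chronogram) {
  ntip <- ape::Ntip(chronogram)
  depth <- ape::node.depth.edgelength(chronogram)
  age <- max(depth[seq_len(ntip)]) - depth
  internal <- ntip + seq_len(chronogram$Nnode)
  stem <- vapply(internal, function(nd) {
    e <- which(chronogram$edge[, 2] == nd)
    if (!length(e)) age[nd] else age[chronogram$edge[e, 1]]
  }, 0)
  data.frame(node = internal, leafset = node_leafset(chronogram, internal),
             age = age[internal], stem_age = stem)
}

#' Gene-tree discordance per reference node
#'
#' Gene-tree nodes below the support cutoff are collapsed; each reference
#' internal node's bipartition is then restricted to the taxa shared with a
#' gene tree and classified as concordant (the gene tree contains the
#' restricted split), conflicting (it contains an incompatible split), or
#' non-decisive (trivial after restriction, or a polytomy that neither
#' contains nor conflicts with the split). The discordance proportion is
#' conflicts over decisive gene trees, reported on the arcsine-square-root
#' scale; a variant over all informative gene trees is returned alongside.
#'
#' @param gene_trees `multiPhylo` (or list) of gene trees whose internal node
#'   labels hold support values (percent).
#' @param reference rooted reference `phylo`.
#' @param support_cut collapse gene-tree nodes with support below this value.
#' @return data.frame per reference internal node: counts of decisive and
#'   conflicting gene trees, raw proportion `p`, `asin_sqrt_p`, and the
#'   all-trees variant `p_total`. Nodes decisive in zero gene trees get `NA`.
#' @export
gene_tree_discordance <- function(gene_trees, reference, support_cut = 95) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  ntip <- ape::Ntip(reference)
  internal <- ntip + seq_len(reference$Nnode)
  ref_clades <- lapply(internal, function(nd)
    reference$tip.label[clade_tips(reference, nd)])

  collapse_low_support <- function(gt) {
    if (is.null(gt$node.label)) return(gt)
    sup <- suppressWarnings(as.numeric(gt$node.label))
    drop <- which(!is.na(sup) & sup < support_cut)
    if (!length(drop)) return(gt)
    gt2 <- gt
    idx <- match(ape::Ntip(gt) + drop, gt2$edge[, 2])
    idx <- idx[!is.na(idx)]  # root carries no edge
    gt2$edge.length[idx] <- 0
    ape::di2multi(gt2, tol = 1e-12)
  }

  gts <- lapply(gene_trees, collapse_low_support)
  gt_splits <- lapply(gts, function(gt) {
    pp <- ape::prop.part(gt)
    lapply(pp, function(i) attr(pp, "labels")[i])
  })
  gt_taxa <- lapply(gts, function(gt) gt$tip.label)

  classify <- function(A, taxa, splits) {
    A <- intersect(A, taxa)
    B <- setdiff(taxa, A)
    if (length(A) < 2 || length(B) < 2) return(NA)  # trivial: not decisive
    for (C in splits) {
      C <- intersect(C, taxa)
      Cb <- setdiff(taxa, C)
      if (setequal(C, A) || setequal(Cb, A)) return("concordant")
    }
    for (C in splits) {
      C <- intersect(C, taxa)
      Cb <- setdiff(taxa, C)
      if (length(intersect(A, C)) && length(intersect(A, Cb)) &&
          length(intersect(B, C)) && length(intersect(B, Cb)))
        return("conflict")
    }
    NA  # polytomy: neither agrees nor conflicts
  }

  rows <- lapply(seq_along(internal), function(i) {
    cls <- vapply(seq_along(gts), function(g)
      as.character(classify(ref_clades[[i]], gt_taxa[[g]], gt_splits[[g]])),
      character(1))
    n_conf <- sum(cls == "conflict", na.rm = TRUE)
    n_dec <- sum(!is.na(cls))
    n_inf <- length(cls)
    p <- if (n_dec > 0) n_conf / n_dec else NA_real_
    data.frame(node = internal[i], n_decisive = n_dec, n_conflict = n_conf,
               p = p, asin_sqrt_p = if (is.na(p)) NA_real_ else asin(sqrt(p)),
               p_total = n_conf / n_inf)
  })
  out <- do.call(rbind, rows)
  out$leafset <- node_leafset(reference, internal)
  out
}

#' Node-level covariates for the boundary analysis
#'
#' @param chronogram ultrametric `phylo`.
#' @param shift_leafsets character vector of canonical leafsets carrying a
#'   shift in any data type (see [node_leafset()]).
#' @param boundary boundary age in Ma.
#' @param discordance optional output of [gene_tree_discordance()] on the
#'   same reference topology.
#' @return data.frame per internal node: `shift` indicator, `stem_age`,
#'   `proximity` predictor, and `discordance` when supplied.
#' @export
node_covariates <- function(chronogram, shift_leafsets, boundary = 66,
                            discordance = NULL) {
  ages <- node_ages(chronogram)
  ages$shift <- as.integer(ages$leafset %in% shift_leafsets)
  ages$proximity <- proximity_predictor(ages$stem_age, boundary)
  if (!is.null(discordance))
    ages$discordance <- discordance$asin_sqrt_p[match(ages$node,
                                                      discordance$node)]
  ages
}

# GEE-style estimating equations for logistic regression with a fixed working
# correlation; with R = I this is exactly the IRLS of an ordinary GLM.
gee_logistic <- function(X, y, Rinv, beta0 = NULL, maxit = 100, tol = 1e-10,
                         ridge = 0) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- sqrt(pmax(mu * (1 - mu), 1e-12))
    Xw <- X * w
    H <- crossprod(Xw, Rinv %*% Xw) + diag(ridge, p)
    g <- crossprod(Xw, Rinv %*% ((y - mu) / w)) - ridge * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; converged <- TRUE; break }
    beta <- beta_new
    if (max(abs(beta)) > 50) break  # separation guard
  }
  list(beta = beta, converged = converged,
       separation = max(abs(beta)) > 25)
}

#' Phylogeny-aware logistic regression of shift presence
#'
#' Binary responses at (grafted) tips are modeled with logistic regression
#' whose estimating equations carry a working correlation derived from the
#' tree: `R(alpha) = exp(-alpha * D)` with `D` the patristic distance matrix
#' scaled to unit maximum, a mean-reverting transform of shared path lengths.
#' The signal parameter `alpha` is estimated by maximizing the Gaussian
#' pseudo-likelihood of the standardized residuals; as `alpha` grows the
#' correlation vanishes and the estimator reduces exactly to ordinary
#' logistic regression (`alpha = Inf` forces that limit). Coefficient
#' uncertainty comes from a parametric bootstrap: responses are re-simulated
#' from the fit through a latent-Gaussian copula with correlation
#' `R(alpha_hat)` and refit with `alpha` held fixed.
#'
#' @param tree `phylo` (typically `grafted$tree`) containing the observation
#'   tips.
#' @param data data.frame with the response and covariates; rownames or a
#'   `tip` column identify tips. Extant terminals should already be excluded
#'   by the caller where the design requires it.
#' @param formula model formula, e.g. `shift ~ proximity`.
#' @param alpha fix the signal parameter instead of estimating it
#'   (`Inf` = no phylogenetic correlation).
#' @param nboot parametric bootstrap replicates (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return a `phylo_glm`: `coefficients`, `alpha`, `boot` (matrix of
#'   bootstrap coefficients), `boot_se`, `naive` (ordinary-GLM coefficients),
#'   `converged`, and `separation`.
#' @export
fit_phylo_logistic <- function(tree, data, formula = shift ~ proximity,
                               alpha = NULL, nboot = 1000, seed = NULL) {
  tips <- if ("tip" %in% names(data)) data$tip else rownames(data)
  if (is.null(tips)) stop("data must carry tip labels (rownames or `tip`)")
  keep <- tips %in% tree$tip.label
  data <- data[keep, , drop = FALSE]; tips <- tips[keep]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; tips <- tips[ok]
  if (all(y == 0) || all(y == 1))
    stop("response needs both positive and negative observations")
  D <- ape::cophenetic.phylo(tree)[tips, tips]
  D <- D / max(D)
  n <- length(y)

  corr <- function(a) if (is.infinite(a)) diag(n) else exp(-a * D)
  pseudo_ll <- function(a, beta) {
    R <- corr(a)
    ch <- tryCatch(chol(R + diag(1e-10, n)), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    mu <- plogis(drop(X %*% beta))
    e <- (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-12))
    v <- backsolve(ch, e, transpose = TRUE)
    -(sum(log(diag(ch))) + 0.5 * sum(v^2))
  }

  fit_at <- function(a, beta0 = NULL, ridge = 0) {
    R <- corr(a)
    Rinv <- if (is.infinite(a)) diag(n) else solve(R + diag(1e-10, n))
    gee_logistic(X, y, Rinv, beta0 = beta0, ridge = ridge)
  }

  naive <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- naive$coefficients
  if (is.null(alpha)) {
    for (round in 1:3) {
      opt <- optimize(function(a) pseudo_ll(a, beta), interval = c(0.5, 100),
                      maximum = TRUE)
      alpha_hat <- opt$maximum
      fit <- fit_at(alpha_hat, beta0 = beta)
      if (max(abs(fit$beta - beta)) < 1e-8) { beta <- fit$beta; break }
      beta <- fit$beta
    }
  } else {
    alpha_hat <- alpha
    fit <- fit_at(alpha_hat, beta0 = beta)
    beta <- fit$beta
  }
  if (fit$separation || !fit$converged) {
    fit <- fit_at(alpha_hat, beta0 = NULL, ridge = 1e-4)
    beta <- fit$beta
  }
  names(beta) <- colnames(X)

  boot <- NULL
  if (nboot > 0) {
    R <- corr(alpha_hat)
    ch <- chol(R + diag(1e-10, n))
    Rinv <- if (is.infinite(alpha_hat)) diag(n) else solve(R + diag(1e-10, n))
    mu_hat <- plogis(drop(X %*% beta))
    boot <- with_seed(seed, {
      t(vapply(seq_len(nboot), function(b) {
        z <- drop(crossprod(ch, rnorm(n)))
        yb <- as.numeric(pnorm(z) < mu_hat)
        if (all(yb == 0) || all(yb == 1)) return(rep(NA_real_, ncol(X)))
        gee_logistic(X, yb, Rinv, beta0 = beta)$beta
      }, numeric(ncol(X))))
    })
    colnames(boot) <- colnames(X)
  }

  structure(list(coefficients = beta, alpha = alpha_hat,
                 boot = boot,
                 boot_se = if (!is.null(boot)) apply(boot, 2, sd, na.rm = TRUE),
                 naive = stats::setNames(naive$coefficients, colnames(X)),
                 converged = fit$converged, separation = fit$separation,
                 n = n, formula = formula),
            class = "phylo_glm")
}

#' @export
print.phylo_glm <- function(x, ...) {
  cat("Phylogenetic logistic regression (", x$n, " observations, alpha = ",
      format(x$alpha, digits = 4), ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients,
               boot_se = if (!is.null(x$boot_se)) x$boot_se else NA,
               naive = x$naive)
  print(round(tab, 4))
  if (x$separation) cat("warning: separation detected; ridge-penalized fit\n")
  invisible(x)
}

#' Predicted shift probability at representative discordance levels
#'
#' Evaluates the fitted model on a proximity grid at low (mean - 1 SD), mean,
#' and high (mean + 1 SD) discordance.
#'
#' @param fit a `phylo_glm` fit with a discordance term.
#' @param covs the covariate table used in the fit.
#' @param proximity grid of proximity-predictor values.
#' @return data.frame of predictions per (proximity, level).
#' @export
predict_discordance_levels <- function(fit, covs,
                                       proximity = seq(-2, 5, length.out = 50)) {
  if (!"discordance" %in% names(covs)) stop("covariates lack discordance")
  m <- mean(covs$discordance, na.rm = TRUE)
  s <- sd(covs$discordance, na.rm = TRUE)
  levels <- c(low = m - s, mean = m, high = m + s)
  out <- do.call(rbind, lapply(names(levels), function(lv) {
    nd <- data.frame(proximity = proximity, discordance = levels[[lv]])
    X <- model.matrix(stats::delete.response(stats::terms(fit$formula)), nd)
    data.frame(proximity = proximity, level = lv,
               prob = plogis(drop(X %*% fit$coefficients[colnames(X)])))
  }))
  out
}
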