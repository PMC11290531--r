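#' Draw equilibrium compositions from a Dirichlet distribution
#'
#' One i.i.d. draw per regime (the first is conventionally the root/ancestral
#' composition). The all-ones concentration gives the uniform Dirichlet used
#' by the validation scenarios.
#'
#' @param n number of compositions.
#' @param concentration Dirichlet concentration parameters (length 4, or a
#'   scalar recycled).
#' @param seed optional RNG seed.
#' @return list of `n` base-frequency vectors.
#' @export
sample_compositions <- function(n, concentration = c(1, 1, 1, 1), seed = NULL) {
  stopifnot(n >= 1)
  a <- rep_len(concentration, 4)
  with_seed(seed, lapply(seq_len(n), function(i) {
    g <- rgamma(4, shape = a)
    # guard astronomically unlikely all-zero draws and keep frequencies > 0
    g <- pmax(g, 1e-12)
    base_frequencies(pmax(g / sum(g), 1e-8) / sum(pmax(g / sum(g), 1e-8)))
  }))
}

#' Sample shift nodes under clade-size, buffer and lineage constraints
#'
#' Reproduces the validation node sampler: eligible nodes have clade sizes in
#' `[min_clade, max_clade]`; selected nodes must be at least `buffer` edges
#' apart on the node path. In independent mode, once a node is selected its
#' lineage (ancestors and descendants) is excluded from later draws; in nested
#' mode the first draw defines the lineage pool (its ancestors and
#' descendants) from which the remaining draws are taken. When the
#' constraints cannot be met the process restarts with a fresh initial node,
#' up to `max_restarts` times.
#'
#' @param tree rooted `phylo`.
#' @param n_shifts number of shift nodes (0 returns an empty set).
#' @param min_clade,max_clade clade-size window; `max_clade = NULL` defaults
#'   to 3/4 of the number of tips.
#' @param buffer minimum node-path distance (edges) between selected nodes.
#' @param nested nested (`TRUE`) or phylogenetically independent (`FALSE`)
#'   configuration.
#' @param seed optional RNG seed.
#' @param max_restarts bound on restarts before an error is raised.
#' @return integer vector of node ids (selection order).
#' @export
sample_shift_nodes <- function(tree, n_shifts, min_clade = 4,
                               max_clade = NULL, buffer = 2, nested = FALSE,
                               seed = NULL, max_restarts = 1000) {
  stopifnot(n_shifts >= 0, buffer >= 0)
  if (n_shifts == 0) return(integer(0))
  ntip <- ape::Ntip(tree)
  if (is.null(max_clade)) max_clade <- floor(0.75 * ntip)
  stopifnot(min_clade <= max_clade)
  elig <- eligible_nodes(tree, min_clade)
  sizes <- vapply(elig, function(nd) length(clade_tips(tree, nd)), integer(1))
  pool0 <- elig[sizes <= max_clade]
  if (length(pool0) < 1) stop("no eligible nodes under the clade-size window")
  D <- node_path_distances(tree)
  lineage <- function(nd) {
    anc <- integer(0)
    p <- nd
    repeat {
      e <- which(tree$edge[, 2] == p)
      if (!length(e)) break
      p <- tree$edge[e, 1]
      anc <- c(anc, p)
    }
    c(nd, anc, unlist(phangorn::Descendants(tree, nd, type = "all")))
  }
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      chosen <- pool0[sample.int(length(pool0), 1)]
      pool <- if (nested) intersect(lineage(chosen), pool0) else
        setdiff(pool0, lineage(chosen))
      ok <- TRUE
      while (length(chosen) < n_shifts) {
        valid <- pool[vapply(pool, function(nd)
          all(D[nd, chosen] >= buffer), logical(1))]
        valid <- setdiff(valid, chosen)
        if (!length(valid)) { ok <- FALSE; break }
        nxt <- valid[sample.int(length(valid), 1)]
        chosen <- c(chosen, nxt)
        if (!nested) pool <- setdiff(pool, lineage(nxt))
      }
      if (ok) return(as.integer(chosen))
    }
    stop("could not satisfy the shift-sampling constraints after ",
         max_restarts, " restarts")
  })
}

#' Simulate an alignment under a regime-painted substitution model
#'
#' Root states are drawn i.i.d. from the ancestral regime's frequencies; each
#' branch then evolves its sites with the transition matrix of the child
#' node's regime (stem-edge convention, matching the search). Sites are
#' independent with uniform rates unless a gamma shape is given, in which
#' case each site is assigned one of `gamma_categories` mean-discretized
#' rates uniformly at random.
#'
#' @param tree rooted `phylo` (branch lengths in substitutions/site).
#' @param painting `regime_painting` (default: no shifts).
#' @param freqs list of per-regime base frequencies (ancestral first).
#' @param kappa HKY transition:transversion rate parameter.
#' @param length alignment length in sites.
#' @param gamma_shape optional gamma shape for site-rate variation.
#' @param gamma_categories categories used when `gamma_shape` is set.
#' @param seed optional RNG seed.
#' @return `DNAbin` matrix (tips x sites); zero-length input yields a
#'   zero-column alignment.
#' @export
simulate_alignment <- function(tree, painting = NULL, freqs, kappa = 2,
                               length, gamma_shape = NULL,
                               gamma_categories = 4, seed = NULL) {
  nsites <- length
  length <- base::length  # restore the generic after consuming the argument
  if (is.null(painting)) painting <- paint_regimes(tree, integer(0))
  stopifnot(length(freqs) == n_regimes(painting))
  freqs <- lapply(freqs, base_frequencies)
  ntip <- ape::Ntip(tree)
  if (nsites == 0)
    return(states_to_dnabin(matrix(integer(0), ntip, 0), tree$tip.label))
  exch <- hky_exchangeabilities(kappa)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode_all <- ntip + po$Nnode
  with_seed(seed, {
    rates <- if (is.null(gamma_shape)) rep(1, nsites) else {
      cat_rates <- gamma_rates(gamma_shape, gamma_categories)
      cat_rates[sample.int(gamma_categories, nsites, replace = TRUE)]
    }
    rate_groups <- split(seq_len(nsites), rates)
    states <- matrix(0L, nnode_all, nsites)
    states[ntip + 1L, ] <- sample.int(4, nsites, replace = TRUE,
                                      prob = freqs[[1]])
    eigs <- lapply(freqs, function(f)
      rev_eigen(build_rate_matrix(exch, f)))
    node_regime <- painting$node_regime
    er <- node_regime[po$edge[, 2]]
    if (!painting$stem_edge && length(painting$shift_nodes)) {
      idx <- match(painting$shift_nodes, po$edge[, 2])
      er[idx] <- node_regime[po$edge[idx, 1]]
    }
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: root towards tips
      pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t_e <- po$edge.length[e]
      eig <- eigs[[er[e] + 1L]]
      for (g in seq_along(rate_groups)) {
        sites <- rate_groups[[g]]
        r <- as.numeric(names(rate_groups)[g])
        P <- matrix(pmat_block(eig, t_e * r)[, 1], 4, 4)
        ps <- states[pa, sites]
        cs <- integer(length(sites))
        for (s in 1:4) {
          idx <- which(ps == s)
          if (length(idx))
            cs[idx] <- sample.int(4, length(idx), replace = TRUE,
                                  prob = pmax(P[s, ], 0))
        }
        states[ch, sites] <- cs
      }
    }
    states_to_dnabin(states[seq_len(ntip), , drop = FALSE], po$tip.label)
  })
}

#' Pure-birth toy tree generator
#'
#' Stands in for an empirical phylogram so the validation pipeline never
#' needs external data. `burst = TRUE` emulates a rapid early radiation by
#' compressing the oldest internodes: the oldest 20% of splits are remapped
#' to occupy the top 5% of tree depth.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed optional RNG seed.
#' @param burst compress basal internodes.
#' @param depth root-to-tip depth in expected substitutions/site.
#' @return rooted ultrametric `phylo` with tip labels `t1..tn`.
#' @export
generate_toy_tree <- function(n_tips, seed = NULL, burst = FALSE,
                              depth = 0.5) {
  stopifnot(n_tips >= 3)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_tips))
    node_depth <- ape::node.depth.edgelength(tr)
    total <- max(node_depth)
    age <- total - node_depth  # time before present
    if (burst) {
      ints <- ape::Ntip(tr) + seq_len(tr$Nnode)
      a80 <- as.numeric(quantile(age[ints], 0.8))
      squash <- function(a) ifelse(a <= a80, a * (0.95 * total) / a80,
        0.95 * total + (a - a80) * (0.05 * total) / (total - a80))
      age <- ifelse(seq_along(age) %in% ints | age == 0, squash(age), age)
      age[seq_len(ape::Ntip(tr))] <- 0
    }
    for (e in seq_len(nrow(tr$edge)))
      tr$edge.length[e] <- age[tr$edge[e, 1]] - age[tr$edge[e, 2]]
    tr$edge.length <- pmax(tr$edge.length, 1e-9) * (depth / total)
    tr
  })
}

#' Simulate a complete regime-shift dataset
#'
#' Samples a shift configuration (per `scenario`), draws regime and root
#' compositions from a uniform Dirichlet, simulates an HKY alignment, and
#' returns the ground truth alongside the data.
#'
#' @param tree rooted `phylo`.
#' @param scenario `"none"`, `"independent"`, or `"nested"`.
#' @param n_shifts shifts to place (ignored for `"none"`).
#' @param length alignment length in sites.
#' @param kappa HKY transition:transversion rate parameter (the validation
#'   setting is 2:1).
#' @param concentration Dirichlet concentration for compositions.
#' @param min_clade,max_clade,buffer sampler constraints (see
#'   [sample_shift_nodes()]).
#' @param gamma_shape optional site-rate heterogeneity (off in the validation
#'   scenarios).
#' @param seed RNG seed (recorded in the output).
#' @return a `sim_dataset`: `tree`, `shift_nodes`, `leafsets`, `painting`,
#'   `freqs`, `alignment`, `annotated_newick`, `truth` (JSON-ready sidecar),
#'   and the echoed `config`.
#' @export
simulate_dataset <- function(tree, scenario = c("none", "independent", "nested"),
                             n_shifts = 2, length = 10000, kappa = 2,
                             concentration = c(1, 1, 1, 1), min_clade = 4,
                             max_clade = NULL, buffer = 2,
                             gamma_shape = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "none") n_shifts <- 0L
  seeds <- derive_seeds(if (is.null(seed)) sample.int(1e6, 1) else seed, 3)
  shift_nodes <- sample_shift_nodes(tree, n_shifts, min_clade, max_clade,
                                    buffer, nested = scenario == "nested",
                                    seed = seeds[1])
  painting <- paint_regimes(tree, shift_nodes)
  freqs <- sample_compositions(n_shifts + 1L, concentration, seed = seeds[2])
  aln <- simulate_alignment(tree, painting, freqs, kappa = kappa,
                            length = length, gamma_shape = gamma_shape,
                            seed = seeds[3])
  ds <- structure(list(
    tree = tree, shift_nodes = shift_nodes,
    leafsets = node_leafset(tree, shift_nodes),
    painting = painting, freqs = freqs, alignment = aln,
    config = list(scenario = scenario, n_shifts = n_shifts, length = length,
                  kappa = kappa, concentration = concentration,
                  min_clade = min_clade, max_clade = max_clade,
                  buffer = buffer, gamma_shape = gamma_shape, seed = seed)),
    class = "sim_dataset")
  ds$annotated_newick <- export_annotated_newick(ds)
  ds$truth <- list(leafsets = ds$leafsets,
                   regimes = seq_along(shift_nodes),
                   freqs = freqs, kappa = kappa, seed = seed,
                   length = length, scenario = scenario)
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", x$config$scenario, "scenario,",
      length(x$shift_nodes), "shift(s),", x$config$length, "sites\n")
  invisible(x)
}

#' Export a simulated dataset as a model-annotated Newick string
#'
#' Each regime's most basal node carries a sequence-simulator style model
#' annotation (`[&model=HKY{kappa}+F{fA/fC/fG/fT}]`); the root model is
#' appended after the closing parenthesis. The JSON sidecar written by
#' [write_sim_dataset()] is the authoritative truth format for tests.
#'
#' @param ds a `sim_dataset`.
#' @return annotated Newick string.
#' @export
export_annotated_newick <- function(ds) {
  tree <- ds$tree
  ntip <- ape::Ntip(tree)
  ann <- function(freq, kappa)
    sprintf("[&model=HKY{%.6g}+F{%.6g/%.6g/%.6g/%.6g}]",
            kappa, freq[1], freq[2], freq[3], freq[4])
  build <- function(nd) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    lab <- if (nd <= ntip) tree$tip.label[nd]
           else paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
    i <- match(nd, ds$shift_nodes)
    if (!is.na(i)) lab <- paste0(lab, ann(ds$freqs[[i + 1]], ds$config$kappa))
    e <- which(tree$edge[, 2] == nd)
    if (!length(e)) return(lab)
    sprintf("%s:%.10g", lab, tree$edge.length[e])
  }
  paste0(build(ntip + 1L), ann(ds$freqs[[1]], ds$config$kappa), ";")
}

#' Write a simulated dataset to disk
#'
#' FASTA alignment, plain and annotated Newick, and a JSON truth sidecar.
#'
#' @param ds a `sim_dataset`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_sim_dataset <- function(ds, prefix) {
  paths <- c(fasta = paste0(prefix, ".fasta"),
             newick = paste0(prefix, ".nwk"),
             annotated = paste0(prefix, ".annotated.nwk"),
             truth = paste0(prefix, ".truth.json"))
  write_alignment(ds$alignment, paths["fasta"])
  writeLines(write_newick(ds$tree), paths["newick"])
  writeLines(ds$annotated_newick, paths["annotated"])
  writeLines(jsonlite::toJSON(ds$truth, auto_unbox = TRUE, digits = NA),
             paths["truth"])
  invisible(paths)
}
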