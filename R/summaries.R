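#' Deviation between two base compositions
#'
#' Primary metric is total-variation distance, `0.5 * sum(|p - q|)`, bounded
#' between 0 and 1; Euclidean distance and per-base deltas are also returned since
#' the magnitude metric used in published figures of this kind is rarely
#' stated.
#'
#' @param p,q base-frequency vectors (A, C, G, T).
#' @return list with `tv`, `euclidean`, and `per_base` (p - q).
#' @export
frequency_deviation <- function(p, q) {
  p <- base_frequencies(p); q <- base_frequencies(q)
  list(tv = 0.5 * sum(abs(p - q)),
       euclidean = sqrt(sum((p - q)^2)),
       per_base = p - q)
}

#' Per-regime composition summaries
#'
#' For each regime of a fitted configuration: its taxon set, empirical base
#' frequencies (counted over the alignment), fitted equilibrium frequencies,
#' the deviation between the two, both GC contents, and (when a trait table
#' is supplied) the clade mean log10 body mass.
#'
#' @param config a `shift_config` from [detect_shifts()] or
#'   [greedy_search()].
#' @param aln the alignment the configuration was fit to (`DNAbin`).
#' @param traits optional data.frame with columns `taxon` and `mass_g`.
#' @return data.frame with one row per regime (ancestral regime first) and a
#'   `taxa` list-column.
#' @export
regime_summaries <- function(config, aln, traits = NULL) {
  stopifnot(inherits(config, "shift_config"))
  tree <- config$tree
  regimes <- seq_along(config$model$freqs) - 1L
  node_regime <- config$model$painting$node_regime
  rows <- lapply(regimes, function(r) {
    taxa <- tree$tip.label[which(node_regime[seq_len(ape::Ntip(tree))] == r)]
    if (!length(taxa)) return(NULL)
    emp <- empirical_frequencies(aln, taxa)
    eq <- config$model$freqs[[r + 1]]
    dev <- frequency_deviation(eq, emp)
    row <- data.frame(regime = r, n_taxa = length(taxa),
                      emp_A = emp[1], emp_C = emp[2], emp_G = emp[3],
                      emp_T = emp[4],
                      eq_A = eq[1], eq_C = eq[2], eq_G = eq[3], eq_T = eq[4],
                      deviation_tv = dev$tv,
                      deviation_euclidean = dev$euclidean,
                      empirical_gc = equilibrium_gc(emp),
                      equilibrium_gc = equilibrium_gc(eq))
    if (!is.null(traits)) {
      m <- traits$mass_g[match(taxa, traits$taxon)]
      row$mean_log10_mass <- mean(log10(m), na.rm = TRUE)
      row$n_mass <- sum(!is.na(m))
    }
    row$taxa <- I(list(taxa))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of regime GC content on clade mean body mass
#'
#' Ordinary least squares of per-regime GC content (both the empirical and
#' the fitted equilibrium value) on the regime's mean log10 body mass, at the
#' regime level. Under GC-biased gene conversion whose efficacy scales with
#' effective population size, and with body mass as an inverse proxy of that
#' size, a negative slope is expected.
#'
#' @param summaries output of [regime_summaries()] including
#'   `mean_log10_mass`.
#' @return data.frame with one row per response (`empirical_gc`,
#'   `equilibrium_gc`): slope, intercept, and R squared.
#' @export
gc_mass_regression <- function(summaries) {
  if (!"mean_log10_mass" %in% names(summaries))
    stop("summaries lack body-mass information")
  ok <- is.finite(summaries$mean_log10_mass)
  if (sum(ok) < 3) stop("need at least 3 regimes with mass data")
  fit_one <- function(response) {
    f <- lm(summaries[[response]][ok] ~ summaries$mean_log10_mass[ok])
    data.frame(response = response,
               slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
               r_squared = summary(f)$r.squared)
  }
  out <- rbind(fit_one("empirical_gc"), fit_one("equilibrium_gc"))
  rownames(out) <- NULL
  out
}
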