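#' HKY exchangeabilities
#'
#' Shared symmetric rate multipliers for the HKY model: transitions (A<->G,
#' C<->T) at rate `kappa`, transversions at 1.
#'
#' @param kappa transition:transversion rate parameter (> 0).
#' @return an `exchangeabilities` object.
#' @export
hky_exchangeabilities <- function(kappa = 2) {
  stopifnot(kappa > 0)
  structure(list(family = "HKY", kappa = kappa), class = "exchangeabilities")
}

#' GTR exchangeabilities
#'
#' @param rates six symmetric rates in the order AC, AG, AT, CG, CT, GT;
#'   conventionally GT is fixed to 1.
#' @return an `exchangeabilities` object.
#' @export
gtr_exchangeabilities <- function(rates = c(1, 2, 1, 1, 2, 1)) {
  stopifnot(length(rates) == 6, all(rates > 0))
  structure(list(family = "GTR", rates = as.numeric(rates)),
            class = "exchangeabilities")
}

# symmetric 4x4 multiplier matrix from exchangeabilities
exch_matrix <- function(exch) {
  s <- matrix(1, 4, 4)
  if (exch$family == "HKY") {
    s[1, 3] <- s[3, 1] <- exch$kappa  # A<->G
    s[2, 4] <- s[4, 2] <- exch$kappa  # C<->T
  } else {
    r <- exch$rates
    s[1, 2] <- s[2, 1] <- r[1]; s[1, 3] <- s[3, 1] <- r[2]
    s[1, 4] <- s[4, 1] <- r[3]; s[2, 3] <- s[3, 2] <- r[4]
    s[2, 4] <- s[4, 2] <- r[5]; s[3, 4] <- s[4, 3] <- r[6]
  }
  diag(s) <- 0
  s
}

n_exch_params <- function(exch, gamma_categories) {
  (if (exch$family == "HKY") 1L else 5L) +
    (if (gamma_categories > 1) 1L else 0L)
}

#' Validate a base-frequency vector
#'
#' @param freq numeric length-4 vector (A, C, G, T).
#' @param tol tolerance on the unit-sum constraint.
#' @return the vector, named, after checks.
#' @export
base_frequencies <- function(freq, tol = 1e-12) {
  freq <- as.numeric(freq)
  stopifnot(length(freq) == 4)
  if (any(freq <= 0)) stop("base frequencies must be strictly positive")
  if (abs(sum(freq) - 1) > max(tol, 1e-8)) stop("frequencies must sum to 1")
  stats::setNames(freq / sum(freq), c("A", "C", "G", "T"))
}

#' Reversible rate matrix from exchangeabilities and frequencies
#'
#' Builds `Q[i,j] = s[i,j] * pi[j]` with rows summing to zero, optionally
#' rescaled to one expected substitution per unit branch length under its own
#' stationary frequencies (so input branch lengths keep their units inside
#' every regime).
#'
#' @param exch an `exchangeabilities` object.
#' @param freq equilibrium base frequencies (A, C, G, T).
#' @param normalize rescale to mean rate 1.
#' @return 4x4 rate matrix with attribute `"freq"`.
#' @export
build_rate_matrix <- function(exch, freq, normalize = TRUE) {
  freq <- base_frequencies(freq)
  Q <- exch_matrix(exch) * rep(freq, each = 4)
  diag(Q) <- -rowSums(Q)
  if (normalize) Q <- Q / sum(freq * -diag(Q))
  dimnames(Q) <- list(names(freq), names(freq))
  attr(Q, "freq") <- freq
  Q
}

# eigendecomposition of a reversible Q via symmetrization; returns the
# ingredients to form P(t) = sum_k exp(lambda_k t) C_k cheaply for many t.
rev_eigen <- function(Q, freq = attr(Q, "freq")) {
  d <- sqrt(freq)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  left <- e$vectors / d        # D^{-1/2} V
  right <- t(e$vectors * d)    # V' D^{1/2}
  # Cmat[k, x + 4*(y-1)] = left[x,k] * right[k,y]  (column-major 4x4 blocks)
  Cmat <- matrix(0, 4, 16)
  for (k in 1:4) Cmat[k, ] <- as.vector(outer(left[, k], right[k, ]))
  list(lambda = e$values, Cmat = Cmat)
}

# P matrices for a vector of branch lengths under one eigendecomposition;
# returns [16 x length(t)] (column-major 4x4 per branch), clamped to [0,1].
pmat_block <- function(eig, t) {
  E <- exp(outer(t, eig$lambda))
  Pf <- E %*% eig$Cmat
  Pf[Pf < 0] <- 0
  t(Pf)
}

#' Discrete-gamma category rates
#'
#' Mean-per-category discretization with unit mean, via
#' [phangorn::discrete.gamma()].
#'
#' @param shape gamma shape parameter (> 0); smaller means more site-rate
#'   heterogeneity.
#' @param k number of categories; `k = 1` returns rate 1 (uniform rates).
#' @return numeric vector of k rates with mean 1.
#' @export
gamma_rates <- function(shape, k = 4) {
  stopifnot(k >= 1, k <= 16)
  if (k == 1) return(1)
  stopifnot(shape > 0)
  phangorn::discrete.gamma(shape, k)
}

#' Transition probability matrices
#'
#' `P(t) = expm(r Q t)` per gamma-category rate `r`.
#'
#' @param Q rate matrix from [build_rate_matrix()].
#' @param t branch length (>= 0).
#' @param rates per-category rates (default: one uniform category).
#' @return list of 4x4 stochastic matrices, one per category.
#' @export
transition_probs <- function(Q, t, rates = 1) {
  if (t < 0) stop("negative branch length")
  eig <- rev_eigen(Q)
  lapply(rates, function(r) {
    P <- matrix(pmat_block(eig, t * r)[, 1], 4, 4)
    dimnames(P) <- dimnames(Q)
    P
  })
}

#' GC content of an equilibrium composition
#' @param freq base frequencies (A, C, G, T).
#' @return `pi_G + pi_C`.
#' @export
equilibrium_gc <- function(freq) {
  freq <- base_frequencies(freq)
  as.numeric(freq["G"] + freq["C"])
}

#' Assemble a regime model
#'
#' Bundles a regime painting with per-regime equilibrium frequencies, shared
#' exchangeabilities, and optional discrete-gamma rate heterogeneity.
#'
#' @param painting a `regime_painting` (see [paint_regimes()]).
#' @param freqs list of base-frequency vectors indexed by regime id + 1 (the
#'   first element is the ancestral/root regime 0).
#' @param exch shared `exchangeabilities`.
#' @param gamma_shape gamma shape, or `NULL` for uniform rates.
#' @param gamma_categories number of categories when `gamma_shape` is set.
#' @return a `regime_model` object.
#' @export
regime_model <- function(painting, freqs, exch = hky_exchangeabilities(2),
                         gamma_shape = NULL, gamma_categories = 4) {
  stopifnot(inherits(painting, "regime_painting"))
  if (length(freqs) != n_regimes(painting))
    stop("need one frequency vector per regime (ancestral regime first)")
  freqs <- lapply(freqs, base_frequencies)
  ncat <- if (is.null(gamma_shape)) 1L else as.integer(gamma_categories)
  structure(list(painting = painting, freqs = freqs, exch = exch,
                 gamma_shape = gamma_shape, ncat = ncat),
            class = "regime_model")
}

#' @export
print.regime_model <- function(x, ...) {
  cat("Regime model:", length(x$freqs), "regime(s),", x$exch$family,
      if (x$ncat > 1) sprintf("+G(%d) shape=%.3g", x$ncat, x$gamma_shape)
      else "(uniform rates)", "\n")
  for (i in seq_along(x$freqs))
    cat(sprintf("  regime %d: %s\n", i - 1L,
                paste(sprintf("%.4f", x$freqs[[i]]), collapse = " ")))
  invisible(x)
}

model_rates <- function(model) {
  if (model$ncat == 1) 1 else gamma_rates(model$gamma_shape, model$ncat)
}

#' Serialize a fitted model or shift report to JSON
#' @param x a `regime_model` or `shift_config`.
#' @param file optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(x, file = NULL) {
  json <- jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.function(x) || is.environment(x)) NULL
  else x
}
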