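#' Match detected shifts against simulation truth
#'
#' With `tolerance = 0`, a detection counts as a true positive only when its
#' clade (canonical leafset) is exactly a truth node. With `tolerance = d`,
#' detected nodes are greedily matched one-to-one to the nearest unmatched
#' truth node within a node-path distance of `d` edges (closest pairs first,
#' ties by postorder index).
#'
#' @param tree the canonical tree both node sets refer to.
#' @param truth integer node ids of the simulated shifts.
#' @param detected integer node ids reported by the search.
#' @param tolerance maximum node-path distance (edges) for a match.
#' @return a `detection_outcome`: `tp`, `fp`, `fn` node sets plus the inputs.
#' @export
match_shifts <- function(tree, truth, detected, tolerance = 0) {
  nnode_all <- ape::Ntip(tree) + tree$Nnode
  if (any(c(truth, detected) > nnode_all) || any(c(truth, detected) < 1))
    stop("node id not on tree")
  truth <- as.integer(truth); detected <- as.integer(detected)
  if (tolerance == 0) {
    tp <- intersect(detected, truth)
    fp <- setdiff(detected, truth)
    fn <- setdiff(truth, detected)
  } else {
    D <- node_path_distances(tree)
    pairs <- expand.grid(det = detected, tru = truth)
    if (nrow(pairs)) {
      pairs$d <- D[cbind(pairs$det, pairs$tru)]
      pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
      pairs <- pairs[order(pairs$d, pairs$det, pairs$tru), , drop = FALSE]
    }
    tp_det <- integer(0); tp_tru <- integer(0)
    for (j in seq_len(nrow(pairs))) {
      if (!(pairs$det[j] %in% tp_det) && !(pairs$tru[j] %in% tp_tru)) {
        tp_det <- c(tp_det, pairs$det[j]); tp_tru <- c(tp_tru, pairs$tru[j])
      }
    }
    tp <- tp_tru
    fp <- setdiff(detected, tp_det)
    fn <- setdiff(truth, tp_tru)
  }
  structure(list(truth = truth, detected = detected, tp = tp, fp = fp,
                 fn = fn, tolerance = tolerance),
            class = "detection_outcome")
}

#' False-positive and false-negative rates across replicates
#'
#' Per dataset, the false-negative rate is `|FN| / |truth|` (0 when no shift
#' was simulated) and the per-node false-positive rate is
#' `|FP| / (eligible - |truth|)`. Because the normalization of published
#' benchmark rates is not fixed by convention, a per-replicate binary
#' false-positive indicator (any spurious shift) is reported alongside.
#'
#' @param outcomes list of [match_shifts()] results.
#' @param eligible_count number of eligible nodes in each replicate's search.
#' @return one-row data.frame: means, standard deviations and `n` for the FN
#'   rate, the per-node FP rate, and the binary FP rate, with per-replicate
#'   values in `attr(, "replicates")`.
#' @export
fp_fn_rates <- function(outcomes, eligible_count) {
  stopifnot(length(outcomes) >= 1)
  fn <- vapply(outcomes, function(o)
    if (length(o$truth)) length(o$fn) / length(o$truth) else 0, 0)
  denom <- vapply(outcomes, function(o) eligible_count - length(o$truth), 0)
  if (any(denom <= 0)) stop("eligible_count must exceed the number of true shifts")
  fp <- vapply(outcomes, function(o) length(o$fp), 0) / denom
  fp_any <- as.numeric(vapply(outcomes, function(o) length(o$fp) > 0, TRUE))
  out <- data.frame(n = length(outcomes),
                    fn_mean = mean(fn), fn_sd = sd(fn),
                    fp_mean = mean(fp), fp_sd = sd(fp),
                    fp_any_mean = mean(fp_any), fp_any_sd = sd(fp_any))
  attr(out, "replicates") <- data.frame(fn = fn, fp = fp, fp_any = fp_any)
  out
}

#' One-sample t and Z tests of a mean rate against zero
#'
#' One-sided tests of the null hypothesis that the average rate is not
#' greater than zero. Degenerate samples follow documented conventions: an
#' all-zero sample gives p = 1 for both tests; a constant positive sample
#' (s.d. 0) gives p = 0 and is flagged.
#'
#' @param rates per-replicate rates (n >= 2).
#' @return data.frame with rows for the t and Z statistics: `statistic`,
#'   `p`, and a `degenerate` flag. Apply [adjust_rate_tests()] across the
#'   family of tests for FDR control.
#' @export
test_rates <- function(rates) {
  n <- length(rates)
  if (n < 2) stop("need at least two replicates")
  m <- mean(rates); s <- sd(rates)
  degenerate <- s == 0
  if (degenerate) {
    p <- if (m <= 0) 1 else 0
    stat <- if (m <= 0) 0 else Inf
    out <- data.frame(test = c("t", "Z"), statistic = stat, p = p,
                      degenerate = TRUE)
  } else {
    tt <- t.test(rates, mu = 0, alternative = "greater")
    z <- m / (s / sqrt(n))
    out <- data.frame(test = c("t", "Z"),
                      statistic = c(unname(tt$statistic), z),
                      p = c(tt$p.value, pnorm(z, lower.tail = FALSE)),
                      degenerate = FALSE)
  }
  out
}

#' Benjamini-Hochberg adjustment across a family of rate tests
#'
#' @param tests data.frame with a `p` column (rows from [test_rates()],
#'   possibly stacked across scenarios and data types).
#' @return the data.frame with an added `p_adjusted` column.
#' @export
adjust_rate_tests <- function(tests) {
  stopifnot("p" %in% names(tests))
  tests$p_adjusted <- p.adjust(tests$p, method = "BH")
  tests
}
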