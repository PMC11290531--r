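# Small shared fixtures, built once per test run.

fx <- new.env()

fx_tree16 <- function() {
  if (is.null(fx$tree16)) fx$tree16 <- generate_toy_tree(16, seed = 101, depth = 0.5)
  fx$tree16
}

fx_tree64 <- function() {
  if (is.null(fx$tree64)) fx$tree64 <- generate_toy_tree(64, seed = 102, depth = 0.5)
  fx$tree64
}

balanced_tree <- function(n, bl = 0.1) {
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}
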