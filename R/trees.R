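#' Read a rooted phylogram from Newick text or a file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the preconditions of
#' the shift search: a single rooted tree whose branch lengths are present and
#' non-negative, with unique tip labels. Trees with a basal polytomy are
#' rejected when `require_binary_root = TRUE` (the default), since the search
#' needs an unambiguous root regime. Support values stored as internal node
#' labels are kept; NHX-style bracket comments are accepted (stripped before
#' parsing).
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file path to a Newick file.
#' @param require_binary_root reject trees whose root has more than two
#'   children.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL, require_binary_root = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  # accept NHX-style bracket comments by stripping them before parsing
  text <- gsub("\\[[^]]*\\]", "", text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse error")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  validate_tree(tr, require_binary_root = require_binary_root)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

validate_tree <- function(tree, require_binary_root = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  root <- ape::Ntip(tree) + 1L
  if (require_binary_root && sum(tree$edge[, 1] == root) > 2L)
    stop("tree is unrooted (basal polytomy); the shift search needs a rooted bifurcation at the root")
  invisible(tree)
}

# internal: postorder sequence of internal node ids (children before parents)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

#' Canonical node identifier from descendant leaves
#'
#' Nodes are identified across trees and runs by the sorted set of descendant
#' tip labels, so a detected shift can be compared to ground truth even when
#' internal node numbering differs.
#'
#' @param tree a `phylo` object.
#' @param node internal node id(s) (ape numbering).
#' @return character vector of `|`-joined sorted tip labels.
#' @export
node_leafset <- function(tree, node) {
  vapply(node, function(nd) {
    tips <- clade_tips(tree, nd)
    paste(sort(tree$tip.label[tips]), collapse = "|")
  }, character(1))
}

#' Find the node matching a canonical leafset
#'
#' @param tree a `phylo` object.
#' @param leafset string(s) as produced by [node_leafset()].
#' @return integer node id(s); `NA` when the clade is absent from the tree.
#' @export
node_from_leafset <- function(tree, leafset) {
  ids <- c(seq_len(ape::Ntip(tree)), ape::Ntip(tree) + seq_len(tree$Nnode))
  key <- node_leafset(tree, ids)
  ids[match(leafset, key)]
}

# tip indices descended from (or equal to) a node
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  unlist(phangorn::Descendants(tree, node, type = "tips"))
}

#' Internal nodes eligible for a composition shift
#'
#' Returns every non-root internal node whose clade contains at least
#' `min_clade` leaves, in postorder (tips-to-root). The root itself is never
#' eligible: it carries the ancestral regime by construction.
#'
#' @param tree rooted `phylo`.
#' @param min_clade minimum number of leaves in the clade (>= 2).
#' @return integer vector of node ids in postorder.
#' @export
eligible_nodes <- function(tree, min_clade = 4) {
  stopifnot(min_clade >= 2)
  root <- ape::Ntip(tree) + 1L
  po <- postorder_nodes(tree)
  po <- po[po != root]
  sizes <- vapply(po, function(nd) length(clade_tips(tree, nd)), integer(1))
  po[sizes >= min_clade]
}

#' Paint regimes onto a tree from a set of shift nodes
#'
#' Each node is assigned the regime of its nearest ancestor-or-self shift
#' node; nodes with no shifted ancestor stay in the ancestral regime 0. Under
#' the default stem-edge convention the branch subtending a shift node belongs
#' to the shifted regime, so regime membership of an *edge* is the regime of
#' its child node.
#'
#' @param tree rooted `phylo`.
#' @param shift_nodes internal node ids where new regimes start (root
#'   excluded); order determines regime numbering (1, 2, ...).
#' @param stem_edge if `FALSE`, the crown convention is used instead: the stem
#'   branch of a shift node stays in the enclosing regime.
#' @return an object of class `regime_painting`: list with `node_regime`
#'   (integer per node, tips first then internals), `edge_regime` (per edge of
#'   `reorder(tree, "postorder")`), `shift_nodes`, and `stem_edge`.
#' @export
paint_regimes <- function(tree, shift_nodes = integer(0), stem_edge = TRUE) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  shift_nodes <- as.integer(shift_nodes)
  if (anyDuplicated(shift_nodes)) stop("duplicate shift nodes")
  if (root %in% shift_nodes) stop("a shift cannot be placed on the root")
  if (any(shift_nodes <= ntip)) stop("shift nodes must be internal")
  nnode_all <- ntip + tree$Nnode
  regime <- integer(nnode_all)
  shift_regime <- seq_along(shift_nodes)
  names(shift_regime) <- shift_nodes
  # preorder sweep: parent regimes are known before children
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    regime[ch] <- if (as.character(ch) %in% names(shift_regime))
      shift_regime[[as.character(ch)]] else regime[pa]
  }
  edge_regime <- regime[po$edge[, 2]]
  if (!stem_edge) {
    # crown convention: the stem branch keeps the parent's regime
    for (e in seq_len(nrow(po$edge))) {
      ch <- po$edge[e, 2]
      if (ch %in% shift_nodes) edge_regime[e] <- regime[po$edge[e, 1]]
    }
  }
  structure(list(node_regime = regime, edge_regime = edge_regime,
                 shift_nodes = shift_nodes, stem_edge = stem_edge),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", length(x$shift_nodes), "shift(s),",
      length(unique(x$node_regime)), "regime(s)\n")
  invisible(x)
}

#' Number of regimes in a painting
#' @param painting a `regime_painting`.
#' @return integer count (ancestral regime included).
#' @export
n_regimes <- function(painting) length(painting$shift_nodes) + 1L

#' Topological (edge-count) distances between nodes
#'
#' @param tree a `phylo` object.
#' @return square matrix of path lengths in edges over all nodes.
#' @export
node_path_distances <- function(tree) {
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  ape::dist.nodes(unit)
}
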