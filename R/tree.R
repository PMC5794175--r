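#' Parse a Newick string into a validated phylogeny
#'
#' Trees are represented throughout the package as [ape] `"phylo"` objects.
#' Parsing enforces the invariants every downstream comparative computation
#' relies on: a single root, unique tip labels, and finite, non-negative
#' branch lengths.
#'
#' @param text A Newick string (branch lengths required).
#' @return A rooted object of class `"phylo"`. Single-tip trees are accepted
#'   but carry the attribute `usable_for_contrasts = FALSE`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("malformed Newick: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')') near character position ",
         regexpr("[()]", text), call. = FALSE)
  }
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0) {
    stop("malformed Newick: missing terminal ';' (string ends at character ",
         nchar(text), ")", call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick near character position 1: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("malformed Newick: could not be parsed (character position 1-",
         nchar(text), ")", call. = FALSE)
  }
  validate_tree(tree)
}

#' Validate the tree invariants used by the comparative machinery
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly unchanged apart from validation attributes.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (ape::Ntip(tree) >= 2L) {
    if (is.null(tree$edge.length)) {
      stop("tree has no branch lengths", call. = FALSE)
    }
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop("branch lengths must be finite and non-negative", call. = FALSE)
    }
    if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
    # every node reachable exactly once from the root
    nn <- ape::Ntip(tree) + tree$Nnode
    if (length(unique(c(tree$edge))) != nn) {
      stop("tree traversal does not visit every node exactly once", call. = FALSE)
    }
    attr(tree, "usable_for_contrasts") <- TRUE
  } else {
    attr(tree, "usable_for_contrasts") <- FALSE
  }
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 12L) {
  ape::write.tree(tree, digits = digits)
}

#' Read and validate a Newick file
#'
#' @param path Path to a Newick file containing one tree.
#' @return A validated `"phylo"` object.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Random ultrametric phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit root-to-tip depth, the substrate
#' used by the simulation studies. Contemporaneous species are expected to sit
#' at equal depth, hence the ultrametric default.
#'
#' @param n_tips Number of tips.
#' @param depth Root-to-tip depth after rescaling (time units).
#' @param birth Birth rate of the Yule process.
#' @param seed Optional integer seed.
#' @return A `"phylo"` object with tips `s1..sn`.
#' @export
random_ultrametric_tree <- function(n_tips, depth = 1, birth = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- paste0("s", seq_len(n_tips))
  h <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length * (depth / h)
  validate_tree(tree)
}

#' Root-to-node depths
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of root-to-node path lengths indexed by node id
#'   (tips `1..n`, internals `n+1..n+Nnode`).
#' @export
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  # edges in preorder: parent always visited before child
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2L]] <- depth[ord$edge[i, 1L]] + ord$edge.length[i]
  }
  depth
}

#' Tree height (maximum root-to-tip depth)
#' @param tree A `"phylo"` object.
#' @return Scalar height.
#' @export
tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

#' Align a named trait vector with the tips of a tree
#'
#' Checks that the trait covers every tip (after optional pruning of tips with
#' missing values) and returns the vector in tip order together with the
#' possibly pruned tree.
#'
#' @param tree A `"phylo"` object.
#' @param x Named numeric vector, names are species / tip labels.
#' @param prune If `TRUE`, tips without a (finite) trait value are dropped
#'   from the tree rather than raising an error.
#' @return List with elements `tree` and `x` (aligned, finite).
#' @export
align_trait <- function(tree, x, prune = FALSE) {
  if (is.null(names(x))) stop("trait vector must be named by species", call. = FALSE)
  x <- x[is.finite(x)]
  extra <- setdiff(names(x), tree$tip.label)
  if (length(extra)) {
    stop("species absent from tree: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing)) {
    if (!prune) {
      stop("missing trait values for species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (length(missing) > ape::Ntip(tree) - 2L) {
      stop("fewer than 2 tips remain after pruning missing species", call. = FALSE)
    }
    tree <- ape::drop.tip(tree, missing)
  }
  list(tree = tree, x = as.numeric(x[tree$tip.label]) |>
         stats::setNames(tree$tip.label))
}
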