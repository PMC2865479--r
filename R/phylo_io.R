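#' Read and validate a rooted newick tree
#'
#' Parses a single newick statement into an [ape::read.tree()] `phylo`
#' object and validates it for use in the constraint simulations: the tree
#' must be rooted, tip labels must be unique and non-empty, and branch
#' lengths must be non-negative. Branch lengths absent from the newick
#' string default to 1.
#'
#' @param text a newick string terminated by `";"`; ignored if `file` is given.
#' @param file path to a newick file (alternative to `text`).
#' @return a rooted `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply either `text` or `file`")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick input")
  if (!grepl(";\\s*$", text)) stop("newick statement must be terminated by ';'")
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in newick input (%d '(' vs %d ')')",
                 n_open, n_close))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("newick parse error: input could not be read as a tree")
  validate_tree(tree)
}

#' Validate a phylogeny for constraint simulation
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label at position ",
                               which(!nzchar(labs))[1])
  dup <- labs[duplicated(labs)]
  if (length(dup)) stop("duplicate tip label: '", dup[1], "'")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 1
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  if (length(labs) > 1 && !ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Convert a tree to speciational form
#'
#' Sets every branch length to exactly 1 so that each branch receives one
#' evolutionary step, modelling change concentrated at speciation events.
#' Topology and labels are unchanged; the operation is idempotent. The root
#' carries no branch and receives no step.
#'
#' @param tree a `phylo` object (validated first).
#' @return the tree with all branch lengths equal to 1.
#' @export
as_speciational <- function(tree) {
  tree <- validate_tree(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$root.edge <- NULL
  tree
}

#' Test whether a tree is in speciational form
#'
#' @param tree a `phylo` object.
#' @return `TRUE` if every branch length equals 1.
#' @export
is_speciational <- function(tree) {
  !is.null(tree$edge.length) && all(tree$edge.length == 1)
}

#' Root-to-tip node order
#'
#' Returns the node indices of a rooted tree in preorder: the root first,
#' and every node strictly after its parent. This is the order in which the
#' simulator walks branches.
#'
#' @param tree a rooted `phylo` object.
#' @return integer vector of node indices (ape numbering: tips `1..n`, root
#'   `n + 1`).
#' @export
root_to_tip_order <- function(tree) {
  tree <- validate_tree(tree)
  edges <- preorder_edges(tree)
  root <- length(tree$tip.label) + 1L
  c(root, edges[, 2L])
}

# Edge matrix reordered so each row's parent node appears before its child
# appears as a parent: ape's cladewise order is exactly this preorder.
preorder_edges <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  tr$edge
}

#' Write a tree to newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the newick string is returned.
#' @return the newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
  }
}
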