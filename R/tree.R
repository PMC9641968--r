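#' @importFrom ape read.tree is.rooted unroot getMRCA Ntip Nnode
NULL

#' Read a Newick tree
#'
#' Parses a Newick string with branch lengths into an [ape::read.tree]
#' `phylo` object. Trees may be unrooted (basal multifurcation). Negative
#' branch lengths are rejected.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(gsub("\\s", "", txt))) stop("empty Newick file: ", path)
  no <- gsub("[^()]", "", txt)
  if (sum(strsplit(no, "")[[1]] == "(") != sum(strsplit(no, "")[[1]] == ")"))
    stop("unbalanced parentheses in Newick file: ", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) in tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  invisible(tr)
}

#' Write a Newick tree at full precision
#'
#' Serialises a `phylo` object to Newick, printing branch lengths with 17
#' significant digits so that a parse -> write -> parse round trip is
#' topology- and length-identical.
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) {
    if (is.null(x) || is.na(x)) "" else paste0(":", sprintf("%.17g", x))
  }
  node_lab <- function(v) {
    if (v <= ntip) tree$tip.label[v]
    else if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
  }
  rec <- function(v, len) {
    ek <- kids[[as.character(v)]]
    if (is.null(ek)) return(paste0(node_lab(v), fmt_len(len)))
    inner <- vapply(ek, function(e)
      rec(tree$edge[e, 2], tree$edge.length[e]), character(1))
    paste0("(", paste(inner, collapse = ","), ")", node_lab(v), fmt_len(len))
  }
  out <- paste0(rec(root, NA), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Tip labels subtended by a node
#' @param tree A rooted `phylo` object.
#' @param node Node number (ape numbering: tips `1..n`, internals `n+1..`).
#' @return Character vector of tip labels below (and including) `node`.
#' @export
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(todo)) {
    v <- todo[[1]]; todo <- todo[-1]
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) tips <- c(tips, v) else todo <- c(todo, ch)
  }
  tree$tip.label[tips]
}

#' Root a tree on an outgroup, splitting the separating branch equally
#'
#' The tree is rooted on the branch that separates the outgroup leaves from
#' the rest; the length of that branch is divided equally between the two
#' children of the new root, so total tree length is conserved. The outgroup
#' must form one side of a bipartition of the unrooted tree.
#'
#' @param tree A `phylo` object (rooted trees are unrooted first).
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted `phylo` whose root has exactly two children.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  validate_tree(tree)
  outgroup <- unique(as.character(outgroup))
  tips <- tree$tip.label
  unknown <- setdiff(outgroup, tips)
  if (length(unknown))
    stop("outgroup labels not in tree: ", paste(unknown, collapse = ", "))
  if (length(outgroup) == 0L || length(outgroup) >= length(tips))
    stop("outgroup must be a non-empty proper subset of the tips")
  tr <- if (ape::is.rooted(tree) && length(tips) > 2L) ape::unroot(tree) else tree

  # monophyly check relative to an anchor tip outside the outgroup
  if (length(outgroup) > 1L) {
    anchor <- setdiff(tips, outgroup)[1]
    anch <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
    m <- ape::getMRCA(anch, outgroup)
    below <- node_tips(anch, m)
    if (!setequal(below, outgroup))
      stop("outgroup is not monophyletic; intruding leaves: ",
           paste(setdiff(below, outgroup), collapse = ", "))
  }

  rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  root <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == root)
  if (length(re) != 2L)
    stop("internal error: rooted tree root does not have two children")
  tot <- sum(rooted$edge.length[re])
  rooted$edge.length[re] <- tot / 2
  rooted
}

#' Most recent common ancestor of a set of taxa
#'
#' @param tree A rooted `phylo` object.
#' @param taxa Character vector of tip labels (non-empty).
#' @return The ape node number of the deepest node whose subtended leaf set
#'   contains `taxa`; for a single taxon, the tip itself.
#' @export
mrca_node <- function(tree, taxa) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("taxa must be non-empty")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L)
    return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Total branch length of a tree
#' @param tree A `phylo` object.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) sum(tree$edge.length)
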