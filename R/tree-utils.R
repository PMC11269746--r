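# Internal helpers around ape "phylo" objects. All public functions index
# nodes by name, so every tree entering the package must have unique tip and
# internal-node labels (the simulators guarantee this; `name_nodes` repairs
# trees that lack internal labels).

#' Ensure every node of a tree is uniquely named
#'
#' Tips keep their labels; missing or duplicated internal-node labels are
#' replaced by `nd<k>` where `k` is the ape node number.
#'
#' @param tree an [ape::phylo] object.
#' @param prefix prefix for generated internal labels.
#' @return the tree with a complete `node.label`.
#' @export
name_nodes <- function(tree, prefix = "nd") {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Nnode(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n)
  bad <- is.na(lab) | lab == "" | duplicated(lab)
  lab[bad] <- paste0(prefix, which(bad) + ape::Ntip(tree))
  tree$node.label <- lab
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("tree labels are not unique")
  tree
}

# name -> ape node id (tips first, then internal nodes)
node_id <- function(tree, name) {
  all <- c(tree$tip.label, tree$node.label)
  id <- match(name, all)
  if (anyNA(id)) stop("node(s) not in tree: ", paste(name[is.na(id)], collapse = ", "))
  id
}

#' All node names of a tree, tips first then internal nodes
#' @param tree a named [ape::phylo] tree.
#' @return character vector in ape node-id order.
#' @export
all_node_names <- function(tree) c(tree$tip.label, tree$node.label)

root_id <- function(tree) ape::Ntip(tree) + 1L

# depth (distance from root) of every node
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree an [ape::phylo] object.
#' @param tol relative tolerance on root-to-tip path lengths.
#' @return logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

# edges ordered so that children are visited before parents (postorder) or
# after parents (preorder); returns a 2-column matrix of ape node ids
edges_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tr$edge
}
edge_lengths_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tr$edge.length
}

# all nodes (ids) in the subtree rooted at `node` (id), including `node`
descendant_ids <- function(tree, node) {
  ed <- tree$edge
  keep <- node
  frontier <- node
  repeat {
    children <- ed[ed[, 1] %in% frontier, 2]
    if (!length(children)) break
    keep <- c(keep, children)
    frontier <- children
  }
  keep
}

#' Tips descending from a named internal node
#' @param tree a named [ape::phylo] tree.
#' @param node internal node name (or a tip name, returned as is).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  id <- node_id(tree, node)
  ids <- descendant_ids(tree, id)
  tree$tip.label[ids[ids <= ape::Ntip(tree)]]
}

#' Node-name path between an ancestor and a descendant
#'
#' Returns the ordered node names from `from` (an ancestor) down to `to`,
#' inclusive; consecutive names delimit the branches of the path, so a path of
#' `m + 1` names has `m` branches.
#'
#' @param tree a named [ape::phylo] tree.
#' @param from,to node names; `from` must be an ancestor of `to`.
#' @return character vector of node names.
#' @export
path_nodes <- function(tree, from, to) {
  a <- node_id(tree, from); b <- node_id(tree, to)
  ed <- tree$edge
  path <- b
  cur <- b
  while (cur != a) {
    p <- ed[ed[, 2] == cur, 1]
    if (!length(p)) stop("'", from, "' is not an ancestor of '", to, "'")
    cur <- p
    path <- c(cur, path)
  }
  all_node_names(tree)[path]
}
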