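#' Read a rooted phylogeny from a Newick file
#'
#' The tree must carry branch lengths. Internal nodes without labels are
#' auto-named `N1`, `N2`, ... by postorder index, so ancestral reports are
#' reproducible across runs. An unrooted (basal trifurcation) tree is accepted
#' only when `root_on` names an outgroup taxon to root on.
#'
#' @param path Newick file (or a literal Newick string).
#' @param root_on optional outgroup leaf label used to root an unrooted tree.
#' @return an `ape` `phylo` object with complete, unique node labels.
#' @export
read_tree <- function(path, root_on = NULL) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse Newick input: ", path)
  prepare_tree(tr, root_on = root_on)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
prepare_tree <- function(tree, root_on = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) {
    if (is.null(root_on))
      stop("tree is unrooted; supply root_on = <outgroup leaf> to root it")
    if (!root_on %in% tree$tip.label)
      stop("root_on taxon '", root_on, "' is not a leaf of the tree")
    tree <- ape::root(tree, outgroup = root_on, resolve.root = TRUE)
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  if (any(tree$edge.length == 0))
    message("note: tree contains zero-length branch(es)")
  label_internal_nodes(tree)
}

# Deterministic internal-node naming: postorder rank, prefix "N".
label_internal_nodes <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  po <- ape::reorder.phylo(tree, "postorder")
  # internal nodes in order of completion (last edge into each parent)
  parents <- po$edge[, 1]
  order_int <- unique(parents[length(parents):1])
  order_int <- rev(order_int)                       # postorder completion
  rank <- match(seq_len(n_int) + ape::Ntip(tree), order_int)
  auto <- paste0("N", rank)
  lab[!nzchar(lab)] <- auto[!nzchar(lab)]
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("node labels are not unique after auto-naming")
  tree$node.label <- lab
  tree
}

#' @rdname read_tree
#' @param file output path.
#' @export
write_tree <- function(tree, file) {
  ape::write.tree(tree, file = file, digits = 12)
  invisible(file)
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

node_id <- function(tree, label) {
  id <- match(label, node_labels(tree))
  if (anyNA(id)) stop("unknown node label(s): ",
                      paste(label[is.na(id)], collapse = ", "))
  id
}

# Postorder edge table used by the C++ engines.
tree_post <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_length = po$edge.length,
       n_tips = ape::Ntip(tree), n_nodes = ape::Ntip(tree) + tree$Nnode,
       root = ape::Ntip(tree) + 1L, labels = node_labels(tree))
}

# Edge row (postorder table) whose child is `node`.
edge_into <- function(tp, node) {
  e <- match(node, tp$edge[, 2])
  if (is.na(e)) stop("node ", node, " has no parent edge (is it the root?)")
  e
}

#' Define a (monophyletic) clade and its foreground nodes
#'
#' The foreground node set of a clade is its member leaves plus all internal
#' nodes of the induced subtree: a 3-leaf clade contributes 3 terminal and 2
#' ancestral nodes, i.e. `2k - 1` nodes for `k` leaves.
#'
#' @param tree a prepared `phylo`.
#' @param members leaf labels; must be monophyletic in `tree`.
#' @param name clade name used in reports.
#' @return a `clade_spec`: members, MRCA, and foreground node ids/labels in
#'   postorder.
#' @export
clade_spec <- function(tree, members, name = "clade") {
  members <- as.character(members)
  miss <- setdiff(members, tree$tip.label)
  if (length(miss)) stop("clade '", name, "': unknown leaves: ",
                         paste(miss, collapse = ", "))
  leaf_ids <- match(members, tree$tip.label)
  if (length(members) == 1L) {
    nodes <- leaf_ids
  } else {
    mrca <- ape::getMRCA(tree, members)
    sub <- ape::extract.clade(tree, mrca)
    if (!setequal(sub$tip.label, members))
      stop("clade '", name, "' is not monophyletic: MRCA also contains ",
           paste(setdiff(sub$tip.label, members), collapse = ", "))
    desc <- phangorn::Descendants(tree, mrca, type = "all")
    nodes <- c(mrca, desc)
  }
  # order foreground nodes by postorder completion
  tp <- tree_post(tree)
  ord <- c(tp$edge[, 2], tp$root)          # postorder over all nodes
  nodes <- ord[ord %in% nodes]
  structure(list(name = name, members = members, leaf_ids = leaf_ids,
                 mrca = if (length(members) > 1L) mrca else leaf_ids,
                 node_ids = nodes, node_labels = node_labels(tree)[nodes]),
            class = "clade_spec")
}

#' @export
print.clade_spec <- function(x, ...) {
  cat("<clade_spec> ", x$name, ": ", length(x$members), " leaves, ",
      length(x$node_ids), " foreground nodes\n", sep = "")
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Resolve focal clades and control scenarios from a configuration
#'
#' @param tree prepared `phylo`.
#' @param config list with elements `focal_a`, `focal_b` (each either a
#'   character vector of leaves or a list with `name` and `members`) and
#'   optional `controls`, a list of scenarios passed to [swap_control()].
#' @return list with `focal_a`, `focal_b` (clade_specs) and `controls`, a
#'   list of control clade-spec pairs.
#' @export
resolve_clades <- function(tree, config) {
  get_clade <- function(x, default_name) {
    if (is.character(x)) clade_spec(tree, x, default_name)
    else clade_spec(tree, x$members, if (!is.null(x$name)) x$name else default_name)
  }
  a <- get_clade(config$focal_a, "focalA")
  b <- get_clade(config$focal_b, "focalB")
  if (length(intersect(a$members, b$members)))
    stop("focal clades overlap: ",
         paste(intersect(a$members, b$members), collapse = ", "))
  controls <- list()
  if (!is.null(config$controls))
    controls <- swap_control(tree, a, b, config$controls)
  list(focal_a = a, focal_b = b, controls = controls)
}

#' Match a tree to an alignment, allowing per-gene taxon subsets
#'
#' Leaves absent from the alignment are pruned with a warning (genes with
#' missing taxa are analysed on the induced subtree); alignment taxa absent
#' from the tree are an error.
#'
#' @param tree prepared `phylo`.
#' @param aln a `paas_aln`.
#' @return possibly pruned tree.
#' @export
match_tree_alignment <- function(tree, aln) {
  extra <- setdiff(rownames(aln), tree$tip.label)
  if (length(extra))
    stop("alignment taxa not in tree: ", paste(extra, collapse = ", "))
  drop <- setdiff(tree$tip.label, rownames(aln))
  if (length(drop)) {
    warning("pruning ", length(drop), " tree leaves absent from alignment: ",
            paste(drop, collapse = ", "))
    tree <- prepare_tree(ape::drop.tip(tree, drop))
  }
  tree
}
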