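#' @importFrom stats coef cor cor.test glm lm pnorm pt quantile rexp rlnorm
#'   rnorm runif sd setNames complete.cases gaussian
#' @importFrom utils combn read.csv write.csv
NULL

# ---- dated_tree: a rooted, dated phylogeny with stable node ids -------------
#
# Wraps an ape "phylo" object. Internal nodes get stable integer ids assigned
# in deterministic preorder (root = 1), so results are reproducible across
# runs and the id -> clade mapping can be emitted alongside outputs.

#' Construct a dated tree with stable preorder node ids
#'
#' @param phy An object of class \code{phylo}: rooted, with branch lengths.
#' @return An object of class \code{dated_tree}: a list with elements
#'   \code{phy} (the cladewise-reordered \code{phylo}), \code{node_map}
#'   (data.frame mapping \code{node_id} to ape's internal node number and
#'   node age in Myr), and \code{tip_sets} (list of descendant tip labels per
#'   \code{node_id}).
#' @details Node ages are measured back from the most distant tip: age(node)
#'   = tree height minus root-to-node path length. On an ultrametric tree all
#'   tips have age 0; departures beyond a relative tolerance of 1e-6 of tree
#'   height raise a warning (ages remain defined as height minus depth).
#' @examples
#' tr <- as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' n_internal_nodes(tr)
#' @export
as_dated_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop("branch lengths must be nonnegative and non-missing")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (phy$Nnode < 1 || length(phy$tip.label) < 2)
    stop("tree must have at least 2 tips")
  n_children <- tabulate(phy$edge[, 1], nbins = length(phy$tip.label) + phy$Nnode)
  internal <- (length(phy$tip.label) + 1L):(length(phy$tip.label) + phy$Nnode)
  if (any(n_children[internal] < 2))
    stop("tree has internal nodes with a single child; collapse them first ",
         "(see ape::collapse.singles)")

  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  # preorder of internal nodes = first appearance as a parent in cladewise edges
  pre <- unique(phy$edge[, 1])
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(ntip)])
  tip_dev <- max(abs(depth[seq_len(ntip)] - height))
  if (height > 0 && tip_dev > 1e-6 * height)
    warning("tree is not ultrametric (max tip-depth deviation ",
            signif(tip_dev, 3), "); node 'ages' are height minus depth")

  tip_sets <- .clade_tip_sets(phy)
  node_map <- data.frame(
    node_id = seq_along(pre),
    ape_node = pre,
    age = height - depth[pre],
    n_tips = vapply(tip_sets[pre - ntip], length, integer(1))
  )
  structure(list(phy = phy, node_map = node_map,
                 tip_sets = setNames(tip_sets[pre - ntip],
                                     as.character(seq_along(pre))),
                 height = height),
            class = "dated_tree")
}

# descendant tip labels for every internal node, postorder accumulation;
# returned as a list indexed by (ape_node - ntip)
.clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  sets <- vector("list", phy$Nnode)
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1] - ntip
    ch <- edge[i, 2]
    add <- if (ch <= ntip) phy$tip.label[ch] else sets[[ch - ntip]]
    sets[[par]] <- c(sets[[par]], add)
  }
  sets
}

#' Read a dated tree from file
#'
#' @param path Path to a tree file.
#' @param format \code{"newick"} or \code{"nexus"}.
#' @return A \code{dated_tree}. If the file holds several trees an error is
#'   raised; use \code{\link{read_trees}} for posterior samples.
#' @export
read_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("file contains ", length(phy), " trees; use read_trees()")
    phy <- phy[[1L]]
  }
  if (is.null(phy)) stop("could not parse a tree from ", path)
  as_dated_tree(phy)
}

#' Read a multi-tree file (e.g. posterior samples), one tree per line
#'
#' @inheritParams read_tree
#' @return A list of \code{dated_tree} objects.
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (inherits(phy, "phylo")) phy <- list(phy)
  lapply(phy, as_dated_tree)
}

#' Write a dated tree to Newick
#'
#' @param tree A \code{dated_tree}.
#' @param path Output path.
#' @param annotations Optional data.frame with columns \code{node_id},
#'   \code{mean_nri}, \code{classification}; internal node labels are written
#'   as \code{"nodeID|meanNRI|class"}.
#' @export
write_tree <- function(tree, path, annotations = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phy
  if (!is.null(annotations)) {
    ntip <- length(phy$tip.label)
    lab <- rep("", phy$Nnode)
    idx <- match(tree$node_map$node_id, annotations$node_id)
    ann <- ifelse(is.na(idx), as.character(tree$node_map$node_id),
                  paste(annotations$node_id[idx],
                        signif(annotations$mean_nri[idx], 6),
                        annotations$classification[idx], sep = "|"))
    lab[tree$node_map$ape_node - ntip] <- ann
    phy$node.label <- lab
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree:", length(x$phy$tip.label), "tips,",
      nrow(x$node_map), "internal nodes, height",
      format(x$height, digits = 6), "Myr\n")
  invisible(x)
}

#' Number of internal nodes
#' @param tree A \code{dated_tree}.
#' @export
n_internal_nodes <- function(tree) nrow(tree$node_map)

#' Tip labels of a dated tree
#' @param tree A \code{dated_tree}.
#' @export
tip_labels <- function(tree) tree$phy$tip.label

#' Node ages (Myr before present) of all internal nodes
#'
#' @param tree A \code{dated_tree}.
#' @return Named numeric vector of ages, names = stable node ids; the root
#'   (id 1) carries the tree height and ages never increase from root to tip.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  setNames(tree$node_map$age, tree$node_map$node_id)
}

#' Patristic (cophenetic) distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips; on an
#' ultrametric tree d(i, j) = 2 x age of the most recent common ancestor.
#'
#' @param tree A \code{dated_tree}.
#' @param labels Optional subset of tip labels; defaults to all tips.
#' @return Symmetric numeric matrix (Myr) with zero diagonal.
#' @export
phylo_cophenetic <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  d <- ape::cophenetic.phylo(tree$phy)
  if (is.null(labels)) return(d)
  labels <- as.character(labels)
  miss <- setdiff(labels, rownames(d))
  if (length(miss))
    stop("unknown tip label(s): ", paste(miss, collapse = ", "))
  d[labels, labels, drop = FALSE]
}

#' Descendant tip labels of an internal node
#'
#' @param tree A \code{dated_tree}.
#' @param node_id Stable internal node id (1 = root).
#' @return Character vector of tip labels in the clade (length >= 2).
#' @export
subtree_tips <- function(tree, node_id) {
  stopifnot(inherits(tree, "dated_tree"))
  key <- as.character(node_id)
  if (length(node_id) != 1L || is.na(node_id) || !key %in% names(tree$tip_sets))
    stop("'node_id' must be an internal node id in 1..", nrow(tree$node_map))
  tree$tip_sets[[key]]
}

#' Drop tips (e.g. outgroups) by label
#'
#' @param tree A \code{dated_tree}.
#' @param drop Character vector of tip labels to remove.
#' @return A new \code{dated_tree}; node ids are reassigned by preorder on
#'   the pruned topology.
#' @export
prune_tips <- function(tree, drop) {
  stopifnot(inherits(tree, "dated_tree"))
  miss <- setdiff(drop, tree$phy$tip.label)
  if (length(miss))
    stop("cannot drop unknown tip(s): ", paste(miss, collapse = ", "))
  if (length(drop) >= length(tree$phy$tip.label) - 1L)
    stop("pruning would leave fewer than 2 tips")
  as_dated_tree(ape::drop.tip(tree$phy, drop, collapse.singles = TRUE))
}
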