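#' Dated rooted trees with branch annotations
#'
#' `treerug` represents a sampled phylodynamic tree as an [ape::phylo] object
#' of class `c("rooted_tree", "phylo")` carrying two extra components:
#'
#' * `node_height` — numeric of length `Ntip + Nnode`, the time of each node
#'   *before the most recently sampled tip* (the latest tip sits at height 0;
#'   heights increase towards the root). Branch durations are
#'   `height(parent) - height(child)` and are kept consistent with
#'   `edge.length` at all times.
#' * `edge_rate` — numeric of length `nrow(edge)`, the evolutionary rate
#'   annotation (substitutions/site/time unit) of the branch subtending each
#'   child node; `NA` where the tree log carried no rate annotation.
#'
#' `rooted_tree(phy, heights, rates)` upgrades a binary rooted `phylo`;
#' heights default to `node.depth.edgelength` re-expressed as time before the
#' latest tip.
#'
#' @param phy A rooted, binary [ape::phylo] object with edge lengths.
#' @param heights Optional numeric node heights (time before latest tip),
#'   indexed by ape node id. Derived from edge lengths when omitted.
#' @param rates Optional per-edge rate annotations aligned to `phy$edge` rows.
#' @return A `rooted_tree`.
#' @examples
#' tr <- rooted_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);"))
#' tree_table(tr)
#' @export
rooted_tree <- function(phy, heights = NULL, rates = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length) && is.null(heights)) {
    phy$edge.length <- rep(1, nrow(phy$edge))
  }
  if (is.null(heights)) {
    depth <- ape::node.depth.edgelength(phy)
    heights <- max(depth[seq_len(ape::Ntip(phy))]) - depth
  }
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  stopifnot(length(heights) == n_nodes)
  if (is.null(rates)) {
    rates <- phy$edge_rate %||% rep(NA_real_, nrow(phy$edge))
  }
  stopifnot(length(rates) == nrow(phy$edge))
  phy$node_height <- as.numeric(heights)
  phy$edge_rate <- as.numeric(rates)
  phy$edge.length <- heights[phy$edge[, 1]] - heights[phy$edge[, 2]]
  class(phy) <- unique(c("rooted_tree", class(phy)))
  validate_rooted_tree(phy)
}

validate_rooted_tree <- function(tree) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels in tree", call. = FALSE)
  }
  kids <- tabulate(edge[, 1], nbins = n_tip + tree$Nnode)
  if (any(kids[seq_len(n_tip)] > 0)) stop("tip with children", call. = FALSE)
  if (any(kids[-seq_len(n_tip)] < 2)) {
    stop("internal node with fewer than two children", call. = FALSE)
  }
  dur <- tree$node_height[edge[, 1]] - tree$node_height[edge[, 2]]
  if (any(dur < -1e-9)) {
    stop("parent height below child height", call. = FALSE)
  }
  tree
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf(
    "Dated rooted tree: %d tips, root height %.4g, %s rate annotations\n",
    length(x$tip.label), x$node_height[root_node(x)],
    if (all(is.na(x$edge_rate))) "no" else "with"
  ))
  invisible(x)
}

root_node <- function(tree) length(tree$tip.label) + 1L

n_tips <- function(tree) length(tree$tip.label)

tip_id <- function(tree, label) {
  id <- match(label, tree$tip.label)
  if (anyNA(id)) {
    stop("unknown tip label(s): ", paste(label[is.na(id)], collapse = ", "),
         call. = FALSE)
  }
  id
}

#' Tabular view of a rooted tree
#'
#' One row per node: ape node id, parent id (`NA` at the root), node height
#' (time before the latest tip), the rate annotation on the subtending branch
#' and the tip label (`NA` for internal nodes). `tree_from_table()` inverts it,
#' renumbering nodes to ape conventions, so tree surgery can be done on the
#' table.
#'
#' @param tree A `rooted_tree`.
#' @return A tibble with columns `node`, `parent`, `height`, `rate`, `label`.
#' @export
tree_table <- function(tree) {
  edge <- tree$edge
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[edge[, 2]] <- edge[, 1]
  rate <- rep(NA_real_, n)
  rate[edge[, 2]] <- tree$edge_rate
  tibble::tibble(
    node = seq_len(n),
    parent = parent,
    height = tree$node_height,
    rate = rate,
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode))
  )
}

#' @rdname tree_table
#' @param tab A node table as produced by `tree_table()`; `node` ids may be
#'   arbitrary unique integers as long as `parent` references them.
#' @export
tree_from_table <- function(tab) {
  stopifnot(all(c("node", "parent", "height", "label") %in% names(tab)))
  if (is.null(tab$rate)) tab$rate <- NA_real_
  if (anyDuplicated(tab$node)) stop("duplicated node ids", call. = FALSE)
  idx <- match(tab$parent, tab$node)
  if (any(is.na(idx) & !is.na(tab$parent))) {
    stop("parent id not present in table", call. = FALSE)
  }
  is_tip <- !is.na(tab$label)
  n_tip <- sum(is_tip)
  n_all <- nrow(tab)
  if (n_tip < 2L) stop("tree needs at least two tips", call. = FALSE)
  root_row <- which(is.na(tab$parent))
  if (length(root_row) != 1L) stop("tree must have exactly one root", call. = FALSE)

  children <- split(seq_len(n_all), factor(idx, levels = seq_len(n_all)))
  # preorder over rows
  order_rows <- integer(n_all)
  stack <- root_row
  k <- 0L
  while (length(stack)) {
    row <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_rows[k] <- row
    ch <- children[[row]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  if (k != n_all) stop("table is not a connected tree", call. = FALSE)

  new_id <- integer(n_all)
  new_id[which(is_tip)[order(match(which(is_tip), order_rows))]] <- seq_len(n_tip)
  internals <- order_rows[!order_rows %in% which(is_tip)]
  new_id[internals] <- n_tip + seq_along(internals)

  edge_rows <- order_rows[order_rows != root_row]
  edge <- cbind(new_id[idx[edge_rows]], new_id[edge_rows])
  heights <- numeric(n_all)
  heights[new_id] <- tab$height
  labels <- character(n_tip)
  labels[new_id[is_tip]] <- tab$label[is_tip]
  phy <- structure(
    list(
      edge = edge,
      edge.length = heights[edge[, 1]] - heights[edge[, 2]],
      Nnode = n_all - n_tip,
      tip.label = labels
    ),
    class = "phylo", order = "cladewise"
  )
  rooted_tree(phy, heights = heights, rates = tab$rate[edge_rows])
}

#' Build a caterpillar (pectinate) dated tree
#'
#' Convenience constructor used throughout for valley-geometry fixtures: tip
#' `labels[1]` and `labels[2]` form the deepest cherry and each further tip
#' attaches one node closer to the root. All tips are contemporaneous
#' (height 0); internal nodes are evenly spaced.
#'
#' @param labels Character vector of tip labels (>= 3).
#' @param step Height increment between successive internal nodes.
#' @return A `rooted_tree`.
#' @export
caterpillar_tree <- function(labels, step = 1) {
  n <- length(labels)
  stopifnot(n >= 3)
  txt <- paste0("(", labels[1], ",", labels[2], ")")
  for (i in 3:n) txt <- paste0("(", txt, ",", labels[i], ")")
  phy <- ape::read.tree(text = paste0(txt, ";"))
  heights <- numeric(ape::Ntip(phy) + phy$Nnode)
  for (nd in (n + 1):(n + phy$Nnode)) {
    heights[nd] <- step * max_tip_dist(phy, nd)
  }
  rooted_tree(phy, heights = heights)
}

max_tip_dist <- function(phy, node) {
  # number of edges from node down to its deepest descendant tip
  n_tip <- ape::Ntip(phy)
  desc <- function(nd) {
    ch <- phy$edge[phy$edge[, 1] == nd, 2]
    if (!length(ch)) return(0L)
    1L + max(vapply(ch, desc, integer(1)))
  }
  desc(node)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
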