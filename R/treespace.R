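# Tree-space geometry: rooted RF distances, tip-relocation (SPR) moves and
# their NNI decompositions (the valley-crossing paths), exact small-instance
# rSPR distance by bidirectional BFS, topology classification, classical MDS
# and posterior-density landscape overlays.

#' Rooted Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' nontrivial rooted clade
#' sets (clades, not unrooted splits).
#'
#' @param t1,t2 Rooted trees on the same taxon set.
#' @return Integer distance.
#' @examples
#' a <- rooted_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' b <- rooted_tree(ape::read.tree(text = "(A:2,(B:1,C:1):1);"))
#' rf_rooted(a, b) # 2
#' @export
rf_rooted <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) {
    abort("trees have different taxon sets")
  }
  c1 <- extract_clades(t1)
  c2 <- extract_clades(t2)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}

#' Pairwise distance matrix over sampled trees
#'
#' @param traces A `tree_trace` or list of them (shared taxon set).
#' @param metric `"rf"` (rooted RF) or `"rspr_small"` (exact rSPR, <= 10 tips).
#' @param max_samples Cap on total samples; when exceeded, each chain is
#'   subsampled at a deterministic even stride.
#' @return A `tree_dist`: list with `matrix` (symmetric, zero diagonal),
#'   `meta` (tibble: chain, index, iteration, density) and `metric`.
#' @export
distance_matrix <- function(traces, metric = c("rf", "rspr_small"),
                            max_samples = 500) {
  metric <- match.arg(metric)
  traces <- as_trace_list(traces)
  total <- sum(vapply(traces, n_samples, integer(1)))
  kept <- lapply(traces, function(tr) {
    n <- n_samples(tr)
    quota <- max(1L, floor(max_samples * n / total))
    if (total <= max_samples) seq_len(n) else unique(round(seq(1, n, length.out = quota)))
  })
  trees <- list()
  meta <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    trees <- c(trees, tr$trees[kept[[i]]])
    meta[[i]] <- tibble::tibble(
      chain = tr$chain_id, index = kept[[i]],
      iteration = tr$iterations[kept[[i]]],
      density = if (is.null(tr$density)) NA_real_ else tr$density[kept[[i]]]
    )
  }
  meta <- dplyr::bind_rows(meta)
  n <- length(trees)
  if (metric == "rspr_small" && length(traces[[1]]$taxa) > 10) {
    abort("rspr_small supports at most 10 tips; use metric = 'rf'")
  }
  d <- matrix(0, n, n)
  if (metric == "rf") {
    keys <- lapply(trees, extract_clades)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <-
          length(setdiff(keys[[i]], keys[[j]])) +
          length(setdiff(keys[[j]], keys[[i]]))
      }
    }
  } else {
    topo <- vapply(trees, topology_key, character(1))
    uniq <- unique(topo)
    utrees <- trees[match(uniq, topo)]
    ud <- matrix(0, length(uniq), length(uniq))
    for (i in seq_along(uniq)) {
      for (j in seq_along(uniq)) {
        if (j > i) ud[i, j] <- ud[j, i] <- rspr_distance_small(utrees[[i]], utrees[[j]])
      }
    }
    idx <- match(topo, uniq)
    d <- ud[idx, idx]
  }
  structure(list(matrix = d, meta = meta, metric = metric),
            class = "tree_dist")
}

#' @export
print.tree_dist <- function(x, ...) {
  cat(sprintf("Tree distance matrix (%s): %d samples\n", x$metric,
              nrow(x$matrix)))
  invisible(x)
}

# ---- tip relocation --------------------------------------------------------

detach_tip <- function(tab, tip) {
  # removes the tip and suppresses its parent; returns list(tab, tip_row)
  t_row <- which(tab$label == tip)
  if (!length(t_row)) abort(sprintf("unknown tip '%s'", tip))
  p <- tab$parent[t_row]
  sibs <- setdiff(tab$node[!is.na(tab$parent) & tab$parent == p], tab$node[t_row])
  if (length(sibs) != 1) abort("tip's parent is not binary")
  g <- tab$parent[tab$node == p]
  tip_row <- tab[t_row, ]
  s_row <- which(tab$node == sibs)
  if (!is.na(g)) {
    d1 <- tab$height[tab$node == p] - tab$height[s_row] # p -> sib
    d2 <- tab$height[tab$node == g] - tab$height[tab$node == p] # g -> p
    r1 <- tab$rate[s_row]; r2 <- tab$rate[tab$node == p]
    tab$rate[s_row] <- if (is.na(r1) || is.na(r2)) {
      NA_real_
    } else if (d1 + d2 > 0) (r1 * d1 + r2 * d2) / (d1 + d2) else mean(c(r1, r2))
    tab$parent[s_row] <- g
  } else {
    tab$parent[s_row] <- NA_integer_
    tab$rate[s_row] <- NA_real_
  }
  tab <- tab[-c(t_row, which(tab$node == p)), ]
  list(tab = tab, tip_row = tip_row, old_sib = sibs)
}

below_sets <- function(tab) {
  # list of sorted tip-label vectors keyed by node id (as character)
  kids <- split(tab$node, factor(tab$parent, levels = tab$node))
  out <- list()
  fill <- function(nd) {
    ch <- kids[[as.character(nd)]]
    labs <- if (length(ch)) {
      sort(unlist(lapply(ch, fill)))
    } else tab$label[tab$node == nd]
    out[[as.character(nd)]] <<- labs
    labs
  }
  fill(tab$node[is.na(tab$parent)])
  out
}

find_dest_node <- function(tab, dest) {
  sets <- below_sets(tab)
  key <- paste(sort(dest), collapse = "|")
  hits <- names(sets)[vapply(sets, function(x) paste(x, collapse = "|") == key,
                             logical(1))]
  if (!length(hits)) {
    abort("destination clade not found in the tree without the focal tip")
  }
  as.integer(hits[1])
}

#' Relocate a tip onto another branch (a single rooted SPR move)
#'
#' The tip's pendant edge is pruned (its old parent suppressed, merged-branch
#' rate = duration-weighted mean) and regrafted onto the destination branch,
#' identified by the set of tip labels below it *in the tree without the
#' focal tip*. The new attachment node sits at the midpoint of the feasible
#' height interval; all other node heights are untouched.
#'
#' @param tree A `rooted_tree`.
#' @param tip Tip label to relocate.
#' @param dest Character vector of tip labels: the clade below the
#'   destination branch (excluding `tip`).
#' @return A `rooted_tree` differing from the input by one SPR move.
#' @export
relocate_tip <- function(tree, tip, dest) {
  det <- detach_tip(tree_table(tree), tip)
  tab <- det$tab
  v <- find_dest_node(tab, setdiff(dest, tip))
  if (v == det$old_sib) abort("destination equals the tip's current attachment")
  u <- tab$parent[tab$node == v]
  if (is.na(u)) abort("cannot attach above the root: no destination branch")
  h_v <- tab$height[tab$node == v]
  h_u <- tab$height[tab$node == u]
  h_t <- det$tip_row$height
  lo <- max(h_t, h_v)
  if (h_u <= lo) {
    abort(sprintf("infeasible relocation: tip height %.4g not below branch top %.4g",
                  h_t, h_u))
  }
  q_id <- max(tab$node, det$tip_row$node) + 1L
  v_rate <- tab$rate[tab$node == v]
  tab$parent[tab$node == v] <- q_id
  new_rows <- tibble::tibble(
    node = c(q_id, det$tip_row$node),
    parent = c(u, q_id),
    height = c((lo + h_u) / 2, h_t),
    rate = c(v_rate, det$tip_row$rate),
    label = c(NA_character_, det$tip_row$label)
  )
  tree_from_table(dplyr::bind_rows(tab, new_rows))
}

#' NNI decomposition of a tip relocation
#'
#' Returns the sequence of trees along the minimal NNI path realizing
#' `relocate_tip(tree, tip, dest)`: the tip's attachment point slides across
#' one internal node per step, so consecutive trees differ by one rooted NNI
#' (rooted RF distance 2), and the path has exactly k moves where k is the
#' number of internal nodes strictly between the old and new attachment
#' points.
#'
#' @inheritParams relocate_tip
#' @return List of `rooted_tree`s of length k + 1, starting at `tree`; the
#'   last element has the topology of `relocate_tip(tree, tip, dest)`.
#' @export
nni_path_tip_relocation <- function(tree, tip, dest) {
  det <- detach_tip(tree_table(tree), tip)
  tab <- det$tab
  sets <- below_sets(tab)
  # attachment edges are identified by their child node in the pruned tree
  old_sib <- old_attachment_node(tree, tip, tab)
  v_dest <- find_dest_node(tab, setdiff(dest, tip))
  if (old_sib == v_dest) abort("destination equals the current attachment")
  path <- edge_path(tab, old_sib, v_dest)
  out <- list(tree)
  current <- tree
  for (nd in path[-1]) {
    current <- relocate_tip(current, tip, sets[[as.character(nd)]])
    out <- c(out, list(current))
  }
  out
}

old_attachment_node <- function(tree, tip, pruned_tab) {
  # child node (in the pruned tree) of the edge the tip was attached to
  tab <- tree_table(tree)
  t_row <- which(tab$label == tip)
  p <- tab$parent[t_row]
  sib <- setdiff(tab$node[!is.na(tab$parent) & tab$parent == p], tab$node[t_row])
  sets <- below_sets(pruned_tab)
  sib_tips <- below_sets(tab)[[as.character(sib)]]
  find_dest_node(pruned_tab, sib_tips)
}

edge_bfs <- function(tab, from) {
  # BFS over the edge-adjacency graph: edges e(c) indexed by child node c;
  # e(c1) ~ e(c2) iff the edges share an endpoint (parent/child or siblings)
  nodes <- tab$node[!is.na(tab$parent)]
  adj <- function(c1) {
    p1 <- tab$parent[tab$node == c1]
    kids <- tab$node[!is.na(tab$parent) & tab$parent == c1]
    if (is.na(p1)) return(kids) # root as pseudo-edge: only its child edges
    sibs <- setdiff(tab$node[!is.na(tab$parent) & tab$parent == p1], c1)
    gp <- tab$parent[tab$node == p1]
    up <- if (!is.na(gp)) p1 else integer()
    c(sibs, kids, up)
  }
  key <- as.character(nodes)
  prev <- setNames(rep(NA_integer_, length(nodes)), key)
  dist <- setNames(rep(NA_integer_, length(nodes)), key)
  dist[as.character(from)] <- 0L
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj(cur)) {
      nk <- as.character(nb)
      if (is.na(dist[nk])) {
        dist[nk] <- dist[as.character(cur)] + 1L
        prev[nk] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  list(dist = dist, prev = prev)
}

edge_path <- function(tab, from, to) {
  bfs <- edge_bfs(tab, from)
  path <- to
  while (path[1] != from) path <- c(bfs$prev[[as.character(path[1])]], path)
  path
}

# ---- exact small-instance rSPR --------------------------------------------

strip_topology <- function(tree) {
  # unit-spaced heights; topology only
  tab <- tree_table(tree)
  phy <- tree_from_table(tab)
  h <- numeric(length(phy$tip.label) + phy$Nnode)
  for (nd in seq_along(h)) h[nd] <- max_tip_dist(phy, nd)
  rooted_tree(phy, heights = h, rates = rep(NA_real_, nrow(phy$edge)))
}

all_spr_neighbor_keys <- function(tree) {
  # canonical topology keys of every tree one rooted SPR away
  tab <- tree_table(tree)
  tips <- tab$label[!is.na(tab$label)]
  root <- tab$node[is.na(tab$parent)]
  sets <- below_sets(tab)
  out <- new.env(parent = emptyenv())
  for (s in tab$node[tab$node != root]) {
    s_set <- sets[[as.character(s)]]
    sub <- prune_subtree(tab, s)
    if (is.null(sub)) next
    rem <- sub$tab
    rem_sets <- below_sets(rem)
    rem_root <- rem$node[is.na(rem$parent)]
    for (v in rem$node) {
      if (v == rem_root) {
        # regraft above the root
        key <- regraft_key(rem, sub, v, above_root = TRUE)
      } else {
        key <- regraft_key(rem, sub, v, above_root = FALSE)
      }
      if (!is.null(key)) assign(key, TRUE, envir = out)
    }
  }
  ls(out)
}

prune_subtree <- function(tab, s) {
  # removes subtree rooted at s and suppresses the freed node
  desc <- subtree_nodes(tab, s)
  if (length(desc) == nrow(tab)) return(NULL)
  p <- tab$parent[tab$node == s]
  sibs <- setdiff(tab$node[!is.na(tab$parent) & tab$parent == p], s)
  if (length(sibs) != 1) return(NULL)
  g <- tab$parent[tab$node == p]
  rem <- tab[!tab$node %in% c(desc, p), ]
  rem$parent[rem$node == sibs] <- g
  if (nrow(rem) < 1) return(NULL)
  list(tab = rem, sub = tab[tab$node %in% desc, ], s = s, old_sib = sibs)
}

subtree_nodes <- function(tab, s) {
  out <- s
  frontier <- s
  while (length(frontier)) {
    kids <- tab$node[!is.na(tab$parent) & tab$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

regraft_key <- function(rem, sub, v, above_root = FALSE) {
  q <- max(rem$node, sub$sub$node) + 1L
  subtab <- sub$sub
  subtab$parent[subtab$node == sub$s] <- q
  if (above_root) {
    old_root <- rem$node[is.na(rem$parent)]
    rem$parent[rem$node == old_root] <- q
    new_row <- tibble::tibble(node = q, parent = NA_integer_, height = 0,
                              rate = NA_real_, label = NA_character_)
  } else {
    u <- rem$parent[rem$node == v]
    rem$parent[rem$node == v] <- q
    new_row <- tibble::tibble(node = q, parent = u, height = 0,
                              rate = NA_real_, label = NA_character_)
  }
  tab <- dplyr::bind_rows(rem, new_row, subtab)
  table_topology_key(tab)
}

table_topology_key <- function(tab) {
  sets <- below_sets(tab)
  root <- as.character(tab$node[is.na(tab$parent)])
  tips <- tab$node[!is.na(tab$label)]
  keys <- vapply(setdiff(names(sets), root), function(nm) {
    paste(sets[[nm]], collapse = "|")
  }, character(1))
  keys <- keys[!keys %in% tab$label] # drop singletons
  paste(sort(keys), collapse = ";")
}

key_to_tree <- function(key, taxa) {
  # rebuild a rooted_tree from a topology key (set of clade keys)
  clades <- if (nzchar(key)) strsplit(key, ";", fixed = TRUE)[[1]] else character()
  groups <- c(lapply(clades, clade_tips), list(taxa))
  groups <- groups[order(lengths(groups))]
  build <- function(labs) {
    inner <- Filter(function(g) length(g) < length(labs) &&
                      all(g %in% labs), groups)
    maximal <- Filter(function(g) {
      !any(vapply(inner, function(h) length(h) > length(g) && all(g %in% h),
                  logical(1)))
    }, inner)
    used <- unlist(maximal)
    parts <- c(maximal, as.list(setdiff(labs, used)))
    if (length(parts) == 1) return(build(parts[[1]]))
    paste0("(", paste(vapply(parts, function(p) {
      if (length(p) == 1) p else build(p)
    }, character(1)), collapse = ","), ")")
  }
  phy <- ape::read.tree(text = paste0(build(taxa), ";"))
  strip_topology(rooted_tree(phy, heights = NULL,
                             rates = rep(NA_real_, nrow(phy$edge))))
}

#' Exact rooted SPR distance for small trees
#'
#' Bidirectional breadth-first search over rooted topology classes; supports
#' up to 10 tips.
#'
#' @param t1,t2 Rooted trees on the same taxon set (<= 10 tips).
#' @return Integer minimum number of rooted SPR moves.
#' @export
rspr_distance_small <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) {
    abort("trees have different taxon sets")
  }
  if (length(t1$tip.label) > 10) {
    abort("rspr_distance_small supports at most 10 tips")
  }
  taxa <- sort(t1$tip.label)
  k1 <- topology_key(strip_topology(t1))
  k2 <- topology_key(strip_topology(t2))
  if (k1 == k2) return(0L)
  front_a <- k1; front_b <- k2
  seen_a <- setNames(0L, k1); seen_b <- setNames(0L, k2)
  dist_a <- 0L; dist_b <- 0L
  repeat {
    # expand the smaller frontier
    if (length(front_a) <= length(front_b)) {
      dist_a <- dist_a + 1L
      nxt <- character()
      for (key in front_a) {
        nbs <- all_spr_neighbor_keys(key_to_tree(key, taxa))
        for (nb in nbs) {
          if (nb %in% names(seen_b)) return(dist_a + seen_b[[nb]])
          if (!nb %in% names(seen_a)) {
            seen_a[nb] <- dist_a
            nxt <- c(nxt, nb)
          }
        }
      }
      front_a <- nxt
    } else {
      dist_b <- dist_b + 1L
      nxt <- character()
      for (key in front_b) {
        nbs <- all_spr_neighbor_keys(key_to_tree(key, taxa))
        for (nb in nbs) {
          if (nb %in% names(seen_a)) return(dist_b + seen_a[[nb]])
          if (!nb %in% names(seen_b)) {
            seen_b[nb] <- dist_b
            nxt <- c(nxt, nb)
          }
        }
      }
      front_b <- nxt
    }
    if (!length(front_a) && !length(front_b)) {
      abort("search exhausted without meeting; trees not connected?")
    }
    if (dist_a + dist_b > 12) abort("rSPR search exceeded depth 12")
  }
}

# ---- topology classes ------------------------------------------------------

#' Classify sampled trees into topology classes
#'
#' @param traces A `tree_trace` or list of them.
#' @return A tibble: `topology` (clade-set key), one `n_<chain>` count column
#'   per chain, `total`, and `representative` (list-column holding the first
#'   sampled tree of each class). Counts partition the samples.
#' @export
topology_classes <- function(traces) {
  traces <- as_trace_list(traces)
  keys <- lapply(traces, function(tr) {
    vapply(tr$trees, topology_key, character(1))
  })
  all_keys <- unique(unlist(keys))
  counts <- vapply(keys, function(k) {
    vapply(all_keys, function(key) sum(k == key), integer(1))
  }, integer(length(all_keys)))
  counts <- matrix(counts, nrow = length(all_keys))
  reps <- lapply(all_keys, function(key) {
    for (i in seq_along(traces)) {
      hit <- which(keys[[i]] == key)
      if (length(hit)) return(traces[[i]]$trees[[hit[1]]])
    }
  })
  out <- tibble::tibble(topology = all_keys)
  ids <- vapply(traces, function(x) x$chain_id, character(1))
  for (i in seq_along(ids)) out[[paste0("n_", ids[i])]] <- counts[, i]
  out$total <- rowSums(counts)
  out$representative <- reps
  dplyr::arrange(out, dplyr::desc(total))
}

# ---- MDS -------------------------------------------------------------------

#' Classical (metric) multidimensional scaling of tree space
#'
#' Double-centers the squared distance matrix, eigendecomposes, and scales the
#' top eigenvectors by the square roots of their (nonnegative-truncated)
#' eigenvalues. Exact on Euclidean input.
#'
#' @param dist A `tree_dist` or a plain symmetric matrix.
#' @param dims 2 or 3 output dimensions.
#' @return An `mds_embedding`: tibble with `axis1..axisK` plus the sample
#'   metadata; attributes `eigenvalues` (all, sorted descending) and `stress`.
#' @export
classical_mds <- function(dist, dims = 2) {
  stopifnot(dims %in% 2:3)
  d <- if (inherits(dist, "tree_dist")) dist$matrix else as.matrix(dist)
  meta <- if (inherits(dist, "tree_dist")) dist$meta else
    tibble::tibble(chain = "all", index = seq_len(nrow(d)),
                   iteration = seq_len(nrow(d)), density = NA_real_)
  n <- nrow(d)
  stopifnot(dims <= n - 1)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- eg$values
  pos <- pmax(lambda[seq_len(dims)], 0)
  coords <- eg$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(pos), dims)
  fitted <- as.matrix(stats::dist(coords))
  denom <- sum(d^2)
  stress <- if (denom > 0) sqrt(sum((d - fitted)^2) / denom) else 0
  out <- meta
  for (k in seq_len(dims)) out[[paste0("axis", k)]] <- coords[, k]
  attr(out, "eigenvalues") <- lambda
  attr(out, "stress") <- stress
  class(out) <- c("mds_embedding", class(out))
  out
}

#' Posterior-density overlays on an MDS embedding
#'
#' @param embedding An `mds_embedding` (or tibble with `axis1`, `axis2`).
#' @param density Per-sample density values aligned to the embedding rows;
#'   defaults to the embedding's own `density` column.
#' @param mode `"heatmap"` (mean density per grid cell), `"top_fraction"`
#'   (keep the highest-density fraction `f` of samples) or `"scatter3d"`
#'   (density as a z coordinate).
#' @param bins Grid resolution per axis for the heatmap.
#' @param f Retained fraction for `top_fraction`.
#' @return A tibble whose shape depends on `mode`.
#' @export
landscape_overlay <- function(embedding, density = NULL,
                              mode = c("heatmap", "top_fraction", "scatter3d"),
                              bins = 50, f = 0.01) {
  mode <- match.arg(mode)
  density <- density %||% embedding$density
  if (length(density) != nrow(embedding)) {
    abort("density length does not match the number of embedded samples")
  }
  x <- embedding$axis1
  y <- embedding$axis2
  if (mode == "heatmap") {
    bx <- cut_index(x, bins)
    by <- cut_index(y, bins)
    df <- tibble::tibble(cell_x = bx, cell_y = by, density = density)
    return(dplyr::summarise(dplyr::group_by(df, cell_x, cell_y),
                            mean_density = mean(density), n = dplyr::n(),
                            .groups = "drop"))
  }
  if (mode == "top_fraction") {
    keep <- ceiling(f * nrow(embedding))
    ord <- order(density, decreasing = TRUE)
    out <- tibble::as_tibble(embedding)[sort(ord[seq_len(keep)]), ]
    return(out)
  }
  tibble::tibble(x = x, y = y, z = density,
                 chain = embedding$chain)
}

cut_index <- function(x, bins) {
  if (diff(range(x)) == 0) return(rep(1L, length(x)))
  pmin(bins, 1L + floor((x - min(x)) / diff(range(x)) * bins))
}

#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, color = "chain", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = axis1, y = axis2,
                                       color = .data[[color]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2") +
    ggplot2::theme_minimal()
}

#' Score profile along a tree path
#'
#' Aligns a per-tree score (posterior density, parsimony, ...) with an
#' ordered tree path, e.g. an NNI valley-crossing path.
#'
#' @param trees List of trees (ordered path).
#' @param scores Numeric scores aligned to `trees`.
#' @return Tibble: `step` (0-based), `topology`, `score`.
#' @export
path_profile <- function(trees, scores) {
  stopifnot(length(trees) == length(scores))
  tibble::tibble(
    step = seq_along(trees) - 1L,
    topology = vapply(trees, topology_key, character(1)),
    score = as.numeric(scores)
  )
}
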