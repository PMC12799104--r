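# Shared fixtures and independent oracles. The oracles deliberately use
# different algorithms from the package internals: exhaustive enumeration for
# parsimony, unit-cost Sankoff dynamic programming for dispersal counts, and
# direct construction for tree-space geometry.

rt <- function(text) rooted_tree(ape::read.tree(text = text))

# alignment from named sequence strings
aln_of <- function(...) read_alignment(seqs = c(...))

bits_of <- function(chr) {
  map <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L, W = 9L,
           K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
           `-` = 15L, `?` = 15L)
  unname(map[chr])
}

# exhaustive parsimony: minimize changes over every assignment of concrete
# states to internal nodes; a pendant edge costs 0 iff the parent state is a
# member of the tip's state set
brute_force_parsimony_site <- function(tree, tip_bits, n_states = 4) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edge <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(seq_len(n_states)), n_int)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_int <- combos[r, ]
    state_of <- function(nd) assign_int[nd - n_tip]
    cost <- 0
    for (i in seq_len(nrow(edge))) {
      p <- state_of(edge[i, 1])
      ch <- edge[i, 2]
      if (ch <= n_tip) {
        if (bitwAnd(bitwShiftL(1L, p - 1L), tip_bits[ch]) == 0L) cost <- cost + 1
      } else {
        if (p != state_of(ch)) cost <- cost + 1
      }
    }
    best <- min(best, cost)
  }
  best
}

brute_force_parsimony <- function(tree, alignment) {
  bits <- alignment[match(tree$tip.label, rownames(alignment)), , drop = FALSE]
  sum(vapply(seq_len(ncol(bits)), function(j) {
    brute_force_parsimony_site(tree, bits[, j])
  }, numeric(1)))
}

# unit-cost Sankoff DP for a discrete character: exact minimum change count
sankoff_min_changes <- function(tree, tip_state_idx, n_states) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  cost <- matrix(Inf, n_all, n_states)
  for (i in seq_len(n_tip)) cost[i, tip_state_idx[[i]]] <- 0
  edge <- tree$edge
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    if (!done[p]) {
      cost[p, ] <- 0
      done[p] <- TRUE
    }
    trans <- vapply(seq_len(n_states), function(s) {
      min(cost[ch, ] + (seq_len(n_states) != s))
    }, numeric(1))
    cost[p, ] <- cost[p, ] + trans
  }
  min(cost[n_tip + 1L, ])
}

# all rooted binary topologies on a label set (1, 3, 15, 105, 945 ... trees)
all_rooted_topologies <- function(labels) {
  if (length(labels) == 1) return(labels)
  if (length(labels) == 2) return(paste0("(", labels[1], ",", labels[2], ")"))
  smaller <- all_rooted_topologies(labels[-length(labels)])
  new_lab <- labels[length(labels)]
  unlist(lapply(smaller, function(s) {
    positions <- attach_positions(s)
    vapply(positions, function(p) {
      paste0(substr(s, 1, p$start - 1),
             "(", p$sub, ",", new_lab, ")",
             substr(s, p$end + 1, nchar(s)))
    }, character(1))
  }))
}

# every subtree substring of a newick-without-lengths string, plus the whole
attach_positions <- function(s) {
  out <- list()
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  i <- 1
  while (i <= n) {
    if (chars[i] == "(") {
      depth <- 0
      for (j in i:n) {
        if (chars[j] == "(") depth <- depth + 1
        if (chars[j] == ")") depth <- depth - 1
        if (depth == 0) break
      }
      out[[length(out) + 1]] <- list(start = i, end = j,
                                     sub = substr(s, i, j))
      i <- i + 1
    } else if (grepl("[A-Za-z0-9_]", chars[i])) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1
      out[[length(out) + 1]] <- list(start = i, end = j - 1,
                                     sub = substr(s, i, j - 1))
      i <- j
    } else i <- i + 1
  }
  out
}

as_rooted <- function(newick_no_lengths) {
  rooted_tree(ape::read.tree(text = paste0(newick_no_lengths, ";")))
}

# random dated rooted tree (contemporaneous tips)
rand_tree <- function(n, seed) {
  simulate_time_tree(n, Ne = 2, seed = seed,
                     labels = sprintf("x%02d", seq_len(n)))
}

# random alignment with occasional ambiguity/missing characters
rand_alignment <- function(labels, n_sites, seed, p_ambig = 0.05) {
  set.seed(seed)
  chars <- c("A", "C", "G", "T")
  ambig <- c("R", "Y", "N", "-")
  seqs <- vapply(labels, function(l) {
    s <- sample(chars, n_sites, replace = TRUE)
    amb <- runif(n_sites) < p_ambig
    s[amb] <- sample(ambig, sum(amb), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  read_alignment(seqs = seqs)
}

# a two-chain, two-peak stuck study used across tests
stuck_study <- function(seed = 4, n_taxa = 15, n_samples = 40, k = 6,
                        n_sites = 200) {
  synthetic_study(n_taxa = n_taxa, n_wobblers = 1, k = k, n_chains = 2,
                  n_samples = n_samples, stay_prob = 1, n_sites = n_sites,
                  seed = seed)
}

# unrooted bipartition (as a canonical string) of the edge the fit rooted on
edge_bipartition <- function(phy, edge_row) {
  n_tip <- ape::Ntip(phy)
  below <- vector("list", n_tip + phy$Nnode)
  below[seq_len(n_tip)] <- as.list(phy$tip.label)
  for (i in rev(seq_len(nrow(phy$edge)))) {
    below[[phy$edge[i, 1]]] <- c(below[[phy$edge[i, 1]]],
                                 below[[phy$edge[i, 2]]])
  }
  side <- sort(below[[phy$edge[edge_row, 2]]])
  other <- sort(setdiff(phy$tip.label, side))
  paste(min(paste(side, collapse = "|"), paste(other, collapse = "|")),
        max(paste(side, collapse = "|"), paste(other, collapse = "|")),
        sep = " vs ")
}

root_bipartition <- function(phy) {
  # bipartition of the (unrooted) edge spanning the root of a rooted tree
  root_child <- phy$edge[phy$edge[, 1] == ape::Ntip(phy) + 1L, 2][1]
  edge_bipartition(phy, which(phy$edge[, 2] == root_child))
}
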