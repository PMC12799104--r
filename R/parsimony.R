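# Fitch parsimony on IUPAC state sets, the model-independent tree diagnostic:
# the minimum number of mutations an alignment requires on a topology is
# determined solely by the topology, so its trace across posterior samples is
# immune to noise in continuous-parameter sampling.

lowbit <- function(x) bitwAnd(x, bitwNot(x - 1L))

tip_state_matrix <- function(tree, alignment) {
  rows <- match(tree$tip.label, rownames(alignment))
  if (anyNA(rows)) {
    abort(paste0("tips missing from alignment: ",
                 paste(tree$tip.label[is.na(rows)], collapse = ", ")))
  }
  alignment[rows, , drop = FALSE]
}

# bottom-up pass; returns preliminary state-set matrix (nodes x sites) and
# per-site union-event counts
fitch_up <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  n_sites <- ncol(tip_states)
  prelim <- matrix(0L, n_all, n_sites)
  prelim[seq_len(n_tip), ] <- tip_states
  events <- numeric(n_sites)
  edge <- tree$edge
  seen <- logical(n_all)
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    if (!seen[p]) {
      prelim[p, ] <- prelim[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(prelim[p, ], prelim[ch, ])
      empty <- inter == 0L
      events <- events + empty
      prelim[p, ] <- ifelse(empty, bitwOr(prelim[p, ], prelim[ch, ]), inter)
    }
  }
  list(prelim = prelim, events = events)
}

# deterministic top-down resolution of one most-parsimonious reconstruction:
# root takes the lexicographically smallest member of its preliminary set;
# every child keeps the parent's state when compatible, else takes its own
# smallest member. Realizes exactly the Fitch minimum.
fitch_resolve <- function(tree, prelim) {
  n_all <- nrow(prelim)
  final <- matrix(0L, n_all, ncol(prelim))
  root <- root_node(tree)
  final[root, ] <- lowbit(prelim[root, ])
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) { # cladewise = parents before children
    p <- edge[i, 1]; ch <- edge[i, 2]
    keep <- bitwAnd(prelim[ch, ], final[p, ]) != 0L
    final[ch, ] <- ifelse(keep, final[p, ], lowbit(prelim[ch, ]))
  }
  final
}

#' Fitch parsimony score of an alignment on a tree
#'
#' Per-site bottom-up Fitch count over IUPAC state sets; fully missing sites
#' (`-`, `?`, `N`) carry the complete state set and contribute no mutations.
#'
#' @param tree A rooted tree whose tips are all present in `alignment`.
#' @param alignment A `dna_alignment`.
#' @return A list with `total` (integer) and `site_scores` (integer per site).
#' @examples
#' aln <- read_alignment(seqs = c(A = "A", B = "A", C = "T", D = "T"))
#' tr <- rooted_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
#' fitch_score(tr, aln)$total # 1
#' @export
fitch_score <- function(tree, alignment) {
  up <- fitch_up(tree, tip_state_matrix(tree, alignment))
  list(total = as.integer(sum(up$events)),
       site_scores = as.integer(up$events))
}

#' Per-branch mutation counts from a resolved parsimony reconstruction
#'
#' Resolves one most-parsimonious ancestral reconstruction with the
#' deterministic top-down (ACCTRAN-style) policy and counts, for every
#' branch, the number of sites whose resolved parent and child states differ.
#' Branch counts sum to the Fitch total.
#'
#' @inheritParams fitch_score
#' @return A tibble with one row per branch: `clade` (key of the tips below
#'   the branch), `node` (ape child-node id), `count`.
#' @export
branch_mutation_counts <- function(tree, alignment) {
  up <- fitch_up(tree, tip_state_matrix(tree, alignment))
  final <- fitch_resolve(tree, up$prelim)
  edge <- tree$edge
  counts <- vapply(seq_len(nrow(edge)), function(i) {
    sum(final[edge[i, 1], ] != final[edge[i, 2], ])
  }, numeric(1))
  # key each branch by the tips below its child node
  below <- node_clade_keys(tree)
  keys <- below[edge[, 2]]
  tibble::tibble(node = edge[, 2], clade = keys, count = as.integer(counts))
}

node_clade_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  below <- vector("list", n_all)
  below[seq_len(n_tip)] <- as.list(tree$tip.label)
  edge <- tree$edge
  for (i in rev(seq_len(nrow(edge)))) {
    below[[edge[i, 1]]] <- c(below[[edge[i, 1]]], below[[edge[i, 2]]])
  }
  vapply(below, function(x) paste(sort(x), collapse = "|"), character(1))
}

#' Parsimony-score trace over a chain
#'
#' One Fitch total per sampled tree; the resulting integer series feeds
#' [ess()] and [psrf()] as the parsimony-score diagnostics.
#'
#' @param trace A `tree_trace`.
#' @param alignment A `dna_alignment` covering all tips.
#' @return Integer vector, one score per sample.
#' @export
parsimony_trace <- function(trace, alignment) {
  vapply(trace$trees, function(tr) fitch_score(tr, alignment)$total, integer(1))
}

#' Parsimony dispersal-event counts for a discrete trait
#'
#' Runs Fitch on the single multistate location character, resolves
#' ambiguities deterministically top-down (root: lexicographically smallest
#' member of its state set; child: parent's state when compatible, else its
#' smallest member), and counts directed parent-to-child state changes.
#'
#' @param tree A rooted tree.
#' @param traits Named character vector (or tibble with `taxon`, `location`)
#'   of tip locations.
#' @param allow_missing Treat absent locations as fully ambiguous rather than
#'   erroring.
#' @return A list with `total` (integer) and `pairwise` (directed
#'   origin-by-destination integer matrix summing to `total`).
#' @export
dispersal_events <- function(tree, traits, allow_missing = FALSE) {
  if (is.data.frame(traits)) {
    traits <- setNames(as.character(traits$location), traits$taxon)
  }
  locs <- traits[tree$tip.label]
  if (any(is.na(locs) | locs == "")) {
    if (!allow_missing) {
      abort(paste0("tips without location: ",
                   paste(tree$tip.label[is.na(locs) | locs == ""], collapse = ", ")))
    }
  }
  states <- sort(unique(locs[!is.na(locs) & locs != ""]))
  if (length(states) > 30) abort("too many discrete states (> 30)")
  full <- sum(bitwShiftL(1L, seq_along(states) - 1L))
  bits <- bitwShiftL(1L, match(locs, states) - 1L)
  bits[is.na(bits)] <- full
  up <- fitch_up(tree, matrix(bits, ncol = 1))
  final <- fitch_resolve(tree, up$prelim)
  state_of <- states[match(final[, 1], bitwShiftL(1L, seq_along(states) - 1L))]
  edge <- tree$edge
  pairwise <- matrix(0L, length(states), length(states),
                     dimnames = list(from = states, to = states))
  for (i in seq_len(nrow(edge))) {
    a <- state_of[edge[i, 1]]; b <- state_of[edge[i, 2]]
    if (a != b) pairwise[a, b] <- pairwise[a, b] + 1L
  }
  list(total = as.integer(sum(pairwise)), pairwise = pairwise)
}

#' Sites at which two sequences are incompatible
#'
#' A difference site is one where the two state sets are disjoint; overlapping
#' ambiguity (e.g. `R` vs `A`) does not count as a difference.
#'
#' @param alignment A `dna_alignment`.
#' @param taxon1,taxon2 Taxon labels.
#' @return Integer vector of 1-based site indices.
#' @export
pairwise_difference_sites <- function(alignment, taxon1, taxon2) {
  for (t in c(taxon1, taxon2)) {
    if (!t %in% rownames(alignment)) abort(sprintf("unknown taxon '%s'", t))
  }
  which(bitwAnd(alignment[taxon1, ], alignment[taxon2, ]) == 0L)
}

#' Data-quality screen of one sequence against references
#'
#' Computes the missingness of a sequence (fraction of fully ambiguous
#' sites and its distribution over codon positions), the per-site Hamming
#' profile against a reference set (mean disjoint-state indicator), and the
#' windowed difference density (default windows: thirds of the alignment).
#'
#' @param alignment A `dna_alignment`.
#' @param taxon Focal taxon.
#' @param reference_taxa Character vector of reference taxa (non-empty).
#' @param frame_offset Codon frame offset in `{0, 1, 2}`.
#' @param windows Optional integer vector of window breakpoints (site indices
#'   ending each window); defaults to thirds.
#' @return A list: `missing_fraction`, `missing_by_codon_position` (length-3
#'   proportions over missing sites), `hamming_profile` (per-site numeric),
#'   `windowed_density` (tibble: window, start, end, density).
#' @export
sequence_screen <- function(alignment, taxon, reference_taxa,
                            frame_offset = 0, windows = NULL) {
  if (!length(reference_taxa)) abort("reference set is empty")
  stopifnot(frame_offset %in% 0:2)
  if (!taxon %in% rownames(alignment)) abort(sprintf("unknown taxon '%s'", taxon))
  n_sites <- ncol(alignment)
  focal <- alignment[taxon, ]
  missing <- focal == 15L
  codon_pos <- ((seq_len(n_sites) - 1 + frame_offset) %% 3) + 1
  by_codon <- if (any(missing)) {
    as.vector(prop.table(table(factor(codon_pos[missing], levels = 1:3))))
  } else c(0, 0, 0)
  prof <- rowMeans(vapply(reference_taxa, function(r) {
    if (!r %in% rownames(alignment)) abort(sprintf("unknown taxon '%s'", r))
    as.numeric(bitwAnd(focal, alignment[r, ]) == 0L)
  }, numeric(n_sites)))
  if (is.null(windows)) {
    windows <- round(n_sites * c(1, 2, 3) / 3)
  }
  starts <- c(1L, head(windows, -1) + 1L)
  dens <- vapply(seq_along(windows), function(i) {
    mean(prof[starts[i]:windows[i]])
  }, numeric(1))
  list(
    missing_fraction = mean(missing),
    missing_by_codon_position = by_codon,
    hamming_profile = prof,
    windowed_density = tibble::tibble(
      window = seq_along(windows), start = starts, end = as.integer(windows),
      density = dens
    )
  )
}
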