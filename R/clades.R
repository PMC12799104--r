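# Rooted clades (not unrooted splits): one clade per non-root internal node,
# keyed canonically by the sorted tip labels it contains. Singletons and the
# full taxon set are excluded everywhere — they are present in every rooted
# tree on the taxon set and would only dilute ASDCF.

#' Extract the nontrivial rooted clades of a tree
#'
#' Each non-root internal node contributes the set of tip labels below it; a
#' binary rooted tree on n tips yields exactly n - 2 nontrivial clades. Clades
#' are keyed as `"lab1|lab2|..."` with labels sorted, so keys are comparable
#' across trees and after pruning.
#'
#' @param tree A `rooted_tree` (any rooted `phylo` works).
#' @return Character vector of clade keys.
#' @export
extract_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  n_all <- n_tip + tree$Nnode
  below <- vector("list", n_all)
  below[seq_len(n_tip)] <- as.list(tree$tip.label)
  # postorder: children appear after parents in cladewise edge order
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  internal <- setdiff((n_tip + 1L):n_all, n_tip + 1L) # drop root
  vapply(below[internal], function(x) paste(sort(x), collapse = "|"),
         character(1))
}

clade_size <- function(keys) lengths(strsplit(keys, "|", fixed = TRUE))

clade_tips <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

#' Topology key of a tree (clade-set identity)
#'
#' Two rooted trees on the same taxon set have equal keys iff they have the
#' same rooted topology.
#' @param tree A rooted tree.
#' @return A single string.
#' @export
topology_key <- function(tree) {
  paste(sort(extract_clades(tree)), collapse = ";")
}

#' Binary occurrence trace of a clade along a chain
#'
#' @param clade A clade key (or character vector of tip labels).
#' @param trace A `tree_trace`.
#' @return Integer 0/1 vector, one entry per sample.
#' @export
clade_occurrence_trace <- function(clade, trace) {
  key <- as_clade_key(clade)
  vapply(trace$trees, function(tr) as.integer(key %in% extract_clades(tr)),
         integer(1))
}

as_clade_key <- function(clade) {
  if (length(clade) > 1) paste(sort(clade), collapse = "|") else clade
}

#' Clade frequency table across chains
#'
#' Enumerates every nontrivial clade observed in any sampled tree and tabulates
#' per-chain occurrence frequencies, the pooled frequency (weighted by chain
#' sample counts), and the across-chain SD of frequencies (SDCF).
#'
#' @param traces List of `tree_trace` objects on one taxon set.
#' @return A `clade_table`: tibble with columns `clade`, `size`, one
#'   `freq_<chain>` column per chain, `pooled`, `sdcf`; the per-sample
#'   occurrence matrices (clades x samples, one per chain) are attached as
#'   attribute `occurrence`.
#' @export
clade_frequencies <- function(traces) {
  traces <- as_trace_list(traces)
  if (any(vapply(traces, n_samples, integer(1)) == 0)) abort("empty tree trace")
  per_tree <- lapply(traces, function(tr) lapply(tr$trees, extract_clades))
  all_clades <- sort(unique(unlist(per_tree)))
  occ <- lapply(per_tree, function(chain) {
    m <- vapply(chain, function(keys) all_clades %in% keys,
                logical(length(all_clades)))
    m <- matrix(as.integer(m), nrow = length(all_clades))
    rownames(m) <- all_clades
    m
  })
  names(occ) <- vapply(traces, function(x) x$chain_id, character(1))
  freqs <- vapply(occ, rowMeans, numeric(length(all_clades)))
  freqs <- matrix(freqs, nrow = length(all_clades),
                  dimnames = list(all_clades, names(occ)))
  wts <- vapply(traces, n_samples, integer(1))
  pooled <- as.vector(freqs %*% wts) / sum(wts)
  sdcf <- if (length(traces) >= 2) apply(freqs, 1, sd) else rep(NA_real_, length(all_clades))
  out <- tibble::tibble(
    clade = all_clades,
    size = clade_size(all_clades)
  )
  for (ch in colnames(freqs)) out[[paste0("freq_", ch)]] <- unname(freqs[, ch])
  out$pooled <- unname(pooled)
  out$sdcf <- unname(sdcf)
  attr(out, "occurrence") <- occ
  class(out) <- c("clade_table", class(out))
  out
}

as_trace_list <- function(traces) {
  if (inherits(traces, "tree_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  taxa <- traces[[1]]$taxa
  for (tr in traces) {
    if (!identical(tr$taxa, taxa)) abort("chains have different taxon sets")
  }
  traces
}

#' Write a clade report TSV
#' @param table A `clade_table`.
#' @param path Output path.
#' @export
write_clade_report <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
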