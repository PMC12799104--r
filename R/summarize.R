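# Posterior summarization and mitigation: MCC summary trees, clade-specific
# variable traces, tip pruning with re-diagnosis, problematic-tip ranking and
# tree-shape summaries.

#' Maximum clade credibility (MCC) summary tree
#'
#' Among the sampled trees (pooled over chains), picks the one maximizing the
#' sum of log pooled clade posterior probabilities over its nontrivial clades;
#' ties broken by first occurrence in trace order. Each internal node is
#' annotated with the clade's posterior probability and the mean, median and
#' 95% interval of its MRCA height over the trees containing the clade.
#'
#' @param traces A `tree_trace` or list of them.
#' @return A `summary_tree`: the winning `rooted_tree` with a
#'   `node_annotations` tibble (`node`, `clade`, `posterior`, `height_mean`,
#'   `height_median`, `height_lo`, `height_hi`) and `log_credibility`.
#' @export
mcc_tree <- function(traces) {
  traces <- as_trace_list(traces)
  ctab <- clade_frequencies(traces)
  prob <- setNames(ctab$pooled, ctab$clade)
  trees <- unlist(lapply(traces, function(x) x$trees), recursive = FALSE)
  cred <- vapply(trees, function(tr) {
    sum(log(prob[extract_clades(tr)]))
  }, numeric(1))
  best <- which.max(cred) # which.max takes the first maximum
  tree <- trees[[best]]

  # height samples per clade (and root) over trees containing it
  keys_per_tree <- lapply(trees, node_clade_keys)
  heights_per_tree <- lapply(trees, function(tr) tr$node_height)
  tree_keys <- node_clade_keys(tree)
  n_tip <- length(tree$tip.label)
  ann <- vector("list", n_tip + tree$Nnode)
  rows <- list()
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    key <- tree_keys[nd]
    hs <- unlist(lapply(seq_along(trees), function(i) {
      hit <- match(key, keys_per_tree[[i]])
      if (is.na(hit)) NULL else heights_per_tree[[i]][hit]
    }))
    post <- if (nd == n_tip + 1L) 1 else unname(prob[key])
    qs <- quantile(hs, c(0.025, 0.975), names = FALSE)
    ann[[nd]] <- c(posterior = post, height_mean = mean(hs),
                   height_median = median(hs))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      node = nd, clade = key, posterior = post, height_mean = mean(hs),
      height_median = median(hs), height_lo = qs[1], height_hi = qs[2]
    )
  }
  tree$node_annotations <- dplyr::bind_rows(rows)
  tree$log_credibility <- cred[best]
  tree$annot_list <- ann
  class(tree) <- unique(c("summary_tree", class(tree)))
  tree
}

#' @export
print.summary_tree <- function(x, ...) {
  cat(sprintf(
    "MCC summary tree: %d tips, log clade credibility %.4f, min clade support %.2f\n",
    length(x$tip.label), x$log_credibility, min(x$node_annotations$posterior)
  ))
  invisible(x)
}

#' Write a summary tree as annotated NEXUS
#' @param tree A `summary_tree`.
#' @param path Output path.
#' @export
write_summary_tree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "Begin trees;"), con)
  writeLines(sprintf("tree MCC = [&R] %s",
                     format_annotated_newick(tree, node_annot = tree$annot_list)),
             con)
  writeLines("End;", con)
  invisible(path)
}

#' Per-sample trace of a clade-specific variable
#'
#' For every sample containing the clade, extracts the clade's MRCA height
#' (`node_age`), the duration of its subtending branch (`branch_duration`),
#' or the rate annotation on that branch (`branch_rate`); samples lacking the
#' clade are masked (`present = FALSE`, value `NA`).
#'
#' @param traces A `tree_trace` or list of them.
#' @param clade Clade key or character vector of tip labels; a single tip
#'   label addresses its pendant branch (for `branch_*` variables).
#' @param variable One of `node_age`, `branch_duration`, `branch_rate`.
#' @return Tibble: `chain`, `iteration`, `present`, `value`.
#' @export
clade_variable_traces <- function(traces,
                                  clade,
                                  variable = c("node_age", "branch_duration",
                                               "branch_rate")) {
  variable <- match.arg(variable)
  traces <- as_trace_list(traces)
  key <- as_clade_key(clade)
  singleton <- !grepl("|", key, fixed = TRUE)
  if (singleton && variable == "node_age") {
    abort("node_age is undefined for a single tip; use branch_* variables")
  }
  out <- purrr::map_dfr(traces, function(tr) {
    vals <- vapply(tr$trees, function(t) {
      keys <- node_clade_keys(t)
      nd <- match(key, keys)
      if (is.na(nd)) return(NA_real_)
      if (variable == "node_age") return(t$node_height[nd])
      parent <- t$edge[t$edge[, 2] == nd, 1]
      if (!length(parent)) return(NA_real_) # clade is the root
      if (variable == "branch_duration") {
        t$node_height[parent] - t$node_height[nd]
      } else {
        t$edge_rate[which(t$edge[, 2] == nd)]
      }
    }, numeric(1))
    tibble::tibble(chain = tr$chain_id, iteration = tr$iterations,
                   present = !is.na(vals), value = vals)
  })
  if (!any(out$present)) {
    warn(sprintf("clade '%s' never present in the sampled trees", key))
  }
  out
}

#' Diagnostics of a clade-specific variable
#'
#' ESS per chain (present-only values) and cross-chain PSRF, with the
#' presence fraction reported; chains are compared over their present-only
#' value series.
#'
#' @inheritParams clade_variable_traces
#' @return One-row tibble: `clade`, `variable`, `presence`, `mean_ess`,
#'   `psrf`.
#' @export
clade_variable_diagnostics <- function(traces, clade, variable) {
  tr <- clade_variable_traces(traces, clade, variable)
  by_chain <- split(tr$value[tr$present], tr$chain[tr$present])
  esses <- vapply(by_chain, function(x) {
    if (length(x) < 10 || is.na(var(x)) || var(x) == 0) NA_real_ else ess(x)
  }, numeric(1))
  rhat <- if (length(by_chain) >= 2 && min(lengths(by_chain)) >= 10) {
    if (var(unlist(by_chain)) == 0) NaN else psrf(by_chain)
  } else NA_real_
  tibble::tibble(
    clade = as_clade_key(clade), variable = variable,
    presence = mean(tr$present),
    mean_ess = if (all(is.na(esses))) NA_real_ else mean(esses, na.rm = TRUE),
    psrf = rhat
  )
}

# ---- pruning ---------------------------------------------------------------

prune_table <- function(tab, tips) {
  tab <- tab[!(tab$label %in% tips) | is.na(tab$label), ]
  repeat {
    kid_count <- table(factor(tab$parent, levels = tab$node))
    internal <- is.na(tab$label)
    lonely <- tab$node[internal & kid_count[as.character(tab$node)] == 1]
    childless <- tab$node[internal & kid_count[as.character(tab$node)] == 0]
    if (length(childless)) {
      tab <- tab[!tab$node %in% childless, ]
      next
    }
    if (!length(lonely)) break
    nd <- lonely[1]
    child <- tab$node[!is.na(tab$parent) & tab$parent == nd]
    g <- tab$parent[tab$node == nd]
    ci <- which(tab$node == child)
    if (is.na(g)) {
      tab$parent[ci] <- NA_integer_
      tab$rate[ci] <- NA_real_
    } else {
      d1 <- tab$height[tab$node == nd] - tab$height[ci]
      d2 <- tab$height[tab$node == g] - tab$height[tab$node == nd]
      r1 <- tab$rate[ci]; r2 <- tab$rate[tab$node == nd]
      tab$rate[ci] <- if (is.na(r1) || is.na(r2)) {
        NA_real_
      } else if (d1 + d2 > 0) (r1 * d1 + r2 * d2) / (d1 + d2) else mean(c(r1, r2))
      tab$parent[ci] <- g
    }
    tab <- tab[tab$node != nd, ]
  }
  tab
}

#' Prune tips from every sampled tree
#'
#' Removes the tips from each tree in each chain, suppressing the freed
#' degree-2 nodes (durations are summed; the merged branch's rate is the
#' duration-weighted mean of the merged branches). Heights of untouched nodes
#' are unchanged, so all diagnostics can be recomputed on the output.
#'
#' @param traces A `tree_trace` or list of them.
#' @param tips Character vector of tip labels to remove.
#' @return A list of `tree_trace` objects on the reduced taxon set (a single
#'   trace input returns a single trace).
#' @export
prune_tips <- function(traces, tips) {
  single <- inherits(traces, "tree_trace")
  traces <- as_trace_list(traces)
  taxa <- traces[[1]]$taxa
  unknown <- setdiff(tips, taxa)
  if (length(unknown)) {
    abort(paste0("tips not in the taxon set: ", paste(unknown, collapse = ", ")))
  }
  if (length(taxa) - length(tips) < 3) {
    abort("pruning would leave fewer than 3 taxa")
  }
  out <- lapply(traces, function(tr) {
    pruned <- lapply(tr$trees, function(t) {
      tree_from_table(prune_table(tree_table(t), tips))
    })
    tree_trace(pruned, tr$iterations, tr$chain_id, tr$density)
  })
  if (single) out[[1]] else out
}

# ---- problematic-tip ranking ----------------------------------------------

#' Rank tips by their association with tree sampling problems
#'
#' Each tip is scored by the maximum SDCF over the nontrivial clades
#' containing it of size at most `max(3, ceiling(0.1 n))` — a wobbling tip's
#' alternative attachment clades carry maximal SDCF. Ties are broken by the
#' PSRF of the tip's pendant branch rate (when rate annotations are present)
#' and then of its pendant branch duration; branch-rate discordance between
#' peaks is the most direct signature of a problematic sequence.
#'
#' @param report A `treerug_report` from [diagnose()] (supplies the clade
#'   SDCFs), or `NULL` to compute clade frequencies afresh.
#' @param traces The `tree_trace` list the report was computed from.
#' @return Tibble, most problematic first: `tip`, `score` (max SDCF),
#'   `rate_psrf`, `duration_psrf`, `evidence` (list-column of triggering
#'   clade keys).
#' @export
rank_problematic_tips <- function(report, traces) {
  traces <- as_trace_list(traces)
  clades <- if (is.null(report)) clade_frequencies(traces) else report$clade_table
  taxa <- traces[[1]]$taxa
  cap <- max(3, ceiling(0.1 * length(taxa)))
  small <- clades[clades$size <= cap, ]
  members <- strsplit(small$clade, "|", fixed = TRUE)
  has_rates <- any(vapply(traces[[1]]$trees, function(t) any(!is.na(t$edge_rate)),
                          logical(1)))
  pend <- pendant_series(traces, taxa)
  rows <- purrr::map_dfr(taxa, function(tip) {
    in_clade <- vapply(members, function(m) tip %in% m, logical(1))
    score <- if (any(in_clade)) max(small$sdcf[in_clade], na.rm = TRUE) else 0
    if (!is.finite(score)) score <- 0
    evidence <- if (any(in_clade)) {
      hits <- small$clade[in_clade & !is.na(small$sdcf) & small$sdcf >= score - 1e-12]
      list(hits)
    } else list(character())
    dur <- series_psrf(lapply(pend, function(ch) ch$duration[, tip]))
    rate <- if (has_rates) {
      series_psrf(lapply(pend, function(ch) ch$rate[, tip]))
    } else NA_real_
    tibble::tibble(tip = tip, score = score, rate_psrf = rate,
                   duration_psrf = dur, evidence = evidence)
  })
  key_rate <- ifelse(is.na(rows$rate_psrf) | is.nan(rows$rate_psrf), 1,
                     rows$rate_psrf)
  key_dur <- ifelse(is.na(rows$duration_psrf) | is.nan(rows$duration_psrf), 1,
                    rows$duration_psrf)
  rows[order(-rows$score, -key_rate, -key_dur, rows$tip), ]
}

pendant_series <- function(traces, taxa) {
  # per chain: samples x taxa matrices of pendant-branch duration and rate
  lapply(traces, function(tr) {
    dur <- matrix(NA_real_, n_samples(tr), length(taxa),
                  dimnames = list(NULL, taxa))
    rate <- dur
    for (i in seq_along(tr$trees)) {
      t <- tr$trees[[i]]
      ids <- match(taxa, t$tip.label)
      erow <- match(ids, t$edge[, 2])
      dur[i, ] <- t$node_height[t$edge[erow, 1]] - t$node_height[ids]
      rate[i, ] <- t$edge_rate[erow]
    }
    list(duration = dur, rate = rate)
  })
}

series_psrf <- function(by_chain) {
  if (length(by_chain) < 2) return(NA_real_)
  if (any(vapply(by_chain, function(x) any(is.na(x)), logical(1)))) {
    return(NA_real_)
  }
  if (min(lengths(by_chain)) < 10) return(NA_real_)
  vals <- unlist(by_chain)
  rng <- range(vals)
  # constant up to rounding noise (e.g. a duration-weighted mean of equal
  # rates): no discordance signal
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), .Machine$double.xmin)) {
    return(NaN)
  }
  within0 <- all(vapply(by_chain, var, numeric(1)) == 0)
  if (within0) return(Inf) # chains constant but different: no mixing at all
  psrf(by_chain)
}

# ---- tree shape ------------------------------------------------------------

#' Lineage-through-time and imbalance summaries
#'
#' `ltt` is the step function of the number of lineages alive at each time
#' before the latest tip (ending at the count of height-0 tips); `colless` is
#' the sum over internal nodes of the absolute difference of left and right
#' descendant-tip counts (errors on non-binary trees).
#'
#' @param tree A dated `rooted_tree`.
#' @return List: `ltt` (tibble `time`, `lineages`; time decreasing towards 0)
#'   and `colless` (integer).
#' @export
tree_shape <- function(tree) {
  n_tip <- length(tree$tip.label)
  h <- tree$node_height
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  events <- rbind(
    data.frame(time = h[internal], delta = 1L),
    data.frame(time = h[seq_len(n_tip)], delta = -1L)
  )
  # tips at height 0 are the present-day boundary: the curve ends with them
  events <- events[!(events$delta == -1L & events$time == 0), ]
  events <- events[order(-events$time, -events$delta), ]
  ltt <- tibble::tibble(
    time = c(events$time, 0),
    lineages = c(1L + cumsum(events$delta),
                 1L + sum(events$delta))
  )
  kids <- tabulate(tree$edge[, 1], nbins = n_tip + tree$Nnode)
  if (any(kids[internal] != 2)) {
    abort("Colless imbalance requires a binary tree")
  }
  sizes <- integer(n_tip + tree$Nnode)
  sizes[seq_len(n_tip)] <- 1L
  edge <- tree$edge
  for (i in rev(seq_len(nrow(edge)))) {
    sizes[edge[i, 1]] <- sizes[edge[i, 1]] + sizes[edge[i, 2]]
  }
  colless <- sum(vapply(internal, function(nd) {
    ch <- edge[edge[, 1] == nd, 2]
    abs(sizes[ch[1]] - sizes[ch[2]])
  }, numeric(1)))
  list(ltt = ltt, colless = as.integer(colless))
}
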