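# Synthetic multimodal posteriors: dated coalescent trees, alignments
# simulated with a true per-branch mutation log, and multi-chain tree traces
# whose topology alternates among peaks created by relocating designated
# "wobbling" tips — the desk-scale stand-in for a rugged phylodynamic
# posterior, with full ground truth for validating every diagnostic.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a dated tree under the heterochronous constant-Ne coalescent
#'
#' Going backwards in time, each pair of active lineages coalesces at rate
#' `1/Ne`; tips become active at their sampling heights.
#'
#' @param n_tips Number of tips (>= 3).
#' @param Ne Effective population size (time units).
#' @param sampling_times Tip heights before the latest tip (length `n_tips`;
#'   default all contemporaneous). The minimum is shifted to 0.
#' @param seed RNG seed.
#' @param labels Tip labels (default `t01`, `t02`, ...).
#' @return A `rooted_tree`.
#' @export
simulate_time_tree <- function(n_tips, Ne, sampling_times = rep(0, n_tips),
                               seed = 1,
                               labels = sprintf("t%02d", seq_len(n_tips))) {
  stopifnot(n_tips >= 2, Ne > 0, length(sampling_times) == n_tips,
            length(labels) == n_tips)
  sampling_times <- sampling_times - min(sampling_times)
  with_seed(seed, {
    ord <- order(sampling_times)
    pending <- ord # tip indices by increasing height
    heights <- c(sampling_times, rep(NA_real_, n_tips - 1))
    parent <- rep(NA_integer_, 2 * n_tips - 1)
    next_node <- n_tips
    tau <- 0
    active <- integer()
    repeat {
      # activate tips sampled at or before tau
      while (length(pending) && sampling_times[pending[1]] <= tau) {
        active <- c(active, pending[1])
        pending <- pending[-1]
      }
      if (!length(pending) && length(active) == 1) break
      k <- length(active)
      next_h <- if (length(pending)) sampling_times[pending[1]] else Inf
      if (k < 2) {
        tau <- next_h
        next
      }
      wait <- stats::rexp(1, rate = k * (k - 1) / 2 / Ne)
      if (tau + wait >= next_h) {
        tau <- next_h
      } else {
        tau <- tau + wait
        pair <- sample(active, 2)
        next_node <- next_node + 1L
        heights[next_node] <- tau
        parent[pair] <- next_node
        active <- c(setdiff(active, pair), next_node)
      }
    }
    tree_from_table(tibble::tibble(
      node = seq_len(2 * n_tips - 1),
      parent = parent,
      height = heights,
      rate = NA_real_,
      label = c(labels, rep(NA_character_, n_tips - 1))
    ))
  })
}

#' Simulate an alignment on a tree with a true mutation log
#'
#' Root states are uniform; mutations occur along each branch as a Poisson
#' process with per-site rate `clock_rate` (expected `duration * clock_rate`
#' substitutions per site). Every event changes the state: under `JC` the new
#' state is uniform over the other three; under `HKY` target states are
#' weighted by `base_freqs` with transitions favored by `kappa`.
#'
#' @param tree A dated `rooted_tree`.
#' @param model `"JC"` or `"HKY"`.
#' @param clock_rate Substitutions/site/time unit.
#' @param n_sites Number of sites.
#' @param seed RNG seed.
#' @param kappa Transition/transversion rate ratio (HKY).
#' @param base_freqs Equilibrium base frequencies A,C,G,T (HKY).
#' @return List: `alignment` (a `dna_alignment`), `truth` (tibble `node`,
#'   `clade`, `count` of true mutations per branch), `total_mutations`.
#' @export
simulate_alignment <- function(tree, model = c("JC", "HKY"), clock_rate,
                               n_sites, seed = 1, kappa = 2,
                               base_freqs = rep(0.25, 4)) {
  model <- match.arg(model)
  stopifnot(clock_rate >= 0, n_sites >= 1)
  transition_of <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_all <- n_tip + tree$Nnode
    seqs <- matrix(0L, n_all, n_sites)
    seqs[root_node(tree), ] <- sample.int(4, n_sites, replace = TRUE)
    edge <- tree$edge
    counts <- integer(nrow(edge))
    mutate_state <- function(s) {
      if (model == "JC") {
        sample(setdiff(1:4, s), 1)
      } else {
        w <- base_freqs
        w[transition_of[s]] <- w[transition_of[s]] * kappa
        w[s] <- 0
        sample.int(4, 1, prob = w)
      }
    }
    for (i in seq_len(nrow(edge))) { # cladewise: parent states already set
      p <- edge[i, 1]; ch <- edge[i, 2]
      dur <- tree$node_height[p] - tree$node_height[ch]
      s <- seqs[p, ]
      n_events <- stats::rpois(n_sites, dur * clock_rate)
      for (j in which(n_events > 0)) {
        for (rep in seq_len(n_events[j])) s[j] <- mutate_state(s[j])
      }
      counts[i] <- sum(n_events)
      seqs[ch, ] <- s
    }
    bits <- matrix(bitwShiftL(1L, seqs[seq_len(n_tip), , drop = FALSE] - 1L),
                   nrow = n_tip)
    rownames(bits) <- tree$tip.label
    keys <- node_clade_keys(tree)
    list(
      alignment = structure(bits, class = c("dna_alignment", "matrix", "array")),
      truth = tibble::tibble(node = edge[, 2], clade = keys[edge[, 2]],
                             count = counts),
      total_mutations = sum(counts)
    )
  })
}

# ---- wobble specs ----------------------------------------------------------

#' Specify a wobbling tip (one tree-space "dimension")
#'
#' A wobbling tip alternates between its attachment in the base tree and an
#' alternative branch, identified by the clade of tip labels below it in the
#' tree without the wobbler. `stay_prob` is the per-step probability of
#' staying on the current peak.
#'
#' @param tip Tip label.
#' @param dest Character vector: the clade below the alternative branch.
#' @param stay_prob Per-step stay probability in (0, 1].
#' @param density_offsets Length-2 pseudo log-density offsets for (base,
#'   alternative) position.
#' @return A `wobble_spec`.
#' @export
wobble_spec <- function(tip, dest, stay_prob = 0.98,
                        density_offsets = c(0, 0)) {
  stopifnot(stay_prob > 0, stay_prob <= 1, length(density_offsets) == 2)
  structure(list(tip = tip, dest = dest, stay_prob = stay_prob,
                 density_offsets = density_offsets),
            class = "wobble_spec")
}

# build every 2^S peak tree, or NULL when the specs interact: a relocation
# fails (a destination clade stops being identifiable once another wobbler
# has moved) or two peak combinations collapse onto the same topology
build_peak_trees <- function(base_tree, wobble_specs, base_rate,
                             alt_rate_factor) {
  s_count <- length(wobble_specs)
  combos <- as.matrix(expand.grid(rep(list(0:1), s_count)))
  colnames(combos) <- vapply(wobble_specs, function(s) s$tip, character(1))
  trees <- vector("list", nrow(combos))
  for (pk in seq_len(nrow(combos))) {
    tr <- base_tree
    for (i in seq_len(s_count)) {
      if (combos[pk, i] == 1) {
        tr <- tryCatch(
          relocate_tip(tr, wobble_specs[[i]]$tip, wobble_specs[[i]]$dest),
          error = function(e) NULL
        )
        if (is.null(tr)) return(NULL)
      }
    }
    for (i in seq_len(s_count)) {
      tip_edge <- which(tr$edge[, 2] == tip_id(tr, wobble_specs[[i]]$tip))
      tr$edge_rate[tip_edge] <- base_rate *
        if (combos[pk, i] == 1) alt_rate_factor else 1
    }
    trees[[pk]] <- tr
  }
  keys <- vapply(trees, topology_key, character(1))
  if (length(unique(keys)) != length(keys)) return(NULL)
  list(combos = combos, trees = trees)
}

wobble_geometry <- function(base_tree, spec) {
  det <- detach_tip(tree_table(base_tree), spec$tip)
  tab <- det$tab
  v <- find_dest_node(tab, setdiff(spec$dest, spec$tip))
  path <- edge_path(tab, det$old_sib, v)
  sets <- below_sets(tab)
  involved <- unique(c(spec$tip,
                       unlist(lapply(path, function(nd) sets[[as.character(nd)]]))))
  list(k = length(path) - 1L, involved = involved)
}

#' Find a feasible wobble destination at a given separation
#'
#' Searches the branches of `tree` (without `tip`) for one exactly `k`
#' internal nodes away from the tip's current attachment that can accommodate
#' the tip's height, whose path does not touch `forbidden` labels.
#'
#' @param tree Base `rooted_tree`.
#' @param tip Candidate wobbler.
#' @param k Required number of intermediate internal nodes (>= 1).
#' @param forbidden Labels that must not be involved in the move.
#' @return The destination clade (character vector), or `NULL` if none.
#' @export
find_wobble_dest <- function(tree, tip, k, forbidden = character()) {
  if (tip %in% forbidden) return(NULL)
  det <- detach_tip(tree_table(tree), tip)
  tab <- det$tab
  sets <- below_sets(tab)
  bfs <- edge_bfs(tab, det$old_sib)
  h_t <- det$tip_row$height
  cand <- as.integer(names(bfs$dist)[!is.na(bfs$dist) & bfs$dist == k])
  for (v in sort(cand)) {
    u <- tab$parent[tab$node == v]
    if (is.na(u)) next
    if (tab$height[tab$node == u] <= max(h_t, tab$height[tab$node == v])) next
    # labels involved along the path
    path <- v
    while (path[1] != det$old_sib) {
      path <- c(bfs$prev[[as.character(path[1])]], path)
    }
    involved <- unique(unlist(lapply(path, function(nd) sets[[as.character(nd)]])))
    if (length(intersect(involved, forbidden))) next
    return(sets[[as.character(v)]])
  }
  NULL
}

# ---- multimodal traces -----------------------------------------------------

#' Generate multi-chain multimodal tree traces
#'
#' Each chain is an independent Markov chain over the `2^S` peak combinations
#' of `S` wobbling tips (each tip flips to its other position with
#' probability `1 - stay_prob` per step). The sampled tree at each step is
#' the base tree with every wobbler at its current attachment; intermediate
#' (valley) topologies are never emitted, mirroring unsampled valleys. All
#' branches carry rate annotations: `base_rate` everywhere, with the
#' wobbler's pendant rate multiplied by `alt_rate_factor` on its alternative
#' peak (the topology-dependent branch-rate signature of a problematic
#' sequence). Pseudo log-densities are the per-peak offsets plus small noise.
#'
#' @param base_tree Base `rooted_tree`.
#' @param wobble_specs List of [wobble_spec()]s; their move regions must be
#'   disjoint (non-interacting).
#' @param n_chains,n_samples Chains and samples per chain.
#' @param init_peaks Integer vector (length `n_chains`) of initial peak
#'   indices in `1..2^S`; default spreads chains over peaks.
#' @param seed RNG seed; identical seeds give identical studies.
#' @param base_rate Baseline branch rate annotation.
#' @param alt_rate_factor Pendant-rate multiplier on the alternative peak.
#' @param density_noise_sd SD of the pseudo-density noise.
#' @return List: `traces` (list of `tree_trace` with density), `params`
#'   (list of `param_trace`), `truth` (tibble: chain, sample, peak,
#'   membership), `peak_trees`, `combos` (peak definition matrix), `specs`.
#' @export
make_multimodal_trace <- function(base_tree, wobble_specs, n_chains = 2,
                                  n_samples = 100, init_peaks = NULL,
                                  seed = 1, base_rate = 0.002,
                                  alt_rate_factor = 2,
                                  density_noise_sd = 0.05) {
  if (inherits(wobble_specs, "wobble_spec")) wobble_specs <- list(wobble_specs)
  s_count <- length(wobble_specs)
  stopifnot(s_count >= 1, n_chains >= 1, n_samples >= 1)
  base_tree$edge_rate <- ifelse(is.na(base_tree$edge_rate), base_rate,
                                base_tree$edge_rate)
  geom <- lapply(wobble_specs, wobble_geometry, base_tree = base_tree)
  if (any(vapply(geom, function(g) g$k, integer(1)) < 1)) {
    abort("wobble separation k must be >= 1")
  }
  tips <- vapply(wobble_specs, function(s) s$tip, character(1))
  if (anyDuplicated(tips)) abort("wobble specs must name distinct tips")
  built <- build_peak_trees(base_tree, wobble_specs, base_rate,
                            alt_rate_factor)
  if (is.null(built)) {
    abort(sprintf("interacting wobble specs (%s): peak topologies are not %d distinct trees",
                  paste(tips, collapse = ", "), 2^s_count))
  }
  combos <- built$combos
  peak_trees <- built$trees
  if (is.null(init_peaks)) {
    # spread chains over maximally different peak combinations so that in a
    # stuck study every wobbler is discordant between some pair of chains
    init_peaks <- if (n_chains == 1) 1L else {
      round(seq(1, nrow(combos), length.out = n_chains))
    }
  }
  stopifnot(length(init_peaks) == n_chains,
            all(init_peaks %in% seq_len(nrow(combos))))
  stay <- vapply(wobble_specs, function(s) s$stay_prob, numeric(1))
  offsets <- vapply(wobble_specs, function(s) s$density_offsets, numeric(2))
  offsets <- matrix(offsets, nrow = 2)
  with_seed(seed, {
    truth <- list()
    traces <- vector("list", n_chains)
    params <- vector("list", n_chains)
    for (ch in seq_len(n_chains)) {
      b <- combos[init_peaks[ch], ]
      peaks <- integer(n_samples)
      dens <- numeric(n_samples)
      for (st in seq_len(n_samples)) {
        pk <- 1L + sum(b * 2^(seq_len(s_count) - 1L))
        peaks[st] <- pk
        dens[st] <- sum(offsets[cbind(b + 1L, seq_len(s_count))]) +
          stats::rnorm(1, 0, density_noise_sd)
        flip <- stats::runif(s_count) > stay
        b <- ifelse(flip, 1L - b, b)
      }
      cid <- sprintf("chain%d", ch)
      traces[[ch]] <- tree_trace(peak_trees[peaks],
                                 iterations = seq_len(n_samples) * 1000L,
                                 chain_id = cid, density = dens)
      p <- tibble::tibble(iteration = seq_len(n_samples) * 1000,
                          posterior = dens)
      attr(p, "chain_id") <- cid
      class(p) <- c("param_trace", class(p))
      params[[ch]] <- p
      truth[[ch]] <- tibble::tibble(
        chain = cid, sample = seq_len(n_samples), peak = peaks,
        membership = apply(combos[peaks, , drop = FALSE], 1, paste,
                           collapse = "")
      )
    }
    list(traces = traces, params = params, truth = dplyr::bind_rows(truth),
         peak_trees = peak_trees, combos = combos, specs = wobble_specs,
         k = vapply(geom, function(g) g$k, integer(1)))
  })
}

#' Generate a complete synthetic phylodynamic study
#'
#' Builds a heterochronous coalescent base tree, designates `n_wobblers`
#' wobbling tips at separation `k`, simulates the multi-chain multimodal
#' trace, an alignment on the base-peak topology (with mutation truth log),
#' pseudo-posterior parameter logs and tip metadata.
#'
#' @param n_taxa Taxa in the study.
#' @param n_wobblers Number of wobbling tips (specs are auto-discovered).
#' @param k Wobble separation (intermediate internal nodes).
#' @param n_chains,n_samples Chains and samples per chain.
#' @param stay_prob Per-step peak stay probability (1 = chains never switch).
#' @param Ne Coalescent population size.
#' @param sampling_span Tips sampled uniformly over this many time units.
#' @param clock_rate,n_sites Alignment simulation settings.
#' @param init_peaks Passed to [make_multimodal_trace()].
#' @param seed Root seed; the whole study is reproducible from it.
#' @param latest_date Decimal year of the most recent tip.
#' @return A `synthetic_study` list: `traces`, `params`, `alignment`,
#'   `metadata`, `truth` (peak membership), `mutation_truth`, `base_tree`,
#'   `peak_trees`, `specs`, `wobblers`, `k`, `seed`.
#' @export
synthetic_study <- function(n_taxa = 20, n_wobblers = 1, k = 6,
                            n_chains = 2, n_samples = 100, stay_prob = 1,
                            Ne = 5, sampling_span = 5, clock_rate = 2e-3,
                            n_sites = 500, init_peaks = NULL, seed = 1,
                            latest_date = 2020) {
  times <- with_seed(seed + 11L, stats::runif(n_taxa, 0, sampling_span))
  base <- simulate_time_tree(n_taxa, Ne, sampling_times = times,
                             seed = seed + 23L)
  specs <- list()
  forbidden <- character()
  k_candidates <- seq_len(k + 3)
  k_candidates <- k_candidates[order(abs(k_candidates - k), k_candidates)]
  used_tips <- character()
  for (w in seq_len(n_wobblers)) {
    found <- FALSE
    for (kk in k_candidates) { # prefer the exact separation, then nearby
      for (tip in setdiff(base$tip.label, c(used_tips, forbidden))) {
        dest <- find_wobble_dest(base, tip, kk, used_tips)
        if (is.null(dest) || any(used_tips %in% dest)) next
        cand <- c(specs, list(wobble_spec(tip, dest, stay_prob = stay_prob)))
        # accept only if every peak combination still builds a distinct tree
        if (is.null(build_peak_trees(base, cand, 0.002, 2))) next
        specs <- cand
        used_tips <- c(used_tips, tip)
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found) {
      abort(sprintf("could not place wobbler %d at separation ~%d; try other seed/taxa",
                    w, k))
    }
  }
  mm <- make_multimodal_trace(base, specs, n_chains = n_chains,
                              n_samples = n_samples, init_peaks = init_peaks,
                              seed = seed + 37L)
  sim <- simulate_alignment(mm$peak_trees[[1]], model = "HKY",
                            clock_rate = clock_rate, n_sites = n_sites,
                            seed = seed + 51L)
  heights <- base$node_height[seq_len(n_taxa)]
  metadata <- tibble::tibble(
    taxon = base$tip.label,
    date = latest_date - heights,
    location = NA_character_
  )
  structure(
    list(traces = mm$traces, params = mm$params, alignment = sim$alignment,
         metadata = metadata, truth = mm$truth, mutation_truth = sim$truth,
         base_tree = base, peak_trees = mm$peak_trees, specs = specs,
         wobblers = vapply(specs, function(s) s$tip, character(1)),
         k = mm$k, seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d taxa, %d chain(s) x %d samples, wobbler(s) %s (k = %s)\n",
    length(x$base_tree$tip.label), length(x$traces),
    n_samples(x$traces[[1]]), paste(x$wobblers, collapse = ", "),
    paste(x$k, collapse = ", ")
  ))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits per-chain NEXUS tree logs and parameter logs, the alignment
#' (FASTA), tip metadata (TSV) and the truth record (JSON).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study$traces)) {
    write_tree_log(study$traces[[i]], file.path(dir, sprintf("chain%d.trees", i)))
    write_param_log(study$params[[i]], file.path(dir, sprintf("chain%d.log", i)))
  }
  write_alignment(study$alignment, file.path(dir, "alignment.fasta"))
  utils::write.table(as.data.frame(study$metadata), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, wobblers = study$wobblers, k = study$k,
         peak_membership = study$truth,
         mutation_truth = study$mutation_truth),
    file.path(dir, "truth.json")
  )
  invisible(dir)
}
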