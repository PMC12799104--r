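test_that("MCC tree maximizes summed log clade credibility", {
  tr1 <- rt("((A:1,B:1):1.5,(C:1,D:1):1.5);")
  single <- mcc_tree(tree_trace(rep(list(tr1), 5)))
  expect_equal(topology_key(single), topology_key(tr1))
  expect_true(all(single$node_annotations$posterior == 1))

  # 6x T1 {AB},{ABC}; 4x T2 {BC},{ABC}
  t1 <- rt("(((A:1,B:1):1,C:2):1,D:3);")
  t2 <- rt("(((B:1,C:1):1,A:2):1,D:3);")
  mix <- mcc_tree(tree_trace(c(rep(list(t1), 6), rep(list(t2), 4))))
  expect_equal(topology_key(mix), topology_key(t1))
  ann <- mix$node_annotations
  expect_setequal(round(ann$posterior[ann$clade %in% c("A|B", "A|B|C")], 10),
                  c(0.6, 1.0))

  # the winner's credibility dominates every sampled tree
  study <- stuck_study(seed = 4, n_taxa = 10, n_samples = 20, k = 3,
                       n_sites = 40)
  mcc <- mcc_tree(study$traces)
  ctab <- clade_frequencies(study$traces)
  prob <- setNames(ctab$pooled, ctab$clade)
  for (tr in study$traces[[1]]$trees[c(1, 10, 20)]) {
    expect_gte(mcc$log_credibility, sum(log(prob[extract_clades(tr)])))
  }
  # round trip through annotated NEXUS
  path <- withr::local_tempfile(fileext = ".nexus")
  write_summary_tree(mcc, path)
  back <- read_tree_log(path)
  expect_equal(topology_key(back$trees[[1]]), topology_key(mcc))
})

test_that("clade variable traces mask absent samples and diagnose discordance", {
  t1 <- rt("(((A:1,B:1):1,C:2):1,D:3);")
  const <- clade_variable_diagnostics(
    list(tree_trace(rep(list(t1), 20), chain_id = "c1"),
         tree_trace(rep(list(t1), 20), chain_id = "c2")),
    c("A", "B"), "node_age")
  expect_true(is.na(const$mean_ess)) # zero variance: undefined, flagged
  expect_equal(const$presence, 1)

  # i.i.d. ages: rescale every tree's heights independently
  set.seed(12)
  trees <- lapply(1:500, function(i) {
    tt <- t1
    tt$node_height <- t1$node_height * runif(1, 0.5, 1.5)
    tt$edge.length <- tt$node_height[tt$edge[, 1]] - tt$node_height[tt$edge[, 2]]
    tt
  })
  iid <- clade_variable_diagnostics(tree_trace(trees), c("A", "B"), "node_age")
  expect_gte(iid$mean_ess, 0.65 * 500)

  # two peaks assigning discordant ages in stuck chains
  t_old <- t1
  t_old$node_height <- t1$node_height * 2
  t_old$edge.length <- t_old$node_height[t_old$edge[, 1]] -
    t_old$node_height[t_old$edge[, 2]]
  stuck <- clade_variable_diagnostics(
    list(tree_trace(rep(list(t1), 20), chain_id = "c1"),
         tree_trace(rep(list(t_old), 20), chain_id = "c2")),
    c("A", "B"), "node_age")
  expect_gt(stuck$psrf, 1.1)

  missing <- suppressWarnings(clade_variable_traces(tree_trace(rep(list(t1), 5)),
                                                    c("A", "C"), "node_age"))
  expect_warning(clade_variable_traces(tree_trace(rep(list(t1), 5)),
                                       c("A", "D"), "node_age"),
                 "never present")
  expect_false(any(missing$present))
})

test_that("pruning wobblers collapses peaks and preserves untouched heights", {
  study <- stuck_study(seed = 4, n_taxa = 12, n_samples = 20, k = 4,
                       n_sites = 40)
  expect_equal(nrow(topology_classes(study$traces)), 2)
  pruned <- prune_tips(study$traces, study$wobblers)
  expect_equal(nrow(topology_classes(pruned)), 1)
  expect_equal(asdcf(clade_frequencies(pruned)), 0)

  # untouched clade heights unchanged
  before <- study$traces[[1]]$trees[[1]]
  after <- pruned[[1]]$trees[[1]]
  keys_b <- extract_clades(before)
  keys_a <- extract_clades(after)
  common <- intersect(keys_a, keys_b)
  expect_gt(length(common), 0)
  hb <- before$node_height[match(common, treerug:::node_clade_keys(before))]
  ha <- after$node_height[match(common, treerug:::node_clade_keys(after))]
  expect_lt(max(abs(hb - ha)), 1e-12)

  expect_error(prune_tips(study$traces, study$traces[[1]]$taxa[1:10]),
               "fewer than 3")
  expect_error(prune_tips(study$traces, "nope"), "not in the taxon set")
})

test_that("pruned-branch rates merge as duration-weighted means", {
  tr <- rt("((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
  # explicit rates: pendants 0.001 (A), 0.002 (B), 0.003 (C), 0.005 (D);
  # the internal branch above the (A,B) cherry gets 0.004
  tr$edge_rate <- numeric(nrow(tr$edge))
  for (i in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[i, 2]
    tr$edge_rate[i] <- if (ch <= 4) c(0.001, 0.002, 0.003, 0.005)[ch] else 0.004
  }
  pruned <- prune_tips(tree_trace(list(tr)), "B")[["trees"]][[1]]
  # A's branch merges its pendant (dur 1, rate 0.001) with the internal
  # branch (dur 2, rate 0.004)
  e <- which(pruned$edge[, 2] == match("A", pruned$tip.label))
  expect_equal(pruned$edge_rate[e], (1 * 0.001 + 2 * 0.004) / 3)
  # topology agrees with ape::drop.tip
  ref <- ape::drop.tip(tr, "B")
  ref$edge_rate <- NULL # drop.tip does not subset the rate annotations
  expect_equal(topology_key(pruned), topology_key(rooted_tree(ref)))
})

test_that("pruning commutes with clade restriction", {
  study <- stuck_study(seed = 6, n_taxa = 10, n_samples = 6, k = 3,
                       n_sites = 30)
  tips <- study$wobblers
  tr <- study$traces[[1]]$trees[[1]]
  pruned <- prune_tips(study$traces, tips)[[1]]$trees[[1]]
  restricted <- lapply(strsplit(extract_clades(tr), "|", fixed = TRUE),
                       setdiff, y = tips)
  restricted <- unique(vapply(
    Filter(function(x) length(x) >= 2 && length(x) < length(pruned$tip.label),
           restricted),
    paste, character(1), collapse = "|"))
  expect_setequal(extract_clades(pruned), restricted)
})

test_that("problematic-tip ranking recovers the wobblers", {
  study <- stuck_study(seed = 4, n_taxa = 15, n_samples = 30, k = 5,
                       n_sites = 40)
  rep1 <- diagnose(study$traces)
  ranked <- rank_problematic_tips(rep1, study$traces)
  expect_equal(ranked$tip[1], study$wobblers)
  expect_gt(ranked$score[1], 0.5)

  # converged study: all scores ~ 0
  tr1 <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  calm <- list(tree_trace(rep(list(tr1), 20), chain_id = "c1"),
               tree_trace(rep(list(tr1), 20), chain_id = "c2"))
  calm_rank <- rank_problematic_tips(NULL, calm)
  expect_true(all(calm_rank$score < 1e-12))

  # three wobblers, chains stuck on complementary peak combinations
  three <- synthetic_study(n_taxa = 24, n_wobblers = 3, k = 3, n_chains = 2,
                           n_samples = 30, stay_prob = 1, n_sites = 30,
                           seed = 5)
  ranked3 <- rank_problematic_tips(NULL, three$traces)
  expect_setequal(ranked3$tip[1:3], three$wobblers)
})

test_that("ranking separates wobblers from bystanders across seeded studies", {
  hits <- 0
  total <- 0
  for (seed in 1:6) {
    study <- synthetic_study(n_taxa = 20 + 4 * (seed %% 3), n_wobblers = 1 + seed %% 2,
                             k = 4, n_chains = 2, n_samples = 40,
                             stay_prob = 1, n_sites = 30, seed = 100 + seed)
    ranked <- rank_problematic_tips(NULL, study$traces)
    nw <- length(study$wobblers)
    hits <- hits + length(intersect(ranked$tip[seq_len(nw)], study$wobblers))
    total <- total + nw
  }
  expect_gte(hits / total, 0.95)
})

test_that("tree shape summaries: LTT endpoint and Colless imbalance", {
  ult <- rt("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  shape <- tree_shape(ult)
  expect_equal(shape$ltt$lineages[nrow(shape$ltt)], 5)
  expect_equal(shape$ltt$time[nrow(shape$ltt)], 0)
  expect_equal(shape$colless, 6) # caterpillar: (n-1)(n-2)/2

  bal <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(tree_shape(bal)$colless, 0)
})
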