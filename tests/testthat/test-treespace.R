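test_that("rooted RF counts incompatible clades", {
  a <- rt("((A:1,B:1):1,C:2);")
  expect_equal(rf_rooted(a, a), 0)
  b <- rt("(A:2,(B:1,C:1):1);")
  expect_equal(rf_rooted(a, b), 2)
  expect_error(rf_rooted(a, rt("((A:1,B:1):1,D:2);")), "taxon sets")
})

test_that("rooted RF is a metric on topology classes", {
  # exhaustive identity/symmetry on n = 4; triangle inequality sampled on n = 5
  topos4 <- lapply(all_rooted_topologies(LETTERS[1:4]), as_rooted)
  for (i in seq_along(topos4)) {
    for (j in seq_along(topos4)) {
      dij <- rf_rooted(topos4[[i]], topos4[[j]])
      expect_equal(dij, rf_rooted(topos4[[j]], topos4[[i]]))
      expect_equal(dij == 0, i == j)
    }
  }
  topos5 <- lapply(all_rooted_topologies(LETTERS[1:5]), as_rooted)
  set.seed(2)
  for (rep in 1:200) {
    ijk <- sample(length(topos5), 3)
    d12 <- rf_rooted(topos5[[ijk[1]]], topos5[[ijk[2]]])
    d23 <- rf_rooted(topos5[[ijk[2]]], topos5[[ijk[3]]])
    d13 <- rf_rooted(topos5[[ijk[1]]], topos5[[ijk[3]]])
    expect_lte(d13, d12 + d23)
  }
})

test_that("tip relocation is a single SPR with RF = 2k", {
  cat12 <- caterpillar_tree(sprintf("T%02d", 1:12))
  # k intermediate nodes: relocate the cherry tip T01 progressively higher
  for (k in 1:6) {
    dest <- sprintf("T%02d", k + 2) # pendant branch k nodes above the cherry
    moved <- relocate_tip(cat12, "T01", dest)
    expect_equal(rf_rooted(cat12, moved), 2 * k, info = sprintf("k = %d", k))
    expect_equal(rspr_distance_small(caterpillar_tree(sprintf("T%02d", 1:8)),
                                     relocate_tip(caterpillar_tree(sprintf("T%02d", 1:8)),
                                                  "T01", "T04")), 1)
    # relocate back restores the topology
    back <- relocate_tip(moved, "T01", "T02")
    expect_equal(rf_rooted(back, cat12), 0)
    if (k >= 3) break # the back-relocation identity is enough at larger k
  }
})

test_that("the NNI path realizes the relocation one node at a time", {
  cat12 <- caterpillar_tree(sprintf("T%02d", 1:12))
  dest <- find_wobble_dest(cat12, "T01", 6)
  path <- nni_path_tip_relocation(cat12, "T01", dest)
  expect_length(path, 7) # 6 moves
  for (i in seq_len(length(path) - 1)) {
    expect_equal(rf_rooted(path[[i]], path[[i + 1]]), 2)
  }
  expect_equal(topology_key(path[[7]]),
               topology_key(relocate_tip(cat12, "T01", dest)))
  # k = 1: single move
  p1 <- nni_path_tip_relocation(cat12, "T01", "T03")
  expect_length(p1, 2)
})

test_that("exact small-instance rSPR distance behaves as a metric oracle", {
  ct <- caterpillar_tree(LETTERS[1:7])
  expect_equal(rspr_distance_small(ct, ct), 0)
  one <- relocate_tip(ct, "A", "E")
  expect_equal(rspr_distance_small(ct, one), 1)
  expect_equal(rspr_distance_small(one, ct), 1)
  # a valid lower bound: an SPR changes at most n - 2 clades on each side
  set.seed(3)
  topos <- lapply(all_rooted_topologies(LETTERS[1:6]), as_rooted)
  for (rep in 1:15) {
    ij <- sample(length(topos), 2)
    rs <- rspr_distance_small(topos[[ij[1]]], topos[[ij[2]]])
    rf <- rf_rooted(topos[[ij[1]]], topos[[ij[2]]])
    expect_gte(rs, ceiling(rf / (2 * 4))) # n - 2 = 4
    expect_lte(rs, 4)
  }
  expect_error(rspr_distance_small(caterpillar_tree(sprintf("T%02d", 1:11)),
                                   caterpillar_tree(sprintf("T%02d", 1:11))),
               "at most 10")
})

test_that("distance matrices subsample deterministically and see both peaks", {
  tr1 <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  same <- distance_matrix(tree_trace(rep(list(tr1), 3)))
  expect_true(all(same$matrix == 0))

  study <- stuck_study(seed = 4, n_taxa = 10, n_samples = 30, k = 4,
                       n_sites = 30)
  dm <- distance_matrix(study$traces)
  offdiag <- dm$matrix[upper.tri(dm$matrix)]
  expect_setequal(sort(unique(offdiag)), c(0, 2 * study$k)) # within 0, across 2k

  big <- tree_trace(rep(list(tr1), 1000))
  sub <- distance_matrix(big, max_samples = 100)
  expect_equal(nrow(sub$matrix), 100)
  expect_equal(sub$meta$index, unique(round(seq(1, 1000, length.out = 100))))
})

test_that("topology classes partition the samples", {
  tr1 <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(nrow(topology_classes(tree_trace(rep(list(tr1), 9)))), 1)

  three <- synthetic_study(n_taxa = 24, n_wobblers = 3, k = 3, n_chains = 2,
                           n_samples = 150, stay_prob = 0.6, n_sites = 30,
                           seed = 5)
  classes <- topology_classes(three$traces)
  expect_gte(nrow(classes), 8)
  expect_equal(sum(classes$total), 2 * 150)
})

test_that("classical MDS is exact on Euclidean input", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d <- as.matrix(dist(pts))
  emb <- classical_mds(d, dims = 2)
  rec <- as.matrix(dist(cbind(emb$axis1, emb$axis2)))
  expect_lt(max(abs(rec - d)), 1e-9)

  emb3 <- classical_mds(d, dims = 3)
  expect_lt(abs(attr(emb3, "eigenvalues")[3]), 1e-9)
  expect_lt(attr(emb, "stress"), 1e-9)

  # agrees with cmdscale up to reflection (distinct eigenvalues needed, so
  # use an asymmetric configuration rather than the square)
  set.seed(31)
  pts2 <- matrix(rnorm(20), ncol = 2) %*% diag(c(3, 1))
  d2 <- as.matrix(dist(pts2))
  emb2 <- classical_mds(d2, dims = 2)
  cmd <- stats::cmdscale(d2, k = 2)
  expect_equal(abs(cor(emb2$axis1, cmd[, 1])), 1, tolerance = 1e-9)
})

test_that("MDS separates the two peaks of a stuck study", {
  study <- stuck_study(seed = 4, n_taxa = 12, n_samples = 30, k = 5,
                       n_sites = 30)
  dm <- distance_matrix(study$traces)
  emb <- classical_mds(dm)
  xy <- cbind(emb$axis1, emb$axis2)
  grp <- emb$chain
  centers <- rowsum(xy, grp) / as.vector(table(grp))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  within <- max(sqrt(rowSums((xy - centers[grp, ])^2)))
  expect_gt(between / max(within, 1e-12), 5)
})

test_that("embedding is invariant to sample relabeling up to rigid motion", {
  study <- stuck_study(seed = 8, n_taxa = 10, n_samples = 20, k = 3,
                       n_sites = 30)
  dm <- distance_matrix(study$traces)
  emb1 <- classical_mds(dm)
  perm <- rev(seq_len(nrow(dm$matrix)))
  dm2 <- dm
  dm2$matrix <- dm$matrix[perm, perm]
  dm2$meta <- dm$meta[perm, ]
  emb2 <- classical_mds(dm2)
  d1 <- as.matrix(dist(cbind(emb1$axis1, emb1$axis2)))[perm, perm]
  d2 <- as.matrix(dist(cbind(emb2$axis1, emb2$axis2)))
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("landscape overlays summarize density over the embedding", {
  set.seed(10)
  emb <- tibble::tibble(chain = "c1", index = 1:1000, iteration = 1:1000,
                        density = rep(1, 1000),
                        axis1 = runif(1000), axis2 = runif(1000))
  class(emb) <- c("mds_embedding", class(emb))
  hm <- landscape_overlay(emb, mode = "heatmap")
  expect_true(all(hm$mean_density == 1))
  top <- landscape_overlay(emb, mode = "top_fraction", f = 0.01)
  expect_equal(nrow(top), 10)
  sc <- landscape_overlay(emb, mode = "scatter3d")
  expect_named(sc, c("x", "y", "z", "chain"))
  expect_error(landscape_overlay(emb, density = 1:3), "length")
})

test_that("path profiles align scores with the valley path", {
  study <- stuck_study(seed = 4, n_taxa = 12, n_samples = 10, k = 5,
                       n_sites = 300)
  base <- study$peak_trees[[1]]
  spec <- study$specs[[1]]
  path <- nni_path_tip_relocation(base, spec$tip, spec$dest)
  scores <- vapply(path, function(t) fitch_score(t, study$alignment)$total,
                   integer(1))
  prof <- path_profile(path, scores)
  expect_equal(nrow(prof), length(path))
  expect_equal(prof$step, 0:(length(path) - 1))
  # the alignment was simulated on the base-peak topology: it minimizes score
  expect_equal(which.min(prof$score), 1)
  flat <- path_profile(path[1:3], c(2, 2, 2))
  expect_true(all(flat$score == 2))
})
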