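test_that("Fitch scores match hand-checkable cases", {
  tr <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_score(tr, aln_of(A = "A", B = "A", C = "T", D = "T"))$total, 1)
  expect_equal(fitch_score(tr, aln_of(A = "A", B = "C", C = "G", D = "T"))$total, 3)
  expect_equal(fitch_score(tr, aln_of(A = "-", B = "-", C = "-", D = "-"))$total, 0)
  expect_error(fitch_score(tr, aln_of(A = "A", B = "A", C = "T")),
               "missing from alignment")
})

test_that("Fitch equals exhaustive minimization on random fixtures", {
  for (i in 1:25) {
    n <- sample(4:7, 1)
    tr <- rand_tree(n, seed = 300 + i)
    aln <- rand_alignment(tr$tip.label, n_sites = 8, seed = 400 + i)
    expect_equal(fitch_score(tr, aln)$total, brute_force_parsimony(tr, aln),
                 info = sprintf("fixture %d", i))
  }
})

test_that("parsimony score is invariant to tip order and rerooting", {
  tr <- rand_tree(7, seed = 77)
  aln <- rand_alignment(tr$tip.label, n_sites = 12, seed = 78, p_ambig = 0)
  base <- fitch_score(tr, aln)$total
  # permuted alignment rows
  perm <- aln[sample(nrow(aln)), , drop = FALSE]
  class(perm) <- class(aln)
  expect_equal(fitch_score(tr, perm)$total, base)
  # reroot on several branches
  phy <- tr
  for (og in c("x01", "x04", "x06")) {
    re <- ape::root(ape::unroot(phy), outgroup = og, resolve.root = TRUE)
    re$edge.length <- rep(1, nrow(re$edge))
    expect_equal(fitch_score(rooted_tree(re), aln)$total, base)
  }
})

test_that("invariant columns add nothing; duplicated columns double", {
  tr <- rand_tree(6, seed = 81)
  aln <- rand_alignment(tr$tip.label, n_sites = 10, seed = 82, p_ambig = 0)
  base <- fitch_score(tr, aln)
  inv <- cbind(aln, rep(1L, nrow(aln)))
  class(inv) <- class(aln)
  expect_equal(fitch_score(tr, inv)$total, base$total)
  dup <- cbind(aln, aln[, 3])
  class(dup) <- class(aln)
  expect_equal(fitch_score(tr, dup)$total, base$total + base$site_scores[3])
})

test_that("branch mutation counts resolve a most-parsimonious history", {
  tr <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  bc <- branch_mutation_counts(tr, aln_of(A = "A", B = "A", C = "T", D = "T"))
  expect_equal(sum(bc$count), 1)
  expect_equal(sum(bc$count == 1), 1)

  same <- branch_mutation_counts(tr, aln_of(A = "ACG", B = "ACG",
                                            C = "ACG", D = "ACG"))
  expect_true(all(same$count == 0))

  for (i in 1:20) {
    tr8 <- rand_tree(8, seed = 500 + i)
    aln <- rand_alignment(tr8$tip.label, n_sites = 15, seed = 600 + i)
    expect_equal(sum(branch_mutation_counts(tr8, aln)$count),
                 fitch_score(tr8, aln)$total)
  }
})

test_that("phangorn agrees with the in-package Fitch totals", {
  skip_if_not_installed("phangorn")
  for (i in 1:5) {
    tr <- rand_tree(8, seed = 700 + i)
    aln <- rand_alignment(tr$tip.label, n_sites = 30, seed = 710 + i,
                          p_ambig = 0)
    chars <- do.call(rbind, lapply(seq_len(nrow(aln)), function(r) {
      c("a", "c", "g", "t")[log2(aln[r, ]) + 1]
    }))
    rownames(chars) <- rownames(aln)
    pd <- phangorn::phyDat(chars)
    expect_equal(fitch_score(tr, aln)$total,
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("parsimony traces track topology and conserve site totals", {
  study <- stuck_study(seed = 13, n_taxa = 10, n_samples = 20, k = 3,
                       n_sites = 80)
  trace <- study$traces[[1]]
  scores <- parsimony_trace(trace, study$alignment)
  expect_length(scores, 20)
  sites <- vapply(trace$trees,
                  function(t) fitch_score(t, study$alignment)$site_scores,
                  numeric(ncol(study$alignment)))
  expect_equal(colSums(sites), as.numeric(scores))
  one <- tree_trace(rep(list(trace$trees[[1]]), 12))
  expect_equal(length(unique(parsimony_trace(one, study$alignment))), 1)
})

test_that("dispersal events match brute-force Sankoff minima", {
  tr <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(dispersal_events(tr, c(A = "K", B = "K", C = "K", D = "K"))$total, 0)
  de <- dispersal_events(tr, c(A = "K", B = "K", C = "B", D = "B"))
  expect_equal(de$total, 1)
  expect_equal(sum(de$pairwise), de$total)

  set.seed(31)
  for (i in 1:15) {
    n <- sample(5:8, 1)
    tr_i <- rand_tree(n, seed = 800 + i)
    states <- c("E", "K", "W")
    traits <- setNames(sample(states, n, replace = TRUE), tr_i$tip.label)
    got <- dispersal_events(tr_i, traits)
    oracle <- sankoff_min_changes(
      tr_i, lapply(traits[tr_i$tip.label], function(s) match(s, states)), 3
    )
    expect_equal(got$total, oracle, info = sprintf("fixture %d", i))
    expect_equal(sum(got$pairwise), got$total)
  }
  expect_error(dispersal_events(tr, c(A = "K", B = "K", C = "B")),
               "without location")
  miss <- dispersal_events(tr, c(A = "K", B = "K", C = "B"),
                           allow_missing = TRUE)
  expect_lte(miss$total, 1)
})

test_that("difference sites require disjoint state sets", {
  aln <- aln_of(A = "ACGTACGTAC", B = "ACGTACGTAC")
  expect_length(pairwise_difference_sites(aln, "A", "B"), 0)
  aln2 <- aln_of(A = "ACGTACGTAC", B = "ACTTACGTAG")
  expect_equal(pairwise_difference_sites(aln2, "A", "B"), c(3L, 10L))
  ambig <- aln_of(A = "A", B = "R") # R = {A,G} intersects {A}
  expect_length(pairwise_difference_sites(ambig, "A", "B"), 0)
  expect_error(pairwise_difference_sites(aln, "A", "Z"), "unknown taxon")
})

test_that("sequence screens quantify missingness and divergence", {
  seqs <- c(A = paste(rep("ACG", 30), collapse = ""),
            B = paste(rep("ACG", 30), collapse = ""),
            C = paste(rep("ACG", 30), collapse = ""))
  # 10 gaps among 90 sites, all at third codon positions
  gapped <- strsplit(seqs[["A"]], "")[[1]]
  gapped[seq(3, 30, by = 3)] <- "-"
  aln <- read_alignment(seqs = c(A = paste(gapped, collapse = ""),
                                 B = seqs[["B"]], C = seqs[["C"]]))
  scr <- sequence_screen(aln, "A", c("B", "C"))
  expect_equal(scr$missing_fraction, 10 / 90, tolerance = 1e-12)
  expect_equal(scr$missing_by_codon_position, c(0, 0, 1))
  expect_true(all(scr$hamming_profile == 0)) # gaps overlap everything
  expect_equal(nrow(scr$windowed_density), 3)
  expect_error(sequence_screen(aln, "A", character()), "empty")
})
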