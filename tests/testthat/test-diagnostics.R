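test_that("ESS approaches N for i.i.d. series and stays in [1, N]", {
  for (n in c(200, 1000, 5000)) {
    set.seed(n)
    e <- ess(rnorm(n))
    expect_gte(e, 0.85 * n)
    expect_lte(e, n)
  }
})

test_that("ESS matches the analytic AR(1) autocorrelation time", {
  set.seed(42)
  n <- 10000
  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), n))
  expected <- n * (1 - rho) / (1 + rho) # ~ 526
  e <- ess(x)
  expect_gt(e, expected * 0.85)
  expect_lt(e, expected * 1.15)
  # independent implementation agrees to within estimator noise
  skip_if_not_installed("coda")
  expect_lt(abs(e - coda::effectiveSize(x)) / e, 0.3)
})

test_that("zero-variance series yield an undefined (NaN) ESS with a warning", {
  expect_warning(out <- ess(rep(2, 100)), "zero-variance")
  expect_true(is.nan(out))
})

test_that("rank-normalized split R-hat is ~1 under the null, large under shift", {
  set.seed(7)
  null_chains <- replicate(4, rnorm(1000), simplify = FALSE)
  expect_lt(psrf(null_chains), 1.02)

  shifted <- c(replicate(2, rnorm(1000, 0), simplify = FALSE),
               replicate(2, rnorm(1000, 3), simplify = FALSE))
  expect_gt(psrf(shifted), 1.5)

  expect_true(is.nan(psrf(replicate(3, rep(1.5, 100), simplify = FALSE))))
  expect_error(psrf(list(rnorm(100))), "length")
})

test_that("R-hat is invariant under a common affine transform of all chains", {
  set.seed(8)
  chains <- replicate(3, cumsum(rnorm(400)), simplify = FALSE)
  r1 <- psrf(chains)
  r2 <- psrf(lapply(chains, function(x) 3.2 * x - 17))
  expect_equal(r1, r2)
})

test_that("internally constant but different chains give infinite R-hat", {
  expect_identical(psrf(list(rep(0, 100), rep(1, 100))), Inf)
})

test_that("SDCF and ASDCF follow their defining arithmetic", {
  tab <- tibble::tibble(
    clade = c("A|B", "C|D"), size = c(2L, 2L),
    freq_c1 = c(1, 0.5), freq_c2 = c(0, 0.5),
    pooled = c(0.5, 0.5), sdcf = c(sd(c(1, 0)), 0)
  )
  class(tab) <- c("clade_table", class(tab))
  expect_equal(sdcf("A|B", tab), 0.7071, tolerance = 1e-4)
  expect_equal(asdcf(tab), mean(c(sd(c(1, 0)), 0)))
  tab2 <- tab
  tab2$sdcf <- c(0.2, 0)
  expect_equal(asdcf(tab2), 0.1)
  tab2$sdcf <- c(0, 0)
  expect_equal(asdcf(tab2), 0)
})

test_that("clade ESS treats occurrence as a binary series", {
  set.seed(5)
  iid <- rbinom(2000, 1, 0.5)
  expect_gte(clade_ess(iid), 1700)

  # sticky two-state chain: rho = 2p - 1; average replicate chains to damp
  # the estimator's single-realization noise
  p <- 0.98
  e <- mean(vapply(1:5, function(rep) {
    x <- integer(2000)
    flips <- runif(1999) > p
    for (i in 2:2000) x[i] <- if (flips[i - 1]) 1L - x[i - 1] else x[i - 1]
    clade_ess(x)
  }, numeric(1)))
  rho <- 2 * p - 1
  expected <- 2000 * (1 - rho) / (1 + rho) # ~ 41
  expect_gt(e, expected * 0.6)
  expect_lt(e, expected * 1.4)

  expect_true(is.na(clade_ess(rep(1L, 500))))
})

test_that("tree pseudo-ESS reflects topological mixing", {
  one_topo <- tree_trace(rep(list(rt("((A:1,B:1):1,(C:1,D:1):1);")), 20))
  expect_true(is.nan(tree_pseudo_ess(one_topo)))

  # near-i.i.d. diffuse sampling: independent coalescent topologies
  trees <- lapply(1:200, function(i) rand_tree(8, seed = 1000 + i))
  diffuse <- tree_trace(trees)
  expect_gte(tree_pseudo_ess(diffuse, seed = 2), 0.6 * 200)

  # sticky two-peak trace: pseudo-ESS tracks the membership indicator's ESS
  study <- synthetic_study(n_taxa = 12, n_wobblers = 1, k = 4, n_chains = 1,
                           n_samples = 400, stay_prob = 0.96, n_sites = 30,
                           seed = 21)
  trace <- study$traces[[1]]
  member <- as.integer(study$truth$peak[study$truth$chain == "chain1"] == 2)
  skip_if(length(unique(member)) < 2)
  e_ind <- clade_ess(member)
  e_tree <- tree_pseudo_ess(trace, seed = 3)
  expect_gt(e_tree, 0.5 * e_ind)
  expect_lt(e_tree, 1.5 * e_ind)
})

test_that("tree PSRF separates stuck from well-mixed chains", {
  stuck <- stuck_study(seed = 4, n_taxa = 12, n_samples = 30, k = 4,
                       n_sites = 30)
  expect_gt(tree_psrf(stuck$traces), 1.1)

  mixing <- synthetic_study(n_taxa = 12, n_wobblers = 1, k = 4, n_chains = 2,
                            n_samples = 300, stay_prob = 0.5, n_sites = 30,
                            seed = 6)
  expect_lt(tree_psrf(mixing$traces), 1.05)

  copied <- stuck$traces[[1]]
  r <- tree_psrf(list(copied, copied))
  expect_true(is.nan(r) || abs(r - 1) < 0.05)
  expect_error(tree_psrf(list(copied)), "2 chains")
})

test_that("diagnose aggregates and flags according to thresholds", {
  # converged: one peak, i.i.d.-like topologies? a single-peak study never
  # leaves its topology, so tree-level diagnostics are undefined but nothing
  # fails; parameter series behave like white noise
  tr1 <- rt("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(9)
  params <- lapply(1:2, function(i) {
    p <- tibble::tibble(iteration = 1:50, posterior = rnorm(50))
    class(p) <- c("param_trace", class(p))
    p
  })
  conv <- diagnose(list(tree_trace(rep(list(tr1), 50), chain_id = "c1"),
                        tree_trace(rep(list(tr1), 50), chain_id = "c2")),
                   params = params)
  expect_false(any(conv$tree$fail))
  expect_equal(conv$tree$value[conv$tree$statistic == "asdcf"], 0)

  stuck <- stuck_study(seed = 4, n_taxa = 12, n_samples = 30, k = 4,
                       n_sites = 60)
  rep1 <- diagnose(stuck$traces, alignment = stuck$alignment)
  tv <- setNames(rep1$tree$fail, rep1$tree$statistic)
  expect_true(tv[["tree_psrf"]])
  expect_true(tv[["asdcf"]])
  expect_true(rep1$parsimony$fail[rep1$parsimony$statistic == "parsimony_psrf"])

  # relaxing the ASDCF cutoff can only reduce failures
  rep2 <- diagnose(stuck$traces, alignment = stuck$alignment,
                   thresholds = diagnostic_thresholds(asdcf_max = 0.02))
  count_fails <- function(r) {
    sum(c(r$tree$fail, r$parsimony$fail, r$clades$poor), na.rm = TRUE)
  }
  expect_lte(count_fails(rep2), count_fails(rep1))
})

test_that("tidy and glance expose the report in broom shape", {
  stuck <- stuck_study(seed = 4, n_taxa = 10, n_samples = 20, k = 3,
                       n_sites = 40)
  rep1 <- diagnose(stuck$traces, params = stuck$params,
                   alignment = stuck$alignment)
  td <- tidy(rep1)
  expect_true(all(c("level", "name", "statistic", "value", "fail") %in% names(td)))
  expect_true(all(c("variable", "tree", "parsimony", "clade", "site") %in% td$level))
  gl <- glance(rep1)
  expect_equal(nrow(gl), 1)
  expect_false(gl$converged)
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
})
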