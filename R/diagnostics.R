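# MCMC diagnostics: ESS (initial-positive-sequence truncation), rank-normalized
# split-Rhat, clade-frequency SDs, and their tree-level analogues built from
# distance-to-reference traces.

#' Effective sample size of a continuous series
#'
#' `ESS = N / (1 + 2 * sum(rho_k))`, with sample autocorrelations summed from
#' lag 1 and truncated by the initial-positive-sequence rule: summation stops
#' before the first lag pair `(2k, 2k+1)` whose autocorrelations sum to <= 0.
#' Maximum lag is `min(N - 1, 2000)`. The result is clipped to `[1, N]`.
#'
#' @param series Numeric vector, length >= 10.
#' @return ESS, or `NaN` (with a warning) for a zero-variance series.
#' @examples
#' set.seed(1)
#' ess(rnorm(1000)) # close to 1000
#' @export
ess <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  stopifnot(n >= 10, all(is.finite(series)))
  if (var(series) == 0) {
    warn("zero-variance series: ESS undefined")
    return(NaN)
  }
  max_lag <- min(n - 1L, 2000L)
  rho <- as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  s <- 0
  k <- 1L
  while (k <= length(rho)) {
    if (k + 1L <= length(rho)) {
      if (rho[k] + rho[k + 1L] <= 0) break
      s <- s + rho[k] + rho[k + 1L]
      k <- k + 2L
    } else {
      if (rho[k] > 0) s <- s + rho[k]
      break
    }
  }
  min(max(n / (1 + 2 * s), 1), n)
}

#' Rank-normalized split potential scale reduction factor
#'
#' Each chain is split in half, the pooled samples are rank-transformed to
#' normal scores (`qnorm((r - 3/8) / (S + 1/4))`), and the classical
#' `sqrt(((N-1)/N * W + B/N) / W)` statistic is computed over the half-chains.
#' Chains are truncated to the shortest length first.
#'
#' @param chains List of numeric vectors (>= 2 chains, each N >= 10).
#' @param rank_normalize Set `FALSE` for the classical R-hat on the original
#'   scale.
#' @return The split R-hat; `NaN` when the pooled sample is constant, `Inf`
#'   when every half-chain is internally constant but the chains differ (no
#'   mixing at all between distinct values).
#' @export
psrf <- function(chains, rank_normalize = TRUE) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- min(lengths(chains))
  stopifnot(n >= 10)
  chains <- lapply(chains, function(x) as.numeric(x[seq_len(n)]))
  half <- floor(n / 2)
  halves <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[seq.int(n - half + 1L, n)])
  }), recursive = FALSE)
  pooled <- unlist(halves)
  if (var(pooled) == 0) return(NaN)
  if (rank_normalize) {
    s <- length(pooled)
    z <- stats::qnorm((rank(pooled, ties.method = "average") - 3 / 8) / (s + 1 / 4))
    halves <- split(z, rep(seq_along(halves), each = half))
  }
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(Inf) # pooled variance > 0: between-chain only
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Clade-frequency convergence diagnostics (SDCF / ASDCF)
#'
#' SDCF is the sample SD (denominator m - 1) of a clade's per-chain
#' frequencies; ASDCF averages SDCF over all clades in the table.
#'
#' @param table A `clade_table` from [clade_frequencies()].
#' @param clade A clade key for `sdcf()`.
#' @return A single numeric value.
#' @export
asdcf <- function(table) {
  if (!nrow(table)) return(NaN)
  mean(table$sdcf)
}

#' @rdname asdcf
#' @export
sdcf <- function(clade, table) {
  key <- as_clade_key(clade)
  hit <- match(key, table$clade)
  if (is.na(hit)) return(0) # never observed: frequency 0 in every chain
  unname(table$sdcf[hit])
}

#' ESS of a clade's binary occurrence trace
#'
#' @param occurrence Integer 0/1 vector from [clade_occurrence_trace()].
#' @return ESS, or `NA` when the clade occurs in all or no samples (such
#'   traces carry no mixing information and are reported as skipped).
#' @export
clade_ess <- function(occurrence) {
  if (length(unique(occurrence)) < 2) return(NA_real_)
  ess(occurrence)
}

#' Topology pseudo-ESS of a tree trace
#'
#' Picks `n_refs` reference trees uniformly from the trace (seeded), computes
#' the rooted-RF distance from every sample to each reference, applies [ess()]
#' to each distance trace, and returns the median.
#'
#' @param trace A `tree_trace`.
#' @param n_refs Number of reference trees.
#' @param seed RNG seed for reference choice.
#' @return Median ESS over references; `NaN` when all sampled topologies are
#'   identical.
#' @export
tree_pseudo_ess <- function(trace, n_refs = 5, seed = 1) {
  n <- n_samples(trace)
  stopifnot(n >= 10)
  keys <- vapply(trace$trees, topology_key, character(1))
  if (length(unique(keys)) == 1) return(NaN)
  refs <- sample_with_seed(seq_len(n), min(n_refs, n), seed)
  vals <- vapply(refs, function(r) {
    d <- vapply(trace$trees, rf_rooted, numeric(1), t2 = trace$trees[[r]])
    if (var(d) == 0) return(NA_real_)
    ess(d)
  }, numeric(1))
  median(vals, na.rm = TRUE)
}

#' Topology PSRF across chains
#'
#' Picks `n_refs` reference trees from the pooled samples, applies [psrf()] to
#' the per-chain distance-to-reference traces, and returns the maximum over
#' references (the most pessimistic view).
#'
#' @param traces List of `tree_trace` objects (>= 2).
#' @inheritParams tree_pseudo_ess
#' @return Max split R-hat over references; `NaN` when every sampled tree is
#'   topologically identical.
#' @export
tree_psrf <- function(traces, n_refs = 5, seed = 1) {
  traces <- as_trace_list(traces)
  if (length(traces) < 2) abort("tree_psrf needs >= 2 chains")
  n <- min(vapply(traces, n_samples, integer(1)))
  traces <- lapply(traces, truncate_trace, n = n)
  pool <- unlist(lapply(traces, function(x) x$trees), recursive = FALSE)
  refs <- sample_with_seed(seq_along(pool), min(n_refs, length(pool)), seed)
  vals <- vapply(refs, function(r) {
    dists <- lapply(traces, function(tr) {
      vapply(tr$trees, rf_rooted, numeric(1), t2 = pool[[r]])
    })
    psrf(dists)
  }, numeric(1))
  if (all(is.nan(vals))) NaN else max(vals, na.rm = TRUE)
}

truncate_trace <- function(trace, n) {
  tree_trace(trace$trees[seq_len(n)], trace$iterations[seq_len(n)],
             trace$chain_id, trace$density[seq_len(n)])
}

sample_with_seed <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x, size)
}

#' Diagnostic pass/fail thresholds
#'
#' Standard cutoffs: minimum ESS 200, maximum PSRF 1.1, maximum ASDCF 0.01
#' (0.02 as the lenient alternative), SDCF above 0.1 marks a nonconverging
#' clade.
#'
#' @param ess_min,psrf_max,asdcf_max,sdcf_nonconverged Cutoff values.
#' @return A `diagnostic_thresholds` list.
#' @export
diagnostic_thresholds <- function(ess_min = 200, psrf_max = 1.1,
                                  asdcf_max = 0.01, sdcf_nonconverged = 0.1) {
  stopifnot(ess_min > 0, psrf_max > 0, asdcf_max > 0, asdcf_max < 1,
            sdcf_nonconverged > 0)
  structure(list(ess_min = ess_min, psrf_max = psrf_max,
                 asdcf_max = asdcf_max,
                 sdcf_nonconverged = sdcf_nonconverged),
            class = "diagnostic_thresholds")
}

#' Aggregated MCMC diagnosis of a phylodynamic study
#'
#' Computes, from whatever inputs are supplied, the full diagnostic report:
#' per-variable ESS/PSRF from parameter logs; tree pseudo-ESS, tree PSRF and
#' ASDCF from the tree traces; parsimony-score and per-site parsimony
#' diagnostics when an alignment is given; per-clade occurrence ESS and SDCF;
#' and fraction-of-poorly-sampled summaries, each flagged against the
#' thresholds. Chains are truncated to the shortest length before any
#' cross-chain statistic.
#'
#' @param traces List of `tree_trace` objects (>= 1).
#' @param params Optional list of `param_trace` tibbles aligned to chains.
#' @param alignment Optional `dna_alignment` covering all tips.
#' @param thresholds A [diagnostic_thresholds()].
#' @param n_refs,seed Passed to the tree-level diagnostics.
#' @param min_clade_freq Optional pooled-frequency filter for the clade table
#'   before ASDCF (default 0 = keep all clades).
#' @return A `treerug_report` (see [tidy.treerug_report()]).
#' @export
diagnose <- function(traces, params = NULL, alignment = NULL,
                     thresholds = diagnostic_thresholds(),
                     n_refs = 5, seed = 1, min_clade_freq = 0) {
  traces <- as_trace_list(traces)
  n <- min(vapply(traces, n_samples, integer(1)))
  traces <- lapply(traces, truncate_trace, n = n)
  m <- length(traces)
  chain_ids <- vapply(traces, function(x) x$chain_id, character(1))

  # --- continuous variables ---
  var_tbl <- NULL
  if (!is.null(params)) {
    if (inherits(params, "param_trace")) params <- list(params)
    vars <- setdiff(names(params[[1]]), "iteration")
    np <- min(vapply(params, nrow, integer(1)))
    var_tbl <- purrr::map_dfr(vars, function(v) {
      series <- lapply(params, function(p) p[[v]][seq_len(np)])
      esses <- vapply(series, function(x) {
        if (var(x) == 0) NaN else ess(x)
      }, numeric(1))
      rhat <- if (m >= 2 || length(series) >= 2) psrf(series) else NA_real_
      tibble::tibble(
        variable = v, mean_ess = mean(esses), psrf = rhat,
        ess_fail = !is.nan(mean(esses)) & mean(esses) < thresholds$ess_min,
        psrf_fail = !is.na(rhat) & !is.nan(rhat) & rhat > thresholds$psrf_max
      )
    })
  }

  # --- clade-level ---
  ctab <- clade_frequencies(traces)
  ctab_f <- if (min_clade_freq > 0) {
    ctab[ctab$pooled >= min_clade_freq & ctab$pooled <= 1 - min_clade_freq, ]
  } else ctab
  occ <- attr(ctab, "occurrence")
  clade_tbl <- tibble::tibble(
    clade = ctab$clade, size = ctab$size, pooled = ctab$pooled,
    sdcf = ctab$sdcf,
    ess = vapply(seq_len(nrow(ctab)), function(i) {
      per_chain <- vapply(occ, function(mch) {
        tr <- mch[i, ]
        if (length(unique(tr)) < 2) NA_real_ else ess(tr)
      }, numeric(1))
      if (all(is.na(per_chain))) NA_real_ else mean(per_chain, na.rm = TRUE)
    }, numeric(1))
  )
  clade_tbl$nonconverged <- !is.na(clade_tbl$sdcf) &
    clade_tbl$sdcf > thresholds$sdcf_nonconverged
  clade_tbl$poor <- (!is.na(clade_tbl$ess) & clade_tbl$ess < thresholds$ess_min &
                       clade_tbl$pooled > 0 & clade_tbl$pooled < 1) |
    clade_tbl$nonconverged %in% TRUE

  # --- tree-level ---
  pseudo <- vapply(traces, tree_pseudo_ess, numeric(1), n_refs = n_refs,
                   seed = seed)
  tpsrf <- if (m >= 2) tree_psrf(traces, n_refs = n_refs, seed = seed) else NA_real_
  asdcf_val <- if (m >= 2) asdcf(ctab_f) else NA_real_
  tree_tbl <- tibble::tibble(
    statistic = c("tree_pseudo_ess", "tree_psrf", "asdcf"),
    value = c(mean(pseudo, na.rm = FALSE), tpsrf, asdcf_val),
    fail = c(
      !is.nan(mean(pseudo)) & mean(pseudo) < thresholds$ess_min,
      !is.na(tpsrf) & !is.nan(tpsrf) & tpsrf > thresholds$psrf_max,
      !is.na(asdcf_val) & asdcf_val > thresholds$asdcf_max
    )
  )

  # --- parsimony-score + per-site ---
  pars_tbl <- NULL
  site_tbl <- NULL
  if (!is.null(alignment)) {
    site_scores <- lapply(traces, function(tr) {
      m <- vapply(tr$trees, function(t) fitch_score(t, alignment)$site_scores,
                  numeric(ncol(alignment)))
      matrix(m, nrow = ncol(alignment))
    }) # sites x samples, one matrix per chain
    scores <- lapply(site_scores, colSums)
    p_ess <- vapply(scores, function(x) {
      if (var(x) == 0) NaN else ess(x)
    }, numeric(1))
    p_psrf <- if (m >= 2) psrf(scores) else NA_real_
    pars_tbl <- tibble::tibble(
      statistic = c("parsimony_ess", "parsimony_psrf"),
      value = c(mean(p_ess), p_psrf),
      fail = c(!is.nan(mean(p_ess)) & mean(p_ess) < thresholds$ess_min,
               !is.na(p_psrf) & !is.nan(p_psrf) & p_psrf > thresholds$psrf_max)
    )
    site_tbl <- purrr::map_dfr(seq_len(ncol(alignment)), function(j) {
      series <- lapply(site_scores, function(mch) mch[j, ])
      variable_site <- any(vapply(series, var, numeric(1)) > 0)
      s_ess <- if (variable_site) {
        mean(vapply(series, function(x) if (var(x) == 0) NA_real_ else ess(x),
                    numeric(1)), na.rm = TRUE)
      } else NA_real_
      s_psrf <- if (m >= 2 && var(unlist(series)) > 0) psrf(series) else NA_real_
      tibble::tibble(site = j, ess = s_ess, psrf = s_psrf,
                     poor = (!is.na(s_ess) & s_ess < thresholds$ess_min) |
                       (!is.na(s_psrf) & !is.nan(s_psrf) & s_psrf > thresholds$psrf_max))
    })
  }

  fractions <- tibble::tibble(
    level = c("clades", "sites"),
    evaluated = c(nrow(clade_tbl),
                  if (is.null(site_tbl)) NA_integer_ else nrow(site_tbl)),
    failing = c(sum(clade_tbl$poor),
                if (is.null(site_tbl)) NA_integer_ else sum(site_tbl$poor)),
  )
  fractions$fraction <- fractions$failing / fractions$evaluated

  structure(
    list(
      chains = chain_ids, n_samples = n, thresholds = thresholds,
      variables = var_tbl, tree = tree_tbl, parsimony = pars_tbl,
      clades = clade_tbl, sites = site_tbl, fractions = fractions,
      clade_table = ctab
    ),
    class = "treerug_report"
  )
}

#' @export
print.treerug_report <- function(x, ...) {
  cat(sprintf("MCMC diagnostics: %d chain(s) x %d samples\n",
              length(x$chains), x$n_samples))
  tv <- x$tree
  for (i in seq_len(nrow(tv))) {
    cat(sprintf("  %-16s %8.4g  %s\n", tv$statistic[i], tv$value[i],
                flag_word(tv$fail[i], tv$value[i])))
  }
  if (!is.null(x$parsimony)) {
    for (i in seq_len(nrow(x$parsimony))) {
      cat(sprintf("  %-16s %8.4g  %s\n", x$parsimony$statistic[i],
                  x$parsimony$value[i],
                  flag_word(x$parsimony$fail[i], x$parsimony$value[i])))
    }
  }
  fr <- x$fractions
  for (i in seq_len(nrow(fr))) {
    if (!is.na(fr$evaluated[i])) {
      cat(sprintf("  poorly sampled %s: %d/%d (%.1f%%)\n", fr$level[i],
                  fr$failing[i], fr$evaluated[i], 100 * fr$fraction[i]))
    }
  }
  invisible(x)
}

flag_word <- function(fail, value) {
  if (is.na(value) || is.nan(value)) "undefined" else if (isTRUE(fail)) "FAIL" else "ok"
}

#' Tidy a diagnostics report
#'
#' `tidy()` returns one row per diagnostic (level, name, value, flag);
#' `glance()` returns a one-row summary with the headline statistics and an
#' overall `converged` verdict.
#'
#' @param x A `treerug_report`.
#' @param ... Unused.
#' @method tidy treerug_report
#' @export
tidy.treerug_report <- function(x, ...) {
  out <- dplyr::bind_rows(
    if (!is.null(x$variables)) {
      dplyr::bind_rows(
        dplyr::transmute(x$variables, level = "variable", name = variable,
                         statistic = "mean_ess", value = mean_ess,
                         fail = ess_fail),
        dplyr::transmute(x$variables, level = "variable", name = variable,
                         statistic = "psrf", value = psrf, fail = psrf_fail)
      )
    },
    dplyr::transmute(x$tree, level = "tree", name = statistic,
                     statistic = statistic, value = value, fail = fail),
    if (!is.null(x$parsimony)) {
      dplyr::transmute(x$parsimony, level = "parsimony", name = statistic,
                       statistic = statistic, value = value, fail = fail)
    },
    dplyr::bind_rows(
      dplyr::transmute(x$clades, level = "clade", name = clade,
                       statistic = "sdcf", value = sdcf, fail = nonconverged),
      dplyr::transmute(x$clades, level = "clade", name = clade,
                       statistic = "ess", value = ess,
                       fail = !is.na(ess) & ess < x$thresholds$ess_min)
    ),
    if (!is.null(x$sites)) {
      dplyr::transmute(x$sites, level = "site", name = as.character(site),
                       statistic = "psrf", value = psrf, fail = poor)
    }
  )
  tibble::as_tibble(out)
}

#' @rdname tidy.treerug_report
#' @method glance treerug_report
#' @export
glance.treerug_report <- function(x, ...) {
  tv <- setNames(x$tree$value, x$tree$statistic)
  pv <- if (!is.null(x$parsimony)) setNames(x$parsimony$value, x$parsimony$statistic)
  fails <- c(x$tree$fail, if (!is.null(x$parsimony)) x$parsimony$fail)
  tibble::tibble(
    n_chains = length(x$chains), n_samples = x$n_samples,
    tree_pseudo_ess = tv[["tree_pseudo_ess"]],
    tree_psrf = tv[["tree_psrf"]],
    asdcf = tv[["asdcf"]],
    parsimony_ess = if (is.null(pv)) NA_real_ else pv[["parsimony_ess"]],
    parsimony_psrf = if (is.null(pv)) NA_real_ else pv[["parsimony_psrf"]],
    frac_poor_clades = x$fractions$fraction[x$fractions$level == "clades"],
    converged = !any(fails, na.rm = TRUE)
  )
}

#' Clade diagnostics scatter (SDCF vs clade ESS)
#'
#' The per-clade analogue of the classic PSRF-vs-ESS quadrant plot: each point
#' is a clade, colored by pooled frequency, with cutoff lines marking the
#' poorly mixing (left) and nonconverging (top) regions.
#'
#' @param object A `treerug_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot treerug_report
#' @export
autoplot.treerug_report <- function(object, ...) {
  df <- object$clades
  th <- object$thresholds
  ggplot2::ggplot(df, ggplot2::aes(x = ess, y = sdcf, color = pooled)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = th$sdcf_nonconverged, linetype = 2) +
    ggplot2::geom_vline(xintercept = th$ess_min, linetype = 2) +
    ggplot2::scale_color_viridis_c(name = "clade freq", limits = c(0, 1)) +
    ggplot2::labs(x = "clade ESS", y = "SDCF") +
    ggplot2::theme_minimal()
}

#' Serialize a report
#' @param report A `treerug_report`.
#' @param path Base path; writes `<path>.json` and `<path>_diagnostics.tsv`.
#' @export
write_report <- function(report, path) {
  tall <- tidy.treerug_report(report)
  utils::write.table(as.data.frame(tall), paste0(path, "_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- glance.treerug_report(report)
  jsonlite::write_json(as.list(gl), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
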