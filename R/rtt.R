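# Root-to-tip regression: place the root at the point of the tree (searched
# continuously along every branch) minimizing the residual sum of squares of
# the regression of root-to-tip genetic distance on sampling date. The slope
# estimates the clock rate; studentized residual outliers flag sequences with
# incongruent dates or genetic composition.

#' Root-to-tip regression with RMS-residual rooting
#'
#' For every branch, the RSS of the OLS fit of root-to-tip distance on
#' sampling date is a quadratic function of the root position along that
#' branch; it is minimized analytically per branch and the global optimum
#' taken (ties broken by the smallest branch index).
#'
#' @param tree A `phylo` whose edge lengths are genetic distances
#'   (substitutions/site); may be rooted or unrooted.
#' @param dates Tip sampling dates: named numeric vector (decimal years) or a
#'   tibble with columns `taxon`, `date`.
#' @return An `rtt_fit` list: `root_edge` (edge row in the input tree),
#'   `position` (distance of the root from the child end of that edge),
#'   `slope`, `intercept`, `x_intercept`, `r_squared`, `rss`, and `tips`
#'   (tibble: taxon, date, distance, residual, studentized).
#' @export
rtt_fit <- function(tree, dates) {
  if (is.data.frame(dates)) dates <- setNames(dates$date, dates$taxon)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  n_tip <- ape::Ntip(tree)
  tips <- tree$tip.label
  t_obs <- dates[tips]
  if (anyNA(t_obs)) {
    abort(paste0("tips without dates: ", paste(tips[is.na(t_obs)], collapse = ", ")))
  }
  if (length(unique(t_obs)) < 2) {
    abort("all sampling dates equal: no temporal signal possible")
  }
  dmat <- ape::dist.nodes(tree) # path distances, effectively unrooted
  edge <- tree$edge
  # tips below each node
  n_all <- n_tip + tree$Nnode
  below <- vector("list", n_all)
  below[seq_len(n_tip)] <- as.list(seq_len(n_tip))
  for (i in rev(seq_len(nrow(edge)))) {
    below[[edge[i, 1]]] <- c(below[[edge[i, 1]]], below[[edge[i, 2]]])
  }
  x_mat <- cbind(1, t_obs)
  hat <- x_mat %*% solve(crossprod(x_mat), t(x_mat))
  m_proj <- diag(n_tip) - hat

  best <- list(rss = Inf, edge = NA_integer_, x = NA_real_)
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    len <- tree$edge.length[e]
    in_v <- seq_len(n_tip) %in% below[[v]]
    s <- ifelse(in_v, 1, -1)
    d0 <- ifelse(in_v, dmat[v, seq_len(n_tip)], len + dmat[u, seq_len(n_tip)])
    md <- m_proj %*% d0
    ms <- m_proj %*% s
    a <- sum(ms * ms)
    b <- 2 * sum(md * ms)
    cc <- sum(md * md)
    x_star <- if (a > 0) min(max(-b / (2 * a), 0), len) else 0
    rss <- a * x_star^2 + b * x_star + cc
    if (rss < best$rss - 1e-12) best <- list(rss = rss, edge = e, x = x_star)
  }
  e <- best$edge
  u <- edge[e, 1]; v <- edge[e, 2]
  len <- tree$edge.length[e]
  in_v <- seq_len(n_tip) %in% below[[v]]
  d <- ifelse(in_v, dmat[v, seq_len(n_tip)] + best$x,
              (len - best$x) + dmat[u, seq_len(n_tip)])
  fit <- stats::lm(d ~ t_obs)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  stud <- suppressWarnings(stats::rstandard(fit))
  # an (essentially) exact fit has no outliers: the studentization divides
  # rounding noise by rounding noise
  if (sum(res^2) <= 1e-16 * sum((d - mean(d))^2)) stud <- rep(0, length(stud))
  out <- list(
    root_edge = e, position = best$x,
    slope = unname(co[2]), intercept = unname(co[1]),
    x_intercept = unname(-co[1] / co[2]),
    r_squared = summary(fit)$r.squared,
    rss = sum(res^2),
    tips = tibble::tibble(taxon = tips, date = unname(t_obs),
                          distance = d, residual = unname(res),
                          studentized = unname(stud)),
    n = n_tip
  )
  class(out) <- "rtt_fit"
  out
}

#' @export
print.rtt_fit <- function(x, ...) {
  cat(sprintf(
    "Root-to-tip regression: %d tips\n  rate %.4g subs/site/yr, origin %.2f, R^2 %.3f\n",
    x$n, x$slope, x$x_intercept, x$r_squared
  ))
  invisible(x)
}

#' @method tidy rtt_fit
#' @export
tidy.rtt_fit <- function(x, ...) x$tips

#' @method glance rtt_fit
#' @export
glance.rtt_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, x_intercept = x$x_intercept,
    r_squared = x$r_squared, rss = x$rss, root_edge = x$root_edge,
    position = x$position, n = x$n
  )
}

#' @method autoplot rtt_fit
#' @export
autoplot.rtt_fit <- function(object, cutoff = 3, ...) {
  df <- object$tips
  df$outlier <- abs(df$studentized) > cutoff
  ggplot2::ggplot(df, ggplot2::aes(x = date, y = distance, color = outlier)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "sampling date", y = "root-to-tip distance") +
    ggplot2::theme_minimal()
}

#' Flag root-to-tip outliers
#'
#' Tips whose internally studentized residual exceeds `cutoff` in absolute
#' value.
#'
#' @param fit An `rtt_fit` (>= 4 tips).
#' @param cutoff Studentized-residual threshold.
#' @return Character vector of tip labels.
#' @export
rtt_outliers <- function(fit, cutoff = 3.0) {
  stopifnot(inherits(fit, "rtt_fit"), fit$n >= 4)
  fit$tips$taxon[abs(fit$tips$studentized) > cutoff]
}
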