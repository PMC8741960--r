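# Longitudinal perfusion statistics: percent change versus baseline and
# one-way ANOVA with Dunnett many-to-one multiple-comparison correction.

#' Percent reduction of a later mean relative to baseline
#'
#' `100 * (1 - later_mean / baseline_mean)`; positive values are reductions.
#'
#' @param baseline_mean Baseline group mean (must be > 0).
#' @param later_mean Later-timepoint group mean.
#' @return Percent change on the 0-100 scale (negative if perfusion rose).
#' @examples
#' percent_change(139, 104) # ~25 % reduction
#' percent_change(139, 84)  # ~40 % reduction
#' @export
percent_change <- function(baseline_mean, later_mean) {
  if (!is.numeric(baseline_mean) || length(baseline_mean) != 1L ||
      !is.finite(baseline_mean) || baseline_mean <= 0) {
    stop("`baseline_mean` must be a single positive number", call. = FALSE)
  }
  stopifnot_scalar_number(later_mean, "later_mean")
  100 * (1 - later_mean / baseline_mean)
}

#' Pre/post reduction ratio
#'
#' Generic pre/post-dialyzer arithmetic: `(pre - post) / pre`, the fraction
#' by which a solute concentration drops across the dialyzer.
#'
#' @param pre Pre-dialyzer value (must be > 0).
#' @param post Post-dialyzer value.
#' @return Fraction removed.
#' @export
reduction_ratio <- function(pre, post) {
  if (!is.numeric(pre) || length(pre) != 1L || !is.finite(pre) || pre <= 0) {
    stop("`pre` must be a single positive number", call. = FALSE)
  }
  stopifnot_scalar_number(post, "post")
  (pre - post) / pre
}

#' Assemble a group table for many-to-one comparisons
#'
#' @param values Named list of numeric vectors, one per group. The first
#'   element is the control (baseline) group, or use `control` to name it.
#' @param control Name of the control group (defaults to the first element).
#' @return An object of class `group_table`.
#' @export
group_table <- function(values, control = NULL) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("`values` must be a named list of numeric vectors", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("group names must be unique", call. = FALSE)
  }
  if (is.null(control)) control <- names(values)[1L]
  if (!control %in% names(values)) {
    stop(sprintf("control group '%s' not found", control), call. = FALSE)
  }
  values <- c(values[control], values[setdiff(names(values), control)])
  for (g in names(values)) {
    v <- values[[g]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop(sprintf("group '%s' must be finite numeric", g), call. = FALSE)
    }
  }
  structure(list(values = values, control = control), class = "group_table")
}

# P(max_j |T_j| <= q) for the many-to-one comparison statistics, by 2-D
# Gauss-Legendre quadrature over the control-mean normal deviate and the
# pooled-SD chi variate (both mapped through their quantile functions).
# lambda_j = sqrt(n_j / (n_j + n0)); conditional on Z0 = z and U = u the
# T_j are independent with
#   P(|T_j| <= q) = pnorm((q u + lambda_j z)/gamma_j)
#                 - pnorm((-q u + lambda_j z)/gamma_j),  gamma_j^2 = 1 - lambda_j^2.
dunnett_pmax <- function(q, lambda, df, n_nodes = 96L) {
  if (q <= 0) return(0)
  gl <- gauss_legendre_01(n_nodes)
  z <- stats::qnorm(gl$nodes)
  u <- sqrt(stats::qchisq(gl$nodes, df) / df)
  gamma <- sqrt(1 - lambda^2)
  acc <- 0
  for (i in seq_along(u)) {
    qu <- q * u[i]
    prod_z <- rep(1, length(z))
    for (j in seq_along(lambda)) {
      lz <- lambda[j] * z
      prod_z <- prod_z *
        (stats::pnorm((qu + lz) / gamma[j]) - stats::pnorm((-qu + lz) / gamma[j]))
    }
    acc <- acc + gl$weights[i] * sum(gl$weights * prod_z)
  }
  min(max(acc, 0), 1)
}

dunnett_pmax_mc <- function(q, lambda, df, draws, seed) {
  gamma <- sqrt(1 - lambda^2)
  with_seed(seed, {
    z0 <- stats::rnorm(draws)
    u <- sqrt(stats::rchisq(draws, df) / df)
    tmax <- rep(0, draws)
    for (j in seq_along(lambda)) {
      tj <- abs(gamma[j] * stats::rnorm(draws) - lambda[j] * z0) / u
      tmax <- pmax(tmax, tj)
    }
    mean(tmax <= q)
  })
}

#' One-way ANOVA with Dunnett many-to-one correction
#'
#' Fits an ordinary (pooled-variance) one-way ANOVA and compares each
#' treatment group against the control with two-sided Dunnett-adjusted
#' p-values. The adjustment evaluates the equicoordinate tail of the
#' many-to-one multivariate-t distribution, by default through a
#' deterministic two-dimensional Gauss-Legendre quadrature (conditioning on
#' the control-mean deviate and the pooled standard deviation); a seeded
#' Monte-Carlo alternative is available for cross-checking. Unbalanced
#' group sizes are supported.
#'
#' @param table A [group_table()], or a named list of numeric vectors
#'   (first element = control), or a data.frame with columns `group` and
#'   `value` (first factor level = control).
#' @param alpha Familywise error rate used only for the `reject` flag.
#' @param method `"integration"` (default, deterministic) or `"mc"`.
#' @param mc_draws Monte-Carlo draws when `method = "mc"` (>= 1e5).
#' @param seed Seed for the Monte-Carlo method.
#' @return An object of class `dunnett_result`: a list with `comparisons`
#'   (data.frame: group, n, mean, diff, se, t, p_unadjusted, p_adjusted,
#'   reject), `F`, `p_overall`, `df1`, `df2`, `control`, `method`, `alpha`.
#' @examples
#' tab <- group_table(list(
#'   baseline = c(10, 12, 14, 11), treated = c(7, 8, 6, 9)))
#' anova_dunnett(tab)
#' @export
anova_dunnett <- function(table, alpha = 0.05,
                          method = c("integration", "mc"),
                          mc_draws = 2e5, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(table)) {
    stopifnot(all(c("group", "value") %in% names(table)))
    g <- if (is.factor(table$group)) table$group else factor(table$group, levels = unique(table$group))
    table <- group_table(split(table$value, g)[levels(g)])
  } else if (!inherits(table, "group_table")) {
    table <- group_table(table)
  }
  vals <- table$values
  k <- length(vals)
  if (k < 2L) stop("need at least 2 groups (control plus one treatment)", call. = FALSE)
  n <- vapply(vals, length, integer(1))
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  means <- vapply(vals, mean, numeric(1))
  N <- sum(n)
  df2 <- N - k
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  mse <- ss_within / df2
  df1 <- k - 1L
  Fstat <- if (mse > 0) (ss_between / df1) / mse else if (ss_between > 0) Inf else 0
  p_overall <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  n0 <- n[1L]
  idx <- seq(2L, k)
  lambda <- sqrt(n[idx] / (n[idx] + n0))
  diffs <- means[idx] - means[1L]
  se <- sqrt(mse * (1 / n[idx] + 1 / n0))
  tstat <- ifelse(se > 0, diffs / se, ifelse(diffs == 0, 0, sign(diffs) * Inf))
  p_unadj <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  p_adj <- vapply(seq_along(tstat), function(i) {
    ti <- abs(tstat[i])
    if (!is.finite(ti)) return(0)
    if (ti == 0) return(1)
    p <- if (method == "integration") {
      1 - dunnett_pmax(ti, lambda, df2)
    } else {
      if (mc_draws < 1e5) stop("`mc_draws` must be >= 1e5", call. = FALSE)
      1 - dunnett_pmax_mc(ti, lambda, df2, draws = mc_draws, seed = derive_seed(seed, "dunnett-mc"))
    }
    min(max(p, p_unadj[i]), 1) # adjusted p can never undercut the raw p
  }, numeric(1))

  comparisons <- data.frame(
    group = names(vals)[idx],
    n = n[idx],
    mean = means[idx],
    diff = diffs,
    se = se,
    t = tstat,
    p_unadjusted = p_unadj,
    p_adjusted = p_adj,
    reject = p_adj < alpha,
    row.names = NULL
  )
  structure(
    list(
      comparisons = comparisons,
      F = Fstat, p_overall = p_overall, df1 = df1, df2 = df2,
      control = table$control, control_n = n0, control_mean = means[1L],
      method = method, alpha = alpha
    ),
    class = "dunnett_result"
  )
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_overall))
  cat(sprintf("Dunnett many-to-one vs '%s' (n = %d, mean = %.4g), %s method\n",
              x$control, x$control_n, x$control_mean, x$method))
  print(x$comparisons, digits = 4)
  invisible(x)
}
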