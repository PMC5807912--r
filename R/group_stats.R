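# Group-level comparison: means with SEM, one-way fixed-effects ANOVA, and
# Duncan's multiple range post hoc test with star-coded significance.

#' Mean and standard error of one group
#'
#' @param values Numeric vector of per-sample metric values.
#' @return A list with `mean`, `sem` (sample sd over sqrt(n); 0 with a
#'   warning for n = 1) and `n`.
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) validation_error("empty group: no values to summarize")
  if (n == 1) {
    warning("group of size 1: SEM reported as 0 (sd undefined)", call. = FALSE)
    return(list(mean = values, sem = 0, n = 1L))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    validation_error("groups must be a named list of numeric vectors")
  lapply(groups, function(v) as.numeric(v[!is.na(v)]))
}

pooled_within <- function(groups) {
  n <- vapply(groups, length, 1L)
  dfw <- sum(n) - length(groups)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0))
  list(ms_within = ssw / dfw, df_within = dfw, n = n)
}

#' One-way fixed-effects ANOVA
#'
#' Classical equal-variance one-way analysis of variance across k groups:
#' F = MS_between / MS_within on (k-1, N-k) degrees of freedom (computed via
#' `stats::oneway.test(var.equal = TRUE)`).
#'
#' @param groups Named list of numeric vectors (one per group, each n >= 2),
#'   or a data frame with `value` and `group` columns.
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`, plus the
#'   pooled `ms_within`, group means and sizes used by the post hoc test.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (k < 2) validation_error("ANOVA needs at least 2 groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) validation_error("every group needs n >= 2 for ANOVA")
  pw <- pooled_within(groups)
  if (pw$ms_within == 0)
    degenerate_variance_error("zero within-group variance in all groups; F is undefined")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), times = n), levels = names(groups)))
  ow <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  structure(list(F = unname(ow$statistic),
                 df_between = as.integer(unname(ow$parameter[1])),
                 df_within = as.integer(unname(ow$parameter[2])),
                 p = unname(ow$p.value),
                 ms_within = pw$ms_within,
                 group_means = vapply(groups, mean, 1.0),
                 group_n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

# Duncan decision at one alpha: means ranked ascending; a comparison spanning
# r ranks uses the studentized-range quantile at the protection level
# alpha_r = 1-(1-alpha)^(r-1); a pair is non-significant if its difference is
# below the critical range or if it lies inside a wider non-significant
# range. Returns a k x k logical matrix (sorted order).
duncan_decide <- function(means_sorted, n_sorted, ms_within, df_within, alpha) {
  k <- length(means_sorted)
  sig <- matrix(FALSE, k, k)
  nonsig_intervals <- list()
  for (r in k:2) {
    alpha_r <- 1 - (1 - alpha)^(r - 1)
    q <- suppressWarnings(stats::qtukey(1 - alpha_r, r, df_within))
    # guard extreme protection levels where the quantile does not converge
    if (!is.finite(q)) q <- if (alpha_r > 0.5) 0 else Inf
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      contained <- any(vapply(nonsig_intervals,
                              function(iv) iv[1] <= i && j <= iv[2], TRUE))
      nh <- 2 / (1 / n_sorted[i] + 1 / n_sorted[j])
      crit <- q * sqrt(ms_within / nh)
      if (contained || (means_sorted[j] - means_sorted[i]) <= crit) {
        nonsig_intervals[[length(nonsig_intervals) + 1L]] <- c(i, j)
      } else {
        sig[i, j] <- sig[j, i] <- TRUE
      }
    }
  }
  sig
}

#' Duncan's multiple range post hoc test
#'
#' Group means are ranked and each pair is compared against a critical range
#' from the studentized range distribution with Duncan's protection levels
#' (`alpha_r = 1-(1-alpha)^(r-1)` for a comparison spanning r ranks); a pair
#' inside a wider non-significant range is never declared significant.
#' Unequal group sizes enter through the harmonic mean of the two compared
#' sizes. For two groups the procedure reduces exactly to the pooled-variance
#' two-sample t-test.
#'
#' Per-pair p-values are the smallest alpha at which the pair becomes
#' significant (found by bisection; Duncan's procedure natively yields
#' decisions, not p-values), and star levels code p <= 0.05 / 0.01 / 0.001
#' as 1/2/3 stars.
#'
#' @param groups Named list of numeric vectors or a `value`/`group` data
#'   frame.
#' @param alpha Significance level of the reported `significant` column
#'   (default 0.05).
#' @param pvalues Compute per-pair p-values by bisection (default `TRUE`).
#'   With `FALSE`, `p_value` is `NA` and star levels come from the decisions
#'   at 0.05/0.01/0.001 directly — much faster inside simulations.
#' @return A `duncan_result` with a `pairs` data frame: `group_a`,
#'   `group_b`, `diff`, `significant`, `p_value`, `star_level`.
#' @export
duncan_posthoc <- function(groups, alpha = 0.05, pvalues = TRUE) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (k < 2) validation_error("post hoc comparison needs at least 2 groups")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    validation_error("alpha must be in (0, 1)")
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) validation_error("every group needs n >= 2")
  if (length(unique(n)) > 1)
    message("unequal group sizes: harmonic-mean n used per comparison")
  pw <- pooled_within(groups)
  if (pw$ms_within == 0)
    degenerate_variance_error("zero within-group variance; critical ranges are undefined")
  means <- vapply(groups, mean, 1.0)
  ord <- order(means)
  ms <- means[ord]; ns <- n[ord]; nms <- names(groups)[ord]
  decide <- function(a) duncan_decide(ms, ns, pw$ms_within, pw$df_within, a)
  sig_alpha <- decide(alpha)
  star_decisions <- if (!pvalues) lapply(c(0.05, 0.01, 0.001), decide)
  pair_idx <- utils::combn(k, 2)
  pairs <- lapply(seq_len(ncol(pair_idx)), function(col) {
    i <- pair_idx[1, col]; j <- pair_idx[2, col]
    if (pvalues) {
      p <- duncan_pair_pvalue(i, j, decide)
      stars <- sum(p <= c(0.05, 0.01, 0.001))
    } else {
      p <- NA_real_
      stars <- sum(vapply(star_decisions, function(d) d[i, j], TRUE))
    }
    data.frame(group_a = nms[i], group_b = nms[j],
               diff = ms[j] - ms[i],
               significant = sig_alpha[i, j],
               p_value = p,
               star_level = stars,
               stringsAsFactors = FALSE)
  })
  structure(list(pairs = do.call(rbind, pairs), alpha = alpha,
                 ms_within = pw$ms_within, df_within = pw$df_within),
            class = "duncan_result")
}

# Smallest alpha at which pair (i, j) (sorted order) is significant,
# bisected over a numerically safe alpha range; values outside are clamped.
duncan_pair_pvalue <- function(i, j, decide) {
  lo <- 1e-5; hi <- 0.999
  if (!decide(hi)[i, j]) return(1)
  if (decide(lo)[i, j]) return(lo)
  for (iter in 1:30) {
    mid <- (lo + hi) / 2
    if (decide(mid)[i, j]) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, df_within = %d)\n",
              x$alpha, x$df_within))
  p <- x$pairs
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s vs %s: diff = %.4g, p = %.3g %s\n",
                p$group_a[i], p$group_b[i], p$diff[i], p$p_value[i],
                strrep("*", p$star_level[i])))
  invisible(x)
}
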