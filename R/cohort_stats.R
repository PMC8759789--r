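#' Split patients into groups at a quantile threshold
#'
#' Median split labels a patient `high` only when the value is strictly
#' above the median; values equal to the threshold always fall in the lower
#' group. The tertile split uses the 33rd and 66th percentiles: `low` when
#' value <= 33rd percentile, `high` when value > 66th percentile,
#' `intermediate` otherwise. Percentiles use linear interpolation
#' (type 7, the R default).
#'
#' @param values Finite numeric vector, length >= 2.
#' @param q `"median"` or `"tertile"`.
#' @return Factor of labels (`low` < `intermediate` < `high`; the median
#'   split has no intermediate level). All-equal input yields all `low`
#'   with a warning.
#' @export
quantile_split <- function(values, q = c("median", "tertile")) {
  q <- match.arg(q)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  if (length(unique(values)) == 1) {
    warning("all values equal; everyone assigned to the lower group")
    lev <- if (q == "median") c("low", "high") else
      c("low", "intermediate", "high")
    return(factor(rep("low", length(values)), levels = lev))
  }
  if (q == "median") {
    thr <- stats::quantile(values, 0.5, type = 7, names = FALSE)
    factor(ifelse(values > thr, "high", "low"), levels = c("low", "high"))
  } else {
    lo <- stats::quantile(values, 0.33, type = 7, names = FALSE)
    hi <- stats::quantile(values, 0.66, type = 7, names = FALSE)
    factor(ifelse(values > hi, "high",
                  ifelse(values <= lo, "low", "intermediate")),
           levels = c("low", "intermediate", "high"))
  }
}

#' Log-rank test and observed/expected hazard ratio
#'
#' Mantel-Cox log-rank chi-square p-value between two groups, with the
#' hazard ratio estimated by the log-rank (O/E) approach:
#' `HR = (O1/E1) / (O2/E2)` with 95% CI
#' `exp(log HR +- 1.96 * sqrt(1/E1 + 1/E2))`, group 1 being the first
#' factor level. Kaplan-Meier curves (right-censored, deaths before
#' censorings at tied times) are returned alongside.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators (1 = event, 0 = censored).
#' @param groups Two-level factor (or coercible).
#' @return List: `p_logrank`, `hr`, `ci_low`, `ci_high`, `observed`,
#'   `expected` (per group), `n` (group sizes), `km` (data frame of
#'   Kaplan-Meier curves: group, time, surv, n.risk, n.event).
#' @export
logrank_hr <- function(times, events, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(times >= 0),
            all(table(groups) > 0))
  events <- as.integer(events)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  obs <- sd_$obs
  exp_ <- sd_$exp
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  if (any(obs == 0)) {
    warning("a group has zero events; the hazard ratio is a bound")
  }
  hr <- (obs[1] / exp_[1]) / (obs[2] / exp_[2])
  se <- sqrt(1 / exp_[1] + 1 / exp_[2])
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  km <- data.frame(
    group = rep(sub("^groups=", "", names(fit$strata)),
                fit$strata),
    time = fit$time, surv = fit$surv,
    n.risk = fit$n.risk, n.event = fit$n.event
  )
  list(p_logrank = p, hr = unname(hr),
       ci_low = unname(exp(log(hr) - 1.96 * se)),
       ci_high = unname(exp(log(hr) + 1.96 * se)),
       observed = unname(obs), expected = unname(exp_),
       n = as.vector(table(groups)), km = km)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The p-value is exact (full
#' enumeration of the U distribution) when the pooled size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return List `U` (statistic for `x`) and `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- any(duplicated(c(x, y)))
  use_exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Overall tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' k - 1 degrees of freedom, followed by Dunn's pairwise z statistics from
#' mean pooled ranks with tie-corrected variance and a Bonferroni family
#' adjustment over all reported pairs.
#'
#' @param groups Named list of numeric vectors (>= 3 non-empty groups).
#' @param p_adjust Adjustment method for the pairwise p-values (default
#'   `"bonferroni"`).
#' @return List: `H`, `p_overall`, `pairwise` (data frame: group1, group2,
#'   z, p, p_adj).
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni") {
  stopifnot(length(groups) >= 3, all(lengths(groups) > 0))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    pairs <- t(utils::combn(levels(g), 2))
    return(list(H = 0, p_overall = 1,
                pairwise = data.frame(group1 = pairs[, 1],
                                      group2 = pairs[, 2],
                                      z = 0, p = 1, p_adj = 1)))
  }
  kw <- stats::kruskal.test(values, g)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  pairs <- t(utils::combn(levels(g), 2))
  z <- apply(pairs, 1, function(p2) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[p2[1]] + 1 / sizes[p2[2]]))
    (mean_rank[p2[1]] - mean_rank[p2[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(H = unname(kw$statistic), p_overall = kw$p.value,
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             z = unname(z), p = unname(p),
                             p_adj = stats::p.adjust(p, method = p_adjust)))
}

#' Spearman rank correlation
#'
#' Correlation of average ranks (ties averaged), with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List `rho` and `p`. Zero variance in either vector yields
#'   `rho = NA` with a warning.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Two-sided two-proportion z test (pooled, no continuity correction)
#'
#' Compares k1/n1 with k2/n2 using the pooled-variance z statistic without
#' continuity correction, so that `z^2` equals the 2x2 chi-square statistic
#' without correction.
#'
#' @param k1,n1,k2,n2 Successes and totals (0 <= k <= n, n > 0).
#' @return List `z` and `p`. Degenerate pooled proportions (both 0 or both
#'   1) give `z = 0, p = 1`.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
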