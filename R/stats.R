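#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Compares the interval ratio across the three cohorts with a one-way
#' ANOVA and Tukey-Kramer adjusted pairwise comparisons (valid for the
#' unequal group sizes of a clinical cohort).
#'
#' @param values numeric observations.
#' @param groups factor or character vector of group labels, same length.
#' @param alpha significance level used for flagging (default 0.05).
#' @return List of class `mrs_group_comparison`: `f`, `anova_p`, `tukey`
#'   (named vector of adjusted pairwise p values), `n` (per-group counts),
#'   `significant_pairs`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    # no variation at all (e.g. the self-normalized Cr2 ratio): no group
    # effect by definition
    labs <- levels(groups)
    pairs <- utils::combn(labs, 2, function(p) paste(p[2], p[1], sep = "-"))
    tukey_p <- stats::setNames(rep(1, length(pairs)), pairs)
    return(structure(
      list(
        f = 0, anova_p = 1, tukey = tukey_p, n = as.integer(counts),
        group_labels = names(counts), significant_pairs = character()
      ),
      class = "mrs_group_comparison"
    ))
  }
  fit <- stats::aov(values ~ groups)
  tab <- stats::anova(fit)
  tukey <- stats::TukeyHSD(fit)$groups
  tukey_p <- tukey[, "p adj"]
  names(tukey_p) <- rownames(tukey)
  structure(
    list(
      f = tab$`F value`[1],
      anova_p = tab$`Pr(>F)`[1],
      tukey = tukey_p,
      n = as.integer(counts),
      group_labels = names(counts),
      significant_pairs = names(tukey_p)[tukey_p < alpha]
    ),
    class = "mrs_group_comparison"
  )
}

# Drop incomplete pairs; shared by the correlation estimators.
complete_pairs <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

cor_result <- function(method, estimate, p, n) {
  structure(
    list(method = method, estimate = estimate, p = p, n = as.integer(n)),
    class = "mrs_cor_result"
  )
}

#' @export
print.mrs_cor_result <- function(x, ...) {
  cat(sprintf(
    "<%s> r = %.3f, p = %.4g, n = %d\n", x$method, x$estimate, x$p, x$n
  ))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, used for ordered clinical
#' scores such as the 0-6 GMFC-MLD scale. The p value uses the t
#' approximation `t = r sqrt((n-2)/(1-r^2))`; for n <= 9 an exact
#' permutation p value over all n! orderings is computed instead.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   p value; default `NULL` uses it when n <= 9.
#' @return An `mrs_cor_result`.
#' @export
spearman <- function(x, y, exact = NULL) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  rx <- rank(cp$x)
  ry <- rank(cp$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) cp$n <= 9L else isTRUE(exact)
  p <- if (use_exact) {
    perm_cor_pvalue(rx, ry, r)
  } else {
    t_cor_pvalue(r, cp$n)
  }
  cor_result("spearman", r, p, cp$n)
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return An `mrs_cor_result` with a t-based two-sided p value.
#' @export
pearson <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(cp$x) == 0 || stats::sd(cp$y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(cp$x, cp$y)
  cor_result("pearson", r, t_cor_pvalue(r, cp$n), cp$n)
}

# Two-sided p from the t distribution of a correlation under the null.
t_cor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Exact two-sided permutation p for a correlation of ranked data:
# enumerate all n! permutations of rx against fixed ry.
perm_cor_pvalue <- function(rx, ry, r_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  # cor is linear in sum(rx[perm] * ry) for fixed marginals
  sums <- perms_apply_sum(perms, rx, ry)
  mx <- mean(rx)
  my <- mean(ry)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  r_all <- (sums - n * mx * my) / denom
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# All permutations of 1..n as an (n! x n) integer matrix: first column
# cycles through each value, recursing on the remaining values.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(v) {
    cbind(v, sub + (sub >= v))
  }))
}

perms_apply_sum <- function(perms, rx, ry) {
  # sum over columns of rx[perm] * ry, vectorized across permutations
  vals <- matrix(rx[perms], nrow(perms), ncol(perms))
  as.numeric(vals %*% ry)
}

#' Threshold odds ratio from a 2 x 2 table
#'
#' Dichotomizes a marker at `threshold` (value >= threshold vs below) and
#' crosses it with a binary outcome. The odds ratio is `(a d) / (b c)`
#' with `a` = above-threshold with outcome, `b` = above without, `c` =
#' below with, `d` = below without. When any cell is zero, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged.
#'
#' @param values numeric marker values (e.g. NAA2 ratio in frontal white
#'   matter).
#' @param outcome logical outcome per record (e.g. IQ >= 85); pairs with
#'   missing entries are dropped.
#' @param threshold cut point on `values`.
#' @return List of class `mrs_odds_ratio`: `odds_ratio`, `table` (2 x 2),
#'   `corrected`, `threshold`, `n`.
#' @export
threshold_odds_ratio <- function(values, outcome, threshold = 1.5) {
  keep <- is.finite(values) & !is.na(outcome)
  values <- values[keep]
  outcome <- as.logical(outcome[keep])
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ge <- values >= threshold
  a <- sum(ge & outcome)
  b <- sum(ge & !outcome)
  c_ <- sum(!ge & outcome)
  d <- sum(!ge & !outcome)
  tab <- matrix(c(a, b, c_, d), 2, 2,
    byrow = TRUE,
    dimnames = list(c(">=thr", "<thr"), c("outcome", "no outcome"))
  )
  corrected <- any(tab == 0)
  cells <- c(a, b, c_, d) + if (corrected) 0.5 else 0
  structure(
    list(
      odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
      table = tab, corrected = corrected, threshold = threshold,
      n = length(values)
    ),
    class = "mrs_odds_ratio"
  )
}

#' Bland-Altman agreement between two measurement methods
#'
#' Limits of agreement are `mean(d) +/- 1.96 sd(d)` with `d = a - b` and
#' the sample (n-1) standard deviation. Points exactly on a limit count as
#' within; when all differences are identical the limits collapse and all
#' points count as within.
#'
#' @param a,b paired measurements of the same quantity by two methods.
#' @return List of class `mrs_bland_altman`: `mean_difference`, `lower`,
#'   `upper`, `percent_within`, `n`.
#' @export
bland_altman <- function(a, b) {
  cp <- complete_pairs(a, b)
  if (cp$n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  d <- cp$x - cp$y
  m <- mean(d)
  s <- stats::sd(d)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  within <- d >= lower & d <= upper
  structure(
    list(
      mean_difference = m, lower = lower, upper = upper,
      percent_within = 100 * mean(within), n = cp$n
    ),
    class = "mrs_bland_altman"
  )
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, the scale-free spread
#' measure used to compare interval-integral variability against
#' model-fitted metabolite estimates.
#'
#' @param values numeric vector, n >= 2, mean bounded away from zero.
#' @return Dimensionless scalar `sd(values) / mean(values)`.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (abs(m) < 1e-12 * max(1, s)) {
    stop("coefficient of variation undefined: mean is ~0", call. = FALSE)
  }
  s / m
}
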