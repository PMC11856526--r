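## Normality-gated group comparisons.
##
## The contribution here is the gate, not the tests: Shapiro-Wilk decides
## between the parametric and the rank-based route, and the result records
## which route was taken. The tests themselves are the standard stats
## routines, plus a hand-rolled Holm-Sidak step-down adjustment and Dunn's
## rank-based pairwise z test (neither ships with base R).

new_test_result <- function(test_name, statistic, p_value, gate,
                            adjusted_p = NULL, alpha = 0.05) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), gate = gate,
         adjusted_p = adjusted_p, alpha = alpha,
         significant = unname(p_value) < alpha),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s (gate: %s)\n", x$test_name,
              paste(sprintf("%s p=%.3g", names(x$gate), x$gate),
                    collapse = ", ")))
  cat(sprintf("  statistic = %.4g, p = %.4g (%ssignificant at alpha = %s)\n",
              x$statistic, x$p_value,
              if (x$significant) "" else "not ", format(x$alpha)))
  if (!is.null(x$adjusted_p)) {
    cat("  pairwise adjusted p:\n")
    for (nm in names(x$adjusted_p))
      cat(sprintf("    %s: %.4g\n", nm, x$adjusted_p[[nm]]))
  }
  invisible(x)
}

## Holm-Sidak step-down: order p ascending, adj_i = 1-(1-p_(i))^(m-i+1),
## enforce monotonicity by cumulative max, cap at 1.
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(p)
  out
}

## Dunn's pairwise z statistics on the pooled ranks, with tie correction;
## two-sided p values multiplied by the number of comparisons (Dunn's
## classical Bonferroni adjustment), capped at 1.
dunn_pairwise <- function(groups) {
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  mean_rk <- tapply(rk, g, mean)
  n <- lengths(groups)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  raw <- adj <- numeric(m)
  labels <- character(m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i1] + 1 / n[i2]))
    z <- (mean_rk[i1] - mean_rk[i2]) / se
    raw[j] <- 2 * stats::pnorm(-abs(z))
    labels[j] <- paste(names(groups)[i1], "vs", names(groups)[i2])
  }
  adj <- pmin(raw * m, 1)
  stats::setNames(adj, labels)
}

shapiro_gate <- function(groups, alpha) {
  small <- lengths(groups) < 3
  if (any(small))
    abort("group(s) too small for the normality gate (need >= 3): ",
          paste(names(groups)[small], collapse = ", "),
          class = "surfrank_gate_error")
  p <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) return(0)  # constant data: not plausibly normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  stats::setNames(p, paste0("shapiro_", names(groups)))
}

#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each group at the same alpha as the main test. If
#' both groups are consistent with normality the unpaired t-test is used;
#' if either is not, the Mann-Whitney (Wilcoxon rank-sum) test is used. The
#' result records the gate's p values so the route taken is auditable.
#'
#' @param x,y Numeric sample vectors (each of length >= 3).
#' @param alpha Two-tailed significance level (default 0.05), also used by
#'   the normality gate.
#' @return Object of class `group_test` with fields `test_name`
#'   (`"t_test"` or `"mann_whitney"`), `statistic`, `p_value`, `gate`,
#'   `significant`.
#' @examples
#' set.seed(1)
#' compare_two_groups(rnorm(30), rnorm(30, mean = 1))
#' @export
compare_two_groups <- function(x, y, alpha = 0.05) {
  groups <- list(x = x, y = y)
  gate <- shapiro_gate(groups, alpha)
  if (all(gate >= alpha)) {
    fit <- stats::t.test(x, y, var.equal = TRUE)
    new_test_result("t_test", fit$statistic, fit$p.value, gate, alpha = alpha)
  } else {
    fit <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    new_test_result("mann_whitney", fit$statistic, fit$p.value, gate,
                    alpha = alpha)
  }
}

#' Normality-gated multi-group comparison
#'
#' With three or more groups: if every group passes Shapiro-Wilk at `alpha`,
#' one-way ANOVA is run with Holm-Sidak-adjusted pairwise t tests (pooled
#' variance); otherwise Kruskal-Wallis with Dunn's pairwise rank test. The
#' adjusted pairwise p values cover all group pairs.
#'
#' @param groups Named list of numeric sample vectors (>= 3 groups, each of
#'   length >= 3). Unnamed lists get names `g1`, `g2`, ...
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Object of class `group_test` with `test_name`
#'   (`"anova_holm_sidak"` or `"kruskal_dunn"`), the omnibus `statistic` and
#'   `p_value`, the `gate` p values, and `adjusted_p` for every pair.
#' @export
compare_many_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) abort("need at least 3 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  gate <- shapiro_gate(groups, alpha)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(gate >= alpha)) {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    ## pairwise t tests with the pooled residual variance, Holm-Sidak adjusted
    mse <- tab["Residuals", "Mean Sq"]
    df_res <- tab["Residuals", "Df"]
    means <- tapply(x, g, mean)
    n <- lengths(groups)
    pairs <- utils::combn(length(groups), 2)
    raw <- numeric(ncol(pairs)); labels <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(mse * (1 / n[i1] + 1 / n[i2]))
      tstat <- (means[i1] - means[i2]) / se
      raw[j] <- 2 * stats::pt(-abs(tstat), df_res)
      labels[j] <- paste(names(groups)[i1], "vs", names(groups)[i2])
    }
    new_test_result("anova_holm_sidak", tab["g", "F value"],
                    tab["g", "Pr(>F)"], gate,
                    adjusted_p = p_adjust_holm_sidak(
                      stats::setNames(raw, labels)),
                    alpha = alpha)
  } else {
    fit <- stats::kruskal.test(x, g)
    new_test_result("kruskal_dunn", fit$statistic, fit$p.value, gate,
                    adjusted_p = dunn_pairwise(groups), alpha = alpha)
  }
}
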