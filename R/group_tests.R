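# Two-group inference: Shapiro-Wilk-gated choice between the independent
# two-sample t-test and the Mann-Whitney U test, pooled-sd Cohen's d,
# Benjamini-Hochberg adjustment within declared families, and analytic
# post-hoc power from the noncentral t distribution.

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' In pipeline use the group order is fixed as (HC, SZ), so a negative d
#' means the patient group scores higher — the reporting convention used
#' throughout.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) {
    rlang::abort("each group needs at least 2 observations",
      class = "brainbody_validation_error"
    )
  }
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    rlang::abort("pooled standard deviation is zero",
      class = "brainbody_validation_error"
    )
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: order the m raw p-values increasingly, form
#' `p_(i) * m / i`, take the cumulative minimum from the largest rank down,
#' and cap at 1. Adjusted values are monotone in the raw values.
#'
#' @param pvals Numeric vector of p-values in [0, 1] (NA passed through).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1]",
      class = "brainbody_validation_error"
    )
  }
  out <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  out[ok[o]] <- adj
  out
}

#' Analytic post-hoc power for the two-sample t-test
#'
#' Two-sided power at significance level `alpha` via the noncentral t
#' distribution: noncentrality `d * sqrt(n1 n2 / (n1 + n2))` on
#' `n1 + n2 - 2` degrees of freedom. At `d = 0` the power equals `alpha`
#' exactly (the size of the test).
#'
#' @param d Cohen's d (sign is irrelevant for two-sided power).
#' @param n1,n2 Group sizes, each >= 2.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in [0, 1].
#' @export
posthoc_power <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + stats::pt(tcrit, df, ncp = ncp,
    lower.tail = FALSE
  )
}

#' Post-hoc power summary at observed and benchmark effect sizes
#'
#' Reports power for the observed Cohen's d and for the conventional small
#' (0.2), medium (0.5) and large (0.8) benchmarks at the given group sizes.
#'
#' @param observed_d Observed Cohen's d.
#' @inheritParams posthoc_power
#' @return One-row tibble with `observed_d`, `power_at_observed`,
#'   `power_small`, `power_medium`, `power_large`, `alpha`, `n1`, `n2`.
#' @export
power_summary <- function(observed_d, n1, n2, alpha = 0.05) {
  tibble(
    observed_d = observed_d,
    power_at_observed = posthoc_power(observed_d, n1, n2, alpha),
    power_small = posthoc_power(0.2, n1, n2, alpha),
    power_medium = posthoc_power(0.5, n1, n2, alpha),
    power_large = posthoc_power(0.8, n1, n2, alpha),
    alpha = alpha, n1 = n1, n2 = n2
  )
}

#' Normality-gated two-group comparison
#'
#' Under `policy = "auto"` each group is tested for normality with the
#' Shapiro-Wilk test at alpha 0.05; if both groups pass, an independent
#' two-sample t-test is used (Welch by default), otherwise a two-sided
#' Mann-Whitney U test (normal approximation with continuity correction when
#' either group exceeds 8 observations, exact otherwise). Cohen's d is always
#' reported, with group order (HC, SZ) when labels carry those levels.
#'
#' @param values Numeric vector of observations.
#' @param labels Group labels (exactly two groups, each n >= 3). Levels
#'   `c("HC", "SZ")` are ordered HC first; otherwise first-appearance order.
#' @param policy `"auto"`, `"t"`, or `"mann_whitney"`.
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @param shapiro_alpha Normality gate level for the auto policy.
#' @return One-row tibble: `test_used`, `statistic`, `raw_p`, `cohens_d`,
#'   `shapiro_p_1`, `shapiro_p_2`, `n_1`, `n_2`.
#' @export
compare_groups <- function(values, labels,
                           policy = c("auto", "t", "mann_whitney"),
                           var_equal = FALSE, shapiro_alpha = 0.05) {
  policy <- match.arg(policy)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) {
    rlang::abort("exactly two groups are required",
      class = "brainbody_validation_error"
    )
  }
  if (all(c("HC", "SZ") %in% groups)) groups <- c("HC", "SZ")
  a <- values[labels == groups[1]]
  b <- values[labels == groups[2]]
  if (length(a) < 3 || length(b) < 3) {
    rlang::abort("each group needs at least 3 observations",
      class = "brainbody_validation_error"
    )
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    rlang::abort("values constant within both groups",
      class = "brainbody_validation_error"
    )
  }

  sw <- function(x) {
    if (stats::sd(x) == 0) return(0) # degenerate: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  sp1 <- sw(a)
  sp2 <- sw(b)
  test_used <- switch(policy,
    t = "t",
    mann_whitney = "mann_whitney",
    auto = if (sp1 > shapiro_alpha && sp2 > shapiro_alpha) "t" else "mann_whitney"
  )

  if (test_used == "t") {
    ht <- stats::t.test(a, b, var.equal = var_equal)
  } else {
    exact <- length(a) <= 8 && length(b) <= 8
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
  }

  tibble(
    test_used = test_used,
    statistic = unname(ht$statistic),
    raw_p = ht$p.value,
    cohens_d = cohens_d(a, b),
    shapiro_p_1 = sp1, shapiro_p_2 = sp2,
    n_1 = length(a), n_2 = length(b)
  )
}

#' Compare many variables between groups with one FDR family
#'
#' Runs [compare_groups()] on each named column of `data`, treats the set as
#' one Benjamini-Hochberg family (optional), and appends post-hoc power at
#' the observed and benchmark effect sizes.
#'
#' @param data Data frame containing `group_col` and the variables.
#' @param vars Character vector of variable columns to test.
#' @param group_col Name of the group label column (default `"group"`).
#' @param adjust Apply BH adjustment across `vars` (`adjusted_p` is `NA`
#'   when `FALSE`, mirroring reporting of unadjusted families).
#' @param alpha Significance level used for the power columns.
#' @inheritParams compare_groups
#' @return Tibble, one row per variable: `variable`, `test_used`,
#'   `statistic`, `raw_p`, `adjusted_p`, `cohens_d`, shapiro columns, group
#'   sizes and power columns.
#' @export
compare_groups_table <- function(data, vars, group_col = "group",
                                 policy = "auto", adjust = TRUE,
                                 var_equal = FALSE, alpha = 0.05) {
  stopifnot(all(vars %in% names(data)))
  labels <- data[[group_col]]
  res <- purrr::map(vars, function(v) {
    dplyr::bind_cols(
      tibble(variable = v),
      compare_groups(data[[v]], labels, policy = policy, var_equal = var_equal)
    )
  }) |> purrr::list_rbind()
  res$adjusted_p <- if (adjust) bh_adjust(res$raw_p) else NA_real_
  pow <- purrr::pmap(
    list(res$cohens_d, res$n_1, res$n_2),
    function(d, n1, n2) power_summary(d, n1, n2, alpha)[
      c("power_at_observed", "power_small", "power_medium", "power_large")
    ]
  ) |> purrr::list_rbind()
  dplyr::bind_cols(res, pow) |>
    dplyr::relocate("adjusted_p", .after = "raw_p")
}
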