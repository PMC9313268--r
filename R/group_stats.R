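# Comparison statistics across clearing conditions: per-condition
# mean +/- SEM and one-way ANOVA with Bonferroni-corrected pairwise
# post-tests on the pooled within-group variance.

#' A named group of attenuation values
#'
#' @param condition Condition label (e.g. `"uncleared"`, `"BABB"`, `"CUBIC"`).
#' @param values Numeric vector of attenuation measurements or per-sample
#'   means, 1/mm; all finite.
#' @return An object of class `condition_group`.
#' @export
condition_group <- function(condition, values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values))) {
    otc_stop("values must be a nonempty finite numeric vector", "otc_invalid_input")
  }
  structure(list(condition = as.character(condition), values = values),
            class = "condition_group")
}

check_groups <- function(groups, min_per_group = 2L) {
  if (!is.list(groups) || length(groups) < 2L ||
      !all(vapply(groups, inherits, logical(1), "condition_group"))) {
    otc_stop("need a list of at least two condition_group objects", "otc_invalid_input")
  }
  n <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(n < min_per_group)) {
    otc_stop(sprintf("every group needs at least %d values", min_per_group), "otc_invalid_input")
  }
  invisible(n)
}

anova_decomposition <- function(groups) {
  x <- lapply(groups, `[[`, "values")
  n <- lengths(x)
  k <- length(x)
  N <- sum(n)
  means <- vapply(x, mean, numeric(1))
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((x[[i]] - means[i])^2), numeric(1)))
  list(k = k, N = N, n = n, means = means,
       ss_between = ss_between, ss_within = ss_within,
       df_between = k - 1L, df_within = N - k)
}

#' One-way fixed-effects analysis of variance
#'
#' Classic decomposition: `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom and an upper-tail p-value from the F
#' distribution.
#'
#' @param groups List of [condition_group()], each with at least two values.
#' @return A list with `f_statistic`, `df_between`, `df_within`, `p_value`.
#' @examples
#' g <- list(condition_group("a", c(1, 2, 3)),
#'           condition_group("b", c(2, 3, 4)),
#'           condition_group("c", c(3, 4, 5)))
#' one_way_anova(g)  # F = 3 on (2, 6) df
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  d <- anova_decomposition(groups)
  if (d$ss_within == 0 && d$ss_between == 0) {
    otc_stop("all values identical: F statistic undefined", "otc_undefined_statistic")
  }
  ms_b <- d$ss_between / d$df_between
  ms_w <- d$ss_within / d$df_within
  f <- ms_b / ms_w  # Inf when groups are internally constant but differ
  list(f_statistic = f, df_between = d$df_between, df_within = d$df_within,
       p_value = stats::pf(f, d$df_between, d$df_within, lower.tail = FALSE))
}

#' Bonferroni-corrected pairwise post-tests
#'
#' For every unordered pair of conditions, a two-sided two-sample t-test in
#' the classic post-test form: the standard error uses the pooled
#' within-group mean square of the full ANOVA on `N - k` degrees of
#' freedom.  Raw p-values are multiplied by the number of pairs
#' `m = k(k-1)/2` and capped at 1.  Set `pooled = FALSE` for independent
#' Welch tests instead.
#'
#' @param groups List of [condition_group()].
#' @param pooled Use the pooled ANOVA `MS_within` (default `TRUE`).
#' @return A data frame with columns `condition_a`, `condition_b`,
#'   `t_statistic`, `df`, `raw_p`, `bonferroni_p`.
#' @export
bonferroni_pairwise <- function(groups, pooled = TRUE) {
  check_groups(groups)
  d <- anova_decomposition(groups)
  labels <- vapply(groups, `[[`, character(1), "condition")
  ms_w <- d$ss_within / d$df_within
  pairs <- utils::combn(d$k, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (pooled) {
      if (ms_w == 0) otc_stop("zero within-group variance: t statistic undefined", "otc_undefined_statistic")
      se <- sqrt(ms_w * (1 / d$n[i1] + 1 / d$n[i2]))
      df <- d$df_within
    } else {
      v1 <- stats::var(groups[[i1]]$values) / d$n[i1]
      v2 <- stats::var(groups[[i2]]$values) / d$n[i2]
      se <- sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (d$n[i1] - 1) + v2^2 / (d$n[i2] - 1))
    }
    t <- (d$means[i1] - d$means[i2]) / se
    raw <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    data.frame(condition_a = labels[i1], condition_b = labels[i2],
               t_statistic = t, df = df, raw_p = raw,
               bonferroni_p = min(1, m * raw), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-condition mean and standard error
#'
#' @param groups List of [condition_group()] (singletons allowed; SEM is
#'   reported as 0 with `sem_defined = FALSE` when n = 1).
#' @return A data frame with columns `condition`, `n`, `mean`, `sem`,
#'   `sem_defined`.
#' @export
summarize_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 1L ||
      !all(vapply(groups, inherits, logical(1), "condition_group"))) {
    otc_stop("need a nonempty list of condition_group objects", "otc_invalid_input")
  }
  do.call(rbind, lapply(groups, function(g) {
    n <- length(g$values)
    data.frame(condition = g$condition, n = n, mean = mean(g$values),
               sem = if (n > 1L) stats::sd(g$values) / sqrt(n) else 0,
               sem_defined = n > 1L, stringsAsFactors = FALSE)
  }))
}

#' Compare attenuation across clearing conditions
#'
#' Full group comparison as plotted in transparency studies: per-condition
#' mean +/- SEM, a one-way ANOVA across conditions, and Bonferroni
#' post-tests for every pair.
#'
#' `data` is a tidy data frame of individual measurements (columns
#' `condition`, `sample_id`, `mu`), e.g. the `measurements` field of
#' [run_protocol()] summaries bound together.  With `unit = "sample"` the
#' replication unit is the per-sample mean; if any condition has fewer than
#' two samples the comparison falls back to measurement level with a
#' pseudo-replication warning, since region-level measurements from one
#' sample are not independent replicates.
#'
#' @param data Data frame with columns `condition`, `sample_id`, `mu`.
#' @param unit `"sample"` (default) or `"measurement"`.
#' @param pooled Passed to [bonferroni_pairwise()].
#' @return An object of class `group_comparison_result` with fields
#'   `f_statistic`, `df_between`, `df_within`, `p_value`, `pairwise`,
#'   `group_summary`, `unit`.
#' @export
compare_conditions <- function(data, unit = c("sample", "measurement"),
                               pooled = TRUE) {
  unit <- match.arg(unit)
  need <- c("condition", "sample_id", "mu")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    otc_stop("data must have columns condition, sample_id, mu", "otc_invalid_input")
  }
  if (unit == "sample") {
    per_sample <- stats::aggregate(mu ~ condition + sample_id, data = data, FUN = mean)
    n_samples <- table(per_sample$condition)
    if (any(n_samples < 2)) {
      warning("fewer than 2 samples in some condition: falling back to ",
              "measurement-level comparison (pseudo-replication)")
      unit <- "measurement"
    } else {
      data <- per_sample
    }
  }
  groups <- lapply(split(data$mu, data$condition), function(v) v)
  groups <- lapply(names(groups), function(nm) condition_group(nm, groups[[nm]]))
  aov_res <- one_way_anova(groups)
  structure(c(aov_res, list(
    pairwise = bonferroni_pairwise(groups, pooled = pooled),
    group_summary = summarize_groups(groups),
    unit = unit
  )), class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat("<group_comparison_result> one-way ANOVA + Bonferroni post-test\n")
  cat(sprintf("  unit of replication: %s\n", x$unit))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("  per-condition mean +/- SEM (mm^-1):\n")
  for (i in seq_len(nrow(x$group_summary))) {
    g <- x$group_summary[i, ]
    cat(sprintf("    %-12s %.4f +/- %.4f (n = %d)\n", g$condition, g$mean, g$sem, g$n))
  }
  cat("  pairwise (Bonferroni-adjusted):\n")
  for (i in seq_len(nrow(x$pairwise))) {
    p <- x$pairwise[i, ]
    cat(sprintf("    %s vs %s: t = %.3f, p_adj = %.3g%s\n",
                p$condition_a, p$condition_b, p$t_statistic, p$bonferroni_p,
                if (p$bonferroni_p < 0.001) " (*)" else ""))
  }
  invisible(x)
}
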