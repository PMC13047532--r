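#' Group summary statistics
#'
#' An endpoint group reported as mean +/- SEM with replicate count, the form
#' in which membrane-protection endpoints (hemolysis %, K+ efflux, TBARS) are
#' typically published.
#'
#' @param mean Group mean (endpoint units).
#' @param sem Standard error of the mean, same units (>= 0).
#' @param n Replicate count (integer >= 1; inferential operations require
#'   `n >= 2`).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  check_nonneg(sem, "sem")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_domain("n must be a positive integer")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.3g (SEM, n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

as_group_summary <- function(x, what) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(group_summary(x[1], x[2], x[3]))
  stop_domain(sprintf("'%s' must be a group_summary or numeric (mean, sem, n)",
                      what))
}

#' Percent reduction relative to the stressor group
#'
#' `100 * (stressor - treated) / stressor`: the fraction of the
#' stressor-induced endpoint suppressed by the treatment, in percent.
#' Positive values mean protection.
#'
#' @param treated,stressor [group_summary()] objects (or `c(mean, sem, n)`
#'   vectors); `stressor` mean must be non-zero.
#' @return Percent reduction (full precision; display convention is one
#'   decimal).
#' @examples
#' percent_reduction(group_summary(4.30, 0.09, 3),
#'                   group_summary(7.59, 0.13, 3))  # ~43.4
#' @export
percent_reduction <- function(treated, stressor) {
  treated <- as_group_summary(treated, "treated")
  stressor <- as_group_summary(stressor, "stressor")
  if (stressor$mean == 0)
    stop_domain("stressor mean is zero; percent reduction undefined")
  100 * (stressor$mean - treated$mean) / stressor$mean
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference for two equal-design groups:
#' per-group SDs are recovered from the SEMs (`sd = sem * sqrt(n)`), pooled
#' as `sqrt((sd_a^2 + sd_b^2) / 2)` (for equal n this equals the
#' df-weighted pooled SD), and the difference of means is divided by the
#' pooled SD. Antisymmetric under swapping the groups. Conventional
#' benchmarks: 0.2 small, 0.5 medium, >= 0.8 large.
#'
#' @param a,b [group_summary()] objects (or `c(mean, sem, n)` vectors), both
#'   with `n >= 2`.
#' @return Cohen's d, dimensionless.
#' @examples
#' cohens_d(group_summary(43.31, 1.29, 3), group_summary(4.39, 0.21, 3))
#' @export
cohens_d <- function(a, b) {
  a <- as_group_summary(a, "a")
  b <- as_group_summary(b, "b")
  if (a$n < 2 || b$n < 2)
    stop_domain("cohens_d requires n >= 2 in both groups")
  sd_a <- a$sem * sqrt(a$n)
  sd_b <- b$sem * sqrt(b$n)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  diff <- a$mean - b$mean
  if (pooled == 0) {
    if (diff == 0) return(0)
    stop_domain("zero pooled SD with unequal means: infinite effect size")
  }
  diff / pooled
}

#' t-based 95% confidence interval for a group mean
#'
#' `mean +/- t(0.975, n - 1) * sem`. The t distribution (not z) is used,
#' matching small-sample practice.
#'
#' @param g A [group_summary()] (or `c(mean, sem, n)`), `n >= 2`.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @examples
#' ci95(group_summary(4.30, 0.09, 3))  # ~ (3.91, 4.69)
#' @export
ci95 <- function(g) {
  g <- as_group_summary(g, "g")
  if (g$n < 2) stop_domain("ci95 requires n >= 2")
  half <- stats::qt(0.975, df = g$n - 1) * g$sem
  c(lower = g$mean - half, upper = g$mean + half)
}

#' Effect measures for a tidy endpoint table
#'
#' Computes a [group_summary()] per group from raw replicates, then, for each
#' group, the percent reduction and Cohen's d relative to the stressor group
#' and the t-based 95% CI. Sign convention: treated-minus-stressor for d, so
#' protective treatments yield negative d versus the stressor.
#'
#' @param table Data frame with columns `group`, `replicate`, `value` (one
#'   row per replicate; every group needs >= 2 replicates).
#' @param stressor_label Label of the stressor group (e.g. the
#'   initiator-only group); must be present in `table`.
#' @param control_label Optional label of the untreated control (carried
#'   through in the output, no special arithmetic).
#' @return Data frame of class `effect_table` with columns `group`, `mean`,
#'   `sem`, `n`, `pct_reduction`, `cohens_d`, `ci_lo`, `ci_hi`; the stressor
#'   row has zero reduction and d by construction.
#' @export
summarize_endpoint <- function(table, stressor_label, control_label = NULL) {
  stopifnot(is.data.frame(table),
            all(c("group", "value") %in% names(table)))
  groups <- unique(as.character(table$group))
  if (!stressor_label %in% groups)
    stop_domain(sprintf("stressor group '%s' not found in table", stressor_label))
  sums <- lapply(groups, function(g) {
    v <- table$value[table$group == g]
    if (length(v) < 2)
      stop_domain(sprintf("group '%s' has fewer than 2 replicates", g))
    group_summary(mean(v), stats::sd(v) / sqrt(length(v)), length(v))
  })
  names(sums) <- groups
  stressor <- sums[[stressor_label]]
  rows <- lapply(groups, function(g) {
    s <- sums[[g]]
    ci <- ci95(s)
    data.frame(group = g, mean = s$mean, sem = s$sem, n = s$n,
               pct_reduction = percent_reduction(s, stressor),
               cohens_d = cohens_d(s, stressor),
               ci_lo = ci[["lower"]], ci_hi = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stressor") <- stressor_label
  attr(out, "control") <- control_label
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("Endpoint effects vs stressor group '%s'\n",
              attr(x, "stressor")))
  y <- data.frame(group = x$group,
                  mean_sem = sprintf("%.4g +/- %.3g", x$mean, x$sem),
                  n = x$n,
                  pct_reduction = sprintf("%.1f", x$pct_reduction),
                  cohens_d = sprintf("%.2f", x$cohens_d),
                  ci95 = sprintf("%.2f-%.2f", x$ci_lo, x$ci_hi))
  print(y, row.names = FALSE)
  invisible(x)
}
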