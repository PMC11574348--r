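# Classical group statistics: one-way ANOVA with Bonferroni post hoc
# comparisons, pooled-variance t-tests, and mean +/- s.e.m. summaries.
# Statistics are computed from the textbook sum-of-squares / pooled-variance
# formulas; tail probabilities come from R's F and t distributions.

as_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups[[2]], groups[[1]])
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition across named groups
#' (typically one value per animal), with the p-value from the F
#' distribution.
#'
#' @param groups Named list of numeric vectors, or a two-column data.frame
#'   (group, value). Each group needs n >= 2.
#' @return List with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}, the sums of squares, and \code{degenerate} (\code{TRUE}
#'   when the within-group variance is zero and the means are equal, in
#'   which case F is \code{NaN}).
#' @export
one_way_anova <- function(groups) {
  g <- as_groups(groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  n <- lengths(g)
  if (any(n < 2)) stop("each group needs n >= 2")
  N <- sum(n)
  grand <- sum(unlist(g)) / N
  means <- vapply(g, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  degenerate <- ms_w == 0 && ss_between == 0
  Fv <- ms_b / ms_w
  p <- if (is.finite(Fv)) stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
       else if (ms_w == 0 && ss_between > 0) 0 else NA_real_
  list(F = Fv, df_between = df_b, df_within = df_w, p = p,
       ss_between = ss_between, ss_within = ss_within,
       degenerate = degenerate)
}

#' Pooled-variance unpaired two-sample t-test
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @return List with \code{t}, \code{df} (n_a + n_b - 2), \code{p}
#'   (two-sided) and \code{degenerate} (zero pooled variance with equal
#'   means).
#' @export
unpaired_t <- function(a, b) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  df <- na + nb - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    return(list(t = if (mean(a) == mean(b)) NaN else Inf * sign(mean(a) - mean(b)),
                df = df, p = if (mean(a) == mean(b)) NA_real_ else 0,
                degenerate = mean(a) == mean(b)))
  }
  tv <- (mean(a) - mean(b)) / se
  list(t = tv, df = df, p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Welch's unequal-variance t-test
#'
#' Available as an alternative to the pooled test used by default.
#'
#' @inheritParams unpaired_t
#' @return List with \code{t}, \code{df} (Welch-Satterthwaite), \code{p}.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  tv <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tv, df = df, p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE))
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All pairwise pooled-variance t-tests between groups, with each raw p
#' multiplied by the number of comparisons (capped at 1), as the post hoc
#' follow-up to a significant one-way ANOVA.
#'
#' @param groups As in \code{\link{one_way_anova}}.
#' @param alpha Significance level for the adjusted p (default 0.05).
#' @param welch Use Welch's t instead of the pooled-variance t.
#' @return Data.frame: group1, group2, t, df, p_raw, p_adjusted,
#'   significant.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05, welch = FALSE) {
  g <- as_groups(groups)
  k <- length(g)
  if (k < 2)
    return(data.frame(group1 = character(0), group2 = character(0),
                      t = numeric(0), df = numeric(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    tt <- if (welch) welch_t(g[[i]], g[[j]]) else unpaired_t(g[[i]], g[[j]])
    p_raw <- if (is.na(tt$p)) 1 else tt$p  # identical groups: no evidence
    data.frame(group1 = names(g)[i], group2 = names(g)[j],
               t = tt$t, df = tt$df, p_raw = p_raw,
               p_adjusted = min(1, p_raw * m))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector.
#' @return Named vector \code{c(mean, sem, n)}; \code{sem} is the sample
#'   standard deviation over sqrt(n) (\code{NA} for n < 2).
#' @export
mean_sem <- function(values) {
  v <- as.numeric(values[is.finite(values)])
  n <- length(v)
  c(mean = mean(v),
    sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
    n = n)
}

#' Tidy group summary table
#'
#' ANOVA plus Bonferroni post hoc results in one exportable table.
#'
#' @param groups As in \code{\link{one_way_anova}}.
#' @param metric Label recorded in the output.
#' @param alpha Significance level.
#' @return List with \code{anova} (one-row data.frame), \code{posthoc}
#'   (the Bonferroni table) and \code{summary} (per-group mean, sem, n).
#' @export
group_comparison <- function(groups, metric = "metric", alpha = 0.05) {
  g <- as_groups(groups)
  an <- one_way_anova(g)
  ms <- t(vapply(g, mean_sem, numeric(3)))
  list(
    anova = data.frame(metric = metric, F = an$F,
                       df_between = an$df_between, df_within = an$df_within,
                       p = an$p),
    posthoc = cbind(metric = metric,
                    bonferroni_pairwise(g, alpha = alpha)),
    summary = data.frame(metric = metric, group = rownames(ms),
                         mean = ms[, "mean"], sem = ms[, "sem"],
                         n = ms[, "n"], row.names = NULL))
}
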