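## Two-group comparison from printed summary statistics (mean, sample SD,
## n). With two groups, a one-way ANOVA and the pooled-variance t-test are
## the same test (F = t^2, identical p), so one operation serves both
## reporting styles and returns both statistics.

#' Summary statistics for one group
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param sd Sample standard deviation (`sd >= 0`).
#' @param n Group size (`n >= 2`).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
  structure(list(label = as.character(label), mean = mean, sd = sd,
                 n = as.integer(n)), class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled (equal-variance) or Welch two-sample t-test computed from group
#' means, sample SDs and sizes, with a two-tailed p-value from the t
#' distribution. The equivalent two-group ANOVA F statistic (`F = t^2`) is
#' reported alongside.
#'
#' @param a,b [group_summary()] objects.
#' @param method `"pooled"` (default; equal-variance, `df = n_a + n_b -
#'   2`) or `"welch"` (Satterthwaite df).
#' @return List of class `summary_ttest` with elements `t`, `df`, `p`
#'   (two-tailed), `F`, `method`, `estimate` (mean difference `a - b`),
#'   `labels`.
#' @export
#' @examples
#' sds <- group_summary("SDS", 11.35, 1.87, 5)
#' ctl <- group_summary("Controls", 10.82, 2.16, 5)
#' summary_ttest(sds, ctl)  # p = 0.69
summary_ttest <- function(a, b, method = c("pooled", "welch")) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  method <- match.arg(method)
  diff <- a$mean - b$mean
  va <- a$sd^2; vb <- b$sd^2
  if (method == "pooled") {
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    if (sp2 == 0)
      stop("degenerate test: pooled variance is zero", call. = FALSE)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    if (va == 0 && vb == 0)
      stop("degenerate test: both variances are zero", call. = FALSE)
    se <- sqrt(va / a$n + vb / b$n)
    df <- (va / a$n + vb / b$n)^2 /
      ((va / a$n)^2 / (a$n - 1) + (vb / b$n)^2 / (b$n - 1))
  }
  t <- diff / se
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, F = t^2, method = method,
                 estimate = diff, labels = c(a$label, b$label)),
            class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): t(%.4g) = %.3f, F = %.3f, p = %.4g\n",
              x$labels[1], x$labels[2], x$method, x$df, x$t, x$F, x$p))
  invisible(x)
}

#' Run summary-statistics t-tests over a table of measures
#'
#' @param summaries Data frame with columns `measure`, `label`, `mean`,
#'   `sd`, `n` — two rows (one per group) for each measure.
#' @param method Passed to [summary_ttest()].
#' @return Data frame with one row per measure: group means/SDs/sizes,
#'   `t`, `df`, `F`, `p`.
#' @export
summary_ttest_table <- function(summaries, method = "pooled") {
  stopifnot(all(c("measure", "label", "mean", "sd", "n") %in%
                  names(summaries)))
  out <- lapply(split(summaries, summaries$measure), function(block) {
    if (nrow(block) != 2L)
      stop("measure '", block$measure[1], "' does not have exactly 2 groups",
           call. = FALSE)
    res <- summary_ttest(
      group_summary(block$label[1], block$mean[1], block$sd[1], block$n[1]),
      group_summary(block$label[2], block$mean[2], block$sd[2], block$n[2]),
      method = method)
    data.frame(measure = block$measure[1],
               group1 = block$label[1], mean1 = block$mean[1],
               sd1 = block$sd[1], n1 = block$n[1],
               group2 = block$label[2], mean2 = block$mean[2],
               sd2 = block$sd[2], n2 = block$n[2],
               t = res$t, df = res$df, F = res$F, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[unique(summaries$measure)])
  rownames(out) <- NULL
  out
}
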