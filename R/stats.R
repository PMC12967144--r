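## Phase-wise summaries and two-tailed unpaired Welch t-tests, the inferential
## procedure used throughout the phase comparisons.

#' Welch two-sample t-test
#'
#' Two-tailed unpaired t-test with Welch's correction for unequal variances:
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)`, degrees of
#' freedom by Welch-Satterthwaite, p from the Student-t survival function.
#' Two identical constant groups return `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  base <- list(mean_a = mean(a), mean_b = mean(b),
               sd_a = stats::sd(a), sd_b = stats::sd(b),
               n_a = length(a), n_b = length(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(c(list(t = 0, df = length(a) + length(b) - 2, p = 1), base))
    stop("both groups constant with unequal means: t undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value), base)
}

#' Significance stars used in the figure legends
#'
#' `*` for p <= 0.05, `**` for p <= 0.01, `***` for p <= 0.001,
#' `****` for p <= 0.0001, `ns` otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Per-phase summary and pairwise Welch comparisons of a metric
#'
#' Summarises one morphometric metric per mitotic phase (mean, s.d. with the
#' n-1 denominator, n) in biological phase order, and runs every pairwise
#' Welch t-test between phases with n >= 2 in both groups. P-values are
#' unadjusted by default, matching the original analysis; `adjust = "holm"`
#' applies a Holm correction.
#'
#' @param values Numeric metric values, one per cell.
#' @param phases Phase label per cell (subset of [PHASE_LEVELS]).
#' @param metric Name of the metric (carried into the output).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List: `summary` (phase, n, mean, sd) and `comparisons`
#'   (phase_a, phase_b, n_a, n_b, t, df, p, stars), ordered by phase.
#' @export
summarize_by_phase <- function(values, phases, metric = "metric",
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  bad <- !(phases %in% PHASE_LEVELS)
  if (any(bad))
    stop("unknown phase label: ", paste(unique(phases[bad]), collapse = ", "),
         call. = FALSE)
  ph <- factor(phases, levels = PHASE_LEVELS)
  keep <- levels(ph)[levels(ph) %in% ph]
  summ <- do.call(rbind, lapply(keep, function(p) {
    v <- values[ph == p]
    data.frame(metric = metric, phase = p, n = length(v),
               mean = mean(v), sd = stats::sd(v))
  }))
  testable <- summ$phase[summ$n >= 2]
  comp <- NULL
  if (length(testable) >= 2) {
    cmb <- utils::combn(as.character(testable), 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      pa <- cmb[1, i]; pb <- cmb[2, i]
      w <- welch_t_test(values[ph == pa], values[ph == pb])
      data.frame(metric = metric, phase_a = pa, phase_b = pb,
                 n_a = w$n_a, n_b = w$n_b,
                 mean_a = w$mean_a, mean_b = w$mean_b,
                 t = w$t, df = w$df, p = w$p)
    }))
    if (adjust == "holm") comp$p <- stats::p.adjust(comp$p, "holm")
    comp$stars <- significance_stars(comp$p)
  }
  list(summary = summ, comparisons = comp)
}
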