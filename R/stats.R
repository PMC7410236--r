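#' d'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transformed sample skewness (D'Agostino 1970) and
#' kurtosis (Anscombe & Glynn 1983) into the omnibus statistic
#' K2 = z_skew^2 + z_kurt^2, chi-squared with 2 df under normality.
#' Requires n >= 8 for the kurtosis transformation to be defined.
#'
#' @param x numeric vector, n >= 8.
#' @return list(statistic, p_value, z_skew, z_kurt, method).
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("d'Agostino-Pearson test requires n >= 8")
  x <- x - mean(x)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  if (m2 == 0) stop("zero variance")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, method = "d'Agostino-Pearson omnibus K2")
}

#' Paired two-tailed comparison of matched per-cell metrics
#'
#' The in vivo comparison: matched pre/post values per cell are screened for
#' normality of their differences with the d'Agostino-Pearson test (the
#' screen's outcome is recorded and flagged, but the t-test proceeds
#' regardless), then compared with a two-tailed paired t-test.
#'
#' @param pre,post matched per-cell metric values (equal length, n >= 3).
#' @param metric metric name carried into the result.
#' @param alpha significance level.
#' @return An object of class \code{test_result}: list(metric, test,
#'   statistic, p_value, n, mean_diff, normality — screen outcome (NULL when
#'   n < 8), normality_ok, alpha).
#' @export
paired_comparison <- function(pre, post, metric = "metric", alpha = 0.05) {
  stopifnot(length(pre) == length(post), length(pre) >= 3)
  d <- post - pre
  if (stats::var(d) == 0) stop("zero-variance differences: paired t undefined")
  screen <- if (length(d) >= 8) dagostino_pearson(d) else NULL
  tt <- stats::t.test(post, pre, paired = TRUE, alternative = "two.sided")
  structure(list(metric = metric, test = "two-tailed paired t-test",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 n = length(d), mean_diff = mean(d),
                 normality = screen,
                 normality_ok = is.null(screen) || screen$p_value >= alpha,
                 alpha = alpha),
            class = "test_result")
}

#' Sidak multiplicity adjustment
#'
#' p_adj = 1 - (1 - p)^m for m comparisons (capped at 1); the matching
#' family-wise adjusted alpha is 1 - (1 - alpha)^(1/m).
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family (default: length of p).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Multi-group comparison with Sidak-corrected post-hoc tests
#'
#' The ex vivo comparison: per-group Shapiro-Wilk normality screening
#' (recorded, not gating), a Kruskal-Wallis rank test across all groups, and
#' pairwise Wilcoxon rank-sum post-hoc comparisons with Sidak-adjusted
#' p-values and the Sidak family-wise adjusted alpha.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param metric metric name carried into the result.
#' @param alpha family-wise significance level.
#' @return An object of class \code{group_test_result}: list(metric,
#'   kruskal — list(statistic, p_value), shapiro — per-group screen,
#'   posthoc — data frame (group1, group2, p_raw, p_sidak), m, alpha,
#'   alpha_adjusted).
#' @export
group_comparison <- function(groups, metric = "metric", alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 3))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  shapiro <- lapply(groups, function(g) {
    if (stats::var(g) == 0) list(statistic = NA, p_value = NA, ok = NA)
    else {
      s <- stats::shapiro.test(g)
      list(statistic = unname(s$statistic), p_value = s$p.value,
           ok = s$p.value >= alpha)
    }
  })
  kw <- stats::kruskal.test(groups)
  cmb <- utils::combn(names(groups), 2)
  m <- ncol(cmb)
  praw <- vapply(seq_len(m), function(i) {
    suppressWarnings(stats::wilcox.test(groups[[cmb[1, i]]],
                                        groups[[cmb[2, i]]])$p.value)
  }, numeric(1))
  structure(list(metric = metric,
                 kruskal = list(statistic = unname(kw$statistic),
                                p_value = kw$p.value),
                 shapiro = shapiro,
                 posthoc = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                                      p_raw = praw,
                                      p_sidak = sidak_adjust(praw, m)),
                 m = m, alpha = alpha,
                 alpha_adjusted = 1 - (1 - alpha)^(1 / m)),
            class = "group_test_result")
}

#' Group-wise summary table of per-cell metrics
#'
#' Per-group n, mean, sample SD (divisor n - 1), SEM and a mean +/- SD
#' display string, for each requested metric, grouped by the given columns.
#'
#' @param records data frame of per-cell records.
#' @param metrics character vector of metric column names.
#' @param group_by character vector of grouping column names (e.g. region
#'   and condition).
#' @return Data frame with one row per metric x group.
#' @export
summarize_metrics <- function(records, metrics,
                              group_by = intersect(c("region", "condition"),
                                                   names(records))) {
  stopifnot(nrow(records) >= 1, all(metrics %in% names(records)),
            all(group_by %in% names(records)))
  key <- if (length(group_by))
    interaction(records[group_by], drop = TRUE, sep = "/") else
      factor(rep("all", nrow(records)))
  out <- list()
  for (met in metrics) {
    for (g in levels(key)) {
      v <- records[[met]][key == g]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        metric = met, group = g, n = length(v), mean = mean(v),
        sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)),
        display = sprintf("%.3g±%.3g", mean(v), stats::sd(v)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
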