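#' @title Validity and reproducibility statistics
#' @description First-principles implementations of the three estimators the
#'   validation uses: Spearman rank correlation (midranks for ties, two-sided
#'   t-approximation p-value), Bland-Altman agreement (mean difference with
#'   limits of agreement at exactly +/- 2 SD), and the one-way random-effects
#'   ANOVA intraclass correlation with an F-based 95% confidence interval.
#'   Only distribution quantile/tail functions are delegated to `stats`.
#' @name agreement
NULL

#' Paired measurements container
#'
#' Pairs with a missing value in either vector are dropped; the number
#' dropped is recorded in the `n_dropped` attribute.
#'
#' @param ids participant identifiers.
#' @param a,b numeric vectors (e.g. kJ/day) of equal length.
#' @return An `aq_pairs` object.
#' @export
paired_measurements <- function(ids, a, b) {
  if (length(a) != length(b) || length(ids) != length(a)) {
    stop("pairs error: ids, a and b must have equal length")
  }
  keep <- !(is.na(a) | is.na(b))
  out <- structure(list(ids = ids[keep], a = a[keep], b = b[keep]),
                   class = "aq_pairs")
  attr(out, "n_dropped") <- sum(!keep)
  if (length(out$a) < 3) stop("pairs error: fewer than 3 complete pairs")
  out
}

midrank <- function(x) {
  # average rank for ties, built from the order statistic
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranked values; two-sided p-value from the
#' large-sample t approximation `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom (the study's n = 37 regime).
#'
#' @param pairs an `aq_pairs`.
#' @return list(r, p, n).
#' @export
spearman_cor <- function(pairs) {
  stopifnot(inherits(pairs, "aq_pairs"))
  ra <- midrank(pairs$a)
  rb <- midrank(pairs$b)
  da <- ra - mean(ra)
  db <- rb - mean(rb)
  va <- sum(da^2)
  vb <- sum(db^2)
  if (va == 0 || vb == 0) {
    stop("undefined correlation: constant measurement vector")
  }
  r <- sum(da * db) / sqrt(va * vb)
  n <- length(ra)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; limits of agreement are the mean difference plus
#' or minus exactly `loa_factor` sample standard deviations (default 2, the
#' published convention here, rather than 1.96).
#'
#' @param pairs an `aq_pairs` (n >= 2 used).
#' @param loa_factor multiple of SD for the limits of agreement.
#' @return list(mean_diff, sd_diff, loa_low, loa_high, points) where `points`
#'   is a plot-ready data.frame of per-pair (mean, diff).
#' @export
bland_altman <- function(pairs, loa_factor = 2) {
  stopifnot(inherits(pairs, "aq_pairs"))
  d <- pairs$a - pairs$b
  n <- length(d)
  mean_diff <- sum(d) / n
  sd_diff <- sqrt(sum((d - mean_diff)^2) / (n - 1))
  list(mean_diff = mean_diff, sd_diff = sd_diff,
       loa_low = mean_diff - loa_factor * sd_diff,
       loa_high = mean_diff + loa_factor * sd_diff,
       points = data.frame(id = pairs$ids, mean = (pairs$a + pairs$b) / 2,
                           diff = d, stringsAsFactors = FALSE))
}

#' ANOVA intraclass correlation for two repeated measurements
#'
#' One-way random-effects estimator (default): with k = 2 measurements per
#' subject, ICC = (MSB - MSW) / (MSB + (k-1) MSW) from the between- and
#' within-subject mean squares. The 95% interval follows from F-distribution
#' bounds on the same one-way model:
#' FL = F / qf(1-alpha/2; n-1, n(k-1)), FU = F * qf(1-alpha/2; n(k-1), n-1),
#' with ICC bounds (FL-1)/(FL+k-1) and (FU-1)/(FU+k-1). A two-way
#' random-effects variant (absolute agreement, single measurement) is exposed
#' via `model = "twoway"`; its interval is not implemented and is returned
#' as NA.
#'
#' @param pairs an `aq_pairs` (administration I in `a`, II in `b`).
#' @param conf_level confidence level (default 0.95).
#' @param model "oneway" (default) or "twoway".
#' @return list(icc, ci_low, ci_high, msb, msw).
#' @export
icc_anova <- function(pairs, conf_level = 0.95,
                      model = c("oneway", "twoway")) {
  stopifnot(inherits(pairs, "aq_pairs"))
  model <- match.arg(model)
  x <- cbind(pairs$a, pairs$b)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  mi <- rowMeans(x)
  ssb <- k * sum((mi - grand)^2)
  ssw <- sum((x - mi)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) {
    stop("undefined ICC: zero total variance")
  }
  if (model == "twoway") {
    mj <- colMeans(x)
    ssc <- n * sum((mj - grand)^2)
    sse <- sum((x - outer(mi, rep(1, k)) -
                  outer(rep(1, n), mj) + grand)^2)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    icc <- (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
    return(list(icc = icc, ci_low = NA_real_, ci_high = NA_real_,
                msb = msb, msw = mse))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf_level
  if (msw == 0) {
    ci <- c(1, 1)
  } else {
    f <- msb / msw
    fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], msb = msb, msw = msw)
}

#' Combined agreement report for a paired-measurement set
#'
#' @param pairs an `aq_pairs`.
#' @param loa_factor limits-of-agreement multiplier (default 2).
#' @return An `aq_agreement_report` with Spearman, Bland-Altman and ICC
#'   fields.
#' @export
agreement_report <- function(pairs, loa_factor = 2) {
  sp <- spearman_cor(pairs)
  ba <- bland_altman(pairs, loa_factor)
  icc <- icc_anova(pairs)
  structure(list(n = length(pairs$a),
                 n_dropped = attr(pairs, "n_dropped") %||% 0L,
                 spearman_r = sp$r, spearman_p = sp$p,
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 ba_points = ba$points,
                 icc = icc$icc, icc_ci_low = icc$ci_low,
                 icc_ci_high = icc$ci_high),
            class = "aq_agreement_report")
}

#' @export
print.aq_agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d, %d pair(s) dropped)\n", x$n,
              x$n_dropped))
  cat(sprintf("  Spearman r = %.3f (p = %.3g)\n", x$spearman_r, x$spearman_p))
  cat(sprintf("  Bland-Altman: mean diff = %.1f, SD = %.1f, LoA [%.1f, %.1f]\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  ICC = %.3f (95%% CI %.3f-%.3f)\n", x$icc, x$icc_ci_low,
              x$icc_ci_high))
  invisible(x)
}
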