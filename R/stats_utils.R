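# Column-wise (per-gene) classical pooled-variance two-sample t-test.
# Degenerate zero-variance columns: equal means -> t = 0, p = 1; unequal
# means -> t = +/-Inf with the smallest representable p, flagged.
col_t_pooled <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(A); m2 <- colMeans(B)
  ss1 <- colSums(sweep(A, 2, m1)^2)
  ss2 <- colSums(sweep(B, 2, m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  zero <- se == 0
  eq <- zero & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  deg <- zero & !eq
  t[deg] <- sign(m1 - m2)[deg] * Inf
  p[deg] <- .Machine$double.xmin
  list(t = t, p = p, df = df, mean1 = m1, mean2 = m2, degenerate = deg)
}

# Column-wise one-way ANOVA over a list of observation matrices (one per
# group, same columns). Zero within-group variance everywhere: equal group
# means -> F = 0, p = 1; unequal -> F = Inf, smallest representable p.
col_oneway_anova <- function(groups) {
  stopifnot(length(groups) >= 2)
  ns <- vapply(groups, nrow, integer(1))
  k <- length(groups); N <- sum(ns)
  if (N - k < 1) .cb_stop("no residual degrees of freedom",
                          "capblood_param_error")
  means <- vapply(groups, colMeans, numeric(ncol(groups[[1]])))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  grand <- as.vector(means %*% ns) / N
  ssb <- as.vector(sweep(means, 1, grand)^2 %*% ns)
  ssw <- Reduce(`+`, lapply(groups, function(g)
    colSums(sweep(g, 2, colMeans(g))^2)))
  df1 <- k - 1; df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  p <- pf(F, df1, df2, lower.tail = FALSE)
  zero <- ssw == 0
  eqm <- zero & (ssb <= .Machine$double.eps * N)
  F[eqm] <- 0; p[eqm] <- 1
  deg <- zero & !eqm
  F[deg] <- Inf; p[deg] <- .Machine$double.xmin
  list(F = F, p = p, df1 = df1, df2 = df2, degenerate = deg)
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard BH q-values and rejection flags at the given FDR. `NA`
#' p-values are excluded from the correction (their q is `NA`, never
#' rejected) and reported via a message.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.05).
#' @return List with `q` (same length as `p`) and logical `reject`.
#' @export
bh_correct <- function(p, fdr = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .cb_stop("p-values must lie in [0, 1]", "capblood_param_error")
  nas <- is.na(p)
  if (any(nas)) message(sum(nas), " NA p-value(s) excluded from BH")
  q <- rep(NA_real_, length(p))
  q[!nas] <- p.adjust(p[!nas], method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Two-proportion z-test on (possibly weighted) counts
#'
#' Computes `z = (p1 - p2) / sqrt(phat (1 - phat) (1/w1 + 1/w2))` with
#' `p1 = x1/w1`, `p2 = x2/w2` and `phat = (x1 + x2)/(w1 + w2)`. With unit
#' weights this is the textbook two-proportion z-test; with fractional
#' weights the weighted totals act as effective sample sizes.
#'
#' @param x1,w1 (Weighted) success count and total of the first sample.
#' @param x2,w2 Same for the second sample.
#' @return List with `z`, `p` (two-sided) and `undefined` flag (pooled
#'   proportion 0 or 1, reported as z = 0).
#' @export
two_prop_z <- function(x1, w1, x2, w2) {
  stopifnot(w1 > 0, w2 > 0, x1 >= 0, x2 >= 0)
  phat <- (x1 + x2) / (w1 + w2)
  den <- sqrt(phat * (1 - phat) * (1 / w1 + 1 / w2))
  undefined <- den == 0
  z <- if (undefined) 0 else (x1 / w1 - x2 / w2) / den
  list(z = z, p = 2 * pnorm(-abs(z)), undefined = undefined)
}

# signed z-statistic convention for plotting: the normal quantile of the
# two-sided p, signed by the AM - PM mean difference
signed_z <- function(p, mean_diff) {
  z <- qnorm(pmin(pmax(p, .Machine$double.xmin), 1) / 2, lower.tail = FALSE)
  sign(mean_diff) * z
}
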