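#' 2x2 contingency table
#'
#' Counts of success/failure in two groups (rows = groups, columns =
#' success/failure).
#'
#' @param a,b successes and failures in group 1.
#' @param c,d successes and failures in group 2.
#' @param labels length-2 character group labels.
#' @return an object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, labels = c("group1", "group2")) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(labels, c("success", "failure")))
  structure(m, class = c("contingency_2x2", "matrix"))
}

as_table2x2 <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == 2))
    return(contingency_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  stop("expected a 2x2 table", call. = FALSE)
}

#' Two-sided Fisher's exact test
#'
#' Exact test of association in a 2x2 table by hypergeometric enumeration:
#' with the margins fixed, every admissible table is enumerated and the
#' two-sided p-value is the total hypergeometric probability of tables whose
#' point probability does not exceed that of the observed table (the
#' probability-mass rule; this is the definition that reproduces the
#' conventional printed values, and differs from mid-p and tail-doubling
#' rules).
#'
#' @param table a [contingency_2x2()] or plain 2x2 matrix.
#' @return list with `p` (two-sided), `odds_ratio` (sample), and `method`.
#' @examples
#' fisher_exact(contingency_2x2(12, 1, 8, 7))$p   # 0.0377
#' @export
fisher_exact <- function(table) {
  tb <- as_table2x2(table)
  a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    warning("a margin of the table is empty; p = 1", call. = FALSE)
    return(list(p = 1, odds_ratio = NA_real_, method = "fisher_exact"))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  # relative tolerance guards against ties broken by floating-point error
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (a * d) / (b * c_)
  list(p = min(p, 1), odds_ratio = or, method = "fisher_exact")
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The U statistic is reported for the
#' first sample. In `exact` mode (automatic when `n1 + n2 <= 16` and there
#' are no ties) the two-sided p-value comes from full enumeration of all
#' `choose(n1 + n2, n1)` group assignments: twice the smaller tail
#' probability of U, capped at 1. Otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U`, `p` (two-sided), `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (all(pooled == pooled[1])) {
    warning("all values identical; p = 1", call. = FALSE)
    return(list(U = U, p = 1, method = "mann_whitney_degenerate"))
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = N <= 16 && !ties)
  if (use_exact && ties)
    stop("exact mode is only defined without ties", call. = FALSE)
  if (use_exact) {
    # full enumeration of rank assignments to sample 1
    combos <- combn(N, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9)))
    return(list(U = U, p = p, method = "mann_whitney_exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  if (sigma == 0) {
    warning("zero variance under ties; p = 1", call. = FALSE)
    return(list(U = U, p = 1, method = "mann_whitney_normal"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sigma   # continuity correction
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "mann_whitney_normal")
}

#' Paired t test
#'
#' Standard paired t on the differences `x - y`, with `df = n - 1`.
#'
#' @param x,y equal-length numeric samples, `n >= 2`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0)
    stop("differences have zero variance; paired t undefined", call. = FALSE)
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}

# One-way ANOVA decomposition shared by the multiple-comparison procedures.
.anova_oneway <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- (ssb / df1) / msw
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = p, df1 = df1, df2 = df2, msw = msw,
       ns = ns, means = means, k = k)
}

#' One-way ANOVA with Newman-Keuls multiple comparisons
#'
#' One-way ANOVA F test followed by the Student-Newman-Keuls stepwise range
#' procedure: group means are ordered and each pair is tested with the
#' studentized range statistic whose parameter is the number of means the
#' pair spans; quantiles come from the studentized range distribution
#' ([stats::ptukey()]), not lookup tables. A pair is declared significant
#' only when every wider range containing it is also significant (the
#' standard step-down protection). Unequal group sizes use the
#' Tukey-Kramer standard error.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha per-step significance level (default 0.05).
#' @return list with `F`, `p`, `df1`, `df2`, and `pairs` (data frame with
#'   group indices, mean difference, q statistic, span, p value and
#'   `significant` flag).
#' @export
anova_newman_keuls <- function(groups, alpha = 0.05) {
  a <- .anova_oneway(groups)
  ord <- order(a$means)
  k <- a$k
  res <- NULL
  sig <- matrix(NA, k, k)       # in ordered-index space
  # step down from the widest range; a range is only tested when the ranges
  # immediately containing it were significant, otherwise it is declared
  # non-significant untested (the SNK protection rule)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      blocked <- FALSE
      if (span < k) {
        parents <- c(if (i > 1) sig[i - 1, j], if (j < k) sig[i, j + 1])
        blocked <- any(!parents)
      }
      gi <- ord[i]; gj <- ord[j]
      se <- sqrt(a$msw / 2 * (1 / a$ns[gi] + 1 / a$ns[gj]))
      diffm <- a$means[gj] - a$means[gi]
      q <- if (se == 0) { if (diffm == 0) 0 else Inf } else diffm / se
      p_q <- ptukey(q, span, a$df2, lower.tail = FALSE)
      is_sig <- !blocked && p_q <= alpha
      sig[i, j] <- is_sig
      res <- rbind(res, data.frame(
        group_lo = gi, group_hi = gj, diff = diffm, q = q, span = span,
        p = if (blocked) NA_real_ else p_q, significant = is_sig))
    }
  }
  list(F = a$F, p = a$p, df1 = a$df1, df2 = a$df2, pairs = res)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t tests
#'
#' All-pairs t tests on the pooled within-group variance, with each p-value
#' multiplied by the number of comparisons `k(k-1)/2` and capped at 1.
#'
#' @inheritParams anova_newman_keuls
#' @return list with `F`, `p`, `df1`, `df2`, and `pairs` (data frame with
#'   `t`, raw `p_raw` and adjusted `p_adj`).
#' @export
anova_bonferroni <- function(groups, alpha = 0.05) {
  a <- .anova_oneway(groups)
  k <- a$k
  ncomp <- k * (k - 1) / 2
  res <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(a$msw * (1 / a$ns[i] + 1 / a$ns[j]))
    diffm <- a$means[j] - a$means[i]
    t_stat <- if (se == 0) { if (diffm == 0) 0 else Inf * sign(diffm) }
              else diffm / se
    p_raw <- 2 * pt(-abs(t_stat), a$df2)
    res <- rbind(res, data.frame(
      group_i = i, group_j = j, diff = diffm, t = t_stat,
      p_raw = p_raw, p_adj = min(1, p_raw * ncomp),
      significant = min(1, p_raw * ncomp) <= alpha))
  }
  list(F = a$F, p = a$p, df1 = a$df1, df2 = a$df2, pairs = res)
}

#' Two-sided variance-ratio (F) test
#'
#' F is the larger sample variance over the smaller; the two-sided p-value
#' doubles the upper tail of the F distribution with the matching degrees of
#' freedom.
#'
#' @param x,y numeric samples, each n >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    stop("both samples have zero variance", call. = FALSE)
  if (v1 >= v2) { f <- if (v2 == 0) Inf else v1 / v2
                  df1 <- length(x) - 1; df2 <- length(y) - 1 }
  else { f <- v2 / v1; df1 <- length(y) - 1; df2 <- length(x) - 1 }
  p <- if (is.infinite(f)) 0 else min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
  list(F = f, df1 = df1, df2 = df2, p = p)
}
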