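# Statistical primitives shared by all pipeline stages. Each kernel is pure
# and deterministic; tests check them against brute-force oracles.

#' Wilson score confidence interval for a binomial proportion
#'
#' Computes the Wilson score interval (without continuity correction) for a
#' binomial proportion, the interval used for amplification-frequency tables.
#'
#' @param successes Number of successes (non-negative integer).
#' @param trials Number of trials (positive integer, `>= successes`).
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return A list with elements `point`, `lower`, `upper` and `confidence`.
#'   `0 <= lower <= point <= upper <= 1` always holds.
#' @examples
#' wilson_ci(3, 203)  # 1.5% point estimate, CI roughly [0.5%, 4.3%]
#' @export
wilson_ci <- function(successes, trials, confidence = 0.95) {
  if (length(successes) != 1L || length(trials) != 1L ||
      !is.finite(successes) || !is.finite(trials)) {
    stop("'successes' and 'trials' must be finite scalars")
  }
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials and trials >= 1")
  }
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must lie strictly between 0 and 1")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  list(
    point = p,
    lower = max(0, centre - half),
    upper = min(1, centre + half),
    confidence = confidence
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment, returned in the original order of the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NA` allowed and
#'   propagated (NA entries are excluded from the family).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Decide whether the exact Wilcoxon null distribution applies.
.wilcox_exact_ok <- function(x, y) {
  length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by enumeration of the null rank distribution when both
#' groups have at most 10 observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param sidedness One of `"two.sided"`, `"greater"`, `"less"` (alternative:
#'   `x` shifted relative to `y`).
#' @return A list with `statistic` (the Mann-Whitney U for `x`), `p_value`
#'   and `method_tag` (`"wilcoxon-exact"` or `"wilcoxon-normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  exact <- .wilcox_exact_ok(x, y)
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = sidedness, exact = exact, correct = TRUE
  ))
  list(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method_tag = if (exact) "wilcoxon-exact" else "wilcoxon-normal"
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank-based Spearman correlation. The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return A list with `rho`, `statistic` (the t value), `p_value` and
#'   `method_tag`.
#' @export
spearman_corr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  r2 <- min(rho^2, 1 - 1e-12)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  list(
    rho = rho,
    statistic = tstat,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
    method_tag = "spearman-t"
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `statistic` (D, the supremum ECDF distance), `p_value`
#'   (asymptotic) and `method_tag`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method_tag = "ks-asymptotic"
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A list with `statistic` (the conditional odds-ratio estimate),
#'   `p_value` and `method_tag`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  ht <- stats::fisher.test(tab)
  list(
    statistic = unname(ht$estimate),
    p_value = ht$p.value,
    method_tag = "fisher-exact"
  )
}

# Newton inversion of the trigamma function (used for the moderated-t prior).
.trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t-test for a two-group contrast
#'
#' Per-gene two-group comparison on a log2 expression matrix with the gene
#' variances shrunk toward a common prior. The prior degrees of freedom `d0`
#' and prior variance `s0^2` are estimated by moment matching on the log
#' sample variances; each gene's posterior variance is
#' `(d0 * s0^2 + dg * s2_g) / (d0 + dg)` and the t statistic is referred to a
#' t distribution on `d0 + dg` degrees of freedom. With fewer than 10 genes,
#' or with `prior_df = 0`, the ordinary pooled two-sample t-test is used.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param group_labels Logical or two-level vector over columns; `TRUE` (or
#'   the first level) marks the group of interest.
#' @param prior_df Optional override of the prior degrees of freedom; `NULL`
#'   (default) estimates it from the data, `0` gives the ordinary t-test,
#'   `Inf` shrinks every gene fully to the prior variance.
#' @return A data.frame with one row per gene: `gene_id`, `log_fc`
#'   (mean(group) - mean(rest)), `t`, `p`, `s2` (sample variance pooled over
#'   groups) and attributes `df_prior` and `s2_prior`.
#' @export
moderated_t_two_group <- function(expr, group_labels, prior_df = NULL) {
  expr <- as.matrix(expr)
  if (is.logical(group_labels)) {
    g1 <- group_labels
  } else {
    lev <- unique(group_labels)
    if (length(lev) != 2L) stop("'group_labels' must have exactly two levels")
    g1 <- group_labels == lev[1L]
  }
  if (length(g1) != ncol(expr)) stop("'group_labels' must match columns of 'expr'")
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(expr[, !g1, drop = FALSE], 1L, stats::var)
  dg <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / dg

  ngene <- nrow(expr)
  if (is.null(prior_df) && ngene < 10L) prior_df <- 0

  if (is.null(prior_df)) {
    pos <- s2 > 0
    if (sum(pos) < 2L) {
      d0 <- Inf
      s02 <- mean(s2)
    } else {
      e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
      emean <- mean(e)
      evar <- stats::var(e) - trigamma(dg / 2)
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigamma_inverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(emean)
      }
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2[s2 > 0]) else NA_real_
    if (d0 > 0 && !is.finite(s02)) s02 <- mean(s2)
  }

  s2_post <- if (is.infinite(d0)) rep(s02, ngene) else if (d0 == 0) s2 else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0] <- 1  # identical, variance-free genes carry no evidence

  out <- data.frame(
    gene_id = if (is.null(rownames(expr))) as.character(seq_len(ngene)) else rownames(expr),
    log_fc = m1 - m2,
    t = tstat,
    p = p,
    s2 = s2,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  out
}

# Lean Wilcoxon p-value used inside per-gene scans: exact via the null U
# distribution for small tie-free groups, otherwise normal approximation
# with tie and continuity corrections. Matches wilcoxon_rank_sum().
wilcox_p_fast <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= 10L && ny <= 10L && !anyDuplicated(c(x, y))) {
    p <- switch(alternative,
      two.sided = {
        if (U > nx * ny / 2) {
          min(1, 2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(U, nx, ny))
        }
      },
      greater = stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE),
      less = stats::pwilcox(U, nx, ny)
    )
    return(p)
  }
  mu <- nx * ny / 2
  tie_tab <- rle(sort.int(c(x, y), method = "quick"))$lengths
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  z <- U - mu
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm((abs(z) - 0.5) / sigma, lower.tail = FALSE),
    greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((z + 0.5) / sigma)
  )
  min(1, max(0, p))
}
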