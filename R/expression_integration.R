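# Per-gene integration of copy-number state with bulk expression: variance
# filtering, the "in cis" gain/upregulation (and loss/downregulation) test,
# and the amplification-expression concordance rules.

#' Filter genes by expression variance
#'
#' Retains genes whose sample variance (n - 1 denominator) is at least
#' `min_variance`; low-variance genes carry no usable dosage signal.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param min_variance Variance cutoff; default 0.1.
#' @return Character vector of retained gene ids (rownames).
#' @export
filter_low_variance <- function(expr, min_variance = 0.1) {
  if (ncol(expr) < 2L) stop("need at least 2 samples to compute variance")
  v <- apply(expr, 1L, stats::var)
  rownames(expr)[v >= min_variance]
}

#' In cis dosage test for a single gene
#'
#' Compares expression between copy-number aberrant (gain or loss) and
#' neutral samples with a two-sided Wilcoxon rank-sum test, and correlates
#' expression with the continuous relative copy-number value by Spearman's
#' rho over all samples with a non-missing copy-number call. FDR adjustment
#' and the final in cis flag are applied across a gene family by
#' [in_cis_scan()].
#'
#' @param expr Numeric expression values per sample.
#' @param cn_state Per-sample state in `{"loss", "neutral", "gain"}` or `NA`.
#' @param cn_value Per-sample relative copy-number value (`NA` allowed).
#' @param direction `"gain-up"` (gain vs neutral) or `"loss-down"` (loss vs
#'   neutral).
#' @param min_per_group Minimum samples required in both the aberrant and
#'   the neutral group; genes below it are flagged not evaluable.
#' @return A list with `wilcoxon_p`, `rho`, `rho_p`, `n_aberrant`,
#'   `n_neutral`, `direction_ok` (aberrant group median on the expected side
#'   of neutral) and `evaluable`.
#' @export
in_cis_test <- function(expr, cn_state, cn_value,
                        direction = c("gain-up", "loss-down"),
                        min_per_group = 10) {
  direction <- match.arg(direction)
  aberrant_state <- if (direction == "gain-up") "gain" else "loss"
  ab <- !is.na(cn_state) & cn_state == aberrant_state
  nt <- !is.na(cn_state) & cn_state == "neutral"
  n_ab <- sum(ab); n_nt <- sum(nt)
  out <- list(wilcoxon_p = NA_real_, rho = NA_real_, rho_p = NA_real_,
              n_aberrant = n_ab, n_neutral = n_nt,
              direction_ok = NA, evaluable = FALSE)
  if (n_ab < min_per_group || n_nt < min_per_group) return(out)
  out$evaluable <- TRUE
  out$wilcoxon_p <- wilcox_p_fast(expr[ab], expr[nt])
  med_diff <- stats::median(expr[ab]) - stats::median(expr[nt])
  out$direction_ok <- if (direction == "gain-up") med_diff > 0 else med_diff < 0
  ok <- !is.na(cn_value)
  if (sum(ok) >= 3 && stats::sd(expr[ok]) > 0 && stats::sd(cn_value[ok]) > 0) {
    sp <- spearman_corr(expr[ok], cn_value[ok])
    out$rho <- sp$rho
    out$rho_p <- sp$p_value
  }
  out
}

#' Genome-wide in cis scan
#'
#' Runs [in_cis_test()] for every gene, applies Benjamini-Hochberg FDR
#' correction across the evaluable genes (one family per direction), and
#' flags a gene as in cis when the Wilcoxon FDR is below `fdr_cutoff`, the
#' expression shift is in the tested direction, Spearman's rho is positive
#' and its FDR is below `fdr_cutoff`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param cn_value,cn_state Matching copy-number matrices from
#'   [gene_cn_matrix()] (same dimnames).
#' @param direction `"gain-up"` or `"loss-down"`.
#' @param min_per_group Minimum group size (10 for genome-wide runs, 3 in
#'   resampling runs).
#' @param fdr_cutoff Significance cutoff on both FDR values; default 0.05.
#' @return data.frame with one row per gene: `gene_id`, `direction`,
#'   `wilcoxon_p`, `fdr`, `rho`, `rho_fdr`, `n_aberrant`, `n_neutral`,
#'   `evaluable`, `in_cis`.
#' @export
in_cis_scan <- function(expr, cn_value, cn_state,
                        direction = c("gain-up", "loss-down"),
                        min_per_group = 10, fdr_cutoff = 0.05) {
  direction <- match.arg(direction)
  genes <- rownames(expr)
  stopifnot(identical(dim(expr), dim(cn_value)), identical(dim(expr), dim(cn_state)))
  n <- length(genes)
  aberrant_state <- if (direction == "gain-up") "gain" else "loss"
  is_ab <- !is.na(cn_state) & cn_state == aberrant_state
  is_nt <- !is.na(cn_state) & cn_state == "neutral"
  has_cn <- !is.na(cn_value)
  n_ab <- rowSums(is_ab); n_nt <- rowSums(is_nt)
  evaluable <- n_ab >= min_per_group & n_nt >= min_per_group
  wilcoxon_p <- rho <- rho_p <- rep(NA_real_, n)
  dir_ok <- rep(NA, n)
  for (i in which(evaluable)) {
    xa <- expr[i, is_ab[i, ]]
    xn <- expr[i, is_nt[i, ]]
    wilcoxon_p[i] <- wilcox_p_fast(xa, xn)
    md <- stats::median(xa) - stats::median(xn)
    dir_ok[i] <- if (direction == "gain-up") md > 0 else md < 0
    ok <- has_cn[i, ]
    if (sum(ok) >= 3L) {
      re <- rank(expr[i, ok]); rv <- rank(cn_value[i, ok])
      if (stats::var(re) > 0 && stats::var(rv) > 0) {
        r1 <- stats::cor(re, rv)
        n0 <- length(re)
        tstat <- r1 * sqrt((n0 - 2) / (1 - min(r1^2, 1 - 1e-12)))
        rho[i] <- r1
        rho_p[i] <- 2 * stats::pt(-abs(tstat), df = n0 - 2)
      }
    }
  }
  fdr <- rho_fdr <- rep(NA_real_, n)
  if (any(evaluable)) {
    fdr[evaluable] <- bh_adjust(wilcoxon_p[evaluable])
    rho_fdr[evaluable] <- bh_adjust(rho_p[evaluable])
  }
  in_cis <- evaluable & !is.na(fdr) & fdr < fdr_cutoff &
    !is.na(dir_ok) & dir_ok &
    !is.na(rho) & rho > 0 & !is.na(rho_fdr) & rho_fdr < fdr_cutoff
  data.frame(
    gene_id = genes, direction = direction,
    wilcoxon_p = wilcoxon_p, fdr = fdr,
    rho = rho, rho_fdr = rho_fdr,
    n_aberrant = n_ab, n_neutral = n_nt,
    evaluable = evaluable, in_cis = in_cis,
    stringsAsFactors = FALSE
  )
}

#' Outlier-expression concordance of an amplification peak
#'
#' A peak passes when at least one covered gene shows outlier expression in
#' the amplified sample: strictly above the third quartile plus 1.5 times
#' the interquartile range, both computed over the full cohort with type-7
#' (linear-interpolation) quantiles.
#'
#' @param peak One row of a peak table (needs `sample` and list-column
#'   `genes`).
#' @param expr Expression matrix over the full cohort.
#' @return A list with `rule = "outlier"`, `passed`, `evaluable` and
#'   `n_genes_tested`.
#' @export
outlier_expression_flag <- function(peak, expr) {
  gset <- intersect(unlist(peak$genes), rownames(expr))
  if (length(gset) == 0L || !(peak$sample %in% colnames(expr))) {
    return(list(rule = "outlier", passed = NA, evaluable = FALSE, n_genes_tested = 0L))
  }
  passed <- FALSE
  for (g in gset) {
    v <- expr[g, ]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    cutoff <- q[2] + 1.5 * (q[2] - q[1])
    if (expr[g, peak$sample] > cutoff) { passed <- TRUE; break }
  }
  list(rule = "outlier", passed = passed, evaluable = TRUE,
       n_genes_tested = length(gset))
}

#' Top-rank concordance of amplification and expression for one gene
#'
#' With `k` amplified samples, the rank window is the top 5 samples by
#' expression when `k < 5`, otherwise the top `ceiling(1.5 * k)`. The gene
#' passes when at least 50% of the amplified samples fall inside the window.
#' Ties in expression are broken by stable sample order.
#'
#' @param amplified_samples Character vector of amplified sample ids
#'   (`k >= 1`).
#' @param expr_values Named numeric vector of the gene's expression over the
#'   cohort.
#' @param window_rounding `"ceiling"` (default) or `"nearest"` for the
#'   `1.5 * k` window size.
#' @return A list with `rule = "top_rank"`, `passed`, `k_amplified`,
#'   `rank_window` and `n_in_window`.
#' @export
top_rank_concordance <- function(amplified_samples, expr_values,
                                 window_rounding = c("ceiling", "nearest")) {
  window_rounding <- match.arg(window_rounding)
  k <- length(amplified_samples)
  if (k == 0L) stop("need at least one amplified sample")
  if (is.null(names(expr_values))) stop("'expr_values' must be named by sample")
  if (!all(amplified_samples %in% names(expr_values))) {
    stop("amplified samples missing from expression values")
  }
  m <- if (k < 5) 5L else if (window_rounding == "ceiling") {
    as.integer(ceiling(1.5 * k))
  } else {
    as.integer(round(1.5 * k))
  }
  m <- min(m, length(expr_values))
  ord <- order(-expr_values)  # stable: ties keep original sample order
  top <- names(expr_values)[ord[seq_len(m)]]
  n_in <- sum(amplified_samples %in% top)
  list(rule = "top_rank", passed = n_in >= 0.5 * k,
       k_amplified = k, rank_window = m, n_in_window = n_in)
}
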