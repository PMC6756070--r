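# Quantifying how much of each CMS subtype's preferential expression is
# copy-number driven: one-vs-rest differential expression, overlap with the
# in cis gain/upregulation set, subtype resampling (three variants),
# gene-list resampling, microenvironment depletion and compartment
# enrichment.

.MICROENV <- c("fibroblast", "endothelial", "leukocyte")

# Deterministic per-iteration sub-seed from the root seed, independent of
# iteration order; kept below 2^31 - 1.
.iter_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483587)
}

#' Genes preferentially upregulated in a subtype
#'
#' One-vs-rest moderated-t contrast of a CMS subtype against the remaining
#' classified samples. A gene is upregulated when its FDR-adjusted p-value
#' is below `fdr_cutoff` and its log2 fold change strictly exceeds
#' `log2(fold_change)`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Per-sample CMS labels (`NA` = unclassified, excluded).
#' @param subtype Subtype to contrast.
#' @param fdr_cutoff FDR threshold; default 0.05.
#' @param fold_change Fold-change threshold on the natural scale; default
#'   1.2.
#' @return data.frame with `gene_id`, `contrast`, `log_fc`, `p`, `fdr`,
#'   `upregulated`.
#' @export
de_upregulated <- function(expr, labels, subtype,
                           fdr_cutoff = 0.05, fold_change = 1.2) {
  keep <- !is.na(labels)
  if (!subtype %in% labels[keep]) stop("subtype '", subtype, "' absent from labels")
  e <- expr[, keep, drop = FALSE]
  grp <- labels[keep] == subtype
  res <- moderated_t_two_group(e, grp)
  fdr <- bh_adjust(res$p)
  data.frame(
    gene_id = res$gene_id,
    contrast = paste0(subtype, "-vs-rest"),
    log_fc = res$log_fc,
    p = res$p,
    fdr = fdr,
    upregulated = fdr < fdr_cutoff & res$log_fc > log2(fold_change),
    stringsAsFactors = FALSE
  )
}

#' Fraction of upregulated genes that are in cis gain/upregulated
#'
#' @param upregulated Character vector of subtype-upregulated gene ids.
#' @param in_cis_gain Character vector of in cis gain/upregulated gene ids.
#' @param subtype Optional subtype label carried through.
#' @return A list with `subtype`, `n_upregulated`, `n_overlap` and
#'   `overlap_fraction` (`NA` with `undefined = TRUE` when the upregulated
#'   set is empty).
#' @export
overlap_fraction <- function(upregulated, in_cis_gain, subtype = NA_character_) {
  n_up <- length(unique(upregulated))
  n_ov <- length(intersect(unique(upregulated), unique(in_cis_gain)))
  list(
    subtype = subtype,
    n_upregulated = n_up,
    n_overlap = n_ov,
    overlap_fraction = if (n_up > 0) n_ov / n_up else NA_real_,
    undefined = n_up == 0
  )
}

#' Subtype resampling of the in cis enrichment
#'
#' Per iteration, `per_group` tumors are drawn without replacement from each
#' of the two subtypes, the in cis gain/upregulation analysis is recomputed
#' on the pooled tumors (FDR within the iteration's own gene family), and
#' the per-subtype overlap fraction of upregulated genes with the in cis set
#' is recorded. Three variants control where the upregulated lists come
#' from: `"i"` recomputes differential expression on the sampled tumors
#' (subtype vs subtype contrast); `"ii"` uses the original all-sample
#' upregulated lists; `"iii"` draws `size` genes at random from the original
#' upregulated lists.
#'
#' `prop_a_greater` counts iterations where subtype a's fraction strictly
#' exceeds subtype b's, with ties (including both fractions zero or
#' undefined) split evenly.
#'
#' @param expr Expression matrix over the cohort.
#' @param cn_value,cn_state Gene-level copy-number matrices.
#' @param labels Per-sample CMS labels.
#' @param pair Character vector of the two subtypes compared, e.g.
#'   `c("CMS2", "CMS4")`.
#' @param variant `"i"`, `"ii"` or `"iii"`.
#' @param n_iter Number of iterations; default 1000.
#' @param per_group Tumors sampled per subtype; default 20.
#' @param seed Root seed; per-iteration sub-seeds are derived from it so the
#'   result is reproducible and independent of iteration order.
#' @param upregulated_a,upregulated_b Original all-sample upregulated gene
#'   lists (required for variants `"ii"` and `"iii"`).
#' @param size Genes drawn per list in variant `"iii"`; default 250.
#' @param min_per_group In cis group-size threshold inside iterations;
#'   default 3.
#' @param fdr_cutoff,fold_change Differential-expression thresholds for
#'   variant `"i"`.
#' @return A list of class `"resample_distribution"`: `pair`, `variant`,
#'   `n_iter`, `seed`, `fractions_a`, `fractions_b`, `prop_a_greater`.
#' @export
resample_enrichment <- function(expr, cn_value, cn_state, labels, pair,
                                variant = c("ii", "i", "iii"),
                                n_iter = 1000, per_group = 20, seed = 1,
                                upregulated_a = NULL, upregulated_b = NULL,
                                size = 250, min_per_group = 3,
                                fdr_cutoff = 0.05, fold_change = 1.2) {
  variant <- match.arg(variant)
  stopifnot(length(pair) == 2L)
  samp_a <- colnames(expr)[!is.na(labels) & labels == pair[1L]]
  samp_b <- colnames(expr)[!is.na(labels) & labels == pair[2L]]
  if (length(samp_a) < per_group || length(samp_b) < per_group) {
    stop("both subtypes need at least ", per_group, " samples")
  }
  if (variant %in% c("ii", "iii") &&
      (is.null(upregulated_a) || is.null(upregulated_b))) {
    stop("variants 'ii' and 'iii' need the original upregulated gene lists")
  }
  if (variant == "iii" &&
      (length(upregulated_a) < size || length(upregulated_b) < size)) {
    stop("variant 'iii' needs upregulated lists of at least ", size, " genes")
  }

  fa <- fb <- rep(NA_real_, n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(.iter_seed(seed, it))
    sa <- sample(samp_a, per_group)
    sb <- sample(samp_b, per_group)
    sel <- c(sa, sb)
    scan <- in_cis_scan(expr[, sel, drop = FALSE],
                        cn_value[, sel, drop = FALSE],
                        cn_state[, sel, drop = FALSE],
                        direction = "gain-up",
                        min_per_group = min_per_group,
                        fdr_cutoff = fdr_cutoff)
    cis_genes <- scan$gene_id[scan$in_cis]
    if (variant == "i") {
      grp <- c(rep(TRUE, per_group), rep(FALSE, per_group))
      de <- moderated_t_two_group(expr[, sel, drop = FALSE], grp)
      defdr <- bh_adjust(de$p)
      up_a <- de$gene_id[defdr < fdr_cutoff & de$log_fc > log2(fold_change)]
      up_b <- de$gene_id[defdr < fdr_cutoff & de$log_fc < -log2(fold_change)]
    } else if (variant == "ii") {
      up_a <- upregulated_a
      up_b <- upregulated_b
    } else {
      up_a <- sample(upregulated_a, size)
      up_b <- sample(upregulated_b, size)
    }
    fa[it] <- overlap_fraction(up_a, cis_genes)$overlap_fraction
    fb[it] <- overlap_fraction(up_b, cis_genes)$overlap_fraction
  }
  fa0 <- ifelse(is.na(fa), 0, fa)
  fb0 <- ifelse(is.na(fb), 0, fb)
  structure(list(
    pair = pair, variant = variant, n_iter = n_iter, seed = seed,
    fractions_a = fa, fractions_b = fb,
    prop_a_greater = mean(fa0 > fb0) + 0.5 * mean(fa0 == fb0)
  ), class = "resample_distribution")
}

#' Gene-list resampling of the overlap fraction
#'
#' Per iteration, `size` genes are drawn without replacement from the
#' subtype-upregulated list and from the in cis gain/upregulated list, and
#' the overlap fraction `|intersection| / size` is recorded. Controls for
#' unequal list lengths across subtypes.
#'
#' @param upregulated,in_cis_gain Gene lists, both of length `>= size`.
#' @param size Genes drawn per list; default 250.
#' @param n_iter Iterations; default 1000.
#' @param seed Root seed.
#' @return A list of class `"resample_distribution"` with `fractions`
#'   (length `n_iter`), `size`, `n_iter`, `seed`.
#' @export
resample_gene_lists <- function(upregulated, in_cis_gain, size = 250,
                                n_iter = 1000, seed = 1) {
  upregulated <- unique(upregulated); in_cis_gain <- unique(in_cis_gain)
  if (length(upregulated) < size || length(in_cis_gain) < size) {
    stop("both gene lists must contain at least ", size, " genes")
  }
  fr <- vapply(seq_len(n_iter), function(it) {
    set.seed(.iter_seed(seed, it))
    su <- sample(upregulated, size)
    sc <- sample(in_cis_gain, size)
    length(intersect(su, sc)) / size
  }, numeric(1))
  structure(list(fractions = fr, size = size, n_iter = n_iter, seed = seed),
            class = "resample_distribution")
}

#' Compartment-specific genes from sorted-cell expression
#'
#' One-vs-rest differential expression over a compartment-sorted reference
#' (epithelial, endothelial, fibroblast, leukocyte), returning the
#' upregulated gene set per compartment at the same FDR and fold-change
#' thresholds as the subtype contrasts.
#'
#' @param compartment_expr Expression matrix of the sorted reference.
#' @param compartment_labels Per-column compartment labels; all four
#'   compartments must be present with at least 2 replicates each.
#' @param fdr_cutoff,fold_change Thresholds; defaults 0.05 and 1.2.
#' @return Named list of character vectors, one gene set per compartment.
#' @export
compartment_specific_genes <- function(compartment_expr, compartment_labels,
                                       fdr_cutoff = 0.05, fold_change = 1.2) {
  comps <- c("epithelial", .MICROENV)
  missing <- setdiff(comps, unique(compartment_labels))
  if (length(missing)) stop("missing compartments: ", paste(missing, collapse = ", "))
  out <- lapply(comps, function(cp) {
    de <- de_upregulated(compartment_expr, compartment_labels, cp,
                         fdr_cutoff = fdr_cutoff, fold_change = fold_change)
    de$gene_id[de$upregulated]
  })
  names(out) <- comps
  out
}

#' Deplete a gene set of microenvironment-specific genes
#'
#' Removes genes upregulated in any of the fibroblast, endothelial or
#' leukocyte compartments; epithelial-specific genes are retained.
#'
#' @param upregulated Character vector of gene ids.
#' @param compartment_sets Named list from [compartment_specific_genes()].
#' @return The retained gene ids.
#' @export
deplete_microenvironment <- function(upregulated, compartment_sets) {
  micro <- unique(unlist(compartment_sets[.MICROENV]))
  setdiff(upregulated, micro)
}

#' Compartment enrichment of the in cis gene set
#'
#' For each compartment, a 2x2 Fisher's exact test of membership in the in
#' cis gain/upregulated set against membership in the compartment-specific
#' set, over a stated gene universe.
#'
#' @param in_cis_gain Character vector of in cis gain/upregulated genes.
#' @param compartment_sets Named list from [compartment_specific_genes()].
#' @param universe All tested genes.
#' @return data.frame with `compartment`, `odds_ratio`, `p`, and the 2x2
#'   counts; rows with an empty in cis set are flagged not evaluable via
#'   `NA` results.
#' @export
compartment_enrichment <- function(in_cis_gain, compartment_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  in_cis <- intersect(unique(in_cis_gain), universe)
  rows <- lapply(names(compartment_sets), function(cp) {
    cset <- intersect(compartment_sets[[cp]], universe)
    a <- length(intersect(in_cis, cset))
    b <- length(setdiff(in_cis, cset))
    c <- length(setdiff(cset, in_cis))
    d <- length(universe) - a - b - c
    if (length(in_cis) == 0L) {
      return(data.frame(compartment = cp, odds_ratio = NA_real_, p = NA_real_,
                        n11 = a, n10 = b, n01 = c, n00 = d,
                        stringsAsFactors = FALSE))
    }
    ft <- fisher_exact(matrix(c(a, c, b, d), 2L))
    data.frame(compartment = cp, odds_ratio = ft$statistic, p = ft$p_value,
               n11 = a, n10 = b, n01 = c, n00 = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of a gene set on one chromosome arm
#'
#' @param genes Character vector of gene ids.
#' @param arm Arm label, e.g. `"20q"`.
#' @param annotation Gene annotation data.frame with `gene_id` and `arm`.
#' @return Proportion of the annotated genes located on the arm;
#'   unannotated genes are dropped from the denominator with a warning.
#' @export
arm_fraction <- function(genes, arm, annotation) {
  genes <- unique(genes)
  known <- genes %in% annotation$gene_id
  if (any(!known)) {
    warning(sum(!known), " gene(s) without annotation excluded from denominator")
  }
  g <- genes[known]
  if (length(g) == 0L) return(NA_real_)
  arms <- annotation$arm[match(g, annotation$gene_id)]
  mean(arms == arm)
}

#' Median copy-number/expression correlation within a sample subset
#'
#' Spearman correlation of each gene's expression with its relative
#' copy-number value over the given samples; returns the median rho across
#' genes (genes with constant expression or copy number are dropped).
#'
#' @param expr Expression matrix.
#' @param cn_value Gene-level copy-number value matrix.
#' @param samples Sample ids of the subset (at least 3).
#' @return Median Spearman rho across evaluable genes (`NA` if none).
#' @export
median_cn_expr_correlation <- function(expr, cn_value, samples) {
  if (length(samples) < 3L) stop("need at least 3 samples")
  e <- expr[, samples, drop = FALSE]
  v <- cn_value[, samples, drop = FALSE]
  rho <- vapply(seq_len(nrow(e)), function(i) {
    ok <- !is.na(v[i, ]) & !is.na(e[i, ])
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(e[i, ok]) == 0 || stats::sd(v[i, ok]) == 0) return(NA_real_)
    stats::cor(rank(e[i, ok]), rank(v[i, ok]))
  }, numeric(1))
  stats::median(rho, na.rm = TRUE)
}

#' Compare two resampled fraction distributions
#'
#' Thin wrapper around [ks_two_sample()] for the density distributions of
#' per-iteration overlap fractions.
#'
#' @param dist_a,dist_b Numeric vectors of fractions.
#' @return As [ks_two_sample()].
#' @export
ks_compare <- function(dist_a, dist_b) ks_two_sample(dist_a, dist_b)
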