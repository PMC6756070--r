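# End-to-end orchestration: copy-number core -> expression integration ->
# CMS enrichment -> survival, with every threshold collected in one
# configuration object that is stamped into the results bundle.

#' Pipeline configuration
#'
#' All analysis thresholds in one place. Defaults follow the study design:
#' gain/loss call thresholds of +/-0.15 on median-centered log-ratios,
#' amplification at >= 5 additional copies over the sample-wise genome-wide
#' median, high-level at >= 15, focality at <= 50 genes in the peak,
#' expression variance filter at 0.1, FDR 0.05, fold change 1.2, ploidy
#' dichotomy at 2.2n, in cis group minima of 10 (genome-wide) and 3
#' (resampling), 20 tumors per subtype per resampling iteration, and a
#' 5-year survival horizon.
#'
#' @param gain_threshold,loss_threshold Copy-number call thresholds.
#' @param amp_min_additional Amplification threshold (additional copies).
#' @param amp_high_level High-level amplification threshold.
#' @param focal_max_genes Focality threshold (genes in peak).
#' @param min_variance Expression variance filter.
#' @param fdr_cutoff FDR significance threshold.
#' @param fold_change Fold-change threshold (natural scale).
#' @param ploidy_cutoff High-ploidy cutoff.
#' @param min_per_group_genomewide,min_per_group_resample In cis group-size
#'   minima.
#' @param resample_iters Resampling iterations.
#' @param resample_per_group Tumors per subtype per iteration.
#' @param resample_size Genes per list in gene-list resampling / variant iii.
#' @param resample_pairs List of subtype pairs compared by resampling
#'   (CMS1 excluded by default for its low sample number).
#' @param min_tumors Recurrence threshold for amplified genes.
#' @param survival_horizon Overall-survival horizon in years.
#' @param seed Root seed for every stochastic step.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(gain_threshold = 0.15,
                            loss_threshold = -0.15,
                            amp_min_additional = 5,
                            amp_high_level = 15,
                            focal_max_genes = 50,
                            min_variance = 0.1,
                            fdr_cutoff = 0.05,
                            fold_change = 1.2,
                            ploidy_cutoff = 2.2,
                            min_per_group_genomewide = 10,
                            min_per_group_resample = 3,
                            resample_iters = 200,
                            resample_per_group = 20,
                            resample_size = 250,
                            resample_pairs = list(c("CMS2", "CMS3"),
                                                  c("CMS2", "CMS4"),
                                                  c("CMS3", "CMS4")),
                            min_tumors = 2,
                            survival_horizon = 5,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$gain_threshold > 0, cfg$loss_threshold < 0,
            cfg$amp_min_additional > 0, cfg$amp_high_level >= cfg$amp_min_additional,
            cfg$focal_max_genes > 0, cfg$fdr_cutoff > 0, cfg$fold_change > 1,
            cfg$survival_horizon > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full integrative pipeline on a cohort
#'
#' Stages, in order: (1) restrict to microsatellite-stable tumors and
#' median-center their relative profiles; (2) gene-level copy-number calls
#' and per-sample genome summaries (aberrant fraction, LOH fraction, ploidy
#' with the 2.2n dichotomy); (3) amplification peaks and recurrently
#' amplified genes with Wilson confidence intervals; (4) variance-filtered
#' in cis gain/upregulation and loss/downregulation scans; (5) peak-level
#' outlier-expression and gene-level top-rank amplification concordance;
#' (6) per-subtype upregulated genes, overlap with the in cis gain set,
#' microenvironment depletion (when a compartment reference is given) and
#' pairwise subtype resampling; (7) survival analysis of carriers of
#' recurrent focal amplifications (high-level primary, >= 5 additional
#' copies secondary).
#'
#' @param cohort A list with `genes`, `rel_segments`, `allelic_segments`,
#'   `expr`, `metadata` — as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param config A [pipeline_config()].
#' @param compartment_ref Optional list with `expr` and `labels` (a sorted
#'   compartment reference); enables depletion and compartment enrichment.
#' @param resample_variant Resampling variant passed to
#'   [resample_enrichment()]; default `"iii"`.
#' @return A results bundle (list) with per-stage tables and the config.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         compartment_ref = NULL,
                         resample_variant = "iii") {
  cfg <- config
  md <- cohort$metadata
  mss <- md$sample[md$msi == "MSS"]
  log_counts <- list(n_total = nrow(md), n_mss = length(mss))

  rel <- cohort$rel_segments[cohort$rel_segments$sample %in% mss, , drop = FALSE]
  ase <- cohort$allelic_segments[cohort$allelic_segments$sample %in% mss, , drop = FALSE]
  rel <- center_profiles(rel)

  # --- per-sample genome summaries -------------------------------------
  summaries <- do.call(rbind, lapply(mss, function(s) {
    rs <- rel[rel$sample == s, , drop = FALSE]
    as <- ase[ase$sample == s, , drop = FALSE]
    pl <- estimate_ploidy(as, cutoff = cfg$ploidy_cutoff)
    data.frame(
      sample = s,
      fraction_aberrant = fraction_genome_aberrant(rs, cfg$gain_threshold, cfg$loss_threshold),
      fraction_loh = call_loh(as)$fraction_loh,
      ploidy = pl$ploidy,
      ploidy_group = pl$ploidy_group,
      median_total_cn = sample_median_total_cn(as),
      stringsAsFactors = FALSE
    )
  }))

  # --- gene-level copy number ------------------------------------------
  cn <- gene_cn_matrix(cohort$genes, rel, cfg$gain_threshold, cfg$loss_threshold)

  # --- amplification peaks ---------------------------------------------
  peaks <- call_amplicon_peaks_cohort(ase, cohort$genes,
                                      min_additional = cfg$amp_min_additional,
                                      high_level_min = cfg$amp_high_level,
                                      focal_max_genes = cfg$focal_max_genes)
  n_mss <- length(mss)
  amp_any <- unique(peaks$sample)
  recurrent <- recurrent_amplified_genes(peaks, n_mss,
                                         min_additional = cfg$amp_min_additional,
                                         min_tumors = cfg$min_tumors)
  recurrent_high <- recurrent_amplified_genes(peaks, n_mss,
                                              min_additional = cfg$amp_high_level,
                                              min_tumors = cfg$min_tumors,
                                              focal_only = TRUE)
  amp_summary <- list(
    n_with_amplification = length(amp_any),
    frac_with_amplification = length(amp_any) / n_mss,
    frac_high_ploidy_with_amp =
      mean(summaries$sample[summaries$ploidy_group == "high"] %in% amp_any),
    frac_low_ploidy_with_amp =
      mean(summaries$sample[summaries$ploidy_group == "low"] %in% amp_any)
  )

  # --- in cis integration ----------------------------------------------
  expr <- cohort$expr[, mss, drop = FALSE]
  keep_genes <- filter_low_variance(expr, cfg$min_variance)
  log_counts$n_genes_variance_kept <- length(keep_genes)
  e <- expr[keep_genes, , drop = FALSE]
  v <- cn$value[keep_genes, mss, drop = FALSE]
  s <- cn$state[keep_genes, mss, drop = FALSE]
  cis_gain <- in_cis_scan(e, v, s, "gain-up",
                          min_per_group = cfg$min_per_group_genomewide,
                          fdr_cutoff = cfg$fdr_cutoff)
  cis_loss <- in_cis_scan(e, v, s, "loss-down",
                          min_per_group = cfg$min_per_group_genomewide,
                          fdr_cutoff = cfg$fdr_cutoff)

  # --- amplification/expression concordance ----------------------------
  hl_focal <- peaks[peaks$high_level & peaks$focal, , drop = FALSE]
  outlier_flags <- if (nrow(hl_focal)) {
    data.frame(
      sample = hl_focal$sample, chrom = hl_focal$chrom, start = hl_focal$start,
      passed = vapply(seq_len(nrow(hl_focal)), function(i) {
        isTRUE(outlier_expression_flag(hl_focal[i, ], expr)$passed)
      }, logical(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sample = character(0), chrom = character(0),
               start = integer(0), passed = logical(0))
  }
  top_rank <- if (nrow(recurrent)) {
    long <- data.frame(
      sample = rep(peaks$sample, lengths(peaks$genes)),
      gene_id = unlist(peaks$genes), stringsAsFactors = FALSE
    )
    long <- unique(long[long$gene_id %in% intersect(recurrent$gene_id, keep_genes), ])
    carriers_by_gene <- split(long$sample, long$gene_id)
    do.call(rbind, lapply(names(carriers_by_gene), function(g) {
      tr <- top_rank_concordance(carriers_by_gene[[g]], expr[g, ])
      data.frame(gene_id = g, passed = tr$passed, k_amplified = tr$k_amplified,
                 rank_window = tr$rank_window, stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  if (is.null(top_rank)) {
    top_rank <- data.frame(gene_id = character(0), passed = logical(0),
                           k_amplified = integer(0), rank_window = integer(0))
  }

  # --- CMS enrichment ---------------------------------------------------
  labels <- md$cms[match(mss, md$sample)]
  subtypes <- intersect(c("CMS1", "CMS2", "CMS3", "CMS4"), unique(stats::na.omit(labels)))
  de_list <- lapply(subtypes, function(st) {
    de_upregulated(e, labels, st, cfg$fdr_cutoff, cfg$fold_change)
  })
  names(de_list) <- subtypes
  cis_gain_genes <- cis_gain$gene_id[cis_gain$in_cis]
  overlaps <- do.call(rbind, lapply(subtypes, function(st) {
    up <- de_list[[st]]$gene_id[de_list[[st]]$upregulated]
    ov <- overlap_fraction(up, cis_gain_genes, st)
    data.frame(subtype = st, n_upregulated = ov$n_upregulated,
               n_overlap = ov$n_overlap, overlap_fraction = ov$overlap_fraction,
               stringsAsFactors = FALSE)
  }))

  compartment <- NULL
  if (!is.null(compartment_ref)) {
    csets <- compartment_specific_genes(compartment_ref$expr[keep_genes, , drop = FALSE],
                                        compartment_ref$labels,
                                        cfg$fdr_cutoff, cfg$fold_change)
    depleted <- do.call(rbind, lapply(subtypes, function(st) {
      up <- de_list[[st]]$gene_id[de_list[[st]]$upregulated]
      ret <- deplete_microenvironment(up, csets)
      ov <- overlap_fraction(ret, cis_gain_genes, st)
      data.frame(subtype = st, n_upregulated = length(up), n_retained = length(ret),
                 retained_fraction = if (length(up)) length(ret) / length(up) else NA_real_,
                 overlap_fraction_depleted = ov$overlap_fraction,
                 stringsAsFactors = FALSE)
    }))
    enrich <- compartment_enrichment(cis_gain_genes, csets, keep_genes)
    compartment <- list(sets = csets, depleted = depleted, enrichment = enrich)
  }

  resample <- list()
  for (pair in cfg$resample_pairs) {
    if (!all(pair %in% subtypes)) next
    na <- sum(labels == pair[1], na.rm = TRUE); nb <- sum(labels == pair[2], na.rm = TRUE)
    if (na < cfg$resample_per_group || nb < cfg$resample_per_group) next
    up_a <- de_list[[pair[1]]]$gene_id[de_list[[pair[1]]]$upregulated]
    up_b <- de_list[[pair[2]]]$gene_id[de_list[[pair[2]]]$upregulated]
    if (resample_variant == "iii" &&
        (length(up_a) < cfg$resample_size || length(up_b) < cfg$resample_size)) next
    resample[[paste(pair, collapse = "_vs_")]] <- resample_enrichment(
      e, v, s, labels, pair, variant = resample_variant,
      n_iter = cfg$resample_iters, per_group = cfg$resample_per_group,
      seed = cfg$seed, upregulated_a = up_a, upregulated_b = up_b,
      size = cfg$resample_size, min_per_group = cfg$min_per_group_resample,
      fdr_cutoff = cfg$fdr_cutoff, fold_change = cfg$fold_change
    )
  }

  # --- survival ---------------------------------------------------------
  carriers_high <- unique(hl_focal$sample[
    vapply(hl_focal$genes, function(g) any(g %in% recurrent_high$gene_id), logical(1))
  ])
  focal5 <- peaks[peaks$focal, , drop = FALSE]
  carriers_5 <- unique(focal5$sample[
    vapply(focal5$genes, function(g) any(g %in% recurrent$gene_id), logical(1))
  ])
  survival <- NULL
  rec <- try(build_survival_records(md, carriers_high, cfg$survival_horizon), silent = TRUE)
  if (!inherits(rec, "try-error") && nrow(rec) > 5 &&
      length(unique(rec$amplified)) == 2 && sum(rec$event) > 0) {
    km <- km_estimate(rec, "amplified", at = cfg$survival_horizon)
    lr <- logrank_test(rec, "amplified")
    uni <- cox_fit(rec, "amplified")
    multi <- try(cox_fit(rec, c("amplified", "age_high", "gender", "localization", "stage")),
                 silent = TRUE)
    survival <- list(records = rec, km_at_horizon = km$surv_at, logrank = lr,
                     cox_univariable = uni,
                     cox_multivariable = if (inherits(multi, "try-error")) NULL else multi,
                     carriers_high = carriers_high, carriers_5 = carriers_5)
  }

  list(
    config = cfg,
    log_counts = log_counts,
    sample_summaries = summaries,
    gene_cn = cn,
    peaks = peaks,
    recurrent = recurrent,
    recurrent_high = recurrent_high,
    amp_summary = amp_summary,
    in_cis_gain = cis_gain,
    in_cis_loss = cis_loss,
    outlier_flags = outlier_flags,
    top_rank = top_rank,
    de = de_list,
    overlaps = overlaps,
    compartment = compartment,
    resample = resample,
    survival = survival
  )
}

#' Write the results bundle to a directory
#'
#' Serializes every tabular result as TSV and the scalar summaries (with
#' the configuration and seed) as JSON, so the bundle alone regenerates
#' every figure-level summary.
#'
#' @param bundle A results bundle from [run_pipeline()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    df <- as.data.frame(df)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    data.table::fwrite(df, file.path(dir, name), sep = "\t", na = "NA")
  }
  tsv(bundle$sample_summaries, "sample_summaries.tsv")
  tsv(bundle$peaks, "amplification_peaks.tsv")
  tsv(bundle$recurrent, "recurrent_amplified_genes.tsv")
  tsv(bundle$recurrent_high, "recurrent_high_level_genes.tsv")
  tsv(bundle$in_cis_gain, "in_cis_gain.tsv")
  tsv(bundle$in_cis_loss, "in_cis_loss.tsv")
  tsv(bundle$overlaps, "cms_overlap_fractions.tsv")
  tsv(bundle$top_rank, "top_rank_concordance.tsv")
  tsv(bundle$outlier_flags, "outlier_flags.tsv")
  if (!is.null(bundle$survival)) {
    tsv(bundle$survival$cox_univariable, "cox_univariable.tsv")
    if (!is.null(bundle$survival$cox_multivariable)) {
      tsv(bundle$survival$cox_multivariable, "cox_multivariable.tsv")
    }
    tsv(bundle$survival$km_at_horizon, "km_at_horizon.tsv")
  }
  scalars <- list(
    config = unclass(bundle$config),
    log_counts = bundle$log_counts,
    amp_summary = bundle$amp_summary,
    logrank_p = if (!is.null(bundle$survival)) bundle$survival$logrank$p_value else NULL,
    resample = lapply(bundle$resample, function(r) {
      r[c("pair", "variant", "n_iter", "seed", "prop_a_greater")]
    })
  )
  jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
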