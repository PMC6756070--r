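# Gene-level copy-number calling, genome-fraction summaries, ploidy, LOH and
# amplification-peak detection from segmented profiles.
#
# Coordinate convention: 0-based, half-open intervals on autosomes "1".."22".
# Relative segments carry a PCF-style mean log-ratio ("value"); allelic
# segments carry integer allele copies nA, nB with total nAB = nA + nB.

#' Weighted median
#'
#' Smallest value whose cumulative weight reaches half of the total weight.
#' Used with base-pair segment lengths as weights throughout.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @return The weighted median of `x`.
#' @export
weighted_median <- function(x, w) {
  if (length(x) == 0L) stop("empty input")
  if (length(x) != length(w) || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative, same length as x, not all zero")
  }
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

.seg_len <- function(segments) segments$end - segments$start

.check_segments <- function(segments, cols) {
  if (!is.data.frame(segments) || nrow(segments) == 0L) stop("empty segment profile")
  miss <- setdiff(cols, names(segments))
  if (length(miss)) stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  if (any(segments$start >= segments$end)) stop("segments must satisfy start < end")
  invisible(segments)
}

#' Median-center a relative copy-number profile
#'
#' Subtracts the base-pair-length-weighted median of the segment values from
#' every segment, so that the weighted median of the centered profile is 0.
#' Operates on one sample's profile.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `value`.
#' @return The same data.frame with `value` centered.
#' @export
median_center_profile <- function(segments) {
  .check_segments(segments, c("chrom", "start", "end", "value"))
  if (any(!is.finite(segments$value))) stop("segment values must be finite")
  segments$value <- segments$value -
    weighted_median(segments$value, .seg_len(segments))
  segments
}

#' Median-center relative profiles for every sample in a cohort table
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `value`.
#' @return Centered table, same row order.
#' @export
center_profiles <- function(segments) {
  .check_segments(segments, c("sample", "chrom", "start", "end", "value"))
  for (idx in split(seq_len(nrow(segments)), segments$sample)) {
    segments$value[idx] <- segments$value[idx] -
      weighted_median(segments$value[idx], segments$end[idx] - segments$start[idx])
  }
  segments
}

#' Call gain/neutral/loss states from relative copy-number values
#'
#' Gain iff `value >= gain_threshold`, loss iff `value <= loss_threshold`,
#' neutral otherwise (thresholds inclusive).
#'
#' @param value Numeric vector of relative log copy-number values.
#' @param gain_threshold,loss_threshold Call thresholds; defaults 0.15 and
#'   -0.15.
#' @return Character vector in `{"loss", "neutral", "gain"}`; `NA` input
#'   yields `NA`.
#' @export
call_state <- function(value, gain_threshold = 0.15, loss_threshold = -0.15) {
  if (any(!is.na(value) & !is.finite(value))) stop("values must be finite or NA")
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- ifelse(value[ok] >= gain_threshold, "gain",
                    ifelse(value[ok] <= loss_threshold, "loss", "neutral"))
  out
}

# Resolve one gene's copy-number value from the values of the segments it
# overlaps, applying the breakpoint-conflict rules:
#   (i)  all gain or all loss        -> most extreme value
#   (ii) all neutral                 -> median of the segment values
#   (iii) neutral + one direction    -> most extreme aberrant value
#   (iv) both gain and loss          -> NA (conflict)
.resolve_gene_value <- function(values, gain_threshold = 0.15, loss_threshold = -0.15) {
  if (length(values) == 0L) return(list(value = NA_real_, reason = "no_coverage"))
  st <- call_state(values, gain_threshold, loss_threshold)
  has_gain <- any(st == "gain"); has_loss <- any(st == "loss")
  if (has_gain && has_loss) return(list(value = NA_real_, reason = "conflict"))
  if (!has_gain && !has_loss) {
    return(list(value = stats::median(values), reason = NA_character_))
  }
  ab <- values[st != "neutral"]
  list(value = ab[which.max(abs(ab))], reason = NA_character_)
}

#' Map relative copy-number segments onto genes for one sample
#'
#' Applies the breakpoint-conflict resolution rules: genes whose overlapping
#' segments are all gained or all lost keep the most extreme value; all
#' neutral, the median segment value; neutral plus one aberrant direction,
#' the most extreme (aberrant) value; both directions, missing. Genes
#' overlapping no segment are missing with reason `"no_coverage"`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param segments One sample's relative segments (`chrom`, `start`, `end`,
#'   `value`), non-overlapping within chromosome.
#' @param gain_threshold,loss_threshold State-call thresholds.
#' @return data.frame with `gene_id`, `value`, `state` (`loss`/`neutral`/
#'   `gain`/`NA`) and `missing_reason` (`NA`, `"conflict"` or
#'   `"no_coverage"`).
#' @export
map_gene_copy_number <- function(genes, segments,
                                 gain_threshold = 0.15, loss_threshold = -0.15) {
  .check_segments(segments, c("chrom", "start", "end", "value"))
  lvls <- unique(c(genes$chrom, segments$chrom))
  gr_genes <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lvls),
    IRanges::IRanges(genes$start + 1L, genes$end)
  )
  gr_seg <- GenomicRanges::GRanges(
    factor(segments$chrom, levels = lvls),
    IRanges::IRanges(segments$start + 1L, segments$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
  vals_by_gene <- split(segments$value[S4Vectors::subjectHits(hits)],
                        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))))
  res <- lapply(vals_by_gene, .resolve_gene_value,
                gain_threshold = gain_threshold, loss_threshold = loss_threshold)
  value <- vapply(res, `[[`, numeric(1), "value")
  reason <- vapply(res, `[[`, character(1), "reason")
  data.frame(
    gene_id = genes$gene_id,
    value = unname(value),
    state = call_state(unname(value), gain_threshold, loss_threshold),
    missing_reason = unname(reason),
    stringsAsFactors = FALSE
  )
}

#' Gene-by-sample copy-number matrices for a cohort
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param segments Cohort relative-segment table (`sample`, `chrom`, `start`,
#'   `end`, `value`), already median-centered.
#' @inheritParams map_gene_copy_number
#' @return A list with matrices `value` (numeric) and `state` (character),
#'   genes in rows, samples in columns.
#' @export
gene_cn_matrix <- function(genes, segments,
                           gain_threshold = 0.15, loss_threshold = -0.15) {
  .check_segments(segments, c("sample", "chrom", "start", "end", "value"))
  samples <- unique(segments$sample)
  value <- matrix(NA_real_, nrow(genes), length(samples),
                  dimnames = list(genes$gene_id, samples))
  state <- matrix(NA_character_, nrow(genes), length(samples),
                  dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    m <- map_gene_copy_number(genes, segments[segments$sample == s, , drop = FALSE],
                              gain_threshold, loss_threshold)
    value[, s] <- m$value
    state[, s] <- m$state
  }
  list(value = value, state = state)
}

#' Fraction of the genome with aberrant copy number
#'
#' Base pairs in non-neutral segments divided by the total base pairs with a
#' copy-number estimate, for one sample's relative profile.
#'
#' @inheritParams median_center_profile
#' @inheritParams call_state
#' @return Proportion in `[0, 1]`.
#' @export
fraction_genome_aberrant <- function(segments,
                                     gain_threshold = 0.15, loss_threshold = -0.15) {
  .check_segments(segments, c("chrom", "start", "end", "value"))
  st <- call_state(segments$value, gain_threshold, loss_threshold)
  len <- .seg_len(segments)
  sum(len[st != "neutral"]) / sum(len)
}

#' Call loss of heterozygosity from allele-specific segments
#'
#' LOH is called where exactly one of the two allele counts is zero and the
#' other is non-zero; homozygous deletion (both zero) is not LOH. The LOH
#' fraction is base-pair weighted over all segments.
#'
#' @param segments One sample's allelic segments (`chrom`, `start`, `end`,
#'   `nA`, `nB`).
#' @return A list: `segments` (input with logical column `loh`) and
#'   `fraction_loh`.
#' @export
call_loh <- function(segments) {
  .check_segments(segments, c("chrom", "start", "end", "nA", "nB"))
  if (any(segments$nA < 0 | segments$nB < 0)) stop("allele counts must be >= 0")
  loh <- xor(segments$nA == 0, segments$nB == 0)
  len <- .seg_len(segments)
  segments$loh <- loh
  list(segments = segments, fraction_loh = sum(len[loh]) / sum(len))
}

#' Estimate sample ploidy from allele-specific segments
#'
#' Base-pair-length-weighted mean of total copy number, with the 2.2n
#' dichotomy into low-/high-ploidy groups.
#'
#' @inheritParams call_loh
#' @param cutoff High-ploidy cutoff; default 2.2.
#' @return A list with `ploidy` and `ploidy_group` (`"low"`/`"high"`).
#' @export
estimate_ploidy <- function(segments, cutoff = 2.2) {
  .check_segments(segments, c("chrom", "start", "end", "nA", "nB"))
  nab <- segments$nA + segments$nB
  ploidy <- stats::weighted.mean(nab, .seg_len(segments))
  list(ploidy = ploidy, ploidy_group = if (ploidy >= cutoff) "high" else "low")
}

#' Sample-wise genome-wide median total copy number
#'
#' @inheritParams call_loh
#' @return Base-pair-length-weighted median of `nA + nB`.
#' @export
sample_median_total_cn <- function(segments) {
  .check_segments(segments, c("chrom", "start", "end", "nA", "nB"))
  weighted_median(segments$nA + segments$nB, .seg_len(segments))
}

#' Detect amplification peaks in one sample
#'
#' A segment is amplified when its total copy number exceeds the sample-wise
#' genome-wide median by at least `min_additional` copies. Peaks are maximal
#' runs of genomically adjacent amplified segments on one chromosome; a peak
#' is focal when it covers at most `focal_max_genes` genes, and high-level
#' when its maximum additional copy number is at least `high_level_min`.
#'
#' @inheritParams call_loh
#' @param genes Gene annotation data.frame.
#' @param min_additional Minimum additional copies; default 5.
#' @param high_level_min High-level cutoff on additional copies; default 15.
#' @param focal_max_genes Focality cutoff on covered genes; default 50.
#' @param median_cn Optional precomputed sample median total copy number.
#' @return data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `max_additional`, `gene_count`, `focal`, `high_level` and a list-column
#'   `genes` of covered gene ids.
#' @export
call_amplicon_peaks <- function(segments, genes, min_additional = 5,
                                high_level_min = 15, focal_max_genes = 50,
                                median_cn = NULL) {
  .check_segments(segments, c("chrom", "start", "end", "nA", "nB"))
  if (is.null(median_cn)) median_cn <- sample_median_total_cn(segments)
  seg <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  additional <- seg$nA + seg$nB - median_cn
  amp <- additional >= min_additional

  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    max_additional = numeric(0), gene_count = integer(0),
    focal = logical(0), high_level = logical(0)
  )
  empty$genes <- list()
  if (!any(amp)) return(empty)

  # runs of adjacent amplified segments (same chromosome, abutting coordinates)
  idx <- which(amp)
  new_run <- c(TRUE, diff(idx) != 1L |
                 seg$chrom[idx[-1]] != seg$chrom[idx[-length(idx)]] |
                 seg$start[idx[-1]] != seg$end[idx[-length(idx)]])
  run_id <- cumsum(new_run)

  peaks <- lapply(split(idx, run_id), function(i) {
    chrom <- seg$chrom[i[1L]]
    start <- seg$start[i[1L]]
    end <- seg$end[i[length(i)]]
    g <- genes$gene_id[genes$chrom == chrom & genes$start < end & genes$end > start]
    data.frame(
      chrom = chrom, start = start, end = end,
      max_additional = max(additional[i]),
      gene_count = length(g),
      focal = length(g) <= focal_max_genes,
      high_level = max(additional[i]) >= high_level_min,
      stringsAsFactors = FALSE
    ) -> row
    row$genes <- list(g)
    row
  })
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Amplification peaks for every sample in a cohort
#'
#' @param segments Cohort allelic-segment table (`sample`, `chrom`, `start`,
#'   `end`, `nA`, `nB`).
#' @inheritParams call_amplicon_peaks
#' @return Peak data.frame with a `sample` column prepended.
#' @export
call_amplicon_peaks_cohort <- function(segments, genes, min_additional = 5,
                                       high_level_min = 15, focal_max_genes = 50) {
  .check_segments(segments, c("sample", "chrom", "start", "end", "nA", "nB"))
  out <- lapply(unique(segments$sample), function(s) {
    p <- call_amplicon_peaks(segments[segments$sample == s, , drop = FALSE],
                             genes, min_additional, high_level_min, focal_max_genes)
    if (nrow(p)) cbind(sample = s, p, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      max_additional = numeric(0), gene_count = integer(0),
                      focal = logical(0), high_level = logical(0))
    out$genes <- list()
  }
  out
}

#' Recurrently amplified genes across a cohort
#'
#' Counts, for every gene, the number of distinct samples in which a
#' qualifying amplification peak covers it, and reports the amplification
#' frequency with a Wilson confidence interval, filtered to genes amplified
#' in at least `min_tumors` samples.
#'
#' @param peaks Cohort peak table from [call_amplicon_peaks_cohort()].
#' @param n_samples Cohort size (denominator of the frequency).
#' @param min_additional Minimum peak `max_additional` for a peak to qualify.
#' @param min_tumors Recurrence threshold; default 2.
#' @param focal_only If `TRUE`, only focal peaks qualify.
#' @param confidence Confidence level of the Wilson interval.
#' @return data.frame with `gene_id`, `n_amplified`, `frequency`,
#'   `ci_lower`, `ci_upper`, sorted by decreasing count.
#' @export
recurrent_amplified_genes <- function(peaks, n_samples, min_additional = 5,
                                      min_tumors = 2, focal_only = FALSE,
                                      confidence = 0.95) {
  keep <- peaks$max_additional >= min_additional
  if (focal_only) keep <- keep & peaks$focal
  p <- peaks[keep, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(gene_id = character(0), n_amplified = integer(0),
                      frequency = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0)))
  }
  long <- data.frame(
    sample = rep(p$sample, lengths(p$genes)),
    gene_id = unlist(p$genes),
    stringsAsFactors = FALSE
  )
  long <- unique(long)
  cnt <- table(long$gene_id)
  cnt <- cnt[cnt >= min_tumors]
  if (length(cnt) == 0L) {
    return(data.frame(gene_id = character(0), n_amplified = integer(0),
                      frequency = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0)))
  }
  ci <- lapply(as.integer(cnt), wilson_ci, trials = n_samples, confidence = confidence)
  out <- data.frame(
    gene_id = names(cnt),
    n_amplified = as.integer(cnt),
    frequency = as.integer(cnt) / n_samples,
    ci_lower = vapply(ci, `[[`, numeric(1), "lower"),
    ci_upper = vapply(ci, `[[`, numeric(1), "upper"),
    stringsAsFactors = FALSE
  )
  out[order(-out$n_amplified, out$gene_id), , drop = FALSE]
}
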