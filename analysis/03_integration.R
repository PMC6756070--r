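#!/usr/bin/env Rscript
# Stage 3: expression/copy-number integration.
#
# Variance-filters the expression matrix, runs the genome-wide in cis
# gain/upregulation and loss/downregulation scans (Wilcoxon FDR < 0.05 and
# Spearman rho > 0 with FDR < 0.05, both groups >= 10 tumors), and the two
# amplification-expression concordance rules.

suppressMessages(library(cnacms))

co <- read_cohort("results/cohort")
md <- co$metadata
mss <- md$sample[md$msi == "MSS"]
rel <- center_profiles(co$rel_segments[co$rel_segments$sample %in% mss, ])
ase <- co$allelic_segments[co$allelic_segments$sample %in% mss, ]
cn <- gene_cn_matrix(co$genes, rel)
expr <- co$expr[, mss]
keep <- filter_low_variance(expr)

e <- expr[keep, ]; v <- cn$value[keep, mss]; s <- cn$state[keep, mss]
gain <- in_cis_scan(e, v, s, "gain-up", min_per_group = 10)
loss <- in_cis_scan(e, v, s, "loss-down", min_per_group = 10)
write.table(gain, "results/in_cis_gain.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(loss, "results/in_cis_loss.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genes kept by the variance filter: %d of %d\n",
            length(keep), nrow(expr)))
cat(sprintf("in cis gain/upregulated: %d of %d evaluable (%.0f%%)\n",
            sum(gain$in_cis), sum(gain$evaluable),
            100 * mean(gain$in_cis[gain$evaluable])))
cat(sprintf("in cis loss/downregulated: %d of %d evaluable (%.0f%%)\n",
            sum(loss$in_cis), sum(loss$evaluable),
            100 * mean(loss$in_cis[loss$evaluable])))

peaks <- call_amplicon_peaks_cohort(ase, co$genes)
hl <- peaks[peaks$high_level & peaks$focal, ]
outlier <- vapply(seq_len(nrow(hl)), function(i) {
  isTRUE(outlier_expression_flag(hl[i, ], expr)$passed)
}, logical(1))
cat(sprintf("high-level focal peaks with outlier expression: %.0f%% (n = %d)\n",
            100 * mean(outlier), nrow(hl)))

rec <- recurrent_amplified_genes(peaks, length(mss))
long <- unique(data.frame(sample = rep(peaks$sample, lengths(peaks$genes)),
                          gene_id = unlist(peaks$genes)))
long <- long[long$gene_id %in% intersect(rec$gene_id, keep), ]
carriers <- split(long$sample, long$gene_id)
tr <- vapply(names(carriers), function(g) {
  top_rank_concordance(carriers[[g]], expr[g, ])$passed
}, logical(1))
cat(sprintf("recurrently amplified genes with top-rank expression: %.0f%% (n = %d)\n",
            100 * mean(tr), length(tr)))
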