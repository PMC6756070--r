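#!/usr/bin/env Rscript
# Stage 4: CMS enrichment of copy-number-driven expression.
#
# Per-subtype upregulated genes (moderated t, FDR < 0.05, fold change >
# 1.2), their overlap with the in cis gain set, microenvironment depletion
# against the sorted-compartment reference, compartment enrichment, and the
# subtype- and gene-list resampling analyses.

suppressMessages(library(cnacms))

co <- read_cohort("results/cohort")
compref <- list(
  expr = read_expression("results/cohort/compartment_expression.tsv"),
  labels = readLines("results/cohort/compartment_labels.txt")
)
md <- co$metadata
mss <- md$sample[md$msi == "MSS"]
labels <- md$cms[match(mss, md$sample)]
rel <- center_profiles(co$rel_segments[co$rel_segments$sample %in% mss, ])
cn <- gene_cn_matrix(co$genes, rel)
expr <- co$expr[, mss]
keep <- filter_low_variance(expr)
e <- expr[keep, ]; v <- cn$value[keep, mss]; s <- cn$state[keep, mss]

gain <- in_cis_scan(e, v, s, "gain-up", min_per_group = 10)
cis_genes <- gain$gene_id[gain$in_cis]

subtypes <- c("CMS1", "CMS2", "CMS3", "CMS4")
up <- lapply(subtypes, function(st) {
  de <- de_upregulated(e, labels, st)
  de$gene_id[de$upregulated]
})
names(up) <- subtypes

cat("overlap of subtype-upregulated genes with the in cis gain set:\n")
ov <- do.call(rbind, lapply(subtypes, function(st) {
  o <- overlap_fraction(up[[st]], cis_genes, st)
  cat(sprintf("  %s: %d/%d = %.0f%%\n", st, o$n_overlap, o$n_upregulated,
              100 * o$overlap_fraction))
  data.frame(subtype = st, n_upregulated = o$n_upregulated,
             n_overlap = o$n_overlap, overlap_fraction = o$overlap_fraction)
}))
write.table(ov, "results/cms_overlap_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

csets <- compartment_specific_genes(compref$expr[keep, ], compref$labels)
cat("after microenvironment depletion:\n")
for (st in c("CMS2", "CMS4")) {
  ret <- deplete_microenvironment(up[[st]], csets)
  o <- overlap_fraction(ret, cis_genes, st)
  cat(sprintf("  %s: retained %d/%d (%.0f%%), overlap %.0f%%\n", st,
              length(ret), length(up[[st]]),
              100 * length(ret) / length(up[[st]]),
              100 * o$overlap_fraction))
}
enr <- compartment_enrichment(cis_genes, csets, keep)
print(enr[, c("compartment", "odds_ratio", "p")])

rs <- resample_enrichment(e, v, s, labels, c("CMS2", "CMS4"), variant = "ii",
                          n_iter = 200, seed = 1,
                          upregulated_a = up$CMS2, upregulated_b = up$CMS4)
cat(sprintf("resampling (20 + 20 tumors, 200 iterations): CMS2 fraction > CMS4 in %.1f%%\n",
            100 * mean(rs$fractions_a > rs$fractions_b)))
ks <- ks_compare(rs$fractions_a, rs$fractions_b)
cat(sprintf("  KS difference in distributions: D = %.2f, p = %.2g\n",
            ks$statistic, ks$p_value))

if (length(up$CMS2) >= 250 && length(cis_genes) >= 250) {
  rg <- resample_gene_lists(up$CMS2, cis_genes, size = 250, n_iter = 200, seed = 1)
  cat(sprintf("gene-list resampling (250 + 250): mean overlap fraction %.2f\n",
              mean(rg$fractions)))
}

# dosage correlation within each subtype, over its retained upregulated genes
for (st in c("CMS2", "CMS4")) {
  ret <- deplete_microenvironment(up[[st]], csets)
  sub <- mss[!is.na(labels) & labels == st]
  rho <- median_cn_expr_correlation(e[ret, , drop = FALSE],
                                    v[ret, , drop = FALSE], sub)
  cat(sprintf("median dosage correlation in %s (retained upregulated genes): rho = %.2f\n",
              st, rho))
}
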