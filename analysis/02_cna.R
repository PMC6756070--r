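#!/usr/bin/env Rscript
# Stage 2: copy-number core on the MSS tumors.
#
# Median-centers the relative profiles, calls per-sample genome summaries
# (aberrant fraction, LOH, ploidy with the 2.2n dichotomy), detects
# amplification peaks (>= 5 additional copies over the genome-wide median)
# and tabulates recurrently amplified genes with Wilson CIs.

suppressMessages(library(cnacms))

co <- read_cohort("results/cohort")
md <- co$metadata
mss <- md$sample[md$msi == "MSS"]
rel <- center_profiles(co$rel_segments[co$rel_segments$sample %in% mss, ])
ase <- co$allelic_segments[co$allelic_segments$sample %in% mss, ]

summaries <- do.call(rbind, lapply(mss, function(s) {
  a <- ase[ase$sample == s, ]
  pl <- estimate_ploidy(a)
  data.frame(sample = s,
             fraction_aberrant = fraction_genome_aberrant(rel[rel$sample == s, ]),
             fraction_loh = call_loh(a)$fraction_loh,
             ploidy = pl$ploidy, ploidy_group = pl$ploidy_group)
}))
write.table(summaries, "results/sample_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

peaks <- call_amplicon_peaks_cohort(ase, co$genes)
rec5 <- recurrent_amplified_genes(peaks, length(mss), min_additional = 5)
rec15 <- recurrent_amplified_genes(peaks, length(mss), min_additional = 15,
                                   focal_only = TRUE)
write.table(peaks[, setdiff(names(peaks), "genes")],
            "results/amplification_peaks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rec5, "results/recurrent_amplified_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("MSS tumors with >=1 amplification: %d/%d (%.0f%%)\n",
            length(unique(peaks$sample)), length(mss),
            100 * length(unique(peaks$sample)) / length(mss)))
hp <- summaries$sample[summaries$ploidy_group == "high"]
cat(sprintf("  high-ploidy (>=2.2n): %.0f%% with amplification; low-ploidy: %.0f%%\n",
            100 * mean(hp %in% peaks$sample),
            100 * mean(setdiff(mss, hp) %in% peaks$sample)))
cat(sprintf("  median aberrant genome fraction: %.0f%%\n",
            100 * median(summaries$fraction_aberrant)))
cat(sprintf("recurrent amplified genes (>=5 additional copies, >=2 tumors): %d\n",
            nrow(rec5)))
cat(sprintf("recurrent focal high-level genes (>=15): %d\n", nrow(rec15)))
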