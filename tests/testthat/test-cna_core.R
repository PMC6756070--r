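seg_df <- function(chrom, start, end, ...) {
  data.frame(chrom = as.character(chrom), start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

test_that("median centering uses the base-pair-weighted median", {
  s <- seg_df("1", c(0, 100), c(100, 400), value = c(0.2, 0.4))
  expect_equal(median_center_profile(s)$value, c(-0.2, 0.0))
  const <- seg_df("1", 0, 1000, value = 0.3)
  expect_equal(median_center_profile(const)$value, 0)
  centered <- median_center_profile(s)
  expect_equal(median_center_profile(centered)$value, centered$value)
  expect_error(median_center_profile(seg_df("1", 1, 2, value = 0.1)[0, ]), "empty")
})

test_that("state calls use inclusive +/-0.15 thresholds", {
  expect_equal(call_state(c(0.16, 0, -0.15, 0.15, 0.149, -0.149)),
               c("gain", "neutral", "loss", "gain", "neutral", "neutral"))
  expect_error(call_state(Inf), "finite")
})

test_that("gene mapping applies the four breakpoint-conflict rules", {
  gene <- data.frame(gene_id = "g1", chrom = "1", start = 50, end = 250)
  run <- function(values, breaks = NULL) {
    if (is.null(breaks)) breaks <- seq(0, 300, length.out = length(values) + 1)
    s <- seg_df("1", head(breaks, -1), breaks[-1], value = values)
    map_gene_copy_number(gene, s)
  }
  # single covering segment
  m <- run(0.3)
  expect_equal(m$value, 0.3); expect_equal(m$state, "gain")
  # rule i: all gain -> most extreme
  expect_equal(run(c(0.3, 0.5))$value, 0.5)
  expect_equal(run(c(-0.3, -0.5))$value, -0.5)
  # rule ii: all neutral -> median of segment values
  expect_equal(run(c(0.05, -0.05))$value, 0.0)
  # rule iii: neutral + one direction -> most extreme aberrant
  m3 <- run(c(0.3, 0.0))
  expect_equal(m3$value, 0.3); expect_equal(m3$state, "gain")
  # rule iv: both directions -> missing, flagged as conflict
  m4 <- run(c(0.3, -0.2))
  expect_true(is.na(m4$value))
  expect_equal(m4$missing_reason, "conflict")
  # no coverage
  far <- data.frame(gene_id = "g2", chrom = "2", start = 0, end = 10)
  m5 <- map_gene_copy_number(far, seg_df("1", 0, 300, value = 0))
  expect_true(is.na(m5$value))
  expect_equal(m5$missing_reason, "no_coverage")
})

test_that("gene mapping equals the per-base brute-force oracle", {
  set.seed(21)
  for (i in 1:200) {
    nb <- sample(1:6, 1)
    breaks <- sort(sample(0:200, nb + 1))
    while (any(diff(breaks) == 0)) breaks <- sort(sample(0:200, nb + 1))
    s <- seg_df("1", head(breaks, -1), breaks[-1],
                value = round(runif(nb, -0.6, 0.6), 2))
    gs <- sort(sample(0:199, 2)); if (gs[1] == gs[2]) gs[2] <- gs[2] + 1
    gene <- data.frame(gene_id = "g", chrom = "1", start = gs[1], end = gs[2])
    got <- map_gene_copy_number(gene, s)
    want <- gene_cn_oracle(gs[1], gs[2], s)
    expect_equal(got$value, want$value, info = paste("config", i))
    if (is.na(want$value)) expect_equal(got$missing_reason, want$reason)
  }
})

test_that("aberrant genome fraction is base-weighted and split-invariant", {
  s <- seg_df("1", c(0, 100), c(100, 400), value = c(0.2, 0.0))
  expect_equal(fraction_genome_aberrant(s), 0.25)
  allneutral <- seg_df("1", c(0, 100), c(100, 400), value = c(0.1, 0.0))
  expect_equal(fraction_genome_aberrant(allneutral), 0)
  # splitting a segment at internal breakpoints changes nothing
  split_s <- seg_df("1", c(0, 50, 100, 250), c(50, 100, 250, 400),
                    value = c(0.2, 0.2, 0.0, 0.0))
  expect_equal(fraction_genome_aberrant(split_s), fraction_genome_aberrant(s))
})

test_that("LOH requires exactly one zero allele", {
  s <- seg_df("1", c(0, 100, 200, 300), c(100, 200, 300, 400),
              nA = c(1, 0, 2, 2), nB = c(0, 0, 1, 0))
  r <- call_loh(s)
  expect_equal(r$segments$loh, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(r$fraction_loh, 0.5)
  # splitting invariance
  s2 <- seg_df("1", c(0, 50, 100, 200, 300), c(50, 100, 200, 300, 400),
               nA = c(1, 1, 0, 2, 2), nB = c(0, 0, 0, 1, 0))
  expect_equal(call_loh(s2)$fraction_loh, r$fraction_loh)
})

test_that("ploidy estimation and the 2.2n dichotomy", {
  dip <- seg_df("1", 0, 1000, nA = 1, nB = 1)
  expect_equal(estimate_ploidy(dip), list(ploidy = 2, ploidy_group = "low"))
  half <- seg_df("1", c(0, 500), c(500, 1000), nA = c(1, 2), nB = c(1, 1))
  r <- estimate_ploidy(half)
  expect_equal(r$ploidy, 2.5); expect_equal(r$ploidy_group, "high")
  tet <- seg_df("1", 0, 1000, nA = 2, nB = 2)
  expect_equal(estimate_ploidy(tet)$ploidy_group, "high")
})

test_that("sample median total copy number is the weighted median", {
  expect_equal(sample_median_total_cn(seg_df("1", 0, 100, nA = 1, nB = 1)), 2)
  s <- seg_df("1", c(0, 600), c(600, 1000), nA = c(1, 2), nB = c(1, 2))
  expect_equal(sample_median_total_cn(s), 2)   # 60% of bases at 2
  s2 <- seg_df("1", c(0, 400), c(400, 1000), nA = c(1, 2), nB = c(1, 2))
  expect_equal(sample_median_total_cn(s2), 4)  # 60% of bases at 4
})

test_that("amplification peaks are median-relative, merged and classified", {
  genes <- data.frame(gene_id = paste0("g", 1:3), chrom = "1",
                      start = c(100, 200, 300), end = c(150, 250, 350))
  dip <- seg_df("1", c(0, 100, 400), c(100, 400, 1000),
                nA = c(1, 6, 1), nB = c(1, 2, 1))
  p <- call_amplicon_peaks(dip, genes)
  expect_equal(nrow(p), 1)
  expect_equal(p$max_additional, 6)
  expect_true(p$focal); expect_false(p$high_level)
  expect_setequal(p$genes[[1]], c("g1", "g2", "g3"))

  # tetraploid: nAB = 8 is only +4 above the median -> no peak
  tet <- seg_df("1", c(0, 100, 400), c(100, 400, 1000),
                nA = c(2, 6, 2), nB = c(2, 2, 2))
  expect_equal(nrow(call_amplicon_peaks(tet, genes)), 0)

  # adjacent amplified segments merge into one broad high-level peak
  many_genes <- data.frame(gene_id = paste0("g", 1:60), chrom = "1",
                           start = seq(100, 6000, by = 100),
                           end = seq(150, 6050, by = 100))
  s <- rbind(
    seg_df("1", c(0, 100, 3000, 6100), c(100, 3000, 6100, 10000),
           nA = c(1, 17, 21, 1), nB = c(1, 1, 1, 1)),
    seg_df("2", 0, 50000, nA = 1, nB = 1)  # keeps the genome median diploid
  )
  p2 <- call_amplicon_peaks(s, many_genes)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$max_additional, 20)
  expect_equal(p2$gene_count, 60)
  expect_true(p2$high_level); expect_false(p2$focal)
})

test_that("peaks are maximal and monotone in the amplification threshold", {
  set.seed(22)
  genes <- data.frame(gene_id = paste0("g", 1:50), chrom = "1",
                      start = seq(0, 9800, by = 200), end = seq(100, 9900, by = 200))
  for (i in 1:20) {
    nb <- sample(3:10, 1)
    breaks <- sort(sample(seq(0, 10000, by = 50), nb + 1))
    while (any(diff(breaks) == 0)) breaks <- sort(sample(seq(0, 10000, by = 50), nb + 1))
    s <- seg_df("1", head(breaks, -1), breaks[-1],
                nA = sample(c(1, 1, 1, 8, 25), nb, replace = TRUE), nB = 1)
    p5 <- call_amplicon_peaks(s, genes, min_additional = 5)
    p15 <- call_amplicon_peaks(s, genes, min_additional = 15)
    # maximality: no two reported peaks are adjacent
    if (nrow(p5) > 1) {
      expect_true(all(p5$start[-1] != p5$end[-nrow(p5)] |
                        p5$chrom[-1] != p5$chrom[-nrow(p5)]))
    }
    # every threshold-15 peak lies inside a threshold-5 peak covering its genes
    if (nrow(p15)) {
      for (k in seq_len(nrow(p15))) {
        covering <- p5$start <= p15$start[k] & p5$end >= p15$end[k]
        expect_true(any(covering))
        expect_true(all(p15$genes[[k]] %in% unlist(p5$genes[covering])))
      }
    }
  }
})

test_that("recurrent gene table counts distinct samples and applies Wilson CIs", {
  genes <- data.frame(gene_id = c("ERBB2", "OTHER"), chrom = "17",
                      start = c(100, 5000), end = c(200, 5100))
  mk <- function(sample, add) {
    seg <- seg_df("17", c(0, 50, 400), c(50, 400, 1000),
                  nA = c(1, 1 + add, 1), nB = 1)
    cbind(sample = sample, seg, stringsAsFactors = FALSE)
  }
  ase <- rbind(mk("s1", 22), mk("s2", 27), mk("s3", 97))
  peaks <- call_amplicon_peaks_cohort(ase, genes)
  rec <- recurrent_amplified_genes(peaks, n_samples = 203, min_tumors = 2)
  expect_equal(rec$gene_id, "ERBB2")
  expect_equal(rec$n_amplified, 3L)
  expect_equal(round(100 * rec$frequency, 1), 1.5)
  expect_equal(round(100 * rec$ci_lower, 1), 0.5)
  expect_equal(round(100 * rec$ci_upper, 1), 4.3)
  # below the recurrence threshold -> excluded
  rec1 <- recurrent_amplified_genes(peaks[peaks$sample == "s1", ], 203)
  expect_equal(nrow(rec1), 0)
  # determinism on repeated input
  expect_identical(rec, recurrent_amplified_genes(peaks, 203, min_tumors = 2))
})
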