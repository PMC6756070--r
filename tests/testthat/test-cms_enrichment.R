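# A tiny cohort with few genes keeps the resampling tests fast.
tiny_config <- function(seed = 51, ...) {
  sim_config(n_samples = 70, n_genes = 300, program_size = 40,
             stromal_program_size = 30, epithelial_marker_size = 20,
             cms_proportions = c(CMS1 = 0.04, CMS2 = 0.45, CMS3 = 0.06, CMS4 = 0.40),
             msi_proportion = 0, seed = seed, ...)
}

tiny_matrices <- function(cohort) {
  rel <- center_profiles(cohort$rel_segments)
  cn <- gene_cn_matrix(cohort$genes, rel)
  list(expr = cohort$expr, value = cn$value, state = cn$state,
       labels = cohort$metadata$cms[match(colnames(cohort$expr), cohort$metadata$sample)])
}

test_that("subtype DE recovers injected shifts and applies strict thresholds", {
  set.seed(41)
  n1 <- 20; n2 <- 60; ngene <- 400
  expr <- matrix(rnorm(ngene * (n1 + n2), 7, 0.3), ngene,
                 dimnames = list(sprintf("g%03d", 1:ngene), paste0("s", 1:(n1 + n2))))
  shifted <- 1:50
  expr[shifted, 1:n1] <- expr[shifted, 1:n1] + 1.0
  labels <- c(rep("CMS2", n1), rep("CMS4", n2))
  de <- de_upregulated(expr, labels, "CMS2")
  expect_gte(sum(de$upregulated[shifted]), 45)
  expect_lte(sum(de$upregulated[-shifted]), 5)
  expect_error(de_upregulated(expr, labels, "CMS9"), "absent")

  # a shift of exactly log2(1.2) with symmetric within-group spread fails ">"
  e2 <- matrix(rep(c(7 - 0.1, 7 + 0.1), 20), nrow = 1)
  e2 <- rbind(e2, e2, e2, e2, e2, e2, e2, e2, e2, e2, e2, e2)
  rownames(e2) <- sprintf("g%02d", 1:12)
  grp <- rep(c("A", "B"), each = 20)
  e2[, grp == "A"] <- e2[, grp == "A"] + log2(1.2)
  de2 <- de_upregulated(e2, grp, "A")
  expect_equal(de2$log_fc, rep(log2(1.2), 12), tolerance = 1e-12)
  expect_false(any(de2$upregulated))
})

test_that("overlap fraction is a pure set computation", {
  expect_equal(overlap_fraction(letters[1:10], letters[1:10])$overlap_fraction, 1)
  expect_equal(overlap_fraction(letters[1:10], LETTERS[1:10])$overlap_fraction, 0)
  expect_equal(overlap_fraction(letters[1:10], letters[6:15])$overlap_fraction, 0.5)
  expect_true(overlap_fraction(character(0), letters)$undefined)
  # invariant under relabeling
  relab <- setNames(sprintf("x%02d", 1:26), letters)
  expect_equal(overlap_fraction(relab[letters[1:10]], relab[letters[6:15]])$overlap_fraction, 0.5)
})

test_that("subtype resampling is deterministic and detects one-sided dosage", {
  co <- cached("tiny51", function() simulate_cohort(tiny_config()))
  m <- tiny_matrices(co)
  up2 <- de_upregulated(m$expr, m$labels, "CMS2")
  up4 <- de_upregulated(m$expr, m$labels, "CMS4")
  r1 <- resample_enrichment(m$expr, m$value, m$state, m$labels, c("CMS2", "CMS4"),
                            variant = "ii", n_iter = 40, seed = 99,
                            upregulated_a = up2$gene_id[up2$upregulated],
                            upregulated_b = up4$gene_id[up4$upregulated])
  r2 <- resample_enrichment(m$expr, m$value, m$state, m$labels, c("CMS2", "CMS4"),
                            variant = "ii", n_iter = 40, seed = 99,
                            upregulated_a = up2$gene_id[up2$upregulated],
                            upregulated_b = up4$gene_id[up4$upregulated])
  expect_identical(r1, r2)
  # CMS2 carries the dosage-driven program
  expect_gte(r1$prop_a_greater, 0.95)
  expect_error(resample_enrichment(m$expr, m$value, m$state, m$labels,
                                   c("CMS2", "CMS3"), variant = "ii",
                                   upregulated_a = "a", upregulated_b = "b"),
               "at least")
})

test_that("resampling is centered near 0.5 without any dosage effect", {
  co <- cached("tinynull", function() simulate_cohort(tiny_config(seed = 52, dosage_effect = 0)))
  m <- tiny_matrices(co)
  up2 <- de_upregulated(m$expr, m$labels, "CMS2")
  up4 <- de_upregulated(m$expr, m$labels, "CMS4")
  r <- resample_enrichment(m$expr, m$value, m$state, m$labels, c("CMS2", "CMS4"),
                           variant = "ii", n_iter = 500, seed = 7,
                           upregulated_a = up2$gene_id[up2$upregulated],
                           upregulated_b = up4$gene_id[up4$upregulated])
  expect_gte(r$prop_a_greater, 0.45)
  expect_lte(r$prop_a_greater, 0.55)
})

test_that("variant iii equals variant ii when the whole list is sampled", {
  co <- cached("tiny51", function() simulate_cohort(tiny_config()))
  m <- tiny_matrices(co)
  up2 <- de_upregulated(m$expr, m$labels, "CMS2")
  up4 <- de_upregulated(m$expr, m$labels, "CMS4")
  la <- up2$gene_id[up2$upregulated]; lb <- up4$gene_id[up4$upregulated]
  sz <- min(length(la), length(lb))
  r2 <- resample_enrichment(m$expr, m$value, m$state, m$labels, c("CMS2", "CMS4"),
                            variant = "ii", n_iter = 15, seed = 5,
                            upregulated_a = la[seq_len(sz)], upregulated_b = lb[seq_len(sz)])
  r3 <- resample_enrichment(m$expr, m$value, m$state, m$labels, c("CMS2", "CMS4"),
                            variant = "iii", n_iter = 15, seed = 5, size = sz,
                            upregulated_a = la[seq_len(sz)], upregulated_b = lb[seq_len(sz)])
  expect_equal(r2$fractions_a, r3$fractions_a)
  expect_equal(r2$fractions_b, r3$fractions_b)
})

test_that("gene-list resampling has the right limits and is reproducible", {
  pool <- sprintf("g%04d", 1:250)
  r <- resample_gene_lists(pool, pool, size = 250, n_iter = 10, seed = 3)
  expect_true(all(r$fractions == 1))
  r0 <- resample_gene_lists(pool, sprintf("h%04d", 1:250), size = 250, n_iter = 10, seed = 3)
  expect_true(all(r0$fractions == 0))
  big <- sprintf("g%04d", 1:600)
  ra <- resample_gene_lists(big, big[301:600], size = 250, n_iter = 25, seed = 11)
  rb <- resample_gene_lists(big, big[301:600], size = 250, n_iter = 25, seed = 11)
  expect_identical(ra, rb)
  expect_error(resample_gene_lists(pool[1:100], pool, size = 250), "at least")
})

test_that("compartment-specific genes recover simulated markers", {
  co <- small_cohort()
  ref <- simulate_compartment_reference(co)
  sets <- compartment_specific_genes(ref$expr, ref$labels)
  roles <- co$truth$gene_roles
  for (cp in c("fibroblast", "endothelial", "leukocyte")) {
    truth_markers <- roles$gene_id[!is.na(roles$compartment) & roles$compartment == cp]
    expect_gte(mean(truth_markers %in% sets[[cp]]), 0.9)
  }
  expect_error(compartment_specific_genes(ref$expr, rep("epithelial", ncol(ref$expr))),
               "missing compartments")
  # no marker effect -> no compartment-specific genes
  ref0 <- simulate_compartment_reference(co, marker_shift = 0)
  sets0 <- compartment_specific_genes(ref0$expr, ref0$labels)
  expect_lte(length(unlist(sets0)), 5)
})

test_that("microenvironment depletion removes exactly the stromal sets", {
  sets <- list(epithelial = c("e1", "e2"), fibroblast = c("f1", "f2"),
               endothelial = "n1", leukocyte = "l1")
  expect_equal(deplete_microenvironment(c("a", "b"), sets), c("a", "b"))
  expect_equal(deplete_microenvironment(c("f1", "f2"), sets), character(0))
  expect_equal(deplete_microenvironment(c("a", "f1", "n1", "l1", "e1"), sets),
               c("a", "e1"))
  # never removes genes absent from the microenvironment sets
  set.seed(42)
  for (i in 1:20) {
    up <- sample(letters, 10)
    kept <- deplete_microenvironment(up, sets)
    expect_true(all(setdiff(up, c("f1", "f2", "n1", "l1")) %in% kept))
  }
})

test_that("compartment enrichment flags containment and is null on random sets", {
  universe <- sprintf("g%03d", 1:500)
  sets <- list(epithelial = universe[1:100], fibroblast = universe[101:150],
               endothelial = universe[151:200], leukocyte = universe[201:250])
  enr <- compartment_enrichment(universe[1:40], sets, universe)
  epi <- enr[enr$compartment == "epithelial", ]
  expect_true(is.infinite(epi$odds_ratio) || epi$odds_ratio > 50)
  expect_lt(epi$p, 1e-10)
  set.seed(43)
  null_or <- replicate(20, {
    enr0 <- compartment_enrichment(sample(universe, 50), sets, universe)
    enr0$odds_ratio[enr0$compartment == "fibroblast"]
  })
  expect_gt(median(null_or), 0.3)
  expect_lt(median(null_or), 3)
  expect_true(all(is.na(compartment_enrichment(character(0), sets, universe)$p)))
  expect_error(compartment_enrichment("g001", sets, character(0)), "empty")
})

test_that("arm fractions and median dosage correlation behave as stated", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:100),
                    arm = rep(c("20q", "13q"), 50), stringsAsFactors = FALSE)
  expect_equal(arm_fraction(sprintf("g%02d", c(1, 3, 5)), "20q", ann), 1)
  expect_equal(arm_fraction(sprintf("g%02d", c(2, 4)), "20q", ann), 0)
  expect_warning(fr <- arm_fraction(c("g01", "nope"), "20q", ann), "without annotation")
  expect_equal(fr, 1)

  samples <- paste0("s", 1:20)
  cn <- matrix(rep(seq(0, 1, length.out = 20), each = 5), 5,
               dimnames = list(paste0("g", 1:5), samples))
  e_perfect <- 2 * cn + 3
  expect_equal(median_cn_expr_correlation(e_perfect, cn, samples), 1)
  set.seed(44)
  e_null <- matrix(rnorm(100), 5, dimnames = dimnames(cn))
  expect_lt(abs(median_cn_expr_correlation(e_null, cn, samples)), 0.35)
  expect_equal(median_cn_expr_correlation(e_perfect[1, , drop = FALSE],
                                          cn[1, , drop = FALSE], samples), 1)
})
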