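# Helper: build expression/copy-number vectors with a known dosage slope.
dosage_gene <- function(n, beta, gain_frac = 0.4, noise = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gained <- seq_len(n) <= round(gain_frac * n)
  cn <- ifelse(gained, 0.58, 0) + rnorm(n, 0, 0.02)
  state <- call_state(cn)
  expr <- 7 + beta * cn + rnorm(n, 0, noise)
  list(expr = expr, cn = cn, state = state)
}

test_that("variance filter keeps genes at or above the cutoff", {
  expr <- rbind(
    flat = rep(5, 10),
    lowv = rnorm(10, sd = 0.05),
    keep = c(0, 1, rep(0.5, 8))
  )
  expect_false("flat" %in% filter_low_variance(expr))
  expect_false("lowv" %in% filter_low_variance(expr))
  # variance of (0,1) over two samples is 0.5 >= 0.1
  expect_true("keep" %in% filter_low_variance(expr[, 1:2]))
  expect_setequal(filter_low_variance(expr, min_variance = 0), rownames(expr))
})

test_that("in cis test separates clear dosage effects and respects group minima", {
  # 12 gained all strictly above 12 neutral
  expr <- c(rep(8, 12) + (1:12) / 100, rep(6, 12) + (1:12) / 100)
  state <- rep(c("gain", "neutral"), each = 12)
  cnv <- rep(c(0.6, 0), each = 12) + seq(0.001, 0.024, by = 0.001)
  r <- in_cis_test(expr, state, cnv, "gain-up", min_per_group = 10)
  expect_true(r$evaluable)
  expect_equal(r$wilcoxon_p, suppressWarnings(
    stats::wilcox.test(expr[1:12], expr[13:24], correct = TRUE, exact = FALSE)$p.value))
  expect_lt(r$wilcoxon_p, 1e-4)
  expect_true(r$direction_ok)
  expect_gt(r$rho, 0)

  # identical distributions: no signal
  r0 <- in_cis_test(rep(c(5, 6), 12), state, cnv, "gain-up", min_per_group = 10)
  expect_gt(r0$wilcoxon_p, 0.5)

  # 9 gained vs 100 neutral at min 10 -> not evaluable
  st <- c(rep("gain", 9), rep("neutral", 100))
  r9 <- in_cis_test(rnorm(109), st, rnorm(109), "gain-up", min_per_group = 10)
  expect_false(r9$evaluable)
  expect_true(is.na(r9$wilcoxon_p))
})

test_that("in cis scan controls FDR on null genes and flags dosage genes", {
  set.seed(31)
  n <- 60; ngene <- 200
  expr <- matrix(NA_real_, ngene, n, dimnames = list(sprintf("n%03d", 1:ngene), paste0("s", 1:n)))
  cnv <- matrix(NA_real_, ngene, n, dimnames = dimnames(expr))
  for (i in 1:ngene) {
    g <- dosage_gene(n, beta = 0)
    expr[i, ] <- g$expr; cnv[i, ] <- g$cn
  }
  st <- matrix(call_state(cnv), ngene, dimnames = dimnames(expr))
  scan0 <- in_cis_scan(expr, cnv, st, "gain-up", min_per_group = 10)
  expect_lte(mean(scan0$in_cis[scan0$evaluable]), 0.10)

  for (i in 1:ngene) {
    g <- dosage_gene(n, beta = 1.5)
    expr[i, ] <- g$expr; cnv[i, ] <- g$cn
  }
  st <- matrix(call_state(cnv), ngene, dimnames = dimnames(expr))
  scan1 <- in_cis_scan(expr, cnv, st, "gain-up", min_per_group = 10)
  expect_gt(mean(scan1$in_cis), 0.9)
})

test_that("in cis flags are anti-monotone in the group-size threshold", {
  set.seed(32)
  n <- 50; ngene <- 80
  expr <- matrix(NA_real_, ngene, n, dimnames = list(sprintf("g%03d", 1:ngene), paste0("s", 1:n)))
  cnv <- matrix(NA_real_, ngene, n, dimnames = dimnames(expr))
  for (i in 1:ngene) {
    g <- dosage_gene(n, beta = runif(1, 0, 2), gain_frac = runif(1, 0.1, 0.5))
    expr[i, ] <- g$expr; cnv[i, ] <- g$cn
  }
  st <- matrix(call_state(cnv), ngene, dimnames = dimnames(expr))
  flags <- lapply(c(3, 10, 15), function(m) {
    sc <- in_cis_scan(expr, cnv, st, "gain-up", min_per_group = m)
    sc$gene_id[sc$in_cis]
  })
  expect_true(all(flags[[2]] %in% flags[[1]]) || length(flags[[2]]) <= length(flags[[1]]))
  # raising the threshold never makes a non-evaluable gene evaluable
  ev <- lapply(c(3, 10, 15), function(m) {
    sc <- in_cis_scan(expr, cnv, st, "gain-up", min_per_group = m)
    sc$gene_id[sc$evaluable]
  })
  expect_true(all(ev[[2]] %in% ev[[1]]))
  expect_true(all(ev[[3]] %in% ev[[2]]))
})

test_that("in cis power grows with effect size and cohort size", {
  set.seed(33)
  betas <- c(0.3, 0.9, 1.8)
  sizes <- c(40, 100)
  power <- matrix(NA_real_, length(betas), length(sizes))
  for (bi in seq_along(betas)) {
    for (ni in seq_along(sizes)) {
      ngene <- 100
      n <- sizes[ni]
      expr <- matrix(NA_real_, ngene, n,
                     dimnames = list(sprintf("g%03d", 1:ngene), paste0("s", 1:n)))
      cnv <- matrix(NA_real_, ngene, n, dimnames = dimnames(expr))
      for (i in 1:ngene) {
        g <- dosage_gene(n, beta = betas[bi])
        expr[i, ] <- g$expr; cnv[i, ] <- g$cn
      }
      st <- matrix(call_state(cnv), ngene, dimnames = dimnames(expr))
      sc <- in_cis_scan(expr, cnv, st, "gain-up", min_per_group = 10)
      power[bi, ni] <- mean(sc$in_cis)
    }
  }
  expect_true(all(diff(power[, 1]) >= 0))
  expect_true(all(diff(power[, 2]) >= 0))
  expect_true(all(power[1, ] <= power[3, ]))
  expect_true(all(power[, 1] <= power[, 2] + 0.05))
})

test_that("outlier flag uses a strict Q3 + 1.5 IQR cohort cutoff", {
  expr <- matrix(seq(1, 40), 1, dimnames = list("g1", paste0("s", 1:40)))
  peak <- data.frame(sample = "s40", stringsAsFactors = FALSE)
  peak$genes <- list("g1")
  # s40 holds the maximum of a uniform grid: 40 < Q3 + 1.5 IQR = 30.25 + 29.25
  expect_false(outlier_expression_flag(peak[1, ], expr)$passed)
  expr2 <- expr; expr2[1, 40] <- 1000
  expect_true(outlier_expression_flag(peak[1, ], expr2)$passed)
  # exactly at the cutoff -> failed (strict inequality)
  v <- c(rep(1:4, 5), 4 + 1.5 * 3)  # Q3 and IQR of the grid part
  names(v) <- paste0("s", seq_along(v))
  e3 <- matrix(v, 1, dimnames = list("g1", names(v)))
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  e3[1, length(v)] <- q[2] + 1.5 * (q[2] - q[1])
  peak3 <- data.frame(sample = names(v)[length(v)]); peak3$genes <- list("g1")
  expect_false(outlier_expression_flag(peak3[1, ], e3)$passed)
  # peak without expression data -> not evaluable
  peak4 <- data.frame(sample = "s1"); peak4$genes <- list("unknown")
  expect_false(outlier_expression_flag(peak4[1, ], expr)$evaluable)
})

test_that("top-rank rule follows the k-dependent window", {
  v <- seq(100, 1, length.out = 100); names(v) <- paste0("s", 1:100)
  # k=2, carriers ranked 1st and 40th: 1 of 2 in top 5 -> passed
  expect_true(top_rank_concordance(c("s1", "s40"), v)$passed)
  # k=6, 2 carriers in top 9 -> 33% -> failed
  r <- top_rank_concordance(c("s1", "s2", "s50", "s60", "s70", "s80"), v)
  expect_equal(r$rank_window, 9L)
  expect_false(r$passed)
  # k=1, carrier is the maximum -> passed
  expect_true(top_rank_concordance("s1", v)$passed)
  expect_error(top_rank_concordance(character(0), v), "at least one")
})

test_that("top-rank rule equals brute-force evaluation on small cohorts", {
  set.seed(34)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    v <- sample(c(rnorm(n), rep(0.5, n)), n)  # allow ties
    names(v) <- paste0("s", 1:n)
    k <- sample(1:n, 1)
    amp <- sample(names(v), k)
    got <- top_rank_concordance(amp, v)$passed
    expect_equal(got, top_rank_oracle(amp, v), info = paste("case", i))
  }
})
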