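# Shared fixtures (built in code, cached per session) and independent
# brute-force oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a compact cohort for fast module tests
small_config <- function(seed = 11, ...) {
  sim_config(n_samples = 60, n_genes = 400, program_size = 60,
             stromal_program_size = 45, epithelial_marker_size = 30,
             seed = seed, ...)
}

small_cohort <- function() cached("small", function() simulate_cohort(small_config()))

# ---- independent oracles -------------------------------------------------

# BH step-up evaluated directly from the definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, ps * n / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided Wilcoxon p by enumeration of all rank assignments.
wilcox_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- colSums(matrix(seq_len(nx + ny)[combos], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Two-sided Fisher p by enumeration over the hypergeometric support.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Per-base oracle for gene-level copy-number mapping: assign every base of
# the gene its covering segment's value, recover the set of overlapped
# segment values from the base multiset, then apply the conflict rules.
gene_cn_oracle <- function(gene_start, gene_end, seg, gain = 0.15, loss = -0.15) {
  base_vals <- rep(NA_real_, gene_end - gene_start)
  base_seg <- rep(NA_integer_, gene_end - gene_start)
  for (i in seq_len(nrow(seg))) {
    lo <- max(gene_start, seg$start[i])
    hi <- min(gene_end, seg$end[i])
    if (lo >= hi) next
    b <- seq(lo, hi - 1)
    if (length(b)) {
      base_vals[b - gene_start + 1] <- seg$value[i]
      base_seg[b - gene_start + 1] <- i
    }
  }
  covered <- unique(base_seg[!is.na(base_seg)])
  if (length(covered) == 0L) return(list(value = NA_real_, reason = "no_coverage"))
  vals <- seg$value[covered]
  st <- ifelse(vals >= gain, "gain", ifelse(vals <= loss, "loss", "neutral"))
  if (any(st == "gain") && any(st == "loss")) {
    return(list(value = NA_real_, reason = "conflict"))
  }
  if (all(st == "neutral")) return(list(value = median(vals), reason = NA))
  ab <- vals[st != "neutral"]
  list(value = ab[which.max(abs(ab))], reason = NA)
}

# Brute-force top-rank rule: rank window membership decided by exhaustive
# pairwise comparison (strictly larger value, or equal value and earlier
# position), no sorting.
top_rank_oracle <- function(amplified, values) {
  k <- length(amplified)
  m <- min(if (k < 5) 5 else ceiling(1.5 * k), length(values))
  nm <- names(values)
  n_above <- vapply(seq_along(values), function(i) {
    sum(values > values[i] | (values == values[i] & seq_along(values) < i))
  }, numeric(1))
  top <- nm[n_above < m]
  sum(amplified %in% top) >= 0.5 * k
}
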