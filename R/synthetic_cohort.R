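# Synthetic cohort generator. Emulates the joint structure the analysis
# assumes: genome-covering segmented copy-number profiles (relative and
# allele-specific), CMS-dependent aberration burden, focal amplifications,
# dosage-driven expression with tumor-purity/stromal admixture, a
# compartment-sorted expression reference, and survival with an
# amplification-dependent hazard. Ground truth is recorded for recovery
# tests.

#' Simulation configuration
#'
#' Returns the full parameter set of the synthetic cohort generator. The
#' defaults describe a scaled-down microsatellite-stratified colorectal
#' cancer cohort: 150 tumors, a 22-autosome genome of 10 Mb chromosomes
#' carrying ~2,000 genes, CMS proportions of roughly 7/42/15/23% (remainder
#' unclassified), higher tumor purity in CMS2 (0.7) than CMS4 (0.45), a
#' CMS-specific expression program of 250 genes per subtype of which a
#' configurable fraction is copy-number driven, and exponential survival
#' with an elevated hazard for carriers of injected high-level focal
#' amplifications.
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes.
#' @param n_chromosomes Autosome count.
#' @param chromosome_length Chromosome length in bases.
#' @param msi_proportion Fraction of microsatellite-instable tumors (near
#'   CNA-free).
#' @param cms_proportions Named proportions of CMS1-4 among all samples; the
#'   remainder is unclassified (`NA` label).
#' @param purity_by_cms Named mean tumor purity per subtype (plus
#'   `unclassified`).
#' @param purity_sd Standard deviation of per-sample purity.
#' @param tetraploid_prob Probability that a tumor is near-tetraploid.
#' @param breakpoint_rate Expected Poisson breakpoints per chromosome.
#' @param gain_prob_bg,loss_prob_bg Background per-segment gain/loss
#'   probabilities in microsatellite-stable tumors.
#' @param gain_prob_program Per-segment gain probability on a subtype's
#'   program chromosomes in samples of that subtype.
#' @param program_chroms_by_cms Named list of program chromosomes per
#'   subtype.
#' @param program_size Genes per subtype expression program.
#' @param dosage_driven_fraction_by_cms Named fraction of each subtype's
#'   program that is copy-number driven (genes placed on the subtype's
#'   program chromosomes, upregulated only through dosage).
#' @param program_shift Intrinsic log2 shift of non-driven program genes in
#'   their subtype.
#' @param stromal_program_size Genes in the stromal (microenvironment)
#'   program, split equally across fibroblast/endothelial/leukocyte.
#' @param epithelial_marker_size Epithelial-specific marker genes.
#' @param stromal_shift Log2 shift of stromal program genes in the stromal
#'   profile.
#' @param epithelial_down Log2 amount by which epithelial markers are lower
#'   in the stromal profile.
#' @param dosage_effect Log2 expression change per additional DNA copy in
#'   the malignant-cell signal.
#' @param dosage_cap,dosage_floor Saturation bounds (in copies above/below
#'   ploidy) of the dosage response.
#' @param amp_rate Expected focal amplifications per microsatellite-stable
#'   sample.
#' @param amp_copies_range Integer range of additional copies per injected
#'   amplification.
#' @param amp_max_genes Maximum genes covered by an injected amplification.
#' @param noise_sd Gaussian noise on bulk log2 expression.
#' @param rel_jitter_sd Jitter on relative segment log-ratios.
#' @param survival_baseline_rate Baseline event rate per year.
#' @param amp_hazard_ratio Hazard multiplier for carriers of an injected
#'   high-level (>= 15 additional copies) focal amplification.
#' @param admin_censor_years Administrative censoring horizon of the raw
#'   follow-up times.
#' @param seed Root seed; all randomness derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 150,
                       n_genes = 2000,
                       n_chromosomes = 22,
                       chromosome_length = 1e7,
                       msi_proportion = 0.2,
                       cms_proportions = c(CMS1 = 0.07, CMS2 = 0.42,
                                           CMS3 = 0.15, CMS4 = 0.23),
                       purity_by_cms = c(CMS1 = 0.60, CMS2 = 0.70,
                                         CMS3 = 0.65, CMS4 = 0.45,
                                         unclassified = 0.60),
                       purity_sd = 0.08,
                       tetraploid_prob = 0.35,
                       breakpoint_rate = 3,
                       gain_prob_bg = 0.10,
                       loss_prob_bg = 0.10,
                       gain_prob_program = 0.70,
                       program_chroms_by_cms = list(CMS1 = "5",
                                                    CMS2 = c("20", "13", "8"),
                                                    CMS3 = "7",
                                                    CMS4 = c("10", "12")),
                       program_size = 250,
                       dosage_driven_fraction_by_cms = c(CMS1 = 0.05,
                                                         CMS2 = 0.50,
                                                         CMS3 = 0.10,
                                                         CMS4 = 0.10),
                       program_shift = 1.0,
                       stromal_program_size = 180,
                       epithelial_marker_size = 100,
                       stromal_shift = 2.0,
                       epithelial_down = 1.0,
                       dosage_effect = 1.0,
                       dosage_cap = 6,
                       dosage_floor = -2,
                       amp_rate = 0.8,
                       amp_copies_range = c(5L, 100L),
                       amp_max_genes = 10,
                       noise_sd = 0.3,
                       rel_jitter_sd = 0.02,
                       survival_baseline_rate = 0.06,
                       amp_hazard_ratio = 3,
                       admin_censor_years = 8,
                       seed = 1) {
  cfg <- as.list(environment())
  if (sum(cfg$cms_proportions) > 1 + 1e-9) stop("cms_proportions must sum to <= 1")
  if (any(unlist(cfg[c("breakpoint_rate", "amp_rate", "noise_sd",
                       "survival_baseline_rate")]) < 0)) {
    stop("rates and noise levels must be non-negative")
  }
  if (cfg$amp_copies_range[1] > cfg$amp_copies_range[2]) {
    stop("invalid amp_copies_range")
  }
  if (cfg$stromal_program_size + cfg$epithelial_marker_size +
      4 * cfg$program_size > cfg$n_genes) {
    stop("infeasible config: programs exceed the gene universe")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Evenly spaced, non-overlapping gene intervals over the autosomes.
.sim_genome <- function(cfg) {
  per_chr <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_genes %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  rows <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    n <- per_chr[ci]
    pitch <- cfg$chromosome_length / n
    start <- floor((seq_len(n) - 1) * pitch)
    width <- max(1000, floor(pitch * 0.4))
    data.frame(chrom = as.character(ci), start = as.integer(start),
               end = as.integer(start + width), stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  g$gene_id <- sprintf("g%04d", seq_len(nrow(g)))
  mid <- (g$start + g$end) / 2
  g$arm <- paste0(g$chrom, ifelse(mid < cfg$chromosome_length / 2, "p", "q"))
  g[, c("gene_id", "chrom", "start", "end", "arm")]
}

# Assign subtype programs, driven genes, stromal and epithelial markers.
# Driven program genes sit on their subtype's program chromosomes; all
# other designated sets sit on chromosomes that are no subtype's program,
# so that intrinsic shifts stay uncorrelated with copy number.
.sim_gene_roles <- function(cfg, genes) {
  cms <- names(cfg$cms_proportions)
  program <- rep(NA_character_, nrow(genes))
  driven <- rep(FALSE, nrow(genes))
  compartment <- rep(NA_character_, nrow(genes))
  all_prog_chroms <- unique(unlist(cfg$program_chroms_by_cms))
  free_neutral <- which(!(genes$chrom %in% all_prog_chroms))
  for (cm in cms) {
    theta <- cfg$dosage_driven_fraction_by_cms[[cm]]
    n_driven <- round(theta * cfg$program_size)
    pool <- which(genes$chrom %in% cfg$program_chroms_by_cms[[cm]] &
                    is.na(program))
    if (length(pool) < n_driven) stop("infeasible config: too few genes on program chromosomes")
    sel_d <- sample(pool, n_driven)
    program[sel_d] <- cm
    driven[sel_d] <- TRUE
    n_intr <- cfg$program_size - n_driven
    free_neutral <- setdiff(free_neutral, which(!is.na(program)))
    if (length(free_neutral) < n_intr) stop("infeasible config: gene universe too small")
    sel_i <- sample(free_neutral, n_intr)
    program[sel_i] <- cm
    free_neutral <- setdiff(free_neutral, sel_i)
  }
  n_str <- cfg$stromal_program_size
  sel_s <- sample(free_neutral, n_str)
  compartment[sel_s] <- rep(c("fibroblast", "endothelial", "leukocyte"),
                            length.out = n_str)
  free_neutral <- setdiff(free_neutral, sel_s)
  sel_e <- sample(free_neutral, cfg$epithelial_marker_size)
  compartment[sel_e] <- "epithelial"
  data.frame(gene_id = genes$gene_id, program = program,
             dosage_driven = driven, compartment = compartment,
             stringsAsFactors = FALSE)
}

# Segment one sample's genome: Poisson breakpoints plus the boundaries of
# injected amplifications, per-segment gain/loss states around the ploidy.
.sim_sample_segments <- function(cfg, genes, cms, msi, ploidy, amps) {
  rows <- vector("list", cfg$n_chromosomes)
  prog_chroms <- if (!is.na(cms)) cfg$program_chroms_by_cms[[cms]] else character(0)
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- as.character(ci)
    nb <- stats::rpois(1, cfg$breakpoint_rate)
    bp <- sort(unique(c(0, cfg$chromosome_length,
                        sample.int(cfg$chromosome_length - 1, nb))))
    a <- amps[amps$chrom == chrom, , drop = FALSE]
    if (nrow(a)) bp <- sort(unique(c(bp, a$start, a$end)))
    start <- bp[-length(bp)]; end <- bp[-1]
    n_seg <- length(start)
    p_gain <- if (msi) 0.01 else if (chrom %in% prog_chroms) cfg$gain_prob_program else cfg$gain_prob_bg
    p_loss <- if (msi) 0.01 else cfg$loss_prob_bg
    u <- stats::runif(n_seg)
    state <- ifelse(u < p_gain, "gain", ifelse(u < p_gain + p_loss, "loss", "neutral"))
    delta <- ifelse(state == "gain", 1L + stats::rbinom(n_seg, 1L, 0.25),
                    ifelse(state == "loss", -1L, 0L))
    nab <- pmax(ploidy + delta, 0L)
    # allele split; occasional copy-neutral LOH
    nb_allele <- nab %/% 2L
    cn_loh <- state == "neutral" & stats::runif(n_seg) < 0.05
    nb_allele[cn_loh] <- 0L
    seg <- data.frame(chrom = chrom, start = start, end = end,
                      nA = nab - nb_allele, nB = nb_allele,
                      stringsAsFactors = FALSE)
    # overlay injected amplifications
    if (nrow(a)) {
      for (k in seq_len(nrow(a))) {
        inside <- seg$start >= a$start[k] & seg$end <= a$end[k]
        tot <- ploidy + a$additional[k]
        seg$nB[inside] <- ploidy %/% 2L
        seg$nA[inside] <- tot - ploidy %/% 2L
      }
    }
    rows[[ci]] <- seg
  }
  do.call(rbind, rows)
}

# Draw injected focal amplifications for one sample.
.sim_sample_amps <- function(cfg, genes) {
  n_amp <- stats::rpois(1, cfg$amp_rate)
  if (n_amp == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      additional = integer(0), n_genes = integer(0),
                      first_gene = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(n_amp), function(k) {
    w <- sample.int(cfg$amp_max_genes, 1)
    chrom <- as.character(sample.int(cfg$n_chromosomes, 1))
    gi <- which(genes$chrom == chrom)
    i0 <- sample.int(length(gi) - w + 1L, 1)
    sel <- gi[i0:(i0 + w - 1L)]
    data.frame(chrom = chrom,
               start = genes$start[sel[1]],
               end = genes$end[sel[length(sel)]],
               additional = sample(seq(cfg$amp_copies_range[1],
                                       cfg$amp_copies_range[2]), 1),
               n_genes = w,
               first_gene = genes$gene_id[sel[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # drop overlapping injections on the same chromosome (keep the first)
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (k in 2:nrow(out)) {
      prev <- out[seq_len(k - 1), , drop = FALSE]
      keep[k] <- !any(prev$chrom == out$chrom[k] &
                        prev$start < out$end[k] & prev$end > out$start[k])
    }
  }
  out[keep, , drop = FALSE]
}

#' Simulate a full synthetic cohort
#'
#' Generates genome-covering allele-specific and relative copy-number
#' segments, bulk log2 expression with malignant/stromal admixture, sample
#' metadata including survival, and the ground truth needed for recovery
#' testing. The malignant-cell signal of a dosage-responsive gene changes by
#' `dosage_effect` log2 units per additional DNA copy (saturating at
#' `dosage_cap`); bulk expression mixes the malignant and stromal profiles
#' on the intensity scale weighted by tumor purity, then adds Gaussian
#' noise. Relative segment values are `log2(total copies / ploidy)` plus
#' jitter. Survival times are exponential with the hazard multiplied by
#' `amp_hazard_ratio` for carriers of an injected high-level focal
#' amplification, administratively censored at `admin_censor_years`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` (annotation), `rel_segments`,
#'   `allelic_segments`, `expr` (genes x samples matrix), `metadata`,
#'   `truth` (gene roles, per-sample purity/ploidy/carrier status, injected
#'   amplifications, baseline and stromal profiles, the config).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  genes <- .sim_genome(cfg)
  roles <- .sim_gene_roles(cfg, genes)
  ng <- nrow(genes)

  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  msi <- stats::runif(cfg$n_samples) < cfg$msi_proportion
  cms_levels <- names(cfg$cms_proportions)
  cms_prob <- c(cfg$cms_proportions, unclassified = 1 - sum(cfg$cms_proportions))
  cms <- sample(names(cms_prob), cfg$n_samples, replace = TRUE, prob = cms_prob)
  cms[cms == "unclassified"] <- NA_character_
  # MSI tumors are predominantly CMS1 or unclassified in this emulation
  cms[msi & !is.na(cms) & cms != "CMS1"] <- NA_character_

  purity_mean <- ifelse(is.na(cms), cfg$purity_by_cms[["unclassified"]],
                        cfg$purity_by_cms[cms])
  purity <- pmin(0.95, pmax(0.20, stats::rnorm(cfg$n_samples, purity_mean, cfg$purity_sd)))
  ploidy <- ifelse(stats::runif(cfg$n_samples) < cfg$tetraploid_prob, 4L, 2L)
  ploidy[msi] <- 2L

  baseline <- stats::rnorm(ng, mean = 7, sd = 1)
  names(baseline) <- genes$gene_id
  stromal <- baseline
  str_idx <- !is.na(roles$compartment) & roles$compartment != "epithelial"
  epi_idx <- !is.na(roles$compartment) & roles$compartment == "epithelial"
  stromal[str_idx] <- stromal[str_idx] + cfg$stromal_shift
  stromal[epi_idx] <- stromal[epi_idx] - cfg$epithelial_down

  gene_mid <- (genes$start + genes$end) / 2

  allelic <- vector("list", cfg$n_samples)
  relative <- vector("list", cfg$n_samples)
  amp_list <- vector("list", cfg$n_samples)
  expr <- matrix(NA_real_, ng, cfg$n_samples,
                 dimnames = list(genes$gene_id, samples))
  carrier_high <- logical(cfg$n_samples)

  for (si in seq_len(cfg$n_samples)) {
    amps <- if (msi[si]) .sim_sample_amps(cfg, genes)[0, , drop = FALSE] else .sim_sample_amps(cfg, genes)
    seg <- .sim_sample_segments(cfg, genes, cms[si], msi[si], ploidy[si], amps)
    nab <- seg$nA + seg$nB
    rel_val <- log2(pmax(nab, 0.25) / ploidy[si]) +
      stats::rnorm(nrow(seg), 0, cfg$rel_jitter_sd)
    allelic[[si]] <- cbind(sample = samples[si], seg, stringsAsFactors = FALSE)
    relative[[si]] <- data.frame(sample = samples[si], chrom = seg$chrom,
                                 start = seg$start, end = seg$end,
                                 value = rel_val, stringsAsFactors = FALSE)
    if (nrow(amps)) amp_list[[si]] <- cbind(sample = samples[si], amps,
                                            stringsAsFactors = FALSE)
    carrier_high[si] <- any(amps$additional >= 15)

    # per-gene total copies at the gene midpoint
    copies <- integer(ng)
    for (chrom in unique(seg$chrom)) {
      gi <- which(genes$chrom == chrom)
      sc <- seg[seg$chrom == chrom, , drop = FALSE]
      idx <- findInterval(gene_mid[gi], sc$start)
      copies[gi] <- (sc$nA + sc$nB)[idx]
    }
    delta <- pmin(pmax(copies - ploidy[si], cfg$dosage_floor), cfg$dosage_cap)

    responds <- roles$dosage_driven
    if (nrow(amps)) {
      for (k in seq_len(nrow(amps))) {
        covered <- genes$chrom == amps$chrom[k] &
          genes$start < amps$end[k] & genes$end > amps$start[k]
        responds <- responds | covered
      }
    }
    malig <- baseline + cfg$dosage_effect * delta * responds
    if (!is.na(cms[si])) {
      intr <- !is.na(roles$program) & roles$program == cms[si] & !roles$dosage_driven
      malig[intr] <- malig[intr] + cfg$program_shift
    }
    bulk <- log2(purity[si] * 2^malig + (1 - purity[si]) * 2^stromal)
    expr[, si] <- bulk + stats::rnorm(ng, 0, cfg$noise_sd)
  }

  stage <- sample(c("I", "II", "III", "IV"), cfg$n_samples, replace = TRUE,
                  prob = c(0.20, 0.30, 0.35, 0.15))
  age <- round(stats::rnorm(cfg$n_samples, 70, 10))
  gender <- sample(c("female", "male"), cfg$n_samples, replace = TRUE)
  localization <- sample(c("distal", "proximal"), cfg$n_samples, replace = TRUE)
  rate <- cfg$survival_baseline_rate * cfg$amp_hazard_ratio^carrier_high
  t_raw <- stats::rexp(cfg$n_samples, rate)
  os_event <- as.integer(t_raw <= cfg$admin_censor_years)
  os_time <- pmin(t_raw, cfg$admin_censor_years)

  metadata <- data.frame(
    sample = samples,
    msi = ifelse(msi, "MSI", "MSS"),
    cms = cms,
    stage = stage,
    age = age,
    gender = gender,
    localization = localization,
    os_time = os_time,
    os_event = os_event,
    stringsAsFactors = FALSE
  )
  amps_all <- do.call(rbind, amp_list[!vapply(amp_list, is.null, logical(1))])
  if (is.null(amps_all)) {
    amps_all <- data.frame(sample = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           additional = integer(0), n_genes = integer(0),
                           first_gene = character(0), stringsAsFactors = FALSE)
  }
  list(
    genes = genes,
    rel_segments = do.call(rbind, relative),
    allelic_segments = do.call(rbind, allelic),
    expr = expr,
    metadata = metadata,
    truth = list(
      gene_roles = roles,
      sample_truth = data.frame(sample = samples, cms = cms, msi = metadata$msi,
                                purity = purity, ploidy = as.numeric(ploidy),
                                carrier_high = carrier_high,
                                stringsAsFactors = FALSE),
      amps = amps_all,
      baseline = baseline,
      stromal_profile = stromal,
      amp_hazard_ratio = cfg$amp_hazard_ratio,
      config = cfg
    )
  )
}

#' Simulate a compartment-sorted expression reference
#'
#' Emulates expression of cell populations sorted into four compartments
#' (epithelial, endothelial, fibroblast, leukocyte). Each compartment's
#' markers are shifted above baseline; the stromal compartments carry the
#' same stromal program that is mixed into bulk expression by
#' [simulate_cohort()], and the epithelial compartment additionally
#' expresses the dosage-responsive genes, emulating a malignant-epithelial
#' expression phenotype.
#'
#' @param cohort A cohort from [simulate_cohort()] (its truth provides the
#'   baseline, the marker sets and the config).
#' @param n_replicates Sorted samples per compartment; default 4.
#' @param marker_shift Log2 marker shift; defaults to the config's
#'   `stromal_shift`.
#' @param seed Seed; defaults to the cohort seed offset by one.
#' @return A list with `expr` (genes x sorted-samples matrix) and `labels`
#'   (per-column compartment).
#' @export
simulate_compartment_reference <- function(cohort, n_replicates = 4,
                                           marker_shift = NULL, seed = NULL) {
  truth <- cohort$truth
  cfg <- truth$config
  if (is.null(marker_shift)) marker_shift <- cfg$stromal_shift
  if (is.null(seed)) seed <- cfg$seed + 1
  set.seed(seed)
  comps <- c("epithelial", "endothelial", "fibroblast", "leukocyte")
  roles <- truth$gene_roles
  markers <- lapply(comps, function(cp) {
    m <- roles$gene_id[!is.na(roles$compartment) & roles$compartment == cp]
    if (cp == "epithelial") m <- union(m, roles$gene_id[roles$dosage_driven])
    m
  })
  names(markers) <- comps
  labels <- rep(comps, each = n_replicates)
  ng <- length(truth$baseline)
  expr <- matrix(NA_real_, ng, length(labels),
                 dimnames = list(names(truth$baseline),
                                 paste0(labels, "_", seq_along(labels))))
  for (j in seq_along(labels)) {
    prof <- truth$baseline
    m <- markers[[labels[j]]]
    prof[m] <- prof[m] + marker_shift
    expr[, j] <- prof + stats::rnorm(ng, 0, cfg$noise_sd)
  }
  list(expr = expr, labels = labels, markers = markers)
}

#' Simulate a two-group exponential survival dataset
#'
#' Small generator for survival recovery checks: exponential event times
#' with a multiplicative hazard for the exposed group, administratively
#' censored.
#'
#' @param n Sample size.
#' @param hazard_ratio True hazard ratio of exposed vs unexposed.
#' @param p_exposed Exposure probability; default 0.3.
#' @param baseline_rate Baseline event rate per year; default 0.1.
#' @param admin_censor_years Administrative censoring horizon; default 8.
#' @param seed Optional seed.
#' @return data.frame with `time`, `event`, `exposed`.
#' @export
simulate_survival_data <- function(n, hazard_ratio, p_exposed = 0.3,
                                   baseline_rate = 0.1,
                                   admin_censor_years = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exposed <- as.integer(stats::runif(n) < p_exposed)
  t_raw <- stats::rexp(n, baseline_rate * hazard_ratio^exposed)
  data.frame(
    time = pmin(t_raw, admin_censor_years),
    event = as.integer(t_raw <= admin_censor_years),
    exposed = exposed
  )
}
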