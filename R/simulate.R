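# Synthetic DArTseq-style data generator. Emulates the structure of a wild
# population with a male-heterogametic sex-determining region: perfectly
# sex-linked SNP loci (all males heterozygous, all females homozygous
# reference), Y-specific presence/absence fragments, a partially recombining
# pseudoautosomal region producing moderately sex-linked loci with three male
# lineages (fully heterozygous; highly heterozygous; a low-heterozygosity
# "feminised-Y" lineage), Hardy-Weinberg autosomal loci, null alleles,
# call-rate metadata noise, unknown-sex samples and optional sex-reversed
# individuals. Output is reproducible bit-exactly from the seed.

#' Simulation parameters
#'
#' @param n_females number of true females.
#' @param n_males1,n_males2,n_males3 true male lineage sizes: fully
#'   heterozygous, highly heterozygous and low-heterozygosity (feminised-Y)
#'   males at the moderately sex-linked loci.
#' @param n_unknown number of samples whose phenotype is masked to `U`
#'   (chosen uniformly at random, i.e. with probability proportional to
#'   class sizes; their genotypes follow their true sex).
#' @param n_perfect_loci,n_moderate_loci,n_pa_loci planted sex-linked locus
#'   counts (perfect SNP, moderate SNP, Y-specific PA).
#' @param n_autosomal_snp,n_autosomal_pa autosomal locus counts.
#' @param p_het lineage heterozygosity levels at the moderate loci
#'   (defaults 1.0, 0.92, 0.16). Each male's heterozygous locus count is
#'   drawn binomially at the lineage level and constrained to the lineage's
#'   band (see Details).
#' @param af_range range of the autosomal reference-allele frequency
#'   distribution (uniform; default \[0.05, 0.95\]).
#' @param null_rate per-cell null-allele probability (default 0).
#' @param callrate_noise fraction of loci assigned a call-rate metadata
#'   value drawn uniformly from \[0.5, 1) instead of 1 (default 0).
#' @param n_sex_reversed number of confidently phenotyped individuals whose
#'   recorded phenotype is flipped relative to their genotypic sex
#'   (default 0).
#' @param n_sites number of sampling sites, assigned near-uniformly.
#' @param group_high,group_low the heterozygosity-group thresholds the
#'   lineage bands are anchored to (defaults 0.85 and 0.20, matching
#'   [assign_groups()]).
#' @param seed integer seed for the single global random stream.
#'
#' @details At the moderate loci, lineage-1 males are heterozygous at every
#' locus; a lineage-2 male is heterozygous at `k ~ Binomial(L, p_het[2])`
#' loci constrained to `[ceiling(group_high * L), L - 1]`; a lineage-3 male
#' at `k ~ Binomial(L, p_het[3])` loci constrained to
#' `[0, floor(group_low * L)]`; heterozygous positions are drawn uniformly
#' per male. Constraining the counts to the lineage bands makes the planted
#' group structure exactly recoverable at any seed while preserving
#' between-male variance; the constraint binds rarely (about 4% of draws at
#' the default L = 47).
#'
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_females = 18L, n_males1 = 13L, n_males2 = 12L,
                       n_males3 = 9L, n_unknown = 8L,
                       n_perfect_loci = 11L, n_moderate_loci = 47L,
                       n_pa_loci = 6L, n_autosomal_snp = 1000L,
                       n_autosomal_pa = 1000L,
                       p_het = c(1.0, 0.92, 0.16),
                       af_range = c(0.05, 0.95), null_rate = 0,
                       callrate_noise = 0, n_sex_reversed = 0L,
                       n_sites = 3L, group_high = 0.85, group_low = 0.20,
                       seed = 1L) {
  counts <- c(n_females, n_males1, n_males2, n_males3, n_unknown,
              n_perfect_loci, n_moderate_loci, n_pa_loci,
              n_autosomal_snp, n_autosomal_pa, n_sex_reversed, n_sites)
  if (any(counts < 0) || any(counts != as.integer(counts)))
    stop("all counts must be non-negative integers", call. = FALSE)
  probs <- c(p_het, null_rate, callrate_noise, group_high, group_low)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  n_males <- n_males1 + n_males2 + n_males3
  if (n_females + n_males < 2L || n_females < 1L || n_males < 1L)
    stop("need at least one male and one female", call. = FALSE)
  if (length(p_het) != 3L) stop("`p_het` must have length 3", call. = FALSE)
  if (af_range[1L] > af_range[2L] || any(af_range < 0 | af_range > 1))
    stop("`af_range` must be an increasing pair in [0, 1]", call. = FALSE)
  if (n_unknown > n_females + n_males)
    stop("`n_unknown` exceeds the number of samples", call. = FALSE)
  structure(list(n_females = n_females, n_males1 = n_males1,
                 n_males2 = n_males2, n_males3 = n_males3,
                 n_unknown = n_unknown, n_perfect_loci = n_perfect_loci,
                 n_moderate_loci = n_moderate_loci, n_pa_loci = n_pa_loci,
                 n_autosomal_snp = n_autosomal_snp,
                 n_autosomal_pa = n_autosomal_pa, p_het = p_het,
                 af_range = af_range, null_rate = null_rate,
                 callrate_noise = callrate_noise,
                 n_sex_reversed = n_sex_reversed, n_sites = n_sites,
                 group_high = group_high, group_low = group_low,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Study-scale preset parameters
#'
#' Parameters emulating a 52-sample wild amphibian population: 34 true males
#' in lineages of 13/12/9, 18 true females, 8 individuals of masked
#' (unknown) phenotype, 11 perfectly sex-linked SNP loci, 47 moderately
#' sex-linked loci, 6 Y-specific PA fragments, and autosomal SNP/PA loci
#' bringing the filtered totals to 20,111 SNP and 19,121 PA loci. Three
#' sampling sites, no noise, fixed seed.
#'
#' @param seed optional seed override (default 20191112).
#' @return a [sim_params()] object.
#' @export
study_preset <- function(seed = 20191112L) {
  sim_params(n_females = 18L, n_males1 = 13L, n_males2 = 12L, n_males3 = 9L,
             n_unknown = 8L, n_perfect_loci = 11L, n_moderate_loci = 47L,
             n_pa_loci = 6L, n_autosomal_snp = 20053L, n_autosomal_pa = 19115L,
             p_het = c(1.0, 0.92, 0.16), af_range = c(0.05, 0.95),
             null_rate = 0, callrate_noise = 0, n_sex_reversed = 0L,
             n_sites = 3L, seed = seed)
}

# Binomial draw constrained to [lo, hi] (clamped, not rejected: keeps the
# draw cheap and the marginal close to binomial when the band is wide).
.rbinom_band <- function(n, size, prob, lo, hi) {
  pmin(pmax(stats::rbinom(n, size, prob), lo), hi)
}

.hw_genotypes <- function(n_loci, n_samples, p) {
  # p: per-locus reference-allele frequency
  u <- matrix(stats::runif(n_loci * n_samples), n_loci, n_samples)
  g <- matrix("HOM_ALT", n_loci, n_samples)
  g[u < p^2 + 2 * p * (1 - p)] <- "HET"
  g[u < p^2] <- "HOM_REF"
  g
}

#' Simulate a DArTseq-style dataset
#'
#' @param params a [sim_params()] object.
#' @return a list of class `sim_result`: `snp` ([snp_matrix()]), `pa`
#'   ([pa_matrix()]), `registry` ([sex_registry()] of recorded phenotypes),
#'   `truth` (list with `samples` — `sample_id`, `true_sex`, `phenotype`,
#'   `lineage`, `site` — and `loci` — `locus_id`, `class` in
#'   `PERFECT_SNP`/`MODERATE_SNP`/`PA_LINKED`/`AUTOSOMAL_SNP`/`AUTOSOMAL_PA`).
#' @export
simulate_dartseq <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_males <- params$n_males1 + params$n_males2 + params$n_males3
  n <- n_males + params$n_females
  if (n_males == 0L && (params$n_perfect_loci > 0L || params$n_pa_loci > 0L ||
                        params$n_moderate_loci > 0L))
    stop("cannot plant sex-linked loci with zero males", call. = FALSE)

  sample_id <- sprintf("S%02d", seq_len(n))
  true_sex <- c(rep("M", n_males), rep("F", params$n_females))
  lineage <- c(rep("MALES1", params$n_males1), rep("MALES2", params$n_males2),
               rep("MALES3", params$n_males3), rep(NA_character_, params$n_females))
  ord <- sample.int(n)            # shuffle so sexes are not column-blocked
  true_sex <- true_sex[ord]; lineage <- lineage[ord]
  site <- sample(rep_len(sprintf("site%d", seq_len(params$n_sites)), n))

  phenotype <- true_sex
  if (params$n_sex_reversed > 0L) {
    rev_idx <- sample.int(n, params$n_sex_reversed)
    phenotype[rev_idx] <- ifelse(true_sex[rev_idx] == "M", "F", "M")
  } else rev_idx <- integer()
  if (params$n_unknown > 0L) {
    mask_idx <- sample(setdiff(seq_len(n), rev_idx), params$n_unknown)
    phenotype[mask_idx] <- "U"
  }

  is_male <- true_sex == "M"
  L_perf <- params$n_perfect_loci
  L_mod <- params$n_moderate_loci
  L_auto <- params$n_autosomal_snp

  # perfectly sex-linked SNP loci: males HET, females HOM_REF
  perf <- matrix(as.character(ifelse(rep(is_male, each = L_perf), "HET",
                                     "HOM_REF")), nrow = L_perf, ncol = n)

  # moderate loci: per-male heterozygous locus count drawn at the lineage
  # level, positions uniform
  mod <- matrix("HOM_REF", nrow = L_mod, ncol = n)
  if (L_mod > 0L) {
    # lineage-band constraints apply only when the lineage heterozygosity
    # level itself lies inside the band; degenerate settings (e.g. all
    # p_het = 1) fall back to the unconstrained draw
    hi_band <- ceiling(params$group_high * L_mod)
    lo_band <- floor(params$group_low * L_mod)
    draw_k <- function(p, lo, hi) {
      if (p >= 1) return(L_mod)
      if (p <= 0) return(0L)
      .rbinom_band(1L, L_mod, p, lo, hi)
    }
    for (s in which(is_male)) {
      k <- switch(lineage[s],
        MALES1 = draw_k(params$p_het[1L], 0L, L_mod),
        MALES2 = if (params$p_het[2L] >= params$group_high &&
                       params$p_het[2L] < 1)
          draw_k(params$p_het[2L], hi_band, max(hi_band, L_mod - 1L))
        else draw_k(params$p_het[2L], 0L, L_mod),
        MALES3 = if (params$p_het[3L] <= params$group_low)
          draw_k(params$p_het[3L], 0L, lo_band)
        else draw_k(params$p_het[3L], 0L, L_mod))
      if (k > 0L) mod[sample.int(L_mod, k), s] <- "HET"
    }
  }

  # autosomal SNP loci: Hardy-Weinberg at drawn reference-allele frequencies
  af <- stats::runif(L_auto, params$af_range[1L], params$af_range[2L])
  auto <- .hw_genotypes(L_auto, n, af)

  snp_calls <- rbind(perf, mod, auto)
  rownames(snp_calls) <- c(sprintf("SNPperf%03d", seq_len(L_perf)),
                           sprintf("SNPmod%03d", seq_len(L_mod)),
                           sprintf("SNPauto%05d", seq_len(L_auto)))
  colnames(snp_calls) <- sample_id

  # PA: Y-specific fragments present in males, absent in females; autosomal
  # fragments at drawn presence frequencies
  L_palink <- params$n_pa_loci
  L_paauto <- params$n_autosomal_pa
  palink <- matrix(as.character(ifelse(rep(is_male, each = L_palink),
                                       "PRESENT", "ABSENT")),
                   nrow = L_palink, ncol = n)
  pf <- stats::runif(L_paauto, params$af_range[1L], params$af_range[2L])
  paauto <- matrix(as.character(
    ifelse(matrix(stats::runif(L_paauto * n), L_paauto, n) < pf,
           "PRESENT", "ABSENT")), L_paauto, n)
  pa_calls <- rbind(palink, paauto)
  rownames(pa_calls) <- c(sprintf("PAlink%03d", seq_len(L_palink)),
                          sprintf("PAauto%05d", seq_len(L_paauto)))
  colnames(pa_calls) <- sample_id

  if (params$null_rate > 0) {
    snp_calls[matrix(stats::runif(length(snp_calls)), nrow(snp_calls)) <
                params$null_rate] <- "NULL_CALL"
    pa_calls[matrix(stats::runif(length(pa_calls)), nrow(pa_calls)) <
               params$null_rate] <- "NULL_CALL"
  }

  make_callrate <- function(n_loci) {
    cr <- rep(1, n_loci)
    if (params$callrate_noise > 0 && n_loci > 0L) {
      noisy <- stats::runif(n_loci) < params$callrate_noise
      cr[noisy] <- stats::runif(sum(noisy), 0.5, 1 - 1e-9)
    }
    cr
  }
  snp_ids <- rownames(snp_calls)
  pa_ids <- if (is.null(rownames(pa_calls))) character() else rownames(pa_calls)
  snp_meta <- data.frame(locus_id = snp_ids,
                         ref_seq = character(length(snp_ids)),
                         alt_seq = character(length(snp_ids)),
                         call_rate = make_callrate(length(snp_ids)),
                         reproducibility = rep(1, length(snp_ids)),
                         stringsAsFactors = FALSE)
  pa_meta <- data.frame(locus_id = pa_ids,
                        sequence = character(length(pa_ids)),
                        call_rate = make_callrate(length(pa_ids)),
                        reproducibility = rep(1, length(pa_ids)),
                        stringsAsFactors = FALSE)

  truth <- list(
    samples = data.frame(sample_id = sample_id, true_sex = true_sex,
                         phenotype = phenotype, lineage = lineage, site = site,
                         stringsAsFactors = FALSE),
    loci = data.frame(locus_id = c(rownames(snp_calls), rownames(pa_calls)),
                      class = c(rep("PERFECT_SNP", L_perf),
                                rep("MODERATE_SNP", L_mod),
                                rep("AUTOSOMAL_SNP", L_auto),
                                rep("PA_LINKED", L_palink),
                                rep("AUTOSOMAL_PA", L_paauto)),
                      stringsAsFactors = FALSE))
  structure(list(snp = snp_matrix(snp_calls, snp_meta),
                 pa = pa_matrix(pa_calls, pa_meta),
                 registry = sex_registry(sample_id, phenotype, site),
                 truth = truth, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", nrow(x$truth$samples), "samples;",
      nrow(x$snp$calls), "SNP loci;", nrow(x$pa$calls), "PA loci\n")
  cat("  phenotypes:", paste(names(table(x$registry$sex)),
                             table(x$registry$sex), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits `snp.csv`, `pa.csv`, `sexes.csv` (the pipeline's canonical dialect)
#' and `truth.tsv` (columns `sample_id`, `true_sex`, `phenotype`, `lineage`,
#' `site` for samples; `locus_id`, `class` for loci, stacked with a `table`
#' column).
#'
#' @param sim a [simulate_dartseq()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(snp = file.path(dir, "snp.csv"), pa = file.path(dir, "pa.csv"),
             sexes = file.path(dir, "sexes.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_snp_table(sim$snp, paths["snp"])
  write_pa_table(sim$pa, paths["pa"])
  write_sex_registry(sim$registry, paths["sexes"])
  samples <- data.frame(record = "sample", id = sim$truth$samples$sample_id,
                        true_sex_or_class = sim$truth$samples$true_sex,
                        phenotype = sim$truth$samples$phenotype,
                        lineage = sim$truth$samples$lineage,
                        site = sim$truth$samples$site, stringsAsFactors = FALSE)
  loci <- data.frame(record = "locus", id = sim$truth$loci$locus_id,
                     true_sex_or_class = sim$truth$loci$class,
                     phenotype = NA, lineage = NA, site = NA,
                     stringsAsFactors = FALSE)
  utils::write.table(rbind(samples, loci), paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
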