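# Per-male heterozygosity profiling over the moderately sex-linked loci.
# Males partition into lineages by their heterozygous fraction: fully
# heterozygous (an unrecombined Y haplotype), highly heterozygous (occasional
# X-Y recombination), and a "feminised-Y" group carrying X-like reference
# alleles at most pseudoautosomal loci. The fraction uses non-null calls as
# the denominator: grouping is per-individual, and a null call carries no
# genotype information for that individual.

#' Per-male heterozygosity profiles over selected loci
#'
#' @param x a [snp_matrix()].
#' @param loci locus ids (typically the moderately sex-linked set).
#' @param males sample ids of the males to profile (phenotypic plus
#'   genotypically assigned).
#' @param denominator `"called"` (default): heterozygous fraction over
#'   non-null calls; `"all"`: over all selected loci.
#' @return data frame with `sample_id`, `n_loci` (non-null calls used),
#'   `het_fraction`, `defined` (`FALSE` when the male has no non-null call
#'   over the loci, in which case `het_fraction` is `NA`).
#' @export
male_het_profiles <- function(x, loci, males,
                              denominator = c("called", "all")) {
  stopifnot(inherits(x, "snp_matrix"))
  denominator <- match.arg(denominator)
  sub <- subset_loci(x, loci = loci, samples = males)
  calls <- sub$calls
  n_called <- colSums(calls != "NULL_CALL")
  n_het <- colSums(calls == "HET")
  denom <- if (denominator == "called") n_called else rep(length(loci), length(males))
  defined <- denom > 0L
  data.frame(sample_id = males,
             n_loci = as.integer(n_called),
             het_fraction = ifelse(defined, n_het / denom, NA_real_),
             defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign males to heterozygosity groups
#'
#' Fixed-threshold rule: `MALES1` at heterozygous fraction exactly 1 (fully
#' heterozygous), `MALES2` at `high <= fraction < 1` (highly heterozygous),
#' `MALES3` at `fraction <= low` (feminised-Y, female-like), otherwise
#' `UNASSIGNED`. Undefined profiles (no informative call) are excluded.
#'
#' @param profiles output of [male_het_profiles()].
#' @param high lower bound of the highly heterozygous group (default 0.85).
#' @param low upper bound of the low-heterozygosity group (default 0.20).
#' @return a list of class `group_assignment`: `assignments` (data frame
#'   `sample_id`, `het_fraction`, `group`), `counts` (named vector over the
#'   four groups), `thresholds`.
#' @export
assign_groups <- function(profiles, high = 0.85, low = 0.20) {
  stopifnot(is.data.frame(profiles), high >= 0, high <= 1, low >= 0, low <= 1)
  p <- profiles[profiles$defined, , drop = FALSE]
  f <- p$het_fraction
  group <- rep("UNASSIGNED", nrow(p))
  group[f <= low] <- "MALES3"
  group[f >= high & f < 1] <- "MALES2"
  group[f == 1] <- "MALES1"
  assignments <- data.frame(sample_id = p$sample_id, n_loci = p$n_loci,
                            het_fraction = f, group = group,
                            stringsAsFactors = FALSE, row.names = NULL)
  counts <- vapply(c("MALES1", "MALES2", "MALES3", "UNASSIGNED"),
                   function(g) sum(group == g), integer(1L))
  structure(list(assignments = assignments, counts = counts,
                 thresholds = c(high = high, low = low)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:",
      paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Shared Welch machinery: t from the two group summaries, degrees of freedom
# by Welch-Satterthwaite, two-tailed p from the t distribution.
.welch <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2)
      stop("Welch t undefined: zero variance in both groups with equal means",
           call. = FALSE)
    t <- sign(mean1 - mean2) * Inf
    df <- n1 + n2 - 2
  } else {
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, df_floor = floor(df), p_two_tailed = p,
                 groups = data.frame(group = c("a", "b"), n = c(n1, n2),
                                     mean = c(mean1, mean2), sd = c(sd1, sd2),
                                     stringsAsFactors = FALSE)),
            class = "welch_test")
}

#' Welch two-sample t-test (unequal variances)
#'
#' `welch_t_from_values()` computes the test from raw values (sample
#' standard deviations with the n-1 denominator); `welch_t_from_summary()`
#' applies the identical formulas to published group summaries, which a raw
#' two-sample test cannot do. The two routes agree to floating point when
#' given consistent inputs.
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @return a list of class `welch_test` with `t`, `df` (real
#'   Welch-Satterthwaite value), `df_floor`, `p_two_tailed` and the group
#'   summaries. `t` follows `mean(a) - mean(b)`.
#' @export
welch_t_from_values <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  out <- .welch(length(a), mean(a), stats::sd(a), length(b), mean(b), stats::sd(b))
  out
}

#' @rdname welch_t_from_values
#' @param n1,mean1,sd1,n2,mean2,sd2 group sizes, means and sample standard
#'   deviations.
#' @export
welch_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  .welch(n1, mean1, sd1, n2, mean2, sd2)
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t(%d) = %.4g (df = %.4g), p = %.4g\n",
              x$df_floor, x$t, x$df, x$p_two_tailed))
  invisible(x)
}
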