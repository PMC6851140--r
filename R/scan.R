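# Per-locus sex-concordance scoring under both heterogametic hypotheses.
#
# Under a male-heterogametic (XX-XY) system, a SNP locus tightly linked to the
# sex-determining region has every male heterozygous (one X/reference allele,
# one Y/alternate allele) and every female homozygous for the reference
# allele; under female heterogamety (ZZ-ZW) the pattern is mirrored. The
# per-locus statistic is
#
#   S = (fraction of the heterogametic sex scored HET)
#     + (fraction of the homogametic sex scored HOM_REF)
#
# with S = 2 exactly when the locus assorts perfectly to sex. Proportions are
# taken over ALL confidently sexed individuals of each sex by default, so
# null alleles and discordant calls count against the score.

.het_sex <- function(system) switch(system, XY = "M", ZW = "F",
                                    stop("system must be 'XY' or 'ZW'", call. = FALSE))
.hom_sex <- function(system) switch(system, XY = "F", ZW = "M")

.sex_groups <- function(registry, samples) {
  sexes <- registry_sex(registry, samples)
  list(M = samples[sexes == "M"], F = samples[sexes == "F"])
}

.check_sexed <- function(groups) {
  if (length(groups$M) == 0L || length(groups$F) == 0L)
    stop("concordance score undefined: need at least one confidently sexed ",
         "male and one female", call. = FALSE)
}

.prop <- function(calls, value, denominator) {
  if (denominator == "all") mean(calls == value)
  else {
    called <- calls[calls != "NULL_CALL"]
    if (!length(called)) 0 else mean(called == value)
  }
}

#' Score one SNP locus for sex concordance
#'
#' @param calls named character vector of SNP calls for one locus (names are
#'   sample ids, values in `SNP_CALLS`).
#' @param registry a [sex_registry()] covering all samples; `U`-sex samples
#'   are excluded from both proportions.
#' @param system `"XY"` (males heterogametic) or `"ZW"`.
#' @param denominator `"all"` (default): proportions over all confidently
#'   sexed individuals of the sex, so nulls count against the score;
#'   `"called"`: proportions over non-null calls only.
#' @return a one-row data frame with `locus_id` (`NA` here; filled by
#'   [scan_snp()]), `system`, `prop_het_heterogametic`,
#'   `prop_homref_homogametic` and `score`.
#' @export
score_snp_locus <- function(calls, registry, system = c("XY", "ZW"),
                            denominator = c("all", "called")) {
  system <- match.arg(system)
  denominator <- match.arg(denominator)
  groups <- .sex_groups(registry, names(calls))
  .check_sexed(groups)
  het_calls <- calls[groups[[.het_sex(system)]]]
  hom_calls <- calls[groups[[.hom_sex(system)]]]
  p_het <- .prop(het_calls, "HET", denominator)
  p_hom <- .prop(hom_calls, "HOM_REF", denominator)
  data.frame(locus_id = NA_character_, system = system,
             prop_het_heterogametic = p_het,
             prop_homref_homogametic = p_hom,
             score = p_het + p_hom, stringsAsFactors = FALSE)
}

# Vectorised scoring over all loci of a matrix; equals row-wise
# score_snp_locus (property-tested).
.scan_snp_system <- function(calls, groups, system, denominator) {
  het <- calls[, groups[[.het_sex(system)]], drop = FALSE]
  hom <- calls[, groups[[.hom_sex(system)]], drop = FALSE]
  if (denominator == "all") {
    p_het <- rowMeans(het == "HET")
    p_hom <- rowMeans(hom == "HOM_REF")
  } else {
    n_het <- rowSums(het != "NULL_CALL")
    n_hom <- rowSums(hom != "NULL_CALL")
    p_het <- ifelse(n_het > 0L, rowSums(het == "HET") / n_het, 0)
    p_hom <- ifelse(n_hom > 0L, rowSums(hom == "HOM_REF") / n_hom, 0)
  }
  data.frame(locus_id = rownames(calls), system = system,
             prop_het_heterogametic = p_het,
             prop_homref_homogametic = p_hom,
             score = p_het + p_hom, stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan all SNP loci under both heterogametic hypotheses
#'
#' Scores every locus under XY and ZW and lists the perfectly sex-linked loci
#' per system. Perfection is decided on exact proportions (both equal to 1,
#' i.e. integer-count equality), never on a floating-point tolerance on the
#' sum.
#'
#' @param x a filtered [snp_matrix()].
#' @inheritParams score_snp_locus
#' @return a list of class `snp_scan`: `scores` (data frame stacking XY and
#'   ZW rows in locus order), `perfect` (list with `XY` and `ZW` character
#'   vectors of locus ids), `n_male`, `n_female`.
#' @export
scan_snp <- function(x, registry, denominator = c("all", "called")) {
  stopifnot(inherits(x, "snp_matrix"))
  denominator <- match.arg(denominator)
  groups <- .sex_groups(registry, sample_ids(x))
  .check_sexed(groups)
  xy <- .scan_snp_system(x$calls, groups, "XY", denominator)
  zw <- .scan_snp_system(x$calls, groups, "ZW", denominator)
  perfect <- lapply(list(XY = xy, ZW = zw), function(s)
    s$locus_id[s$prop_het_heterogametic == 1 & s$prop_homref_homogametic == 1])
  structure(list(scores = rbind(xy, zw), perfect = perfect,
                 n_male = length(groups$M), n_female = length(groups$F)),
            class = "snp_scan")
}

#' @export
print.snp_scan <- function(x, ...) {
  cat("snp_scan:", nrow(x$scores) / 2L, "loci;", x$n_male, "males,",
      x$n_female, "females\n")
  cat("  perfect XY:", length(x$perfect$XY),
      " perfect ZW:", length(x$perfect$ZW), "\n")
  invisible(x)
}

#' Score one presence/absence locus for sex concordance
#'
#' A sex-linked PA locus (restriction fragment on the sex-limited chromosome)
#' is present in the heterogametic and absent in the homogametic sex.
#' `contradiction_free` is `TRUE` when no heterogametic-sex individual is
#' scored ABSENT and no homogametic-sex individual PRESENT — null alleles,
#' which often reflect heterozygous fragment dosage, are tolerated.
#'
#' @param calls named character vector of PA calls for one locus.
#' @inheritParams score_snp_locus
#' @return one-row data frame with per-sex present/absent/null proportions
#'   and the `contradiction_free` flag.
#' @export
score_pa_locus <- function(calls, registry, system = c("XY", "ZW")) {
  system <- match.arg(system)
  groups <- .sex_groups(registry, names(calls))
  .check_sexed(groups)
  het_calls <- calls[groups[[.het_sex(system)]]]
  hom_calls <- calls[groups[[.hom_sex(system)]]]
  data.frame(locus_id = NA_character_, system = system,
             prop_present_heterogametic = mean(het_calls == "PRESENT"),
             prop_absent_homogametic = mean(hom_calls == "ABSENT"),
             prop_null_heterogametic = mean(het_calls == "NULL_CALL"),
             prop_null_homogametic = mean(hom_calls == "NULL_CALL"),
             contradiction_free = !any(het_calls == "ABSENT") &&
               !any(hom_calls == "PRESENT"),
             stringsAsFactors = FALSE)
}

.scan_pa_system <- function(calls, groups, system) {
  het <- calls[, groups[[.het_sex(system)]], drop = FALSE]
  hom <- calls[, groups[[.hom_sex(system)]], drop = FALSE]
  data.frame(locus_id = rownames(calls), system = system,
             prop_present_heterogametic = rowMeans(het == "PRESENT"),
             prop_absent_homogametic = rowMeans(hom == "ABSENT"),
             prop_null_heterogametic = rowMeans(het == "NULL_CALL"),
             prop_null_homogametic = rowMeans(hom == "NULL_CALL"),
             contradiction_free = rowSums(het == "ABSENT") == 0L &
               rowSums(hom == "PRESENT") == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan all presence/absence loci under both hypotheses
#'
#' A locus is called sex-linked under a system when at least `min_prop` of
#' the heterogametic sex is PRESENT, at least `min_prop` of the homogametic
#' sex is ABSENT, and (by default) no contradictory call exists in either
#' sex.
#'
#' @param x a filtered [pa_matrix()].
#' @param registry a [sex_registry()]; `U` samples are excluded.
#' @param min_prop minimum presence/absence proportion (default 0.9).
#' @param require_contradiction_free require zero contradictory calls
#'   (default `TRUE`).
#' @return a list of class `pa_scan`: `scores`, `linked` (`XY`/`ZW` locus-id
#'   vectors), `n_male`, `n_female`, `min_prop`.
#' @export
scan_pa <- function(x, registry, min_prop = 0.9,
                    require_contradiction_free = TRUE) {
  stopifnot(inherits(x, "pa_matrix"), min_prop >= 0, min_prop <= 1)
  groups <- .sex_groups(registry, sample_ids(x))
  .check_sexed(groups)
  xy <- .scan_pa_system(x$calls, groups, "XY")
  zw <- .scan_pa_system(x$calls, groups, "ZW")
  linked <- lapply(list(XY = xy, ZW = zw), function(s) {
    ok <- s$prop_present_heterogametic >= min_prop &
      s$prop_absent_homogametic >= min_prop
    if (require_contradiction_free) ok <- ok & s$contradiction_free
    s$locus_id[ok]
  })
  structure(list(scores = rbind(xy, zw), linked = linked,
                 n_male = length(groups$M), n_female = length(groups$F),
                 min_prop = min_prop),
            class = "pa_scan")
}

#' @export
print.pa_scan <- function(x, ...) {
  cat("pa_scan:", nrow(x$scores) / 2L, "loci;", x$n_male, "males,",
      x$n_female, "females\n")
  cat("  linked XY:", length(x$linked$XY),
      " linked ZW:", length(x$linked$ZW), "\n")
  invisible(x)
}

#' Find moderately sex-linked SNP loci
#'
#' Moderately sex-linked loci are interpreted as a pseudoautosomal,
#' occasionally recombining region of the sex-limited chromosome: every
#' homogametic-sex individual is homozygous for the reference allele, while
#' only a subset of the heterogametic sex is heterozygous. The registry may
#' carry genotypically assigned sexes for initially unknown individuals
#' (see [augment_registry()]), which sharpens the male-side proportions.
#'
#' The male-side floor and the homozygous-alternate exclusion control false
#' positives: among tens of thousands of autosomal loci, a locus can match
#' the female-side rule by chance when its reference allele is common, and
#' such loci carry modest male heterozygosity. With ~18 females and ~34
#' males, a floor of 0.5 keeps the expected chance count per 20,000
#' autosomal loci below 0.01, while a genuinely pseudoautosomal locus — at
#' which one male lineage is fully heterozygous and a second mostly so —
#' sits well above it. A male homozygous for the alternate allele is
#' impossible when the alternate allele is confined to the Y, so such loci
#' are excluded too (configurable).
#'
#' @param x a filtered [snp_matrix()].
#' @param registry a [sex_registry()] (possibly genotype-augmented).
#' @param system `"XY"` or `"ZW"`.
#' @param min_het_prop minimum heterozygous proportion in the heterogametic
#'   sex (default 0.5); loci at proportion 1 belong to the perfect class and
#'   are excluded.
#' @param exclude locus ids to exclude (typically the perfect list).
#' @param allow_null_homogametic if `TRUE`, null calls in the homogametic sex
#'   are tolerated; by default every homogametic call must be exactly
#'   `HOM_REF`.
#' @param allow_homalt_heterogametic if `TRUE`, heterogametic-sex
#'   homozygous-alternate calls are tolerated; excluded by default.
#' @param denominator see [score_snp_locus()].
#' @return character vector of locus ids, in matrix order.
#' @export
find_moderate_loci <- function(x, registry, system = c("XY", "ZW"),
                               min_het_prop = 0.5, exclude = character(),
                               allow_null_homogametic = FALSE,
                               allow_homalt_heterogametic = FALSE,
                               denominator = c("all", "called")) {
  stopifnot(inherits(x, "snp_matrix"))
  system <- match.arg(system)
  denominator <- match.arg(denominator)
  groups <- .sex_groups(registry, sample_ids(x))
  .check_sexed(groups)
  het <- x$calls[, groups[[.het_sex(system)]], drop = FALSE]
  hom <- x$calls[, groups[[.hom_sex(system)]], drop = FALSE]
  hom_ok <- if (allow_null_homogametic)
    rowSums(hom == "HET" | hom == "HOM_ALT") == 0L & rowSums(hom == "HOM_REF") > 0L
  else
    rowSums(hom == "HOM_REF") == ncol(hom)
  p_het <- if (denominator == "all") rowMeans(het == "HET") else {
    n <- rowSums(het != "NULL_CALL")
    ifelse(n > 0L, rowSums(het == "HET") / n, 0)
  }
  het_ok <- p_het >= min_het_prop & p_het < 1
  if (!allow_homalt_heterogametic)
    het_ok <- het_ok & rowSums(het == "HOM_ALT") == 0L
  ids <- locus_ids(x)[hom_ok & het_ok]
  setdiff(ids, exclude)
}

#' Infer the sex-determining system from marker counts
#'
#' Conservative rule: a system is called only when all evidence points one
#' way — any conflicting marker (or no marker at all) yields `UNDETERMINED`.
#'
#' @param perfect_xy,perfect_zw counts of perfectly sex-linked SNP loci under
#'   each hypothesis.
#' @param pa_xy,pa_zw counts of sex-linked PA loci under each hypothesis.
#' @return `"XY"`, `"ZW"` or `"UNDETERMINED"`.
#' @export
infer_system <- function(perfect_xy, perfect_zw, pa_xy = 0L, pa_zw = 0L) {
  stopifnot(perfect_xy >= 0, perfect_zw >= 0, pa_xy >= 0, pa_zw >= 0)
  xy <- perfect_xy + pa_xy
  zw <- perfect_zw + pa_zw
  if (xy > 0 && zw == 0) "XY"
  else if (zw > 0 && xy == 0) "ZW"
  else "UNDETERMINED"
}

# ---- spurious sex-linkage model ---------------------------------------------

#' Probability that one locus is sex-linked by chance
#'
#' The screening model assumes each individual independently matches a
#' sex-specific genotype with probability 1/2, so a locus passes the perfect
#' sex-linkage screen by chance with probability `0.5^n` for `n` confidently
#' sexed individuals. This is a heterozygosity-0.5 approximation — the true
#' null probability depends on allele frequency and is typically smaller (see
#' the permutation oracle in the test-suite) — so it is a conservative
#' screening bound, not an exact null.
#'
#' @param n number of confidently sexed individuals (positive integer).
#' @return `0.5^n`.
#' @export
spurious_probability <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    stop("`n` must be a positive integer", call. = FALSE)
  0.5^n
}

#' Expected number of spuriously sex-linked loci
#'
#' @param m number of quality loci screened (non-negative integer).
#' @inheritParams spurious_probability
#' @return `m * 0.5^n`.
#' @export
expected_spurious <- function(m, n) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != as.integer(m))
    stop("`m` must be a non-negative integer", call. = FALSE)
  m * spurious_probability(n)
}

#' Smallest sample size keeping expected spurious linkage below a threshold
#'
#' Returns the smallest integer `n` with `m * 0.5^n < max_expected`
#' (strict inequality).
#'
#' @inheritParams expected_spurious
#' @param max_expected threshold on the expected spurious count (default 1).
#' @return integer sample size.
#' @export
min_sample_size <- function(m, max_expected = 1.0) {
  stopifnot(m >= 1, max_expected > 0)
  n <- max(1L, as.integer(ceiling(log2(m / max_expected))))
  while (expected_spurious(m, n) >= max_expected) n <- n + 1L
  # guard against ceiling overshoot at exact powers of two
  while (n > 1L && expected_spurious(m, n - 1L) < max_expected) n <- n - 1L
  n
}

# ---- linkage report ----------------------------------------------------------

#' Assemble a linkage report
#'
#' Combines the SNP and PA scans, the moderate-locus list and the spurious
#' estimates into a single report object.
#'
#' @param snp_scan output of [scan_snp()].
#' @param pa_scan output of [scan_pa()] (optional).
#' @param moderate character vector of moderately sex-linked locus ids
#'   (under the inferred system).
#' @param m_snp,m_pa numbers of quality loci screened (for the spurious
#'   estimates); default taken from the scans.
#' @return a list of class `linkage_report` with fields `inferred_system`,
#'   `perfect_snp_loci`, `moderate_snp_loci`, `pa_linked_loci`, `scores`
#'   (SNP and PA score tables), and `spurious` (per marker class).
#' @export
linkage_report <- function(snp_scan, pa_scan = NULL, moderate = character(),
                           m_snp = NULL, m_pa = NULL) {
  stopifnot(inherits(snp_scan, "snp_scan"))
  pa_linked <- if (is.null(pa_scan)) list(XY = character(), ZW = character())
  else pa_scan$linked
  system <- infer_system(length(snp_scan$perfect$XY), length(snp_scan$perfect$ZW),
                         length(pa_linked$XY), length(pa_linked$ZW))
  n <- snp_scan$n_male + snp_scan$n_female
  if (is.null(m_snp)) m_snp <- nrow(snp_scan$scores) / 2L
  if (is.null(m_pa)) m_pa <- if (is.null(pa_scan)) 0L else nrow(pa_scan$scores) / 2L
  spurious <- list(
    snp = list(n = n, m = m_snp, p_per_locus = spurious_probability(n),
               expected_spurious = expected_spurious(m_snp, n)),
    pa = list(n = n, m = m_pa, p_per_locus = spurious_probability(n),
              expected_spurious = expected_spurious(m_pa, n)))
  perfect <- if (system == "ZW") snp_scan$perfect$ZW else snp_scan$perfect$XY
  pa_loci <- if (system == "ZW") pa_linked$ZW else pa_linked$XY
  moderate <- setdiff(moderate, perfect)
  structure(list(inferred_system = system,
                 perfect_snp_loci = perfect,
                 moderate_snp_loci = moderate,
                 pa_linked_loci = pa_loci,
                 perfect_by_system = snp_scan$perfect,
                 pa_by_system = pa_linked,
                 scores = list(snp = snp_scan$scores,
                               pa = if (is.null(pa_scan)) NULL else pa_scan$scores),
                 spurious = spurious),
            class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("linkage_report\n")
  cat("  inferred system:", x$inferred_system, "\n")
  cat("  perfect SNP loci:", length(x$perfect_snp_loci),
      " moderate SNP loci:", length(x$moderate_snp_loci),
      " PA-linked loci:", length(x$pa_linked_loci), "\n")
  cat(sprintf("  expected spurious: SNP %.3g (m=%d, n=%d), PA %.3g (m=%d, n=%d)\n",
              x$spurious$snp$expected_spurious, x$spurious$snp$m, x$spurious$snp$n,
              x$spurious$pa$expected_spurious, x$spurious$pa$m, x$spurious$pa$n))
  invisible(x)
}

#' Write a linkage report as TSV plus a key-value summary
#'
#' The per-locus table has one row per (locus, system) with the proportions,
#' score and assigned class; the summary file holds the marker counts,
#' inferred system and spurious estimates as `key<TAB>value` lines.
#'
#' @param report a [linkage_report()].
#' @param scores_path path for the per-locus TSV.
#' @param summary_path path for the key-value summary.
#' @return invisibly, the two paths.
#' @export
write_linkage_report <- function(report, scores_path, summary_path) {
  stopifnot(inherits(report, "linkage_report"))
  snp <- report$scores$snp
  cls <- rep("unlinked", nrow(snp))
  cls[snp$locus_id %in% report$perfect_snp_loci &
        snp$system == report$inferred_system] <- "perfect"
  cls[snp$locus_id %in% report$moderate_snp_loci &
        snp$system == report$inferred_system] <- "moderate"
  snp$class <- cls
  snp$marker_type <- "SNP"
  out <- snp[, c("locus_id", "marker_type", "system", "prop_het_heterogametic",
                 "prop_homref_homogametic", "score", "class")]
  if (!is.null(report$scores$pa)) {
    pa <- report$scores$pa
    pa$class <- ifelse(pa$locus_id %in% report$pa_linked_loci &
                         pa$system == report$inferred_system, "pa_linked", "unlinked")
    pa_out <- data.frame(locus_id = pa$locus_id, marker_type = "PA",
                         system = pa$system,
                         prop_het_heterogametic = pa$prop_present_heterogametic,
                         prop_homref_homogametic = pa$prop_absent_homogametic,
                         score = pa$prop_present_heterogametic +
                           pa$prop_absent_homogametic,
                         class = pa$class, stringsAsFactors = FALSE)
    out <- rbind(out, pa_out)
  }
  utils::write.table(out, scores_path, sep = "\t", row.names = FALSE, quote = FALSE)
  kv <- c(inferred_system = report$inferred_system,
          n_perfect_snp = length(report$perfect_snp_loci),
          n_moderate_snp = length(report$moderate_snp_loci),
          n_pa_linked = length(report$pa_linked_loci),
          n_sexed = report$spurious$snp$n,
          m_snp = report$spurious$snp$m,
          m_pa = report$spurious$pa$m,
          p_spurious_per_locus = format(report$spurious$snp$p_per_locus, digits = 6),
          expected_spurious_snp = format(report$spurious$snp$expected_spurious,
                                         digits = 6),
          expected_spurious_pa = format(report$spurious$pa$expected_spurious,
                                        digits = 6))
  writeLines(paste(names(kv), unname(kv), sep = "\t"), summary_path)
  invisible(c(scores_path, summary_path))
}
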