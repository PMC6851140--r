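# Genotypic sexing from the discovered sex-linked markers. Under XY, a
# heterozygous SNP call or a present PA fragment is evidence of maleness; a
# homozygous-reference SNP call or an absent fragment is evidence of
# femaleness (mirrored under ZW). SNP and PA votes are pooled with equal
# weight. A homozygous-alternate call at a perfectly sex-linked locus is
# impossible under the clean model, so it counts as an informative vote for
# neither sex and lowers concordance rather than being silently dropped.

#' Genotypically sex individuals from sex-linked markers
#'
#' @param snp a [snp_matrix()] (may be `NULL` if only PA markers are used).
#' @param pa a [pa_matrix()] (may be `NULL`).
#' @param perfect_snp_loci,pa_linked_loci locus ids of the discovered
#'   sex-linked markers; jointly non-empty.
#' @param system `"XY"` or `"ZW"`.
#' @param samples sample ids to sex (default: all samples present in either
#'   matrix). A sample absent from both matrices is an error.
#' @param unanimity minimum fraction of informative votes that must agree
#'   for a call (default 1.0, i.e. perfect conformity); below it the call is
#'   `AMBIGUOUS`.
#' @return data frame of class `sex_calls`: `sample_id`, `genotypic_sex`
#'   (`M`/`F`/`AMBIGUOUS`), `n_informative`, `votes_m`, `votes_f`,
#'   `concordance` (winning-vote fraction of informative markers).
#' @export
assign_sex <- function(snp = NULL, pa = NULL,
                       perfect_snp_loci = character(),
                       pa_linked_loci = character(),
                       system = c("XY", "ZW"), samples = NULL,
                       unanimity = 1.0) {
  system <- match.arg(system)
  stopifnot(unanimity >= 0, unanimity <= 1)
  if (length(perfect_snp_loci) + length(pa_linked_loci) == 0L)
    stop("no sex-linked loci supplied", call. = FALSE)
  known <- unique(c(if (!is.null(snp)) sample_ids(snp),
                    if (!is.null(pa)) sample_ids(pa)))
  if (is.null(samples)) samples <- known
  missing <- setdiff(samples, known)
  if (length(missing))
    stop("sample(s) absent from both matrices: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)

  het_is_male <- system == "XY"
  votes_m <- votes_f <- votes_neither <- stats::setNames(integer(length(samples)),
                                                         samples)
  tally <- function(calls, male_call, female_call) {
    present <- intersect(samples, colnames(calls))
    vm <- colSums(calls[, present, drop = FALSE] == male_call)
    vf <- colSums(calls[, present, drop = FALSE] == female_call)
    vn <- colSums(calls[, present, drop = FALSE] != "NULL_CALL") - vm - vf
    votes_m[present] <<- votes_m[present] + vm
    votes_f[present] <<- votes_f[present] + vf
    votes_neither[present] <<- votes_neither[present] + vn
  }
  if (!is.null(snp) && length(perfect_snp_loci)) {
    calls <- subset_loci(snp, loci = perfect_snp_loci)$calls
    if (het_is_male) tally(calls, "HET", "HOM_REF") else tally(calls, "HOM_REF", "HET")
  }
  if (!is.null(pa) && length(pa_linked_loci)) {
    calls <- subset_loci(pa, loci = pa_linked_loci)$calls
    if (het_is_male) tally(calls, "PRESENT", "ABSENT") else tally(calls, "ABSENT", "PRESENT")
  }
  n_informative <- votes_m + votes_f + votes_neither
  top <- pmax(votes_m, votes_f)
  concordance <- ifelse(n_informative > 0L, top / n_informative, 0)
  sex <- ifelse(n_informative == 0L | concordance < unanimity | votes_m == votes_f,
                "AMBIGUOUS", ifelse(votes_m > votes_f, "M", "F"))
  out <- data.frame(sample_id = samples,
                    genotypic_sex = unname(sex),
                    n_informative = as.integer(unname(n_informative)),
                    votes_m = as.integer(unname(votes_m)),
                    votes_f = as.integer(unname(votes_f)),
                    concordance = unname(concordance),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sex_calls", "data.frame")
  out
}

#' Flag phenotype-genotype sex discordance
#'
#' A call is discordant (putative sex reversal or field mis-sexing) when the
#' phenotypic sex is a confident `M` or `F`, the genotypic call is `M` or
#' `F`, and the two differ. Unknown phenotypes are never discordant.
#'
#' @param calls output of [assign_sex()].
#' @param registry a [sex_registry()] covering the called samples.
#' @return `calls` with added columns `phenotypic_sex` and
#'   `discordant_with_phenotype`.
#' @export
flag_discordance <- function(calls, registry) {
  stopifnot(inherits(calls, "sex_calls"))
  pheno <- registry_sex(registry, calls$sample_id)
  calls$phenotypic_sex <- unname(pheno)
  calls$discordant_with_phenotype <- pheno %in% c("M", "F") &
    calls$genotypic_sex %in% c("M", "F") & pheno != calls$genotypic_sex
  calls
}

#' Augment a sex registry with genotypic assignments
#'
#' Replaces the sex of `U`-phenotype samples with their unambiguous
#' genotypic call, leaving confident phenotypes untouched. Used before the
#' moderate-locus scan so initially unsexed individuals contribute to the
#' per-sex proportions.
#'
#' @param registry a [sex_registry()].
#' @param calls output of [assign_sex()].
#' @return a new `sex_registry`.
#' @export
augment_registry <- function(registry, calls) {
  stopifnot(inherits(registry, "sex_registry"))
  sex <- registry$sex
  idx <- match(registry$sample_id, calls$sample_id)
  geno <- calls$genotypic_sex[idx]
  replace_it <- sex == "U" & !is.na(geno) & geno %in% c("M", "F")
  sex[replace_it] <- geno[replace_it]
  sex_registry(registry$sample_id, sex, registry$site)
}

#' Population sex ratio after genotypic sexing
#'
#' Proportion of males among all samples, counting confident phenotypic
#' males plus genotypic males among the initially unknown individuals.
#'
#' @param registry the phenotypic [sex_registry()].
#' @param calls output of [assign_sex()] covering at least the `U` samples.
#' @return fraction of males in \[0, 1\] (samples still ambiguous after
#'   genotyping count in the denominator only).
#' @export
sex_ratio <- function(registry, calls) {
  stopifnot(inherits(registry, "sex_registry"))
  aug <- augment_registry(registry, calls)
  mean(aug$sex == "M")
}

#' Write sex calls as TSV
#'
#' @param calls output of [flag_discordance()] (or [assign_sex()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sex_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
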