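# Quality filtering on the provider-reported per-locus metadata. Filtering
# deliberately uses the metadata columns, not recomputed non-null fractions:
# the upstream call rate is computed over technical context (replicates, all
# samples) that the downstream matrix no longer carries.

#' Quality-filter thresholds
#'
#' Defaults encode a stringent marker-quality policy for sex-linkage work:
#' SNP loci must have perfect call rate and reproducibility; dominant
#' presence/absence loci, which typically score at a somewhat lower call
#' rate, must have call rate of at least 0.90 and perfect reproducibility.
#'
#' @param snp_min_call_rate minimum SNP call rate (default 1.0).
#' @param snp_min_reproducibility minimum SNP reproducibility (default 1.0).
#' @param pa_min_call_rate minimum PA call rate (default 0.90).
#' @param pa_min_reproducibility minimum PA reproducibility (default 1.0).
#' @param pa_call_rate_strict if `TRUE`, the PA call-rate comparison is
#'   strict (`>`) instead of inclusive (`>=`). Default `FALSE`: the inclusive
#'   reading retains loci scored exactly at the threshold.
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(snp_min_call_rate = 1.0,
                              snp_min_reproducibility = 1.0,
                              pa_min_call_rate = 0.90,
                              pa_min_reproducibility = 1.0,
                              pa_call_rate_strict = FALSE) {
  vals <- c(snp_min_call_rate, snp_min_reproducibility,
            pa_min_call_rate, pa_min_reproducibility)
  if (any(!is.finite(vals) | vals < 0 | vals > 1))
    stop("all thresholds must lie in [0, 1]", call. = FALSE)
  structure(list(snp_min_call_rate = snp_min_call_rate,
                 snp_min_reproducibility = snp_min_reproducibility,
                 pa_min_call_rate = pa_min_call_rate,
                 pa_min_reproducibility = pa_min_reproducibility,
                 pa_call_rate_strict = isTRUE(pa_call_rate_strict)),
            class = "filter_thresholds")
}

.apply_filter <- function(x, keep, stage) {
  kept <- subset_loci(x, loci = locus_ids(x)[keep])
  attr(kept, "filter_report") <- data.frame(
    stage = stage, input_loci = length(keep), retained_loci = sum(keep),
    stringsAsFactors = FALSE)
  kept
}

#' Filter SNP loci on call rate and reproducibility
#'
#' Keeps loci with `call_rate >= snp_min_call_rate` and
#' `reproducibility >= snp_min_reproducibility`; the sample set and locus
#' order are unchanged. The retained/dropped counts are attached as the
#' `"filter_report"` attribute (a one-row data frame).
#'
#' @param x a [snp_matrix()].
#' @param thresholds a [filter_thresholds()].
#' @return the filtered `snp_matrix` (possibly with zero loci).
#' @export
filter_snp <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "snp_matrix"), inherits(thresholds, "filter_thresholds"))
  keep <- x$meta$call_rate >= thresholds$snp_min_call_rate &
    x$meta$reproducibility >= thresholds$snp_min_reproducibility
  .apply_filter(x, keep, "snp")
}

#' Filter presence/absence loci on call rate and reproducibility
#'
#' As [filter_snp()] with the PA thresholds; the call-rate comparison is
#' inclusive by default and strict when `pa_call_rate_strict` is set.
#'
#' @param x a [pa_matrix()].
#' @param thresholds a [filter_thresholds()].
#' @return the filtered `pa_matrix`.
#' @export
filter_pa <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "pa_matrix"), inherits(thresholds, "filter_thresholds"))
  cr_ok <- if (thresholds$pa_call_rate_strict)
    x$meta$call_rate > thresholds$pa_min_call_rate
  else
    x$meta$call_rate >= thresholds$pa_min_call_rate
  keep <- cr_ok & x$meta$reproducibility >= thresholds$pa_min_reproducibility
  .apply_filter(x, keep, "pa")
}

#' Write a filter report
#'
#' Writes the `"filter_report"` attributes of one or more filtered matrices
#' as a TSV with columns `stage`, `input_loci`, `retained_loci`.
#'
#' @param ... filtered matrices (outputs of [filter_snp()] / [filter_pa()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(..., path) {
  reports <- lapply(list(...), attr, "filter_report")
  if (any(vapply(reports, is.null, logical(1L))))
    stop("all inputs must carry a filter_report attribute", call. = FALSE)
  utils::write.table(do.call(rbind, reports), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
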