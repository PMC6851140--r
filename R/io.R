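# Canonical on-disk dialect for the pipeline: comma-separated UTF-8 tables with
# one header row, locus metadata columns first, then one column per sample.
# This replaces the proprietary multi-header DArT exports; calls are categorical
# tokens ("0"/"1"/"2"/"-" for SNPs, "1"/"0"/"-" for presence/absence), never
# numeric counts.

#' Call categories
#'
#' Valid call categories for SNP and presence/absence (PA) matrices.
#' SNP calls are `HOM_REF` (homozygous for the reference allele), `HOM_ALT`
#' (homozygous for the alternate, SNP-containing allele), `HET` (heterozygous)
#' and `NULL_CALL` (a null allele: the fragment was not confidently scored).
#' PA calls are `PRESENT`, `ABSENT` and `NULL_CALL` (non-zero counts too low
#' to score as present).
#'
#' @name call-categories
#' @keywords internal
NULL

SNP_CALLS <- c("HOM_REF", "HOM_ALT", "HET", "NULL_CALL")
PA_CALLS  <- c("PRESENT", "ABSENT", "NULL_CALL")
SEX_CODES <- c("M", "F", "U")

.snp_token_map <- c("0" = "HOM_REF", "1" = "HOM_ALT", "2" = "HET", "-" = "NULL_CALL")
.pa_token_map  <- c("1" = "PRESENT", "0" = "ABSENT", "-" = "NULL_CALL")

#' Construct a SNP call matrix
#'
#' A `snp_matrix` holds one row per locus and one column per sample of
#' categorical SNP calls, plus per-locus metadata (reference/alternate allele
#' sequences and the genotyping provider's call rate and reproducibility).
#'
#' @param calls character matrix (loci x samples) with entries in
#'   `c("HOM_REF","HOM_ALT","HET","NULL_CALL")`; dimnames give locus and
#'   sample ids.
#' @param meta data frame with columns `locus_id`, `ref_seq`, `alt_seq`,
#'   `call_rate`, `reproducibility`, one row per locus in matrix order.
#'   Sequences may be empty strings; call rate and reproducibility must lie
#'   in \[0, 1\]. These are upstream metadata: the stored call rate need not
#'   equal the recomputed non-null fraction.
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, meta) {
  .validate_matrix(calls, meta, SNP_CALLS,
                   c("locus_id", "ref_seq", "alt_seq", "call_rate", "reproducibility"))
  structure(list(calls = calls, meta = meta), class = "snp_matrix")
}

#' Construct a presence/absence call matrix
#'
#' A `pa_matrix` holds dominant (SilicoDArT-style) restriction-fragment
#' presence/absence calls, one row per locus, one column per sample.
#'
#' @param calls character matrix (loci x samples) with entries in
#'   `c("PRESENT","ABSENT","NULL_CALL")`.
#' @param meta data frame with columns `locus_id`, `sequence`, `call_rate`,
#'   `reproducibility`.
#' @return an object of class `pa_matrix`.
#' @export
pa_matrix <- function(calls, meta) {
  .validate_matrix(calls, meta, PA_CALLS,
                   c("locus_id", "sequence", "call_rate", "reproducibility"))
  structure(list(calls = calls, meta = meta), class = "pa_matrix")
}

.validate_matrix <- function(calls, meta, valid_calls, meta_cols) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix", call. = FALSE)
  if (!is.data.frame(meta)) stop("`meta` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(meta_cols, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != nrow(calls))
    stop("metadata rows (", nrow(meta), ") do not match call matrix loci (",
         nrow(calls), ")", call. = FALSE)
  if ((is.null(rownames(calls)) && nrow(calls) > 0L) || is.null(colnames(calls)))
    stop("`calls` must carry locus ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(calls)))
    stop("duplicate locus id: ",
         rownames(calls)[duplicated(rownames(calls))][1L], call. = FALSE)
  if (anyDuplicated(colnames(calls)))
    stop("duplicate sample id: ",
         colnames(calls)[duplicated(colnames(calls))][1L], call. = FALSE)
  if (nrow(calls) > 0L &&
      !identical(as.character(meta$locus_id), rownames(calls)))
    stop("metadata locus ids must equal call-matrix rownames, in order",
         call. = FALSE)
  bad <- matrix(!(calls %in% valid_calls), nrow = nrow(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid call '", calls[idx[1L], idx[2L]], "' at locus '",
         rownames(calls)[idx[1L]], "', sample '", colnames(calls)[idx[2L]], "'",
         call. = FALSE)
  }
  for (col in intersect(c("call_rate", "reproducibility"), meta_cols)) {
    v <- meta[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1))
      stop("metadata column `", col, "` must be numeric in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", nrow(x$calls), "loci x", ncol(x$calls), "samples\n")
  tab <- table(factor(x$calls, levels = SNP_CALLS))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("pa_matrix:", nrow(x$calls), "loci x", ncol(x$calls), "samples\n")
  tab <- table(factor(x$calls, levels = PA_CALLS))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$calls)
#' @export
dim.pa_matrix <- function(x) dim(x$calls)

#' Sample and locus ids
#'
#' @param x a `snp_matrix` or `pa_matrix`.
#' @return character vector of ids.
#' @export
sample_ids <- function(x) colnames(x$calls)

#' @rdname sample_ids
#' @export
locus_ids <- function(x) rownames(x$calls)

#' Subset a call matrix by locus and/or sample
#'
#' Order of `loci`/`samples` is preserved in the result.
#'
#' @param x a `snp_matrix` or `pa_matrix`.
#' @param loci character vector of locus ids (default: all).
#' @param samples character vector of sample ids (default: all).
#' @return an object of the same class as `x`.
#' @export
subset_loci <- function(x, loci = locus_ids(x), samples = sample_ids(x)) {
  missing_l <- setdiff(loci, locus_ids(x))
  if (length(missing_l))
    stop("unknown locus id(s): ", paste(utils::head(missing_l, 3L), collapse = ", "),
         call. = FALSE)
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s))
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 3L), collapse = ", "),
         call. = FALSE)
  calls <- x$calls[loci, samples, drop = FALSE]
  meta <- x$meta[match(loci, x$meta$locus_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (inherits(x, "snp_matrix")) snp_matrix(calls, meta) else pa_matrix(calls, meta)
}

#' Construct a sex registry
#'
#' Maps each sample id to a phenotypic sex code (`M`ale, `F`emale or
#' `U`nknown, for individuals whose morphological sexing was inconclusive)
#' and an optional sampling-site label.
#'
#' @param sample_id character vector of unique sample ids.
#' @param sex character vector of codes in `c("M","F","U")`
#'   (case-insensitive; normalised to upper case).
#' @param site optional character vector of site labels (`NA` permitted).
#' @return a data frame of class `sex_registry` with columns
#'   `sample_id`, `sex`, `site`.
#' @export
sex_registry <- function(sample_id, sex, site = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1L],
         call. = FALSE)
  sex <- toupper(trimws(as.character(sex)))
  bad <- !(sex %in% SEX_CODES)
  if (any(bad))
    stop("unknown sex code '", sex[bad][1L], "' for sample '",
         sample_id[bad][1L], "' (expected M, F or U)", call. = FALSE)
  out <- data.frame(sample_id = sample_id, sex = sex,
                    site = rep_len(as.character(site), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_registry", "data.frame")
  out
}

#' Look up sexes for a set of samples
#'
#' @param registry a `sex_registry`.
#' @param samples character vector of sample ids; every id must be registered.
#' @return named character vector of sex codes.
#' @export
registry_sex <- function(registry, samples) {
  idx <- match(samples, registry$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from sex registry: ",
         paste(utils::head(samples[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  stats::setNames(registry$sex[idx], samples)
}

# ---- readers -----------------------------------------------------------------

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, header = TRUE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
}

.parse_calls <- function(df, meta_cols, token_map, path) {
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols))
    stop("'", path, "' is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols)) stop("'", path, "' contains no sample columns", call. = FALSE)
  tokens <- trimws(as.matrix(df[, sample_cols, drop = FALSE]))
  calls <- matrix(unname(token_map[tokens]), nrow = nrow(df),
                  dimnames = list(trimws(df$locus_id), sample_cols))
  if (anyNA(calls)) {
    idx <- which(is.na(calls), arr.ind = TRUE)[1L, ]
    stop("unknown call token '", tokens[idx[1L], idx[2L]], "' at locus '",
         rownames(calls)[idx[1L]], "', sample '", colnames(calls)[idx[2L]],
         "' in '", path, "'", call. = FALSE)
  }
  calls
}

#' Read a SNP genotype table
#'
#' Reads the pipeline's comma-separated SNP dialect: one header row with the
#' metadata columns `locus_id,ref_seq,alt_seq,call_rate,reproducibility`
#' followed by one column per sample. Cell tokens are `"0"` (homozygous
#' reference), `"1"` (homozygous alternate), `"2"` (heterozygous) and `"-"`
#' (null allele). Row and column order is preserved.
#'
#' @param path path to a CSV file.
#' @return a [snp_matrix()].
#' @export
read_snp_table <- function(path) {
  df <- .read_table(path)
  meta_cols <- c("locus_id", "ref_seq", "alt_seq", "call_rate", "reproducibility")
  calls <- .parse_calls(df, meta_cols, .snp_token_map, path)
  meta <- data.frame(locus_id = rownames(calls),
                     ref_seq = trimws(df$ref_seq),
                     alt_seq = trimws(df$alt_seq),
                     call_rate = as.numeric(df$call_rate),
                     reproducibility = as.numeric(df$reproducibility),
                     stringsAsFactors = FALSE)
  snp_matrix(calls, meta)
}

#' Read a presence/absence (SilicoDArT-style) table
#'
#' Same dialect as [read_snp_table()] with metadata columns
#' `locus_id,sequence,call_rate,reproducibility` and tokens `"1"` (fragment
#' present), `"0"` (absent), `"-"` (null).
#'
#' @param path path to a CSV file.
#' @return a [pa_matrix()].
#' @export
read_pa_table <- function(path) {
  df <- .read_table(path)
  meta_cols <- c("locus_id", "sequence", "call_rate", "reproducibility")
  calls <- .parse_calls(df, meta_cols, .pa_token_map, path)
  meta <- data.frame(locus_id = rownames(calls),
                     sequence = trimws(df$sequence),
                     call_rate = as.numeric(df$call_rate),
                     reproducibility = as.numeric(df$reproducibility),
                     stringsAsFactors = FALSE)
  pa_matrix(calls, meta)
}

#' Read a sex registry file
#'
#' Two- or three-column CSV (`sample_id,sex[,site]`); sex tokens are
#' case-insensitive `M`, `F` or `U`.
#'
#' @param path path to a CSV file.
#' @return a [sex_registry()].
#' @export
read_sex_registry <- function(path) {
  df <- .read_table(path)
  if (!all(c("sample_id", "sex") %in% names(df)))
    stop("'", path, "' must have columns sample_id, sex[, site]", call. = FALSE)
  sex <- toupper(trimws(df$sex))
  bad <- !(sex %in% SEX_CODES)
  if (any(bad))
    stop("unknown sex token '", df$sex[bad][1L], "' at row ", which(bad)[1L],
         " (sample '", df$sample_id[bad][1L], "') in '", path, "'", call. = FALSE)
  sex_registry(trimws(df$sample_id), sex,
               if ("site" %in% names(df)) trimws(df$site) else NA_character_)
}

# ---- writers -----------------------------------------------------------------

.write_calls <- function(x, meta_df, token_map, path) {
  rev_map <- stats::setNames(names(token_map), token_map)
  tokens <- matrix(rev_map[x$calls], nrow = nrow(x$calls),
                   dimnames = dimnames(x$calls))
  out <- cbind(meta_df, as.data.frame(tokens, stringsAsFactors = FALSE,
                                      check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write SNP / PA tables
#'
#' Writes the canonical dialect read by [read_snp_table()] /
#' [read_pa_table()]; writing then re-reading yields an identical matrix.
#'
#' @param x a `snp_matrix` or `pa_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(x, path) {
  stopifnot(inherits(x, "snp_matrix"))
  .write_calls(x, x$meta, .snp_token_map, path)
}

#' @rdname write_snp_table
#' @export
write_pa_table <- function(x, path) {
  stopifnot(inherits(x, "pa_matrix"))
  .write_calls(x, x$meta, .pa_token_map, path)
}

#' Write a sex registry
#'
#' @param registry a `sex_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sex_registry <- function(registry, path) {
  stopifnot(inherits(registry, "sex_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
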