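# Population-structure support statistics. Allele frequencies come straight
# from genotype counts: at a biallelic locus the reference-allele frequency
# of a group is (2 * n_HOM_REF + n_HET) / (2 * n_called); for a single
# individual this is 1 (HOM_REF), 0.5 (HET) or 0 (HOM_ALT).

.ref_allele_freq <- function(calls) {
  # calls: loci x samples character matrix; returns per-locus freq and call count
  n_rr <- rowSums(calls == "HOM_REF")
  n_het <- rowSums(calls == "HET")
  n_aa <- rowSums(calls == "HOM_ALT")
  called <- n_rr + n_het + n_aa
  list(p = ifelse(called > 0L, (2 * n_rr + n_het) / (2 * called), NA_real_),
       called = called)
}

#' Pairwise and overall F_ST between sampling sites
#'
#' Nei-style G_ST on expected heterozygosities: for each locus,
#' `H_S` is the unweighted mean within-site expected heterozygosity
#' `2p(1-p)` and `H_T` the expected heterozygosity of the mean site allele
#' frequency; `F_ST = sum(H_T - H_S) / sum(H_T)` across loci
#' (ratio of averages). Loci monomorphic across the compared sites are
#' skipped; no small-sample correction is applied, so the values are
#' descriptive rather than estimator-grade.
#'
#' @param x a [snp_matrix()].
#' @param sites named character vector (or factor) of site labels, names
#'   being sample ids covering all samples of `x`.
#' @return a list of class `fst_result`: `pairwise` (symmetric site x site
#'   matrix, zero diagonal), `overall` (single F_ST over all sites),
#'   `n_loci` (loci used in the overall estimate).
#' @export
pairwise_fst <- function(x, sites) {
  stopifnot(inherits(x, "snp_matrix"))
  sites <- stats::setNames(as.character(sites), names(sites))
  if (is.null(names(sites))) stop("`sites` must be named by sample id", call. = FALSE)
  missing <- setdiff(sample_ids(x), names(sites))
  if (length(missing))
    stop("site label missing for sample(s): ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  sites <- sites[sample_ids(x)]
  levels <- unique(sites)
  if (length(levels) < 2L) stop("need at least two sites", call. = FALSE)
  site_freq <- vapply(levels, function(s)
    .ref_allele_freq(x$calls[, sites == s, drop = FALSE])$p,
    numeric(nrow(x$calls)))
  if (nrow(x$calls) == 1L) site_freq <- matrix(site_freq, nrow = 1L,
                                               dimnames = list(NULL, levels))
  gst <- function(freq_subset) {
    # freq_subset: loci x groups matrix of reference-allele frequencies
    ok <- rowSums(is.na(freq_subset)) == 0L
    freq <- freq_subset[ok, , drop = FALSE]
    p_bar <- rowMeans(freq)
    poly <- p_bar > 0 & p_bar < 1
    freq <- freq[poly, , drop = FALSE]
    p_bar <- p_bar[poly]
    if (!length(p_bar)) return(list(fst = NA_real_, n_loci = 0L))
    h_t <- 2 * p_bar * (1 - p_bar)
    h_s <- rowMeans(2 * freq * (1 - freq))
    list(fst = sum(h_t - h_s) / sum(h_t), n_loci = length(p_bar))
  }
  k <- length(levels)
  pw <- matrix(0, k, k, dimnames = list(levels, levels))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    g <- gst(site_freq[, c(i, j), drop = FALSE])
    pw[i, j] <- pw[j, i] <- g$fst
  }
  overall <- gst(site_freq)
  if (is.na(overall$fst))
    stop("F_ST undefined: all loci monomorphic", call. = FALSE)
  structure(list(pairwise = pw, overall = overall$fst, n_loci = overall$n_loci),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result: overall F_ST = %.4g over %d loci\n",
              x$overall, x$n_loci))
  print(round(x$pairwise, 4))
  invisible(x)
}

#' Nei genetic distance between individuals
#'
#' For individuals x and y with per-locus allele frequencies (from single
#' genotypes: 1/0.5/0 for the reference allele), the identity terms
#' `J_xy = sum over loci and alleles of x_a * y_a`, `J_x = sum x_a^2`,
#' `J_y = sum y_a^2` are accumulated across loci before the ratio, and
#' `D = -ln(J_xy / sqrt(J_x * J_y))`. Aggregating before the log keeps the
#' distance finite when single loci carry opposite homozygotes. Loci where
#' either individual has a null call are dropped pairwise.
#'
#' @param x a [snp_matrix()].
#' @param loci locus ids to use (non-empty).
#' @param individuals sample ids (default: all).
#' @param sentinel distance reported, with a warning, for pairs with
#'   `J_xy = 0` (opposite homozygotes at every shared locus) or with no
#'   shared called locus (default 50).
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(x, loci = locus_ids(x), individuals = sample_ids(x),
                         sentinel = 50) {
  stopifnot(inherits(x, "snp_matrix"), length(loci) >= 1L)
  calls <- subset_loci(x, loci = loci, samples = individuals)$calls
  # per (locus, individual) reference-allele frequency; NA at null calls
  p <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  p[calls == "HOM_REF"] <- 1
  p[calls == "HET"] <- 0.5
  p[calls == "HOM_ALT"] <- 0
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  degenerate <- FALSE
  for (i in seq_len(n)) {
    pi <- p[, i]
    for (j in seq_len(n)) {
      if (j <= i) next
      pj <- p[, j]
      ok <- !is.na(pi) & !is.na(pj)
      if (!any(ok)) { d[i, j] <- d[j, i] <- sentinel; degenerate <- TRUE; next }
      a <- pi[ok]; b <- pj[ok]
      j_xy <- sum(a * b + (1 - a) * (1 - b))
      j_x <- sum(a^2 + (1 - a)^2)
      j_y <- sum(b^2 + (1 - b)^2)
      if (j_xy == 0) { d[i, j] <- d[j, i] <- sentinel; degenerate <- TRUE; next }
      d[i, j] <- d[j, i] <- -log(j_xy / sqrt(j_x * j_y))
    }
  }
  if (degenerate)
    warning("some pairs had zero genetic identity or no shared called locus; ",
            "sentinel distance ", sentinel, " reported", call. = FALSE)
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2` with the centering projector, eigendecomposes,
#' and scales the eigenvectors by the square root of their (nonnegative)
#' eigenvalues. Negative eigenvalues — arising when the distances are not
#' Euclidean-embeddable — are dropped, and their magnitude is excluded from
#' the reported variance proportions. Axis signs follow a fixed convention
#' (the coordinate of largest magnitude on each axis is positive) so results
#' are reproducible across platforms.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of axes requested (default 2); truncated with a warning
#'   if fewer positive eigenvalues exist.
#' @return a list of class `pcoa_result`: `points` (n x k coordinates,
#'   column-centered), `eig` (positive eigenvalues, decreasing),
#'   `prop_var` (share of the positive-eigenvalue total per returned axis).
#' @export
pcoa <- function(d, k = 2L) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), k >= 1L)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) + mean(a)
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > max(e$values[1L], 0) * 1e-12 & e$values > 0
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("no positive eigenvalue; degenerate distances",
                        call. = FALSE)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " axes", call. = FALSE)
    k <- n_pos
  }
  values <- e$values[pos][seq_len(k)]
  vectors <- e$vectors[, pos, drop = FALSE][, seq_len(k), drop = FALSE]
  pts <- sweep(vectors, 2L, sqrt(values), `*`)
  # fixed sign convention: largest-magnitude coordinate positive
  for (a in seq_len(k)) {
    m <- which.max(abs(pts[, a]))
    if (pts[m, a] < 0) pts[, a] <- -pts[, a]
  }
  dimnames(pts) <- list(rownames(d), paste0("axis", seq_len(k)))
  structure(list(points = pts, eig = e$values[pos],
                 prop_var = values / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$points), "points,", ncol(x$points), "axes;",
      "variance:", paste(sprintf("%.1f%%", 100 * x$prop_var), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a distance matrix as square TSV
#'
#' @param d symmetric matrix with ids as dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(id = rownames(d), as.data.frame(d, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write PCoA coordinates and eigenvalues
#'
#' @param p a [pcoa()] result.
#' @param coords_path TSV path for coordinates (`sample_id`, `axis1..k`).
#' @param eigen_path TSV path for eigenvalues and variance proportions.
#' @return invisibly, the two paths.
#' @export
write_pcoa <- function(p, coords_path, eigen_path) {
  stopifnot(inherits(p, "pcoa_result"))
  coords <- data.frame(sample_id = rownames(p$points),
                       as.data.frame(p$points, check.names = FALSE),
                       check.names = FALSE)
  utils::write.table(coords, coords_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ev <- data.frame(axis = seq_along(p$eig), eigenvalue = p$eig,
                   prop_var = c(p$prop_var,
                                rep(NA_real_, length(p$eig) - length(p$prop_var))))
  utils::write.table(ev, eigen_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(coords_path, eigen_path))
}
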