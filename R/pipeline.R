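# End-to-end orchestration: quality filter -> discovery scan under both
# heterogametic hypotheses -> spurious-linkage estimate -> genotypic sexing
# -> genotype-augmented moderate-locus scan -> heterozygosity grouping and
# Welch test -> Nei distances, PCoA and F_ST. Logs go to stderr; data only
# to files, so pipes stay clean.

#' Pipeline run configuration
#'
#' @param snp_path,pa_path,sexes_path input file paths (see
#'   [read_snp_table()], [read_pa_table()], [read_sex_registry()]);
#'   `pa_path` may be `NULL` to run SNP-only.
#' @param out_dir output directory, created if needed.
#' @param thresholds a [filter_thresholds()].
#' @param min_prop PA sex-linkage proportion threshold (default 0.9).
#' @param min_het_prop moderate-locus male heterozygosity floor
#'   (default 0.5).
#' @param unanimity sexing vote threshold (default 1.0).
#' @param group_high,group_low heterozygosity-group thresholds
#'   (defaults 0.85, 0.20).
#' @param plots if `TRUE` and the `pheatmap` package is available, writes a
#'   Nei-distance heat map and a PCoA scatter as PNG files.
#' @return a list of class `run_config`.
#' @export
run_config <- function(snp_path, pa_path = NULL, sexes_path, out_dir,
                       thresholds = filter_thresholds(), min_prop = 0.9,
                       min_het_prop = 0.5, unanimity = 1.0,
                       group_high = 0.85, group_low = 0.20, plots = FALSE) {
  structure(list(snp_path = snp_path, pa_path = pa_path,
                 sexes_path = sexes_path, out_dir = out_dir,
                 thresholds = thresholds, min_prop = min_prop,
                 min_het_prop = min_het_prop, unanimity = unanimity,
                 group_high = group_high, group_low = group_low,
                 plots = isTRUE(plots)),
            class = "run_config")
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("done (%.1fs)", proc.time()[["elapsed"]] - t0))
  out
}

.fmt_num <- function(x) {
  if (is.numeric(x) && length(x) == 1L && is.finite(x) &&
      x == round(x) && abs(x) < 1e15) format(x, scientific = FALSE)
  else format(x, digits = 6)
}

#' Run the full sex-linkage analysis pipeline
#'
#' Reads the inputs, runs every stage and writes all report files plus a
#' top-level `summary.md` / `summary.json` pair into `out_dir`. Every number
#' in the markdown summary is re-derivable from the stage TSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`filtered_snp`, `filtered_pa`, `report`, `sex_calls`, `groups`,
#'   `welch`, `fst`, `nei`, `pcoa`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$snp_path, config$pa_path, config$sexes_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  snp <- .stage("read", read_snp_table(config$snp_path))
  pa <- if (!is.null(config$pa_path)) read_pa_table(config$pa_path) else NULL
  registry <- read_sex_registry(config$sexes_path)

  fsnp <- .stage("filter", filter_snp(snp, config$thresholds))
  fpa <- if (!is.null(pa)) filter_pa(pa, config$thresholds) else NULL
  if (is.null(fpa)) write_filter_report(fsnp, path = out("filter_report.tsv"))
  else write_filter_report(fsnp, fpa, path = out("filter_report.tsv"))

  snp_sc <- .stage("scan", scan_snp(fsnp, registry))
  pa_sc <- if (!is.null(fpa)) scan_pa(fpa, registry, min_prop = config$min_prop)
  else NULL
  system <- infer_system(length(snp_sc$perfect$XY), length(snp_sc$perfect$ZW),
                         if (is.null(pa_sc)) 0L else length(pa_sc$linked$XY),
                         if (is.null(pa_sc)) 0L else length(pa_sc$linked$ZW))

  calls <- NULL
  aug <- registry
  if (system %in% c("XY", "ZW")) {
    perfect <- snp_sc$perfect[[system]]
    pa_loci <- if (is.null(pa_sc)) character() else pa_sc$linked[[system]]
    calls <- .stage("assign-sex",
                    flag_discordance(
                      assign_sex(fsnp, fpa, perfect, pa_loci, system,
                                 unanimity = config$unanimity), registry))
    write_sex_calls(calls, out("sex_calls.tsv"))
    aug <- augment_registry(registry, calls)
  }

  moderate <- if (system %in% c("XY", "ZW"))
    .stage("moderate-scan",
           find_moderate_loci(fsnp, aug, system,
                              min_het_prop = config$min_het_prop,
                              exclude = snp_sc$perfect[[system]]))
  else character()

  report <- linkage_report(snp_sc, pa_sc, moderate)
  write_linkage_report(report, out("linkage_scores.tsv"),
                       out("linkage_summary.txt"))

  groups <- welch <- NULL
  if (length(moderate)) {
    het_sex <- if (system == "ZW") "F" else "M"
    males <- aug$sample_id[aug$sex == het_sex]
    profiles <- .stage("groups",
                       male_het_profiles(fsnp, moderate, males))
    groups <- assign_groups(profiles, high = config$group_high,
                            low = config$group_low)
    utils::write.table(groups$assignments, out("groups.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    g2 <- groups$assignments$het_fraction[groups$assignments$group == "MALES2"]
    g3 <- groups$assignments$het_fraction[groups$assignments$group == "MALES3"]
    if (length(g2) >= 2L && length(g3) >= 2L) {
      welch <- welch_t_from_values(100 * g2, 100 * g3)
      kv <- c(t = welch$t, df = welch$df, df_floor = welch$df_floor,
              p_two_tailed = welch$p_two_tailed,
              n_males2 = length(g2), mean_males2 = mean(100 * g2),
              sd_males2 = stats::sd(100 * g2),
              n_males3 = length(g3), mean_males3 = mean(100 * g3),
              sd_males3 = stats::sd(100 * g3))
      writeLines(paste(names(kv), vapply(kv, .fmt_num, character(1L)),
                       sep = "\t"), out("welch.txt"))
    }
  }

  fst <- nei <- pc <- NULL
  sexlinked <- c(report$perfect_snp_loci, report$moderate_snp_loci)
  if (length(unique(registry$site[!is.na(registry$site)])) >= 2L) {
    sites <- stats::setNames(registry$site, registry$sample_id)
    fst <- .stage("fst", pairwise_fst(fsnp, sites))
    write_distance_matrix(fst$pairwise, out("fst_pairwise.tsv"))
  }
  if (length(sexlinked)) {
    nei <- .stage("nei-distance", nei_distance(fsnp, loci = sexlinked))
    write_distance_matrix(nei, out("nei_distances.tsv"))
    pc <- tryCatch(pcoa(nei, k = 2L), error = function(e) NULL)
    if (!is.null(pc)) write_pcoa(pc, out("pcoa_coords.tsv"),
                                 out("pcoa_eigen.tsv"))
    if (config$plots) .write_plots(nei, pc, registry, config$out_dir)
  }

  summary <- .build_summary(config, fsnp, fpa, report, calls, registry,
                            groups, welch, fst)
  writeLines(summary$md, out("summary.md"))
  jsonlite::write_json(summary$json, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(filtered_snp = fsnp, filtered_pa = fpa, report = report,
                 sex_calls = calls, groups = groups, welch = welch, fst = fst,
                 nei = nei, pcoa = pc, summary = summary))
}

.build_summary <- function(config, fsnp, fpa, report, calls, registry,
                           groups, welch, fst) {
  sp <- report$spurious
  ratio <- if (!is.null(calls)) sex_ratio(registry, calls) else NA_real_
  n_discordant <- if (!is.null(calls)) sum(calls$discordant_with_phenotype)
  else NA_integer_
  json <- list(
    inferred_system = report$inferred_system,
    n_snp_retained = nrow(fsnp$calls),
    n_pa_retained = if (is.null(fpa)) 0L else nrow(fpa$calls),
    n_perfect_snp = length(report$perfect_snp_loci),
    n_moderate_snp = length(report$moderate_snp_loci),
    n_pa_linked = length(report$pa_linked_loci),
    n_sexed = sp$snp$n,
    p_spurious_per_locus = sp$snp$p_per_locus,
    expected_spurious_snp = sp$snp$expected_spurious,
    expected_spurious_pa = sp$pa$expected_spurious,
    sex_ratio_male = ratio,
    n_discordant = n_discordant,
    groups = if (!is.null(groups)) as.list(groups$counts) else NULL,
    welch = if (!is.null(welch))
      list(t = welch$t, df = welch$df, df_floor = welch$df_floor,
           p_two_tailed = welch$p_two_tailed) else NULL,
    fst_overall = if (!is.null(fst)) fst$overall else NULL)
  md <- c(
    "# Sex-linkage analysis summary", "",
    paste0("- Inferred sex-determining system: **", report$inferred_system, "**"),
    paste0("- SNP loci retained after filtering: ", json$n_snp_retained),
    paste0("- PA loci retained after filtering: ", json$n_pa_retained),
    paste0("- Perfectly sex-linked SNP loci: ", json$n_perfect_snp),
    paste0("- Moderately sex-linked SNP loci: ", json$n_moderate_snp),
    paste0("- Sex-linked PA loci: ", json$n_pa_linked),
    paste0("- Confidently sexed individuals: ", json$n_sexed),
    paste0("- Per-locus spurious-linkage probability (0.5^n): ",
           format(json$p_spurious_per_locus, digits = 3)),
    paste0("- Expected spuriously sex-linked loci: SNP ",
           format(json$expected_spurious_snp, digits = 3), ", PA ",
           format(json$expected_spurious_pa, digits = 3)))
  if (!is.na(ratio))
    md <- c(md, paste0("- Sex ratio after genotypic sexing: ",
                       sprintf("%.1f%% male", 100 * ratio)),
            paste0("- Phenotype-genotype discordant individuals: ",
                   n_discordant))
  if (!is.null(groups))
    md <- c(md, paste0("- Heterozygosity groups: ",
                       paste(names(groups$counts), groups$counts,
                             sep = " = ", collapse = ", ")))
  if (!is.null(welch))
    md <- c(md, sprintf(
      "- Welch t-test (high vs low heterozygosity males): t(%d) = %.2f, p = %.3g",
      welch$df_floor, welch$t, welch$p_two_tailed))
  if (!is.null(fst))
    md <- c(md, sprintf("- Overall F_ST across sites: %.4f (max pairwise %.4f)",
                        fst$overall, max(fst$pairwise)))
  list(md = md, json = json)
}

.write_plots <- function(nei, pc, registry, out_dir) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(file.path(out_dir, "nei_heatmap.png"), width = 900,
                   height = 900)
    pheatmap::pheatmap(nei)
    grDevices::dev.off()
  }
  if (!is.null(pc)) {
    grDevices::png(file.path(out_dir, "pcoa.png"), width = 700, height = 700)
    sex <- registry_sex(registry, rownames(pc$points))
    plot(pc$points[, 1L], pc$points[, 2L],
         col = c(M = "steelblue", F = "tomato", U = "grey40")[sex],
         pch = 19, xlab = sprintf("Axis 1 (%.1f%%)", 100 * pc$prop_var[1L]),
         ylab = if (ncol(pc$points) > 1L)
           sprintf("Axis 2 (%.1f%%)", 100 * pc$prop_var[2L]) else "",
         main = "PCoA of Nei genetic distances")
    graphics::legend("topright", legend = names(table(sex)), pch = 19,
                     col = c(M = "steelblue", F = "tomato", U = "grey40")[
                       names(table(sex))])
    grDevices::dev.off()
  }
  invisible(NULL)
}
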