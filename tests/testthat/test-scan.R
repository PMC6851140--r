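test_that("SNP locus concordance score matches the counting construction", {
  reg <- tiny_registry(31, 13)
  calls <- setNames(c(rep("HET", 31), rep("HOM_REF", 13)), reg$sample_id)
  xy <- score_snp_locus(calls, reg, "XY")
  expect_equal(xy$prop_het_heterogametic, 1)
  expect_equal(xy$prop_homref_homogametic, 1)
  expect_equal(xy$score, 2)
  # the same data under the mirrored hypothesis scores zero
  zw <- score_snp_locus(calls, reg, "ZW")
  expect_equal(zw$score, 0)

  # nulls count against the proportion under the all-individuals denominator
  reg2 <- tiny_registry(10, 10)
  calls2 <- setNames(c(rep("HET", 9), "NULL_CALL", rep("HOM_REF", 10)),
                     reg2$sample_id)
  s <- score_snp_locus(calls2, reg2, "XY")
  expect_equal(s$prop_het_heterogametic, 0.9)
  expect_equal(s$score, 1.9)
  # but not under the called-only denominator
  s_called <- score_snp_locus(calls2, reg2, "XY", denominator = "called")
  expect_equal(s_called$prop_het_heterogametic, 1)

  # unknown-sex samples are excluded from both proportions
  reg3 <- tiny_registry(2, 2, 1)
  calls3 <- setNames(c("HET", "HET", "HOM_REF", "HOM_REF", "HOM_ALT"),
                     reg3$sample_id)
  expect_equal(score_snp_locus(calls3, reg3, "XY")$score, 2)

  expect_error(score_snp_locus(calls3[1:2], tiny_registry(2, 0)), "undefined")
})

test_that("score is conserved as the sum of its two stored proportions", {
  set.seed(21)
  reg <- tiny_registry(7, 5)
  for (i in 1:20) {
    calls <- setNames(sample(c("HOM_REF", "HOM_ALT", "HET", "NULL_CALL"),
                             12, replace = TRUE), reg$sample_id)
    for (sys in c("XY", "ZW")) {
      s <- score_snp_locus(calls, reg, sys)
      expect_identical(s$score,
                       s$prop_het_heterogametic + s$prop_homref_homogametic)
    }
  }
})

test_that("matrix scan equals per-locus scoring and is permutation-invariant", {
  set.seed(33)
  reg <- tiny_registry(6, 5, 2)
  calls <- matrix(sample(c("HOM_REF", "HOM_ALT", "HET", "NULL_CALL"), 20 * 13,
                         replace = TRUE), 20, 13,
                  dimnames = list(sprintf("L%02d", 1:20), reg$sample_id))
  m <- tiny_snp(calls)
  sc <- scan_snp(m, reg)
  for (i in c(1, 7, 20)) {
    row <- score_snp_locus(calls[i, ], reg, "XY")
    got <- sc$scores[sc$scores$system == "XY", ][i, ]
    expect_equal(got$score, row$score)
    expect_equal(got$prop_het_heterogametic, row$prop_het_heterogametic)
  }
  # permuting loci and samples changes nothing but order
  perm <- subset_loci(m, loci = sample(locus_ids(m)),
                      samples = sample(sample_ids(m)))
  sc_perm <- scan_snp(perm, reg)
  expect_setequal(sc_perm$perfect$XY, sc$perfect$XY)
  merged <- merge(sc$scores, sc_perm$scores, by = c("locus_id", "system"))
  expect_equal(merged$score.x, merged$score.y)
})

test_that("swapping every M/F label exchanges the XY and ZW outputs", {
  sim <- simulate_dartseq(sim_params(n_autosomal_snp = 200,
                                     n_autosomal_pa = 50, seed = 9))
  reg <- sim$registry
  swapped <- sex_registry(reg$sample_id,
                          c(M = "F", F = "M", U = "U")[reg$sex], reg$site)
  sc <- scan_snp(sim$snp, reg)
  sc_sw <- scan_snp(sim$snp, swapped)
  expect_identical(sc$perfect$XY, sc_sw$perfect$ZW)
  expect_identical(sc$perfect$ZW, sc_sw$perfect$XY)
  pa <- scan_pa(sim$pa, reg)
  pa_sw <- scan_pa(sim$pa, swapped)
  expect_identical(pa$linked$XY, pa_sw$linked$ZW)
  expect_identical(pa$linked$ZW, pa_sw$linked$XY)
})

test_that("zero-noise planted loci are recovered exactly and exclusively", {
  sim <- simulate_dartseq(sim_params(n_autosomal_snp = 500,
                                     n_autosomal_pa = 500, seed = 2))
  truth <- sim$truth$loci
  sc <- scan_snp(sim$snp, sim$registry)
  expect_setequal(sc$perfect$XY, truth$locus_id[truth$class == "PERFECT_SNP"])
  expect_identical(sc$perfect$ZW, character(0))
  pa <- scan_pa(sim$pa, sim$registry)
  expect_setequal(pa$linked$XY, truth$locus_id[truth$class == "PA_LINKED"])
  expect_identical(pa$linked$ZW, character(0))
})

test_that("spuriously perfect loci are effectively absent at n = 44", {
  # 1,000 Hardy-Weinberg loci at allele frequency 0.5, 31 males + 13 females,
  # 20 independent datasets: the 0.5^44-scale null predicts essentially zero
  # perfect loci.
  set.seed(101)
  total <- 0L
  reg <- tiny_registry(31, 13)
  for (rep in 1:20) {
    calls <- hw_calls(1000, 44, 0.5)
    colnames(calls) <- reg$sample_id
    sc <- scan_snp(tiny_snp(calls), reg)
    total <- total + length(sc$perfect$XY) + length(sc$perfect$ZW)
  }
  expect_lte(total, 1L)
})

test_that("PA locus scoring mirrors the presence/absence construction", {
  reg <- tiny_registry(50, 13)
  calls <- setNames(c(rep("PRESENT", 49), "NULL_CALL", rep("ABSENT", 13)),
                    reg$sample_id)
  s <- score_pa_locus(calls, reg, "XY")
  expect_equal(s$prop_present_heterogametic, 0.98)
  expect_equal(s$prop_null_heterogametic, 0.02)
  expect_equal(s$prop_absent_homogametic, 1)
  expect_true(s$contradiction_free)
  # per-sex proportions always partition
  expect_equal(s$prop_present_heterogametic + s$prop_null_heterogametic +
                 mean(calls[male_ids(reg)] == "ABSENT"), 1)

  all_null <- setNames(rep("NULL_CALL", 63), reg$sample_id)
  s0 <- score_pa_locus(all_null, reg, "XY")
  expect_equal(s0$prop_present_heterogametic, 0)
  expect_equal(s0$prop_absent_homogametic, 0)

  contra <- calls
  contra[reg$sample_id[reg$sex == "F"][1]] <- "PRESENT"
  expect_false(score_pa_locus(contra, reg, "XY")$contradiction_free)
})

test_that("PA scan applies the 90% rule with contradiction-freedom", {
  # six-locus pattern: >=0.90 presence in males, full absence in females,
  # shortfalls only from null alleles
  reg <- tiny_registry(50, 13)
  p_present <- c(0.98, 0.90, 0.94, 0.94, 0.90, 0.90)
  calls <- do.call(rbind, lapply(p_present, function(p) {
    n_present <- round(p * 50)
    c(rep("PRESENT", n_present), rep("NULL_CALL", 50 - n_present),
      rep("ABSENT", 13))
  }))
  dimnames(calls) <- list(sprintf("P%d", 1:6), reg$sample_id)
  m <- tiny_pa(calls)
  sc <- scan_pa(m, reg)
  expect_setequal(sc$linked$XY, rownames(calls))
  expect_identical(sc$linked$ZW, character(0))
  # full strictness rejects any locus with a null
  expect_identical(scan_pa(m, reg, min_prop = 1)$linked$XY, "P1"[0])
  # a locus below the proportion floor is excluded
  low <- tiny_pa(matrix(c(rep("PRESENT", 40), rep("NULL_CALL", 10),
                          rep("ABSENT", 13)), 1, 63,
                        dimnames = list("low", reg$sample_id)))
  expect_identical(scan_pa(low, reg)$linked$XY, character(0))
})

test_that("moderate loci require all-reference females and partial male heterozygosity", {
  reg <- tiny_registry(34, 18)
  males <- male_ids(reg); females <- female_ids(reg)
  base <- setNames(rep("HOM_REF", 52), reg$sample_id)
  l_mod <- base; l_mod[males[1:13]] <- "HET"         # 13/34 = 0.38 het males
  l_fem_het <- l_mod; l_fem_het[females[1]] <- "HET" # one heterozygous female
  l_perfect <- base; l_perfect[males] <- "HET"       # S = 2
  l_low <- base; l_low[males[1:2]] <- "HET"          # 0.06 < min_het_prop
  calls <- rbind(moderate = l_mod, female_het = l_fem_het,
                 perfect = l_perfect, low = l_low)
  m <- tiny_snp(calls)
  sc <- scan_snp(m, reg)
  # 13/34 ~ 0.38 heterozygous males: admitted at a permissive floor
  mod <- find_moderate_loci(m, reg, "XY", min_het_prop = 0.25,
                            exclude = sc$perfect$XY)
  expect_identical(mod, "moderate")
  # but below the stricter default floor of 0.5
  expect_identical(find_moderate_loci(m, reg, "XY", exclude = sc$perfect$XY),
                   character(0))
  # a male homozygous-alternate call disqualifies a locus unless tolerated
  l_homalt <- l_mod; l_homalt[males[20]] <- "HOM_ALT"
  l_homalt[males[14:19]] <- "HET"  # 19/34 het, above the default floor
  l_half <- l_mod; l_half[males[14:20]] <- "HET"  # 20/34 het, clean
  m3 <- tiny_snp(rbind(homalt = l_homalt, clean = l_half))
  expect_identical(find_moderate_loci(m3, reg, "XY"), "clean")
  expect_setequal(find_moderate_loci(m3, reg, "XY",
                                     allow_homalt_heterogametic = TRUE),
                  c("homalt", "clean"))
  # female nulls are forbidden by default, tolerated on request
  l_null <- l_mod; l_null[females[2]] <- "NULL_CALL"
  m2 <- tiny_snp(rbind(modnull = l_null))
  expect_identical(find_moderate_loci(m2, reg, "XY", min_het_prop = 0.25),
                   character(0))
  expect_identical(find_moderate_loci(m2, reg, "XY", min_het_prop = 0.25,
                                      allow_null_homogametic = TRUE), "modnull")
})

test_that("system inference is conservative under conflict", {
  expect_identical(infer_system(11, 0, 6, 0), "XY")
  expect_identical(infer_system(0, 11, 0, 6), "ZW")
  expect_identical(infer_system(0, 0, 0, 0), "UNDETERMINED")
  expect_identical(infer_system(3, 2, 0, 0), "UNDETERMINED")
  expect_identical(infer_system(0, 0, 0, 2), "ZW")
})

test_that("spurious-linkage model follows 0.5^n exactly", {
  expect_equal(spurious_probability(1), 0.5)
  expect_equal(spurious_probability(2), 0.25)
  expect_equal(spurious_probability(44), 0.5^44)
  expect_equal(expected_spurious(0, 10), 0)
  expect_equal(expected_spurious(20111, 44), 20111 * 0.5^44)
  expect_error(spurious_probability(0), "positive integer")
  expect_error(expected_spurious(-1, 4), "non-negative")
})

test_that("minimum sample size is the smallest n with m * 0.5^n below threshold", {
  expect_equal(min_sample_size(20111), 15L)   # 20111*0.5^14 = 1.23, *0.5^15 = 0.61
  expect_equal(min_sample_size(1), 1L)
  expect_equal(min_sample_size(2), 2L)        # 2*0.5 = 1 is not < 1
  for (m in c(3, 10, 999, 2^20)) {
    n <- min_sample_size(m)
    expect_lt(expected_spurious(m, n), 1)
    if (n > 1L) expect_gte(expected_spurious(m, n - 1L), 1)
  }
})

test_that("linkage report classifies loci consistently and serialises", {
  sim <- simulate_dartseq(sim_params(n_autosomal_snp = 100,
                                     n_autosomal_pa = 50, seed = 4))
  sc <- scan_snp(sim$snp, sim$registry)
  pa <- scan_pa(sim$pa, sim$registry)
  mod <- find_moderate_loci(sim$snp, sim$registry, "XY",
                            exclude = sc$perfect$XY)
  rep <- linkage_report(sc, pa, mod)
  expect_identical(rep$inferred_system, "XY")
  expect_length(intersect(rep$perfect_snp_loci, rep$moderate_snp_loci), 0)
  expect_true(all(rep$moderate_snp_loci %in% locus_ids(sim$snp)))
  expect_equal(rep$spurious$snp$expected_spurious,
               rep$spurious$snp$m * rep$spurious$snp$p_per_locus)

  scores_path <- withr::local_tempfile(fileext = ".tsv")
  summary_path <- withr::local_tempfile(fileext = ".txt")
  write_linkage_report(rep, scores_path, summary_path)
  tab <- read.delim(scores_path)
  expect_equal(sum(tab$class == "perfect"), length(rep$perfect_snp_loci))
  expect_equal(sum(tab$class == "pa_linked"), length(rep$pa_linked_loci))
  kv <- read.delim(summary_path, header = FALSE)
  expect_true("inferred_system" %in% kv$V1)
})
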