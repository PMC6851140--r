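test_that("F_ST matches the hand-evaluated two-site example", {
  calls <- matrix(c("HOM_REF", "HOM_REF", "HOM_REF", "HET"), nrow = 1,
                  dimnames = list("L1", c("a1", "a2", "b1", "b2")))
  m <- tiny_snp(calls)
  sites <- setNames(c("A", "A", "B", "B"), colnames(calls))
  f <- pairwise_fst(m, sites)
  # p_A = 1, p_B = 0.75, H_S = 0.1875, H_T = 0.21875
  expect_equal(f$pairwise["A", "B"], 0.142857, tolerance = 1e-5)
  expect_equal(f$pairwise["A", "B"], 0.03125 / 0.21875, tolerance = 1e-12)
  expect_equal(f$overall, f$pairwise["A", "B"])
  expect_equal(f$n_loci, 1L)
})

test_that("F_ST spans its extremes and stays in [0, 1]", {
  fixed <- matrix(c(rep("HOM_REF", 4), rep("HOM_ALT", 4)), nrow = 2,
                  byrow = FALSE, dimnames = list(c("L1", "L2"), paste0("s", 1:4)))
  fixed[, 3:4] <- "HOM_ALT"; fixed[, 1:2] <- "HOM_REF"
  m <- tiny_snp(fixed)
  sites <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  expect_equal(pairwise_fst(m, sites)$overall, 1)

  same <- matrix(rep(c("HOM_REF", "HET", "HOM_REF", "HET"), 3), nrow = 3,
                 byrow = TRUE, dimnames = list(paste0("L", 1:3), paste0("s", 1:4)))
  expect_equal(pairwise_fst(tiny_snp(same), sites)$overall, 0)

  set.seed(55)
  calls <- hw_calls(200, 20, runif(200, 0.1, 0.9))
  sites20 <- setNames(rep(c("A", "B", "C"), length.out = 20), colnames(calls))
  f <- pairwise_fst(tiny_snp(calls), sites20)
  expect_true(all(f$pairwise >= 0 & f$pairwise <= 1))
  expect_gte(f$overall, 0); expect_lte(f$overall, 1)
  # locus order invariance
  perm <- subset_loci(tiny_snp(calls), loci = sample(rownames(calls)))
  expect_equal(pairwise_fst(perm, sites20)$overall, f$overall)

  mono <- tiny_snp(matrix("HOM_REF", 2, 4,
                          dimnames = list(c("L1", "L2"), paste0("s", 1:4))))
  expect_error(pairwise_fst(mono, sites), "monomorphic")
})

test_that("Nei distance reproduces the closed-form single-locus value", {
  m <- tiny_snp(matrix(c("HET", "HOM_REF"), nrow = 1,
                       dimnames = list("L1", c("x", "y"))))
  d <- nei_distance(m)
  expect_equal(d["x", "y"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(d["x", "y"], 0.34657, tolerance = 1e-4)
  expect_equal(diag(d), c(x = 0, y = 0))
  expect_equal(d, t(d))
})

test_that("identical genotypes are at distance zero across many loci", {
  set.seed(66)
  calls <- hw_calls(58, 6, 0.5)
  calls[, 2] <- calls[, 1]
  d <- nei_distance(tiny_snp(calls))
  expect_equal(d[1, 2], 0)
  # an all-HOM_REF block is mutually identical
  fem <- matrix("HOM_REF", 58, 4, dimnames = list(rownames(calls), paste0("f", 1:4)))
  df <- nei_distance(tiny_snp(fem))
  expect_true(all(df == 0))
})

test_that("Nei distance grows with genotype mismatches and handles nulls pairwise", {
  base <- matrix("HOM_REF", 10, 3,
                 dimnames = list(paste0("L", 1:10), c("ref", "near", "far")))
  base[1:2, "near"] <- "HET"
  base[1:8, "far"] <- "HOM_ALT"
  d <- nei_distance(tiny_snp(base))
  expect_lt(d["ref", "near"], d["ref", "far"])
  # adding one more mismatch never decreases the distance
  base2 <- base; base2[3, "near"] <- "HET"
  d2 <- nei_distance(tiny_snp(base2))
  expect_gte(d2["ref", "near"], d["ref", "near"])
  # null calls are dropped pairwise, not globally
  base3 <- base; base3[1, "near"] <- "NULL_CALL"
  d3 <- nei_distance(tiny_snp(base3))
  expect_equal(d3["ref", "far"], d["ref", "far"])
  # completely opposite homozygotes hit the sentinel with a warning
  opp <- matrix(c("HOM_REF", "HOM_ALT"), nrow = 1,
                dimnames = list("L1", c("x", "y")))
  expect_warning(ds <- nei_distance(tiny_snp(opp), sentinel = 99), "sentinel")
  expect_equal(ds["x", "y"], 99)
})

test_that("feminised-Y males sit closer to females than to unrecombined males", {
  sim <- simulate_dartseq(sim_params(n_autosomal_snp = 0L, n_autosomal_pa = 0L,
                                     n_pa_loci = 0L, n_unknown = 0L, seed = 12))
  truth <- sim$truth$samples
  sexlinked <- sim$truth$loci$locus_id[
    sim$truth$loci$class %in% c("PERFECT_SNP", "MODERATE_SNP")]
  d <- nei_distance(sim$snp, loci = sexlinked)
  m3 <- truth$sample_id[truth$lineage %in% "MALES3"]
  m1 <- truth$sample_id[truth$lineage %in% "MALES1"]
  fem <- truth$sample_id[truth$true_sex == "F"]
  expect_lt(mean(d[m3, fem]), mean(d[m3, m1]))
})

test_that("PCoA reproduces closed-form and Euclidean embeddings", {
  # two points at distance 4 embed at +/- 2 on one axis
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  expect_warning(p2 <- pcoa(d2, k = 2), "positive eigenvalue")
  expect_equal(sort(p2$points[, 1]), c(-2, 2), ignore_attr = TRUE)
  # collinear points: axis-1 distances reproduce the input exactly
  x <- c(0, 1, 3, 7)
  d1 <- as.matrix(dist(x)); dimnames(d1) <- list(letters[1:4], letters[1:4])
  p1 <- pcoa(d1, k = 1)
  expect_equal(as.matrix(dist(p1$points[, 1])), unname(d1),
               ignore_attr = TRUE, tolerance = 1e-10)
  # random 3-D cloud: distances reconstructed from 3 axes
  set.seed(88)
  pts <- matrix(rnorm(60), 20, 3)
  dd <- as.matrix(dist(pts))
  p3 <- pcoa(dd, k = 3)
  expect_equal(as.matrix(dist(p3$points)), dd, tolerance = 1e-8,
               ignore_attr = TRUE)
  # axes ordered by decreasing eigenvalue; coordinates centered
  expect_true(all(diff(p3$eig) <= 1e-8))
  expect_equal(colMeans(p3$points), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("PCoA agrees with classical scaling from the stats oracle", {
  set.seed(99)
  pts <- matrix(rnorm(45), 15, 3)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(paste0("s", 1:15), paste0("s", 1:15))
  mine <- pcoa(dd, k = 3)
  ref <- cmdscale(dd, k = 3, eig = TRUE)
  expect_equal(abs(mine$points), abs(ref$points), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(mine$eig[1:3], ref$eig[1:3], tolerance = 1e-8)
})

test_that("distance and PCoA writers round-trip through TSV", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  back <- read.delim(path)
  expect_equal(as.matrix(back[, -1]), d, ignore_attr = TRUE)

  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  dd <- as.matrix(dist(pts)); dimnames(dd) <- list(paste0("s", 1:10), paste0("s", 1:10))
  p <- pcoa(dd, k = 2)
  cp <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_pcoa(p, cp, ep)
  coords <- read.delim(cp)
  expect_equal(as.matrix(coords[, c("axis1", "axis2")]), p$points,
               ignore_attr = TRUE, tolerance = 1e-6)
  ev <- read.delim(ep)
  expect_equal(ev$eigenvalue, p$eig, tolerance = 1e-6)
})
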