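test_that("diversity table matches closed forms", {
  # 5 AA + 5 aa homozygotes: Ho = 0, p = 0.5, unbiased He = 0.5 * 20/19
  gm <- genotype_matrix(matrix(rep(c(2L, 0L), each = 5), ncol = 1,
                               dimnames = list(sprintf("s%d", 1:10), "L1")),
                        pop = rep("P", 10))
  d <- diversity(gm)
  expect_equal(d$Ho, 0)
  expect_equal(d$He, 2 * 0.25 * 20 / 19)
  expect_equal(d$Fis, 1)
  # all heterozygotes: Ho = 1, excess heterozygosity gives negative Fis
  gm2 <- genotype_matrix(matrix(1L, 10, 1), pop = rep("P", 10))
  d2 <- diversity(gm2)
  expect_equal(d2$Ho, 1)
  expect_lt(d2$Fis, 0)
  # monomorphic locus: He = 0 and Fis undefined, never coerced to zero
  gm3 <- genotype_matrix(matrix(2L, 6, 1), pop = rep("P", 6))
  d3 <- diversity(gm3)
  expect_equal(d3$He, 0)
  expect_true(is.na(d3$Fis))
})

test_that("allelic richness rarefaction: g = 2n recovers the observed allele count", {
  calls <- cbind(poly = c(2L, 1L, 0L, 0L), mono = c(2L, 2L, 2L, 2L))
  gm <- genotype_matrix(calls, pop = rep("P", 4))
  d <- diversity(gm, rarefaction_g = 8)
  expect_equal(d$Ar[d$locus == "poly"], 2)
  expect_equal(d$Ar[d$locus == "mono"], 1)
  # rarefying to fewer copies can only lower expected richness
  d2 <- diversity(gm, rarefaction_g = 2)
  expect_lt(d2$Ar[d2$locus == "poly"], 2)
  expect_gte(d2$Ar[d2$locus == "poly"], 1)
})

test_that("HWE exact test equals brute-force enumeration for n <= 10", {
  cases <- list(c(1, 0, 1), c(0, 2, 0), c(2, 2, 2), c(3, 1, 4),
                c(5, 0, 5), c(1, 5, 1), c(4, 2, 0), c(0, 3, 7))
  for (cs in cases) {
    expect_equal(hwe_exact(cs[1], cs[2], cs[3]),
                 oracle_hwe_bruteforce(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12,
                 label = paste(cs, collapse = "/"))
  }
})

test_that("HWE exact test: monomorphic input and probability bounds", {
  expect_equal(hwe_exact(0, 0, 25), 1)
  expect_equal(hwe_exact(25, 0, 0), 1)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    g <- as.vector(stats::rmultinom(1, n, prob = stats::runif(3)))
    p <- hwe_exact(g[1], g[2], g[3])
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("Bonferroni flags divide alpha by the number of tests", {
  flags <- bonferroni(c(0.01, rep(0.5, 83)), alpha = 0.05)
  expect_false(flags[1])                      # 0.01 > 0.05/84 = 5.95e-4
  expect_true(bonferroni(0.04, alpha = 0.05)) # m = 1 reduces to p <= alpha
  expect_true(bonferroni(c(0, 0.9), alpha = 0.05)[1])
  expect_error(bonferroni(numeric(0)), "no p-values")
})

test_that("Weir-Cockerham theta matches an independent transcription of the 1984 equations", {
  # the two-population toy: pop1 (AA=8, Aa=2), pop2 (Aa=2, aa=8)
  calls <- matrix(c(rep(2L, 8), rep(1L, 2), rep(1L, 2), rep(0L, 8)), ncol = 1)
  rownames(calls) <- sprintf("i%02d", 1:20)
  gm <- genotype_matrix(calls, pop = rep(c("p1", "p2"), each = 10))
  comp <- hybridscan:::wc_components(gm$calls, gm$pop)
  oracle <- oracle_wc84_locus(list(calls[1:10, 1], calls[11:20, 1]))
  expect_equal(unname(comp$theta[1]), unname(oracle["theta"]), tolerance = 1e-12)

  # random multi-locus, three populations, with missing calls
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 30 * 12, replace = TRUE,
                         prob = c(.35, .3, .3, .05)), 30, 12)
  rownames(calls) <- sprintf("i%02d", 1:30)
  gm <- genotype_matrix(calls, pop = rep(c("x", "y", "z"), each = 10))
  comp <- hybridscan:::wc_components(gm$calls, gm$pop)
  oracle <- oracle_wc84_multilocus(gm$calls, gm$pop)
  expect_equal(unname(comp$theta), unname(oracle$per_locus), tolerance = 1e-10)
  expect_equal(hybridscan:::wc_multilocus(comp), oracle$multilocus,
               tolerance = 1e-10)
})

test_that("pairwise F_ST: fixation gives theta = 1, duplicated pops give none", {
  gm_fixed <- genotype_matrix(
    matrix(rep(c(2L, 0L), each = 8), ncol = 1,
           dimnames = list(sprintf("s%d", 1:16), "L")),
    pop = rep(c("A", "B"), each = 8))
  res <- pairwise_fst(gm_fixed, n_permutations = 99, seed = 1)
  expect_equal(res$pairs$theta, 1)
  expect_lt(res$pairs$p_value, 0.05)

  set.seed(5)
  half <- matrix(sample(0:2, 20 * 30, replace = TRUE), 20, 30)
  gm_dup <- genotype_matrix(rbind(half, half), pop = rep(c("A", "B"), each = 20))
  res2 <- pairwise_fst(gm_dup, n_permutations = 99, seed = 1)
  expect_lte(res2$pairs$theta, 0.01)
  expect_gt(res2$pairs$p_value, 0.05)
})

test_that("pairwise F_ST excludes singleton populations with a warning", {
  set.seed(6)
  calls <- matrix(sample(0:2, 21 * 10, replace = TRUE), 21, 10)
  gm <- genotype_matrix(calls, pop = c(rep("A", 10), rep("B", 10), "solo"))
  expect_warning(res <- pairwise_fst(gm, n_permutations = 19, seed = 1),
                 "solo")
  expect_identical(sort(unique(c(res$pairs$pop1, res$pairs$pop2))),
                   c("A", "B"))
})

test_that("exact-test F_ST significance detects strong differentiation", {
  set.seed(8)
  sim <- simulate_reference_pops(30, 20, F_div = 0.4, seed = 81)
  res <- pairwise_fst(sim$gm, n_permutations = 200, seed = 2,
                      method = "exact")
  expect_lt(res$pairs$p_value, 0.01)
})

test_that("multilocus theta recovers the Balding-Nichols divergence parameter", {
  sim <- simulate_reference_pops(10000, 40, F_div = 0.5, seed = 101)
  comp <- hybridscan:::wc_components(sim$gm$calls, sim$gm$pop)
  expect_equal(hybridscan:::wc_multilocus(comp), 0.5, tolerance = 0.05)
  sim2 <- simulate_reference_pops(10000, 40, F_div = 0.15, seed = 102)
  comp2 <- hybridscan:::wc_components(sim2$gm$calls, sim2$gm$pop)
  expect_equal(hybridscan:::wc_multilocus(comp2), 0.15, tolerance = 0.05)
})

test_that("AMOVA separates between-group variation on a toy hierarchy", {
  gm <- toy_two_group_gm()
  res <- amova(gm, n_permutations = 99, seed = 1)
  expect_identical(res$table$df, c(1L, 2L, 4L))       # sums to n - 1
  expect_gt(res$table$percent[1], 90)
  expect_equal(sum(res$table$percent), 100, tolerance = 0.1)
  expect_true(all(res$table$p_value >= 1 / 100 & res$table$p_value <= 1))
})

test_that("AMOVA matches direct nested sums of squares on the toy matrix", {
  gm <- toy_two_group_gm()
  comp <- hybridscan:::amova_components(
    hybridscan:::impute_pop_mean(gm$calls, gm$pop), gm$pop, gm$group)
  # hand computation: 4 loci, calls 2 in the west group and 0 in the east;
  # grand mean 1 per locus -> SS_total = 8 * 4 * 1 = 32, all between groups
  expect_equal(comp$SS, c(32, 0, 0))
  expect_equal(comp$sigma2[2:3], c(0, 0))
  expect_equal(comp$ss_total, 32)
})

test_that("AMOVA percentages are invariant to relabelling pops within groups", {
  set.seed(12)
  calls <- matrix(sample(0:2, 40 * 20, replace = TRUE), 40, 20)
  pop <- rep(c("p1", "p2", "p3", "p4"), each = 10)
  grp <- rep(c("G1", "G2"), each = 20)
  gm1 <- genotype_matrix(calls, pop = pop, group = grp)
  relabel <- c(p1 = "p2", p2 = "p1", p3 = "p4", p4 = "p3")
  calls2 <- calls; rownames(calls2) <- rownames(gm1$calls)
  gm2 <- genotype_matrix(calls2, pop = unname(relabel[pop]), group = grp)
  r1 <- amova(gm1, n_permutations = 19, seed = 1)
  r2 <- amova(gm2, n_permutations = 19, seed = 1)
  expect_equal(r1$table$percent, r2$table$percent, tolerance = 1e-10)
})

test_that("AMOVA flags identical individuals as degenerate and demands >= 2 groups", {
  gm <- genotype_matrix(matrix(1L, 8, 3),
                        pop = rep(c("a", "b", "c", "d"), each = 2),
                        group = rep(c("g1", "g2"), each = 4))
  expect_warning(res <- amova(gm, n_permutations = 19, seed = 1),
                 "degenerate|identical")
  expect_true(all(is.na(res$table$percent)))
  gm_one <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 4, 1),
                            pop = rep(c("a", "b"), each = 2),
                            group = rep("g1", 4))
  expect_error(amova(gm_one), "single group")
})

test_that("allele-frequency correlation: self, antisymmetry, hand value", {
  set.seed(13)
  calls <- matrix(sample(0:2, 20 * 5, replace = TRUE), 20, 5)
  gm <- genotype_matrix(rbind(calls, calls, 2L - calls),
                        pop = rep(c("A", "Acopy", "Aflip"), each = 20))
  r <- allele_freq_correlation(gm)
  expect_equal(r["A", "Acopy"], 1)
  expect_equal(r["A", "Aflip"], -1)
  pf <- allele_freqs(gm, by = "pop")
  expect_equal(r["A", "Aflip"],
               stats::cor(pf["A", ], pf["Aflip", ]))
  # hand-computed Pearson r on a fixed 5-locus toy table
  fA <- c(0.1, 0.3, 0.5, 0.7, 0.9); fB <- c(0.2, 0.2, 0.6, 0.6, 1.0)
  hand <- sum((fA - mean(fA)) * (fB - mean(fB))) /
    sqrt(sum((fA - mean(fA))^2) * sum((fB - mean(fB))^2))
  expect_equal(stats::cor(fA, fB), hand, tolerance = 1e-12)
  gm_const <- genotype_matrix(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L), c(0L, 1L)),
                              pop = c("C", "C", "D", "D"))
  expect_true(is.na(allele_freq_correlation(gm_const)["C", "D"]))
})
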