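test_that("class genotype probabilities match enumeration of gamete origins", {
  # diagnostic locus: F1 heterozygous with certainty, F2 segregates 1:2:1
  expect_equal(class_genotype_prob(1, p_A = 1, p_B = 0, z = "F1"), 1)
  expect_equal(vapply(0:2, class_genotype_prob, numeric(1),
                      p_A = 1, p_B = 0, z = "F2"), c(0.25, 0.5, 0.25))
  # backcross at intermediate frequencies: 0.5 * 0.81 + 0.5 * 0.18
  expect_equal(class_genotype_prob(2, p_A = 0.9, p_B = 0.2, z = "BCA"), 0.495)
  set.seed(21)
  for (i in 1:25) {
    pa <- stats::runif(1); pb <- stats::runif(1)
    g <- sample(0:2, 1); z <- sample(hybrid_classes(), 1)
    expect_equal(class_genotype_prob(g, pa, pb, z),
                 oracle_class_prob(g, pa, pb, z), tolerance = 1e-12)
  }
  expect_error(class_genotype_prob(1, 0.5, 0.5, "F9"), "unknown class")
})

test_that("genotype probabilities sum to one over genotypes for every class", {
  set.seed(22)
  for (i in 1:50) {
    pa <- stats::runif(1); pb <- stats::runif(1)
    for (z in hybrid_classes()) {
      s <- sum(vapply(0:2, class_genotype_prob, numeric(1),
                      p_A = pa, p_B = pb, z = z))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
  # missing genotype contributes probability one (locus skipped)
  expect_equal(class_genotype_prob(NA, 0.3, 0.8, "F2"), 1)
})

test_that("ML classification: diagnostic loci, uninformative loci, normalization", {
  # all-heterozygous individual at 50 fully diagnostic loci is F1 with
  # likelihood ratio >= 2^50 against the nearest class
  gm <- genotype_matrix(matrix(1L, 1, 50), pop = "x")
  post <- classify_ml(gm, p_A = rep(1, 50), p_B = rep(0, 50))
  expect_gt(post$posterior[1, "F1"], 0.999)
  # identical frequencies carry no information: posterior equals the prior
  prior <- c(0.3, 0.1, 0.2, 0.15, 0.15, 0.1)
  gm2 <- genotype_matrix(matrix(sample(0:2, 20, replace = TRUE), 2, 10),
                         pop = c("x", "y"))
  post2 <- classify_ml(gm2, p_A = rep(0.4, 10), p_B = rep(0.4, 10),
                       prior = prior)
  expect_equal(unname(post2$posterior[1, ]), prior / sum(prior),
               tolerance = 1e-12)
  expect_equal(rowSums(post2$posterior), c(1, 1), ignore_attr = TRUE)
  # all-missing individual: uniform posterior, flagged
  gm3 <- genotype_matrix(matrix(NA_integer_, 1, 10), pop = "x")
  post3 <- classify_ml(gm3, p_A = rep(0.9, 10), p_B = rep(0.1, 10))
  expect_equal(unname(post3$posterior[1, ]), rep(1 / 6, 6))
  expect_true(post3$diagnostics$all_missing[1])
})

test_that("swapping population frequencies mirrors the posterior classes", {
  set.seed(23)
  panel <- simulate_reference_pops(40, 10, F_div = 0.5, seed = 61)$panel
  sim <- simulate_hybrid_classes(panel, 8, seed = 62)
  a <- classify_ml(sim$gm, panel$p_A, panel$p_B)$posterior
  b <- classify_ml(sim$gm, panel$p_B, panel$p_A)$posterior
  expect_equal(a[, "PureA"], b[, "PureB"], tolerance = 1e-12)
  expect_equal(a[, "BCA"], b[, "BCB"], tolerance = 1e-12)
  expect_equal(a[, "F1"], b[, "F1"], tolerance = 1e-12)
  expect_equal(a[, "F2"], b[, "F2"], tolerance = 1e-12)
})

test_that("threshold assignment handles single classes, pooling and the sum rule", {
  post <- rbind(c(0.97, 0.01, 0.005, 0.005, 0.005, 0.005),
                c(0.45, 0.05, 0.30, 0.20, 0.00, 0.00),
                c(0.20, 0.20, 0.30, 0.20, 0.10, 0.00))
  colnames(post) <- hybrid_classes()
  expect_identical(assign_classes(post, 0.8),
                   c("PureA", "unassigned", "unassigned"))
  expect_identical(assign_classes(post, 0.5)[2], "unassigned")
  # pooled hybrid posterior 0.6 = F1 0.3 + F2 0.2 + BCA 0.1 passes at 0.5
  pooled <- assign_classes(post, 0.5,
                           pooling = list(hybrid = c("F1", "F2", "BCA", "BCB")))
  expect_identical(pooled[3], "hybrid")
  expect_warning(assign_classes(post, 0.3), "below 0.5")
  expect_error(assign_classes(post, 1), "< 1")
})

test_that("Gibbs classification recovers simulated classes and matches the ML oracle", {
  sim <- simulate_reference_pops(84, 40, F_div = 0.5, seed = 71)
  hyb <- simulate_hybrid_classes(sim$panel, 24, seed = 72)
  fit <- classify_gibbs(hyb$gm, burnin = 500, sweeps = 4500, seed = 73)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, nrow(fit$posterior)),
               tolerance = 1e-9)
  expect_lte(fit$diagnostics$discrepancy, 0.1)
  fit <- hybridscan:::orient_to_reference(
    fit, list(p_A = sim$panel$p_A, p_B = sim$panel$p_B))
  modal <- hybrid_classes()[max.col(fit$posterior)]
  pure <- hyb$labels %in% c("PureA", "PureB")
  expect_gte(mean(modal[pure] == hyb$labels[pure]), 0.95)
  # agreement with the fixed-true-frequency ML path on modal classes
  ml <- classify_ml(hyb$gm, sim$panel$p_A, sim$panel$p_B)
  modal_ml <- hybrid_classes()[max.col(ml$posterior)]
  expect_gte(mean(modal == modal_ml), 0.9)
  expect_error(classify_gibbs(hyb$gm, burnin = 100, sweeps = 0), "sweeps")
})

test_that("Gibbs orientation rule is deterministic under label swap of the input", {
  sim <- simulate_reference_pops(60, 30, F_div = 0.6, seed = 81)
  hyb <- simulate_hybrid_classes(sim$panel, 12,
                                 classes = c("PureA", "PureB"), seed = 82)
  f1 <- classify_gibbs(hyb$gm, burnin = 300, sweeps = 2700, seed = 83)
  f2 <- classify_gibbs(hyb$gm, burnin = 300, sweeps = 2700, seed = 84)
  # two independent seeds agree on the oriented posterior up to MC noise
  expect_lt(max(abs(f1$posterior - f2$posterior)), 0.1)
  # the orientation contract: cluster A has the higher mean frequency
  expect_gte(mean(f1$freq_A), mean(f1$freq_B))
})
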