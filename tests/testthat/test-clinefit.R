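make_cline_counts <- function(distances, centre, width, n_per_site,
                              pmin = 0, pmax = 1, seed = 1) {
  set.seed(seed)
  p <- pmin + (pmax - pmin) / (1 + exp(-4 * (distances - centre) / width))
  data.frame(distance_km = distances,
             allele_count = stats::rbinom(length(distances), n_per_site, p),
             allele_total = n_per_site)
}

test_that("symmetric three-site construction centres near the midpoint", {
  d <- data.frame(distance_km = c(0, 500, 1000),
                  allele_count = c(0, 50, 100),
                  allele_total = 100)
  fit <- fit_cline(d, variant = "fixed", seed = 1)
  grid <- oracle_cline_grid(d$distance_km, d$allele_count, d$allele_total,
                            c_grid = seq(0, 1000, by = 5),
                            w_grid = seq(50, 2000, by = 25))
  expect_equal(fit$centre, 500, tolerance = 0.05)
  expect_equal(unname(grid["centre"]), 500, tolerance = 5)
  expect_gte(fit$logL, grid["logL"] - 0.1)   # MLE at least as good as grid
})

test_that("the fitted frequency at the centre is the asymptote midpoint", {
  d <- make_cline_counts(seq(0, 1200, by = 100), centre = 600, width = 150,
                         n_per_site = 100, pmin = 0.1, pmax = 0.9, seed = 2)
  fit <- fit_cline(d, variant = "free", seed = 3)
  expect_equal(predict(fit, fit$centre), (fit$pmin + fit$pmax) / 2,
               tolerance = 1e-9)
})

test_that("reversing the transect mirrors the centre and keeps the fit", {
  d <- make_cline_counts(seq(0, 1200, by = 100), centre = 700, width = 200,
                         n_per_site = 80, seed = 4)
  fit <- fit_cline(d, variant = "fixed", seed = 5)
  d_rev <- d
  d_rev$distance_km <- 1200 - d$distance_km
  d_rev$allele_count <- d$allele_total - d$allele_count   # frequency 1 - p
  fit_rev <- fit_cline(d_rev, variant = "fixed", seed = 5)
  expect_equal(fit_rev$centre, 1200 - fit$centre, tolerance = 15)
  expect_equal(fit_rev$logL, fit$logL, tolerance = 0.5)
})

test_that("parameter recovery: median centre error <= 30 km at c=600, w=150", {
  errs <- w_ratio <- numeric(20)
  for (i in 1:20) {
    d <- make_cline_counts(seq(0, 1200, by = 100), centre = 600, width = 150,
                           n_per_site = 50, seed = 100 + i)
    fit <- fit_cline(d, variant = "fixed", n_starts = 5, seed = i)
    errs[i] <- abs(fit$centre - 600)
    w_ratio[i] <- fit$width / 150
  }
  expect_lte(stats::median(errs), 30)
  # width recovered within a factor of two for most runs
  expect_gte(mean(w_ratio > 0.5 & w_ratio < 2), 0.8)
})

test_that("flat frequencies are flagged unidentifiable", {
  d <- data.frame(distance_km = c(0, 300, 600, 900),
                  allele_count = rep(50, 4), allele_total = 100)
  expect_warning(fit <- fit_cline(d, variant = "free", seed = 6),
                 "flat|unidentifiable")
  expect_true(fit$flat)
})

test_that("site-size filter and input validation apply before fitting", {
  d <- data.frame(distance_km = c(0, 400, 800, 1200),
                  allele_count = c(0, 10, 35, 40),
                  allele_total = c(40, 40, 40, 8))   # last site n = 4 < 10
  fit <- fit_cline(d, variant = "fixed", seed = 7)
  expect_equal(nrow(fit$data), 3L)
  expect_error(fit_cline(d[1:2, ], variant = "fixed"), "3 sites")
  bad <- d; bad$allele_count[1] <- 99
  expect_error(fit_cline(bad), "allele_count")
})

test_that("AIC model choice prefers parsimony within two log-likelihood units", {
  d <- make_cline_counts(seq(0, 1200, by = 100), centre = 600, width = 150,
                         n_per_site = 60, seed = 8)   # true asymptotes 0/1
  f_fixed <- fit_cline(d, variant = "fixed", seed = 9)
  f_free <- fit_cline(d, variant = "free", seed = 9)
  best <- select_cline_model(list(f_free, f_fixed))
  # the free scaling gains < 2 logL units here, so 2 extra params lose
  expect_identical(best$variant, "fixed")
  # scaled simulation: free scaling wins only when asymptotes truly differ
  d2 <- make_cline_counts(seq(0, 1200, by = 100), centre = 600, width = 150,
                          n_per_site = 200, pmin = 0.25, pmax = 0.75, seed = 10)
  b2 <- select_cline_model(list(fit_cline(d2, "fixed", seed = 11),
                                fit_cline(d2, "free", seed = 11)))
  expect_identical(b2$variant, "free")
  # exact AIC tie goes to fewer parameters
  t1 <- f_fixed; t1$AIC <- 100; t1$k <- 2L
  t2 <- f_free;  t2$AIC <- 100; t2$k <- 4L
  expect_identical(select_cline_model(list(t2, t1))$variant, "fixed")
})

test_that("centre support limits bracket the estimate and narrow with data", {
  d_small <- make_cline_counts(seq(0, 1200, by = 100), 600, 150,
                               n_per_site = 30, seed = 12)
  d_big <- make_cline_counts(seq(0, 1200, by = 100), 600, 150,
                             n_per_site = 300, seed = 12)
  f_small <- centre_support(fit_cline(d_small, "fixed", seed = 13))
  f_big <- centre_support(fit_cline(d_big, "fixed", seed = 13))
  expect_lte(f_small$centre_support[1], f_small$centre)
  expect_gte(f_small$centre_support[2], f_small$centre)
  expect_lt(diff(f_big$centre_support), diff(f_small$centre_support))
})

test_that("displacement calls follow support-interval overlap", {
  f <- centre_support(fit_cline(
    make_cline_counts(seq(0, 1200, by = 100), 600, 150, 100, seed = 14),
    "fixed", seed = 15))
  g <- centre_support(fit_cline(
    make_cline_counts(seq(0, 1200, by = 100), 600, 150, 30, seed = 17),
    "fixed", seed = 17))
  h <- centre_support(fit_cline(
    make_cline_counts(seq(0, 1200, by = 100), 1100, 100, 200, seed = 18),
    "fixed", seed = 19))
  expect_identical(displacement_test(f, f)$call, "concordant")
  # overlapping supports: 787-1087 style interval vs one containing it
  expect_identical(displacement_test(f, g)$call, "concordant")
  expect_identical(displacement_test(f, h)$call, "displaced")
  # hand intervals mirroring a reference centre 799 (787-1087)
  fa <- f; fa$centre_support <- c(780, 820)
  fb <- f; fb$centre_support <- c(787, 1087)
  expect_identical(displacement_test(fa, fb)$call, "concordant")
  fc <- f; fc$centre_support <- c(100, 200)
  fd <- f; fd$centre_support <- c(800, 900)
  expect_identical(displacement_test(fc, fd)$call, "displaced")
  f_open <- f; attr(f_open$centre_support, "open") <- TRUE
  res <- displacement_test(f_open, h)
  expect_identical(res$call, "concordant")
  expect_true(res$open)
  expect_error(displacement_test(fit_cline(
    make_cline_counts(seq(0, 1200, by = 100), 600, 150, 100, seed = 14),
    "fixed", seed = 15), f), "centre_support")
})
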