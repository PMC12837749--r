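test_that("contingency cells enumerate joint presence states", {
  t <- contingency(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(t[c("a", "b", "c", "d")], list(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(t$n, 4L)
  same <- contingency(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$b + same$c, 0L)
  expect_error(contingency(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("phi spans [-1, 1] with the textbook extremes", {
  expect_equal(phi_coef(list(a = 5, b = 0, c = 0, d = 5, n = 10)), 1)
  expect_equal(phi_coef(list(a = 0, b = 5, c = 5, d = 0, n = 10)), -1)
  t <- list(a = 30, b = 20, c = 5, d = 12, n = 67)
  expect_equal(phi_coef(t), 0.2665, tolerance = 1e-4)
  expect_warning(out <- phi_coef(list(a = 3, b = 0, c = 2, d = 0, n = 5)),
                 "zero margin")
  expect_true(is.na(out))
})

test_that("phi equals the Pearson correlation of the presence vectors", {
  set.seed(21)
  for (i in 1:200) {
    t <- random_table()
    v <- table_to_vectors(t)
    if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0) next
    expect_equal(phi_coef(t), stats::cor(v$x, v$y), tolerance = 1e-12)
    # phi^2 * n is the uncorrected chi-square
    suppressWarnings(
      chi0 <- stats::chisq.test(matrix(c(t$a, t$c, t$b, t$d), 2),
                                correct = FALSE)$statistic)
    expect_equal(phi_coef(t)^2 * t$n, unname(chi0), tolerance = 1e-9)
  }
})

test_that("Yates chi-square clamps at zero and matches the standard test", {
  expect_equal(yates_chi2(list(a = 10, b = 10, c = 10, d = 10, n = 40)), 0)
  expect_equal(yates_chi2(list(a = 20, b = 5, c = 5, d = 20, n = 50)), 15.68)
  # |ad - bc| = n/2 boundary: 5*3 - 2*4 = 7 = 14/2
  expect_equal(yates_chi2(list(a = 5, b = 2, c = 4, d = 3, n = 14)), 0)
  set.seed(22)
  for (i in 1:200) {
    t <- random_table()
    ref <- suppressWarnings(stats::chisq.test(matrix(c(t$a, t$c, t$b, t$d), 2),
                                              correct = TRUE))$statistic
    expect_equal(yates_chi2(t), unname(ref), tolerance = 1e-9)
  }
})

test_that("significance classes split at 3.841 and 6.635, strict on both sides", {
  expect_equal(classify_association(c(2, 5, 25.32)),
               c("none", "significant", "highly_significant"))
  expect_equal(classify_association(c(3.841, 6.635)),
               c("none", "significant"))
  expect_true(is.na(classify_association(NA_real_)))
})

test_that("variance ratio reproduces closed-form communities", {
  # two species perfectly co-occurring at half the sites: T_j in {0, 2}
  pres <- cbind(rep(c(TRUE, FALSE), each = 10), rep(c(TRUE, FALSE), each = 10))
  expect_equal(variance_ratio(pres)$vr, 2)
  # mutually exclusive species covering all sites: constant richness
  pres2 <- cbind(rep(c(TRUE, FALSE), 10), rep(c(FALSE, TRUE), 10))
  expect_equal(variance_ratio(pres2)$vr, 0)
  expect_error(variance_ratio(matrix(TRUE, 5, 3)), "all sites or none")
})

test_that("variance ratio agrees with a literal transcription and is >= 0", {
  set.seed(23)
  for (i in 1:50) {
    pres <- matrix(stats::runif(50) < stats::runif(1, 0.2, 0.8), 10, 5)
    if (all(colSums(pres) %in% c(0, 10))) next
    vr <- suppressWarnings(variance_ratio(pres))
    expect_equal(vr$vr, literal_vr(pres), tolerance = 1e-12)
    expect_gte(vr$vr, 0)
    expect_equal(vr$w, vr$vr * 10)
  }
})

test_that("W verdict compares the statistic against the chi-square band", {
  pres <- cbind(rep(c(TRUE, FALSE), each = 30), rep(c(TRUE, FALSE), each = 30))
  out <- variance_ratio(pres)  # VR = 2, W = 120 >> upper band at df = 60
  expect_equal(out$band, stats::qchisq(c(0.05, 0.95), df = 60))
  expect_equal(out$verdict, "significant_positive")
  out2 <- variance_ratio(pres, df = 100)   # wider band brackets W = 120
  expect_equal(out2$verdict, "not_significant")
})

test_that("lambda is a proportional reduction in prediction error", {
  expect_equal(gk_lambda(list(a = 5, b = 0, c = 0, d = 5, n = 10),
                         n_boot = 10)$lambda, 1)
  expect_equal(gk_lambda(list(a = 5, b = 5, c = 5, d = 5, n = 20),
                         n_boot = 10)$lambda, 0)
  t <- list(a = 30, b = 20, c = 5, d = 12, n = 67)
  expect_equal(gk_lambda(t, "ab", n_boot = 10)$lambda,
               brute_force_lambda(t, "ab"))
  set.seed(24)
  for (i in 1:50) {
    t <- random_table()
    for (dir in c("ab", "ba")) {
      est <- gk_lambda(t, dir, n_boot = 50)$lambda
      oracle <- brute_force_lambda(t, dir)
      if (is.na(oracle)) next
      expect_equal(est, oracle, tolerance = 1e-12)
      expect_gte(est, 0)
      expect_lte(est, 1)
    }
  }
})

test_that("lambda is asymmetric and its bootstrap interval brackets the estimate", {
  # B almost nested in A: predicting B from A is informative, not vice versa
  t <- list(a = 25, b = 10, c = 1, d = 31, n = 67)
  ab <- gk_lambda(t, "ab", n_boot = 500, seed = 9)
  ba <- gk_lambda(t, "ba", n_boot = 500, seed = 9)
  expect_false(isTRUE(all.equal(ab$lambda, ba$lambda)))
  expect_lte(ab$lower, ab$lambda + 1e-12)
  expect_gte(ab$upper, ab$lambda - 1e-12)
  # determinism under a fixed seed
  again <- gk_lambda(t, "ab", n_boot = 500, seed = 9)
  expect_identical(ab[c("lower", "upper")], again[c("lower", "upper")])
  expect_error(gk_lambda(t, "ab", n_boot = 0), "positive")
  # degenerate: predicted species everywhere
  expect_warning(out <- gk_lambda(list(a = 5, b = 0, c = 5, d = 0, n = 10),
                                  "ab", n_boot = 10), "undefined")
  expect_true(is.na(out$lambda))
})

test_that("pair_associations tabulates every pair with consistent sign and class", {
  set.seed(25)
  pres <- matrix(stats::runif(67 * 4) < 0.5, 67, 4,
                 dimnames = list(NULL, c("w", "x", "y", "z")))
  m <- structure(list(counts = pres * 1L, presence = pres),
                 class = "site_species_matrix")
  out <- pair_associations(m)
  expect_equal(nrow(out), 6)
  expect_equal(out$a + out$b + out$c + out$d, rep(67L, 6))
  pos <- !is.na(out$phi) & out$sign == "positive"
  expect_true(all(out$phi[pos] > 0))
  expect_equal(out$class, classify_association(out$chi2))
  sub <- pair_associations(m, species = c("w", "y"))
  expect_equal(nrow(sub), 1)
  expect_error(pair_associations(m, species = c("w", "nope")), "nope")
})
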