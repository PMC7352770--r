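# Agreement and inference statistics.

test_that("bland_altman honors its exact identities", {
  a <- c(3, 8, 15, 22, 9)
  ba <- bland_altman(a, a)
  expect_identical(ba$bias, 0)
  expect_identical(ba$sd_diff, 0)

  shift <- bland_altman(a + 1, a)
  expect_equal(shift$bias, 1)
  expect_equal(shift$sd_diff, 0)
  expect_equal(shift$loa_high - shift$loa_low, 2 * 1.96 * shift$sd_diff)

  # antisymmetry
  b <- c(5, 6, 14, 25, 7)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)

  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("sample SD of injected differences falls in its chi-square band", {
  pc <- generate_paired_counts(rpois(500, 15) + 5,
                               sd_a = 5 / sqrt(2), sd_b = 5 / sqrt(2),
                               seed = 11)
  ba <- bland_altman(pc$a, pc$b)
  expect_gt(ba$sd_diff, 4.5)
  expect_lt(ba$sd_diff, 5.5)
  expect_lt(abs(ba$bias), 0.75)
})

test_that("pearson_matrix matches cor.test and handles degeneracies", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4, 7.2, 6.0)
  d <- data.frame(x = x, y = 2 * x, z = c(7, 3, 5, 1, 4, 2, 6))
  cm <- pearson_matrix(d)
  expect_equal(cm$R["x", "y"], 1)
  expect_equal(unname(diag(cm$R)), rep(1, 3))
  expect_equal(cm$R, t(cm$R))

  ct <- cor.test(d$x, d$z)
  expect_equal(cm$R["x", "z"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["x", "z"], ct$p.value, tolerance = 1e-12)

  # affine invariance with sign flip on negative scaling
  d2 <- transform(d, z = -3 * z + 10)
  cm2 <- pearson_matrix(d2)
  expect_equal(cm2$R["x", "z"], -cm$R["x", "z"], tolerance = 1e-12)

  expect_warning(cmc <- pearson_matrix(data.frame(x = x, k = 1)),
                 "zero-variance")
  expect_true(is.na(cmc$R["x", "k"]))
  expect_error(pearson_matrix(data.frame(x = 1:2, y = 2:3)), "3")
})

test_that("copula profiles recover a strong negative correlation", {
  p <- generate_depth_profile(500, seed = 5)
  cm <- pearson_matrix(p[, c("depth", "necrotic_fraction")])
  r <- cm$R["depth", "necrotic_fraction"]
  expect_gt(r, -0.91)
  expect_lt(r, -0.84)
  expect_lt(cm$p["depth", "necrotic_fraction"], 0.01)
})

test_that("permutation test is valid on identical groups and errors on
           undersized ones", {
  set.seed(1)
  d <- data.frame(v = rnorm(80), s = rep(1:8, each = 10),
                  g = rep(c("a", "b"), each = 40))
  # symmetric null with identical group values
  d$v <- rep(rnorm(40), 2)
  p <- clustered_permutation_test(d$v, d$s, d$g, n_perm = 499, seed = 2)
  expect_gte(p$p, 0.5)
  expect_lte(p$p, 1)

  bad <- data.frame(v = rnorm(30), s = rep(1:3, each = 10),
                    g = rep(c("a", "a", "b"), each = 10))
  expect_error(clustered_permutation_test(bad$v, bad$s, bad$g,
                                          n_perm = 199),
               "at least 2 slices")
  expect_error(clustered_permutation_test(1:10, rep(1:2, 5), rep("a", 10),
                                          n_perm = 199),
               "two groups")
})

test_that("permutation p-values are reproducible and monotone in effect", {
  set.seed(3)
  base <- rnorm(150)
  s <- rep(1:10, each = 15)
  g <- rep(c("ctrl", "irr"), each = 75)
  pvals <- sapply(c(0, 1, 3), function(delta) {
    v <- base + ifelse(g == "irr", delta, 0)
    clustered_permutation_test(v, s, g, n_perm = 999, seed = 7)$p
  })
  expect_true(all(diff(pvals) <= 0))
  expect_true(all(pvals > 0 & pvals <= 1))

  p1 <- clustered_permutation_test(base, s, g, n_perm = 499, seed = 9)
  p2 <- clustered_permutation_test(base, s, g, n_perm = 499, seed = 9)
  expect_identical(p1$p, p2$p)
})

test_that("permutation test agrees with a slice-level t-test on clear
           effects", {
  set.seed(4)
  s <- rep(1:12, each = 8)
  g <- rep(c("ctrl", "irr"), each = 48)
  v <- rnorm(96) + rep(rnorm(12, 0, 0.3), each = 8) +
    ifelse(g == "irr", 2, 0)
  perm <- clustered_permutation_test(v, s, g, n_perm = 4999, seed = 5)
  sm <- tapply(v, s, mean)
  tt <- t.test(sm[1:6], sm[7:12], var.equal = TRUE)
  expect_lt(perm$p, 0.01)
  expect_lt(tt$p.value, 0.01)
  expect_equal(perm$observed, unname(mean(sm[1:6]) - mean(sm[7:12])),
               tolerance = 1e-12)
})
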