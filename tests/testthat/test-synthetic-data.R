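# Generators: determinism, truth consistency and degenerate inputs.

test_that("foci scene generation is deterministic and truth-consistent", {
  a <- generate_foci_scene(10, foci_counts = 5, seed = 42)
  b <- generate_foci_scene(10, foci_counts = 5, seed = 42)
  expect_identical(a, b)
  c <- generate_foci_scene(10, foci_counts = 5, seed = 43)
  expect_false(identical(a$dapi, c$dapi))

  # declared areas are exact pixel counts of the truth mask
  px <- tabulate(a$truth$mask[a$truth$mask > 0], nbins = 10)
  expect_identical(a$truth$nuclei$area_px, px)
  expect_equal(a$truth$nuclei$area_um2, px * a$truth$pixel_size^2)
  expect_true(all(a$truth$nuclei$area_um2 > 0))

  # every focus lies inside its parent nucleus mask
  f <- a$truth$foci
  owner <- a$truth$mask[cbind(round(f$y), round(f$x))]
  expect_identical(owner, f$nucleus)

  # rendered rasters match the declared raster size
  expect_identical(dim(a$dapi), a$truth$dim)
  expect_identical(dim(a$gamma), a$truth$dim)
})

test_that("foci scene handles empty and zero-foci cases", {
  e <- generate_foci_scene(0, seed = 1)
  expect_identical(nrow(e$truth$nuclei), 0L)
  expect_true(all(e$truth$mask == 0L))

  z <- generate_foci_scene(20, width = 384, foci_counts = 0,
                           noise_level = 0, seed = 2)
  expect_identical(nrow(z$truth$nuclei), 20L)
  expect_identical(nrow(z$truth$foci), 0L)
  # gamma channel is pure background when there are no foci and no noise
  expect_true(all(z$gamma == z$gamma[1, 1]))
})

test_that("unsatisfiable foci separation and bad sizes fail explicitly", {
  expect_error(
    generate_foci_scene(1, foci_counts = 80, foci_sigma = 3,
                        min_foci_separation = 12, seed = 3),
    "separation unsatisfiable")
  expect_error(generate_foci_scene(2, width = 0, seed = 1), "positive")
})

test_that("pan-bright classes carry no truth foci", {
  sc <- generate_foci_scene(12, foci_counts = 6,
                            class_probs = c(normal = 0.5, apoptotic = 0.25,
                                            mitotic = 0.25),
                            width = 320, seed = 5)
  abnormal <- sc$truth$nuclei$class != "normal"
  expect_true(any(abnormal))  # seed chosen freely; just needs both kinds
  expect_true(all(sc$truth$nuclei$foci_count[abnormal] == 0L))
  expect_false(any(sc$truth$foci$nucleus %in%
                     sc$truth$nuclei$label[abnormal]))
})

test_that("stain scenes mix per Beer-Lambert and report exact fractions", {
  half <- generate_stain_scene(layout_halves(64, 64), mode = "he",
                               noise_sd = 0, seed = 1)
  expect_equal(half$truth$class2_fraction, 0.5)
  # noise-free pixel equals 10^-OD of its class concentrations
  W <- half$truth$stain_matrix
  conc <- half$truth$concentrations
  expected_viable <- 10^-(as.vector(conc[1, ] %*% t(W)))
  expect_equal(as.vector(half$rgb[10, 10, ]), expected_viable,
               tolerance = 1e-12)

  expect_warning(
    bg <- generate_stain_scene(matrix(0L, 8, 8), mode = "he", seed = 1),
    "no tissue")
  expect_true(is.na(bg$truth$class2_fraction))
})

test_that("degenerate stain vectors are rejected", {
  W <- cbind(a = c(1, 0, 0), b = c(1, 0, 0))
  expect_error(generate_stain_scene(layout_halves(8, 8), stain_matrix = W),
               "unit|collinear")
  W2 <- sweep(cbind(a = c(1, 2, 1), b = c(2, 4, 2)), 2,
              sqrt(colSums(cbind(c(1, 2, 1), c(2, 4, 2))^2)), "/")
  expect_error(check_stain_matrix <- generate_stain_scene(
    layout_halves(8, 8), stain_matrix = W2), "collinear")
})

test_that("assay truth validates its invariants", {
  expect_error(assay_truth(c(0.6, 0.6)), "sum")
  expect_error(assay_truth(0.2, noise_sd = -1), "non-negative")
  tr <- assay_truth(c(0.25, 0.25))
  expect_equal(tr$residual, 0.5)
})

test_that("assay series recovers its truth through the survival chain", {
  # zero noise: closed form
  plate <- generate_assay_series(assay_truth(c(0.25, 0.25)), seed = 1)
  sig <- ldh_from_plate(plate)
  ss <- survival_series(sig$daily, sig$lysis)
  expect_equal(ss$surviving, c(0.75, 0.50), tolerance = 1e-12)

  # all-zero daily fractions: nothing dies
  p0 <- generate_assay_series(assay_truth(c(0, 0, 0)), seed = 2)
  s0 <- ldh_from_plate(p0)
  ss0 <- survival_series(s0$daily, s0$lysis)
  expect_equal(ss0$surviving, c(1, 1, 1), tolerance = 1e-12)

  # noisy plate: recovered daily deaths within 3 sd of truth
  fr <- c(0.10, 0.20, 0.15, 0.05)
  tr <- assay_truth(fr, noise_sd = 0.01)
  pl <- generate_assay_series(tr, seed = 3)
  s <- ldh_from_plate(pl)
  ssn <- survival_series(s$daily, s$lysis)
  # noise on each signal propagates through the ratio; 3 sd with margin
  expect_true(all(abs(ssn$cell_death - fr) < 3 * 0.01 * sqrt(2) + 0.01))
})

test_that("paired counts honor trivial error laws", {
  tc <- c(0, 3, 10, 25)
  z <- generate_paired_counts(tc, seed = 1)
  expect_identical(z$a, z$b)
  expect_identical(z$a, as.integer(tc))

  off <- generate_paired_counts(tc, bias_a = 1, seed = 1)
  ba <- bland_altman(off$a, off$b)
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, 0)

  expect_error(generate_paired_counts(integer(0)), "non-empty")
})

test_that("depth profiles keep fractions bounded and obey the depth grid", {
  prof <- generate_depth_profile(50, seed = 4)
  fracs <- as.matrix(prof[, c("necrotic_fraction", "cd44_fraction",
                              "dapi_fraction")])
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_equal(prof$depth, (0:49) * 500)
  expect_true(all(diff(prof$depth) > 0))

  expect_warning(one <- generate_depth_profile(1, seed = 1), "undefined")
  expect_false(attr(one, "correlations_defined"))
})

test_that("copula generator hits identity and strong targets", {
  # identity target: off-diagonal |R| below the null 95% bound at n = 200
  id <- diag(4)
  dimnames(id) <- dimnames(default_morphology_correlations())
  prof <- generate_depth_profile(200, correlation_targets = id, seed = 6)
  R <- cor(as.matrix(prof[, rownames(id)]))
  expect_true(all(abs(R[upper.tri(R)]) < 0.2))

  # strong target: empirical R near 0.83 for depth vs DAPI at n = 500
  p5 <- generate_depth_profile(500, seed = 5)
  r <- cor(p5$depth, p5$dapi_fraction)
  expect_gt(r, 0.78)
  expect_lt(r, 0.87)
})

test_that("invalid correlation targets are rejected", {
  bad <- default_morphology_correlations()
  bad[1, 2] <- 0.5  # asymmetric
  expect_error(generate_depth_profile(10, correlation_targets = bad),
               "symmetric")
  npd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  dimnames(npd) <- list(c("depth", "a", "b"), c("depth", "a", "b"))
  expect_error(generate_depth_profile(10, correlation_targets = npd),
               "positive semi-definite")
})
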