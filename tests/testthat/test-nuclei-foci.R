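# Nucleus segmentation, inclusion rules, focus counting, cfoci and binary
# positivity.

test_that("segmentation handles flat rasters and recovers disjoint nuclei", {
  expect_warning(seg0 <- segment_nuclei(matrix(0.2, 64, 64), 0.25),
                 "no nuclei")
  expect_identical(nrow(seg0$records), 0L)

  sc <- generate_foci_scene(20, width = 448, foci_counts = 0,
                            noise_level = 0.02, seed = 8)
  seg <- segment_nuclei(sc$dapi, pixel_size = 0.25)
  expect_identical(nrow(seg$records), 20L)
  # match segmented to truth nuclei by centroid proximity; areas within 5%
  truth <- sc$truth$nuclei
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((seg$records$x - truth$x[i])^2 +
                (seg$records$y - truth$y[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 5)
    expect_lt(abs(seg$records$area_um2[j] - truth$area_um2[i]) /
                truth$area_um2[i], 0.05)
  }
})

test_that("watershed splits touching nucleus pairs", {
  sc <- generate_foci_scene(2, width = 192, foci_counts = 0,
                            touching_pairs = 1, noise_level = 0.01,
                            seed = 21)
  seg <- segment_nuclei(sc$dapi, pixel_size = 0.25, split_touching = TRUE)
  expect_identical(nrow(seg$records), 2L)
  # truth centroids land in two distinct labels
  labs <- seg$labels[cbind(round(sc$truth$nuclei$y),
                           round(sc$truth$nuclei$x))]
  expect_length(unique(labs), 2L)
  expect_true(all(labs > 0L))

  merged <- segment_nuclei(sc$dapi, pixel_size = 0.25,
                           split_touching = FALSE)
  expect_identical(nrow(merged$records), 1L)
})

test_that("inclusion applies the strict area rule and the exclusion list", {
  rec <- data.frame(label = 1:5,
                    area_um2 = c(60, 65, 65.0001, 80, 100),
                    on_border = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- apply_inclusion(rec, foci_params(area_min = 65),
                         border_policy = "drop")
  expect_identical(out$exclusion_reason,
                   c("below_area", "below_area", "none", "none", "border"))
  expect_identical(out$included, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  kept <- apply_inclusion(rec, foci_params(area_min = 65),
                          border_policy = "keep")
  expect_true(kept$included[5])

  listed <- apply_inclusion(rec, foci_params(area_min = 65),
                            exclusion_list = c(4L), border_policy = "keep")
  expect_identical(listed$exclusion_reason[4], "listed_excluded")
  expect_error(apply_inclusion(rec, foci_params(), exclusion_list = 99L),
               "99")
})

test_that("raising area_min never increases the included count", {
  sc <- generate_foci_scene(15, width = 384, foci_counts = 1, seed = 13)
  seg <- segment_nuclei(sc$dapi, 0.25)
  n_prev <- Inf
  for (amin in c(0, 50, 65, 90, 120, 200)) {
    n <- sum(apply_inclusion(seg$records,
                             foci_params(area_min = amin))$included)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("count_foci matches trivial cases", {
  mask <- matrix(0L, 48, 48)
  mask[10:38, 10:38] <- 1L
  flat <- matrix(0.1, 48, 48)
  expect_identical(unname(count_foci(flat, mask, foci_params())), 0L)

  one <- flat
  xs <- 1:48
  one <- one + 0.5 * exp(-(outer((xs - 24)^2, (xs - 24)^2, `+`)) / (2 * 4))
  expect_identical(unname(count_foci(one, mask, foci_params())), 1L)
  expect_error(count_foci(matrix(0, 10, 10), mask, foci_params()),
               "co-registered")
})

test_that("well-separated spots are counted exactly, matching the oracle", {
  p <- foci_params()
  for (seed in c(7, 70)) {
    sc <- generate_foci_scene(5, width = 256, foci_counts = 12,
                              min_foci_separation = 4 * 2, seed = seed)
    counts <- count_foci(sc$gamma, sc$truth$mask, p)
    expect_identical(unname(counts), rep(12L, 5))
    expect_identical(unname(counts),
                     oracle_count_foci(sc$gamma, sc$truth$mask, p))
  }
})

test_that("counter equals the exhaustive oracle on noisy mixed scenes", {
  p <- foci_params()
  for (seed in 1:5) {
    sc <- generate_foci_scene(4, width = 192, foci_mean = 5,
                              nucleus_area_mean = 90, nucleus_area_sd = 15,
                              noise_level = 0.03,
                              class_probs = c(normal = 0.8, apoptotic = 0.2,
                                              mitotic = 0),
                              seed = seed)
    expect_identical(unname(count_foci(sc$gamma, sc$truth$mask, p)),
                     oracle_count_foci(sc$gamma, sc$truth$mask, p))
  }
})

test_that("cfoci obeys its defining identities", {
  rec <- data.frame(label = 1:4, area_um2 = c(100, 200, 50, 100),
                    foci_count = c(10, 10, 4, 0),
                    included = TRUE)
  out <- compute_cfoci(rec, mean_area = 100)
  expect_equal(out$cfoci, c(10, 5, 8, 0))

  # equal areas: mean cfoci equals mean foci exactly
  eq <- data.frame(label = 1:6, area_um2 = 120,
                   foci_count = c(3, 9, 1, 0, 7, 2), included = TRUE)
  ceq <- compute_cfoci(eq)
  expect_equal(mean(ceq$cfoci), mean(eq$foci_count), tolerance = 1e-12)

  # conservation: sum(cfoci * area / mean_area) = sum(foci)
  set.seed(99)
  rnd <- data.frame(label = 1:50,
                    area_um2 = runif(50, 66, 200),
                    foci_count = rpois(50, 8), included = TRUE)
  crnd <- compute_cfoci(rnd)
  m <- attr(crnd, "mean_area")
  expect_equal(sum(crnd$cfoci * crnd$area_um2 / m), sum(rnd$foci_count),
               tolerance = 1e-9)

  expect_error(compute_cfoci(data.frame(label = 1, area_um2 = 0,
                                        foci_count = 1, included = TRUE)),
               "area")
})

test_that("binary positivity separates pan-bright from background nuclei", {
  mask <- matrix(0L, 64, 64)
  mask[5:20, 5:20] <- 1L
  mask[30:45, 30:45] <- 2L
  flat <- matrix(0.05, 64, 64)
  expect_equal(score_binary_positivity(flat, mask)$fraction, 0)

  bright <- flat
  bright[mask > 0L] <- 0.5
  expect_equal(score_binary_positivity(bright, mask)$fraction, 1)

  expect_warning(
    r <- score_binary_positivity(flat, matrix(0L, 64, 64)),
    "undefined")
  expect_true(is.na(r$fraction))
})

test_that("positive fraction recovers the rendered truth fraction", {
  sc <- generate_foci_scene(40, width = 512, foci_counts = 0,
                            class_probs = c(normal = 0.6, apoptotic = 0.4,
                                            mitotic = 0),
                            seed = 31)
  truth_frac <- mean(sc$truth$nuclei$class != "normal")
  res <- score_binary_positivity(sc$gamma, sc$truth$mask, threshold = 2)
  expect_equal(res$fraction, truth_frac, tolerance = 0.025)
})

test_that("excluded nuclei carry zero foci in the pipeline output", {
  sc <- generate_foci_scene(8, width = 320, foci_counts = 6, seed = 17)
  res <- foci_pipeline(sc$dapi, sc$gamma,
                       params = foci_params(area_min = 65),
                       exclusion_list = 2L)
  rec <- res$records
  expect_true(all(rec$foci_count[!rec$included] == 0L))
  expect_identical(rec$exclusion_reason[rec$label == 2L], "listed_excluded")
  expect_true(all(rec$cfoci[!rec$included] == 0))
})
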