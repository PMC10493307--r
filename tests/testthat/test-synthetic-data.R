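# The generator's ground truth is defined on the continuous centerline
# tree; these tests pin it against closed-form geometry and dense-sampling
# oracles, and check the degradation factors behave as documented.

star_model <- function(len = 22)
  astrocyte_model(soma_radius = 3, primary_processes = 4, branch_prob = 0,
                  segment_mean = len, segment_sd = 0, angle_spread = 0,
                  max_depth = 1)

test_that("four-ray star has exact analytic ground truth", {
  g <- generate_astrocyte(star_model(), seed = 1, pixel_size = 0.25)
  expect_identical(g$truth$n_branches, 4L)
  expect_identical(g$truth$n_endpoints, 4L)
  expect_equal(g$truth$total_length, 88)
  expect_equal(g$truth$sholl_counts,
               c(4L, 4L, 4L, 4L, rep(0L, 9)))
  # centerline hull of a 22-um 4-ray star: square with diagonal 44
  expect_equal(g$truth$cha, 2 * 22^2, tolerance = 1e-3)
})

test_that("soma-only and degenerate models behave as specified", {
  g <- generate_astrocyte(astrocyte_model(primary_processes = 0),
                          seed = 1, pixel_size = 0.5)
  expect_identical(g$truth$n_branches, 0L)
  expect_identical(g$truth$n_endpoints, 0L)
  expect_equal(g$truth$total_length, 0)
  expect_true(sum(g$mask$pixels) > 0)

  m0 <- astrocyte_model(primary_processes = 0)
  m0$soma_radius <- 0
  expect_error(generate_astrocyte(m0, seed = 1),
               "zero primary processes and zero soma")

  expect_error(generate_astrocyte(astrocyte_model(), seed = 1,
                                  pixel_size = 0.5, canvas_um = 30),
               "canvas overflow along [xy]")
})

test_that("ground-truth Sholl counts match the dense-sampling oracle", {
  m <- astrocyte_model(primary_processes = 6, branch_prob = 0.5,
                       segment_mean = 8, segment_sd = 2, max_depth = 3)
  for (s in c(42, 1:8)) {
    g <- generate_astrocyte(m, seed = s, pixel_size = 0.5)
    expect_equal(g$truth$sholl_counts,
                 oracle_ring_crossings(g$truth$segments,
                                       g$truth$sholl_radii),
                 info = paste("seed", s))
  }
})

test_that("total length is additive over recorded segments, exactly", {
  for (s in 1:10) {
    g <- generate_astrocyte(astrocyte_model(), seed = s, pixel_size = 0.5)
    tr <- g$truth$segments
    expect_equal(g$truth$total_length,
                 sum(sqrt((tr$x - tr$x0)^2 + (tr$y - tr$y0)^2)),
                 tolerance = 1e-12)
  }
})

test_that("ground-truth Sholl counts are invariant under rigid rotation", {
  g <- generate_astrocyte(astrocyte_model(), seed = 5, pixel_size = 0.5)
  tr <- g$truth$segments
  for (th in c(0.3, 1.1, 2.5)) {
    rot <- tr
    rot$x0 <- cos(th) * tr$x0 - sin(th) * tr$y0
    rot$y0 <- sin(th) * tr$x0 + cos(th) * tr$y0
    rot$x <- cos(th) * tr$x - sin(th) * tr$y
    rot$y <- sin(th) * tr$x + cos(th) * tr$y
    expect_equal(astromorph:::segment_ring_crossings(rot,
                                                     g$truth$sholl_radii),
                 g$truth$sholl_counts)
  }
})

test_that("atrophy strictly shrinks length; deramification never adds branches", {
  base <- astrocyte_model()
  for (s in 1:12) {
    lens <- sapply(c(1, 0.8, 0.6, 0.4), function(f) {
      m <- astrocyte_model(atrophy_factor = f)
      generate_astrocyte(m, seed = s, pixel_size = 1)$truth$total_length
    })
    expect_true(all(diff(lens) < 0), info = paste("seed", s))
    brs <- sapply(c(1, 0.8, 0.5, 0.3), function(f) {
      m <- astrocyte_model(deramification_factor = f)
      generate_astrocyte(m, seed = s, pixel_size = 1)$truth$n_branches
    })
    expect_true(all(diff(brs) <= 0), info = paste("seed", s))
  }
})

test_that("noise-free add_noise thresholds back to the input mask", {
  g <- generate_astrocyte(astrocyte_model(), seed = 2, pixel_size = 0.5)
  img <- add_noise(g$mask, 0, 0, poisson = FALSE, seed = 1)
  for (level in c(1, 100, 199))
    expect_identical(img$data >= level, g$mask$pixels)
})

test_that("salt-and-pepper flips match the binomial expectation", {
  g <- generate_astrocyte(astrocyte_model(), seed = 2, pixel_size = 0.5)
  frac <- 0.01
  img <- add_noise(g$mask, frac, 0, seed = 11)
  bg <- !g$mask$pixels
  flipped <- sum(img$data[bg] > 0)
  n <- sum(bg)
  expect_lt(abs(flipped - frac * n), 3 * sqrt(n * frac * (1 - frac)))
})

test_that("add_noise is deterministic for a fixed seed and validates input", {
  g <- generate_astrocyte(astrocyte_model(), seed = 2, pixel_size = 0.5)
  a <- add_noise(g$mask, 0.02, 5, poisson = TRUE, seed = 3)
  b <- add_noise(g$mask, 0.02, 5, poisson = TRUE, seed = 3)
  expect_identical(a$data, b$data)
  expect_error(add_noise(g$mask, 1), "salt_pepper_fraction")
})

test_that("generator masks are a single connected component", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    g <- generate_astrocyte(astrocyte_model(), seed = s, pixel_size = 0.5)
    co <- which(g$mask$pixels, arr.ind = TRUE)
    edges <- astromorph:::.pixel_edges(co, dim(g$mask$pixels))
    keep <- rep(TRUE, nrow(co))
    expect_identical(astromorph:::.count_components(keep, edges), 1L)
  }
})

test_that("simulated cohorts are deterministic and recover their means", {
  sp <- cohort_spec(seed = 9)
  expect_identical(simulate_cohort(sp), simulate_cohort(sp))

  big <- cohort_spec(n = 5000, seed = 4)
  ch <- simulate_cohort(big)
  for (g in c("sham", "PID", "EA"))
    for (m in colnames(big$means))
      expect_lt(abs(mean(ch[ch$group == g, m]) - big$means[g, m]), 0.5)
  expect_true(all(ch$spt >= 0 & ch$spt <= 100))
  expect_true(all(ch$si_ratio >= 0))
  expect_true(all(ch$epm_open >= 0 & ch$fst_immobility >= 0))
})

test_that("a null cohort yields composite Z group means near zero", {
  mu <- .default_cohort_means(); sdm <- .default_cohort_sds()
  mu["PID", ] <- mu["sham", ]; mu["EA", ] <- mu["sham", ]
  sdm["PID", ] <- sdm["sham", ]; sdm["EA", ] <- sdm["sham", ]
  ch <- simulate_cohort(cohort_spec(n = 50, means = mu, sds = sdm,
                                    seed = 21))
  z <- zscore_table(ch)
  gm <- tapply(z$z_composite, z$group, mean)
  expect_true(all(abs(gm) < 4 / sqrt(50)))
})
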