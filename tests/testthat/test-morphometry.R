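# Skeletonization, skeleton measurement, convex hulls, scenario labels.

test_that("a thick bar thins to its 1-px centerline", {
  px <- matrix(FALSE, 9, 26)
  px[4:6, 3:22] <- TRUE
  sk <- skeletonize(binary_mask(px, 1))
  expect_true(all(colSums(sk$pixels) <= 1))
  a <- analyze_skeleton(sk)
  expect_identical(a$n_branches, 1L)
  expect_identical(a$n_endpoints, 2L)
  expect_gt(a$total_length, 15); expect_lt(a$total_length, 22)
  # no 2x2 foreground block anywhere
  s <- sk$pixels
  blocks <- s[-1, -1] & s[-nrow(s), -1] & s[-1, -ncol(s)] &
    s[-nrow(s), -ncol(s)]
  expect_false(any(blocks))
})

test_that("a filled disk collapses to a degenerate skeleton inside itself", {
  n <- 31
  d <- sqrt(outer((1:n - 16)^2, (1:n - 16)^2, `+`))
  px <- d <= 10
  sk <- skeletonize(binary_mask(px, 1))
  expect_lte(sum(sk$pixels), 12)
  expect_true(all(px[sk$pixels]))
})

test_that("skeletonization preserves components and holes", {
  skip_if_not_installed("igraph")
  # two blobs and a ring (one hole)
  px <- matrix(FALSE, 40, 60)
  d1 <- sqrt(outer((1:40 - 12)^2, (1:60 - 12)^2, `+`))
  px[d1 <= 6] <- TRUE
  d2 <- sqrt(outer((1:40 - 25)^2, (1:60 - 45)^2, `+`))
  px[d2 >= 6 & d2 <= 11] <- TRUE
  comp_count <- function(p) {
    co <- which(p, arr.ind = TRUE)
    astromorph:::.count_components(rep(TRUE, nrow(co)),
                                   astromorph:::.pixel_edges(co, dim(p)))
  }
  sk <- skeletonize(binary_mask(px, 1))
  expect_identical(comp_count(sk$pixels), comp_count(px))

  # a lone ring keeps its hole: the skeleton is a closed loop, no endpoints
  ring <- matrix(FALSE, 40, 40)
  dr <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, `+`))
  ring[dr >= 6 & dr <= 11] <- TRUE
  ra <- analyze_skeleton(skeletonize(binary_mask(ring, 1)))
  expect_identical(ra$n_endpoints, 0L)
  expect_gte(ra$n_branches, 1L)
  expect_error(skeletonize(binary_mask(matrix(FALSE, 5, 5), 1)),
               "empty mask")
})

test_that("rasterized star skeleton hugs the generator centerlines", {
  m <- astrocyte_model(soma_radius = 3, primary_processes = 4,
                       branch_prob = 0, segment_mean = 22, segment_sd = 0,
                       angle_spread = 0, max_depth = 1)
  g <- generate_astrocyte(m, seed = 1, pixel_size = 0.25)
  sk <- skeletonize(g$mask)
  co <- which(sk$pixels, arr.ind = TRUE)
  x <- (co[, 2] - 1) * 0.25 - g$truth$soma_center[["x"]]
  y <- (co[, 1] - 1) * 0.25 - g$truth$soma_center[["y"]]
  # distance of each skeleton pixel to the nearest axis ray
  dh <- ifelse(abs(x) <= 22.2, abs(y), Inf)
  dv <- ifelse(abs(y) <= 22.2, abs(x), Inf)
  expect_lt(max(pmin(dh, dv)), 0.26)
})

test_that("line and cross skeletons measure exactly", {
  px <- matrix(FALSE, 5, 15); px[3, 3:13] <- TRUE
  a <- analyze_skeleton(as_skeleton(px, 1))
  expect_identical(a$n_endpoints, 2L)
  expect_identical(a$n_branches, 1L)
  expect_equal(a$total_length, 10)

  cr <- matrix(FALSE, 25, 25)
  cr[13, 3:23] <- TRUE; cr[3:23, 13] <- TRUE
  a <- analyze_skeleton(as_skeleton(cr, 1))
  expect_identical(a$n_endpoints, 4L)
  expect_identical(a$n_branches, 4L)
  expect_identical(a$n_junctions, 1L)
  expect_equal(a$total_length, 40)
})

test_that("skeleton measurement agrees with the independent pixel-graph oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    g <- generate_astrocyte(astrocyte_model(), seed = s, pixel_size = 0.5)
    sk <- skeletonize(g$mask)
    a <- analyze_skeleton(sk)
    o <- oracle_skeleton(sk$pixels, sk$pixel_size)
    expect_identical(a$n_branches, as.integer(o$n_branches))
    expect_identical(a$n_endpoints, as.integer(o$n_endpoints))
    expect_lt(abs(a$total_length - o$total_length), 1e-9)
  }
})

test_that("endpoint/junction labels equal reduced-graph degrees everywhere", {
  g <- generate_astrocyte(astrocyte_model(), seed = 3, pixel_size = 0.5)
  sk <- skeletonize(g$mask)
  adj <- astromorph:::.skeleton_adjacency(sk$pixels)
  deg <- lengths(adj$adj)
  cls <- sk$node_class[adj$which]
  expect_true(all(cls[deg == 1] == 1L))
  expect_true(all(cls[deg == 2] == 2L))
  expect_true(all(cls[deg >= 3] == 3L))
})

test_that("pipeline metrics match continuous ground truth on clean rasters", {
  # sparse, sector-separated cells; junction clusters fused at twice the
  # process width, calibrated step weights for unbiased digital length
  m <- astrocyte_model(soma_radius = 4, primary_processes = 5,
                       branch_prob = 0.4, segment_mean = 12,
                       segment_sd = 2, angle_spread = 45, max_depth = 3)
  for (s in 1:15) {
    g <- generate_astrocyte(m, seed = s, pixel_size = 0.2)
    a <- analyze_skeleton(skeletonize(g$mask),
                          fuse_junctions_um = 2 * m$process_width,
                          calibrate_lengths = TRUE)
    expect_lte(abs(a$n_branches - g$truth$n_branches), 1)
    expect_lte(abs(a$n_endpoints - g$truth$n_endpoints), 1)
    expect_lt(abs(a$total_length - g$truth$total_length) /
                g$truth$total_length, 0.05)
  }
})

test_that("total length is stable under rotations and flips", {
  g <- generate_astrocyte(astrocyte_model(), seed = 6, pixel_size = 0.5)
  base <- analyze_skeleton(skeletonize(g$mask))$total_length
  variants <- list(t(g$mask$pixels),
                   g$mask$pixels[nrow(g$mask$pixels):1, ],
                   g$mask$pixels[, ncol(g$mask$pixels):1])
  for (v in variants) {
    l <- analyze_skeleton(skeletonize(binary_mask(v, 0.5)))$total_length
    expect_lt(abs(l - base) / base, 0.05)
  }
})

test_that("hull metrics are exact for squares and near-exact for disks", {
  px <- matrix(FALSE, 15, 15); px[3:13, 3:13] <- TRUE  # 10x10 px span
  h <- convex_hull_metrics(binary_mask(px, 1))
  expect_equal(h$chp, 40)
  expect_equal(h$cha, 100)

  n <- 51
  d <- sqrt(outer((1:n - 26)^2, (1:n - 26)^2, `+`))
  disk <- binary_mask(d <= 20, 1)
  h <- convex_hull_metrics(disk)
  expect_lt(abs(h$chp - 2 * pi * 20) / (2 * pi * 20), 0.02)
  expect_lt(abs(h$cha - pi * 400) / (pi * 400), 0.02)
})

test_that("hulls equal the brute-force monotone-chain oracle on random masks", {
  set.seed(5)
  for (i in 1:20) {
    px <- matrix(runif(30 * 30) < 0.12, 30, 30)
    if (sum(px) < 5) next
    got <- convex_hull_metrics(binary_mask(px, 0.7))
    want <- oracle_hull(px, 0.7)
    expect_equal(got$chp, want$chp, tolerance = 1e-9)
    expect_equal(got$cha, want$cha, tolerance = 1e-9)
  }
})

test_that("adding a pixel never shrinks the hull area; degenerate masks warn", {
  set.seed(9)
  px <- matrix(FALSE, 20, 20)
  px[cbind(sample(20, 8), sample(20, 8))] <- TRUE
  base <- convex_hull_metrics(binary_mask(px, 1))$cha
  for (i in 1:10) {
    px2 <- px
    px2[sample(400, 1)] <- TRUE
    expect_gte(convex_hull_metrics(binary_mask(px2, 1))$cha, base)
  }

  lin <- matrix(FALSE, 10, 10); lin[5, 2:8] <- TRUE
  expect_warning(h <- convex_hull_metrics(binary_mask(lin, 2)),
                 "degenerate")
  expect_equal(h$chp, 2 * 6 * 2)
  expect_equal(h$cha, 0)
})

test_that("scenario classification separates atrophy from deramification", {
  ref <- list(mean = c(total_length = 500, n_branches = 40,
                       n_endpoints = 20),
              sd = c(total_length = 50, n_branches = 6, n_endpoints = 4))
  at_mean <- list(total_length = 500, n_branches = 40, n_endpoints = 20)
  expect_identical(classify_scenario(at_mean, ref), "none")
  short <- list(total_length = 350, n_branches = 40, n_endpoints = 20)
  expect_identical(classify_scenario(short, ref), "atrophy")
  sparse <- list(total_length = 500, n_branches = 20, n_endpoints = 8)
  expect_identical(classify_scenario(sparse, ref), "deramification")
  both <- list(total_length = 300, n_branches = 20, n_endpoints = 8)
  expect_identical(classify_scenario(both, ref), "combined")
  expect_error(classify_scenario(both, NULL), "reference")
})
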