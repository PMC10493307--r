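# Soma localization, Sholl intersection profiles, distal-window sums.

test_that("the soma centre is the largest inscribed disk centre", {
  n <- 41
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, `+`))
  ctr <- find_soma_center(binary_mask(d <= 8, 0.5))
  expect_lte(abs(ctr[["x"]] - 20 * 0.5), 0.5)
  expect_lte(abs(ctr[["y"]] - 20 * 0.5), 0.5)

  for (s in 1:5) {
    g <- generate_astrocyte(astrocyte_model(), seed = s, pixel_size = 0.5)
    ctr <- find_soma_center(g$mask)
    off <- sqrt((ctr[["x"]] - g$truth$soma_center[["x"]])^2 +
                  (ctr[["y"]] - g$truth$soma_center[["y"]])^2)
    expect_lt(off, astrocyte_model()$soma_radius)
  }
  expect_error(find_soma_center(binary_mask(matrix(FALSE, 4, 4), 1)),
               "empty")
})

test_that("two-blob masks resolve to the larger disk with a deterministic tie-break", {
  px <- matrix(FALSE, 60, 60)
  d1 <- sqrt(outer((1:60 - 15)^2, (1:60 - 15)^2, `+`))
  d2 <- sqrt(outer((1:60 - 45)^2, (1:60 - 45)^2, `+`))
  big_small <- (d1 <= 9) | (d2 <= 5)
  ctr <- find_soma_center(binary_mask(big_small, 1))
  expect_equal(unname(ctr), c(14, 14))

  equal <- (d1 <= 7) | (d2 <= 7)
  ctr <- find_soma_center(binary_mask(equal, 1))
  expect_equal(unname(ctr), c(14, 14))  # lowest (y, x) wins the tie
})

test_that("the 4-ray star yields the analytic profile", {
  m <- astrocyte_model(soma_radius = 3, primary_processes = 4,
                       branch_prob = 0, segment_mean = 22, segment_sd = 0,
                       angle_spread = 0, max_depth = 1)
  g <- generate_astrocyte(m, seed = 1, pixel_size = 0.25)
  pr <- sholl_profile(skeletonize(g$mask), find_soma_center(g$mask))
  expect_identical(pr$counts, c(4L, 4L, 4L, 4L, rep(0L, 9)))
  expect_identical(pr$total, 16L)
  expect_identical(pr$total, sum(pr$counts))
})

test_that("rings beyond the cell extent count zero", {
  m <- astrocyte_model(max_depth = 2, segment_mean = 6, segment_sd = 1)
  g <- generate_astrocyte(m, seed = 2, pixel_size = 0.5)
  pr <- sholl_profile(skeletonize(g$mask), find_soma_center(g$mask),
                      step_um = 30, n_radii = 5)
  expect_true(all(pr$counts[2:5] == 0L))
})

test_that("a single straight ray crosses every ring short of its tip once", {
  for (ang in c(0, 18, 45, 71, 133, 260)) {
    rs <- ray_skeleton(22, ang)
    pr <- sholl_profile(rs$skel, rs$center)
    expect_identical(pr$counts[1:4], rep(1L, 4))
    expect_true(all(pr$counts[5:13] == 0L))
  }
})

test_that("profiles are invariant under 90-degree rotation of skeleton and centre", {
  g <- generate_astrocyte(astrocyte_model(), seed = 9, pixel_size = 0.5)
  sk <- skeletonize(g$mask)
  ctr <- find_soma_center(g$mask)
  pr <- sholl_profile(sk, ctr)
  # rotate 90 degrees: new[i, j] = old[j, n + 1 - i]
  n <- nrow(sk$pixels)
  rot <- t(sk$pixels)[n:1, ]
  ctr2 <- c(x = ctr[["y"]], y = (n - 1) * 0.5 - ctr[["x"]])
  pr2 <- sholl_profile(as_skeleton(rot, 0.5), ctr2)
  expect_identical(pr$counts, pr2$counts)
})

test_that("profile counts match the continuous crossing oracle ring by ring", {
  m <- astrocyte_model(soma_radius = 3, primary_processes = 4,
                       branch_prob = 1, segment_mean = 8.6,
                       segment_sd = 0.2, angle_spread = 60,
                       process_width = 1, max_depth = 2)
  for (s in 1:25) {
    g <- generate_astrocyte(m, seed = s, pixel_size = 0.2)
    pr <- sholl_profile(skeletonize(g$mask), find_soma_center(g$mask))
    expect_true(all(abs(pr$counts - g$truth$sholl_counts) <= 1),
                info = paste("seed", s))
  }
})

test_that("sholl_profile validates its arguments", {
  rs <- ray_skeleton(10, 30)
  expect_error(sholl_profile(rs$skel, rs$center, n_radii = 0), "n_radii")
  expect_error(sholl_profile(rs$skel, c(x = -5, y = 2)), "outside")
})

test_that("distal sums are inclusive window sums on the radius grid", {
  rs <- ray_skeleton(22, 30)
  pr <- sholl_profile(rs$skel, rs$center)
  pr$counts <- c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 3L, 1L, 0L, 0L, 0L, 0L)
  pr$total <- sum(pr$counts)
  expect_identical(distal_sum(pr, c(35, 45)), 9L)
  expect_identical(distal_sum(pr, c(5, 65)), pr$total)
  expect_identical(distal_sum(pr, c(50, 60)), 0L)
  expect_error(distal_sum(pr, c(33, 45)), "radius grid")
})

test_that("deramification never raises the expected total intersections", {
  totals <- sapply(1:20, function(s) {
    full <- generate_astrocyte(astrocyte_model(), seed = s,
                               pixel_size = 1)$truth
    der <- generate_astrocyte(astrocyte_model(deramification_factor = 0.6),
                              seed = s, pixel_size = 1)$truth
    c(full = sum(full$sholl_counts), der = sum(der$sholl_counts))
  })
  # paired sign test: reductions should dominate
  expect_gte(sum(totals["der", ] <= totals["full", ]), 18)
  expect_lt(mean(totals["der", ]), mean(totals["full", ]))
})
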