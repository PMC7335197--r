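test_that("pixel tuning map inherits axon values and excludes shared pixels", {
  ax1 <- list(axon_id = 1, pixel_mask = cbind(1:10, rep(1, 10)))
  resp <- data.frame(axon_id = 1, amp_c2 = 2, amp_b2 = 0.5, wsi = 0.9)
  map <- pixel_tuning_map(list(ax1), resp)
  expect_equal(nrow(map), 10)
  expect_true(all(map$pixel_wsi == 0.9))
  expect_true(all(map$response_c2 == 2))

  # two axons overlapping on 2 pixels: those pixels vanish
  ax2 <- list(axon_id = 2, pixel_mask = cbind(9:12, rep(1, 4)))
  resp2 <- rbind(resp, data.frame(axon_id = 2, amp_c2 = 0, amp_b2 = 1,
                                  wsi = -0.8))
  map2 <- pixel_tuning_map(list(ax1, ax2), resp2)
  expect_equal(nrow(map2), 10)
  expect_false(any(paste(map2$row, map2$col) %in% c("9 1", "10 1")))

  expect_equal(nrow(pixel_tuning_map(list(), resp)), 0)
})

test_that("confidence ellipse geometry follows the chi-square scaling", {
  # points with exactly unit sample covariance -> area = pi * chi2_{0.9,2}
  set.seed(2)
  pts <- matrix(rnorm(400), 200, 2)
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- pts %*% solve(chol(cov(pts)))
  e <- fit_confidence_ellipse(pts)
  expect_equal(e$area, pi * qchisq(0.9, 2), tolerance = 1e-9)
  expect_equal(e$area, 14.46766, tolerance = 1e-4)

  # isotropic scaling by k scales the area by k^2
  e3 <- fit_confidence_ellipse(pts * 3)
  expect_equal(e3$area, 9 * e$area, tolerance = 1e-9)

  expect_error(fit_confidence_ellipse(cbind(1:5, 2 * (1:5))), "degenerate")
  expect_error(fit_confidence_ellipse(cbind(1, 1)), "at least 3")
})

test_that("fitted 90% ellipse contains 90% of Gaussian samples", {
  set.seed(7)
  n <- 1e5
  pts <- cbind(rnorm(n, 3, 2), rnorm(n, -1, 0.5) + 0.3 * rnorm(n, 3, 2))
  e <- fit_confidence_ellipse(pts, 0.9)
  d <- sweep(pts, 2, e$center)
  u <- d %*% e$orientation
  inside <- (u[, 1] / e$semi_axes[1])^2 + (u[, 2] / e$semi_axes[2])^2 <= 1
  expect_lt(abs(mean(inside) - 0.9), 0.01)
})

test_that("overlap index spans its denotation: identical 1, disjoint 0, nested 0.4", {
  e <- make_ellipse(c(0, 0), c(2, 1), angle = 0.3)
  expect_equal(ellipse_overlap_index(e, e)$overlap_index, 1, tolerance = 1e-9)

  far <- make_ellipse(c(400, 0), c(2, 1))
  expect_equal(ellipse_overlap_index(e, far)$overlap_index, 0)

  # concentric circles with areas A and 4A: intersection A, mean 2.5A
  c1 <- make_ellipse(c(5, 5), c(1, 1))
  c2 <- make_ellipse(c(5, 5), c(2, 2))
  expect_equal(ellipse_overlap_index(c1, c2)$overlap_index, 0.4,
               tolerance = 1e-6)
})

test_that("overlap index is invariant under rigid motions and bounded by containment", {
  e1 <- make_ellipse(c(0, 0), c(3, 1), angle = 0.5)
  e2 <- make_ellipse(c(1.5, 0.5), c(2, 1.2), angle = -0.4)
  base <- ellipse_overlap_index(e1, e2)$overlap_index

  shift <- c(17, -9); rot <- 1.1
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  move <- function(e) make_ellipse(as.vector(Rm %*% e$center) + shift,
                                   e$semi_axes,
                                   angle = atan2(e$orientation[2, 1],
                                                 e$orientation[1, 1]) + rot)
  moved <- ellipse_overlap_index(move(e1), move(e2))$overlap_index
  expect_equal(moved, base, tolerance = 1e-6)

  # bound: index <= min(A1, A2) / mean(A1, A2), equality iff containment
  a1 <- e1$area; a2 <- e2$area
  expect_lte(base, min(a1, a2) / mean(c(a1, a2)) + 1e-9)
  nested <- ellipse_overlap_index(make_ellipse(c(0, 0), c(1, 1)),
                                  make_ellipse(c(0.2, 0), c(4, 4)))
  a <- pi; A <- 16 * pi
  expect_equal(nested$overlap_index, min(a, A) / mean(c(a, A)),
               tolerance = 1e-4)
})

test_that("polygon clipping agrees with a Monte-Carlo oracle", {
  set.seed(12)
  for (i in 1:8) {
    e1 <- make_ellipse(runif(2, -1, 1), sort(runif(2, 0.5, 3)),
                       angle = runif(1, 0, pi))
    e2 <- make_ellipse(e1$center + runif(2, -1, 1) * max(e1$semi_axes),
                       sort(runif(2, 0.5, 3)), angle = runif(1, 0, pi))
    poly <- ellipse_overlap_index(e1, e2)$intersection_area
    mc <- mc_intersection_area(e1, e2, n_points = 2e5, seed = i)
    expect_equal(poly, mc, tolerance = 0.02)
  }
})

test_that("tuned VPM-like pixels form two separated spatial clusters", {
  pop <- population_config(n_axons = 40,
                           class_proportions = c(VPM_like = 1, POmFO_like = 0,
                                                 POmHO_like = 0))
  truth <- generate_axon_population(pop, seed = 4)
  # ground-truth map: every axon pixel labeled by its true WSI
  resp <- data.frame(axon_id = vapply(truth, `[[`, numeric(1), "axon_id"),
                     amp_c2 = 1, amp_b2 = 1,
                     wsi = vapply(truth, `[[`, numeric(1), "true_wsi"))
  axons <- lapply(truth, function(a)
    list(axon_id = a$axon_id, pixel_mask = do.call(rbind, a$segment_masks)))
  map <- pixel_tuning_map(axons, resp)
  c2 <- map[map$pixel_wsi > 0.75, c("row", "col")]
  b2 <- map[map$pixel_wsi < -0.75, c("row", "col")]
  expect_gt(nrow(c2), 10); expect_gt(nrow(b2), 10)
  centroid_dist <- sqrt(sum((colMeans(c2) - colMeans(b2))^2))
  spread <- mean(c(sd(c2$row), sd(c2$col), sd(b2$row), sd(b2$col)))
  expect_gt(centroid_dist, spread)

  ov <- field_overlap(map)
  expect_lt(ov$overlap_index, 0.5)
})
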