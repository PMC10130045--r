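test_that("convex hull handles canonical configurations", {
  tri <- cbind(c(0, 2, 1), c(0, 0, 2))
  h <- convex_hull(tri)
  expect_equal(nrow(h), 3)
  expect_setequal(apply(h, 1, paste, collapse = ","),
                  apply(tri, 1, paste, collapse = ","))
  # unit square corners plus interior centre: centre excluded
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  hs <- convex_hull(sq)
  expect_equal(nrow(hs), 4)
  expect_false(any(hs[, 1] == 0.5))
  # counter-clockwise orientation (positive signed area)
  area2 <- sum(hs[, 1] * hs[c(2:4, 1), 2] - hs[c(2:4, 1), 1] * hs[, 2])
  expect_gt(area2, 0)
  expect_error(convex_hull(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(convex_hull(rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("monotone-chain hull matches brute force and grDevices::chull", {
  set.seed(31)
  for (rep in 1:50) {
    pts <- cbind(rnorm(50), rnorm(50))
    h <- convex_hull(pts)
    bf <- brute_hull_vertices(pts)
    expect_setequal(apply(h, 1, paste, collapse = ","),
                    apply(bf, 1, paste, collapse = ","))
    ch <- pts[grDevices::chull(pts), , drop = FALSE]
    expect_setequal(apply(h, 1, paste, collapse = ","),
                    apply(ch, 1, paste, collapse = ","))
  }
})

test_that("point-in-polygon counts interior, edge and vertex as inside", {
  tri <- convex_hull(cbind(c(0, 4, 2), c(0, 0, 3)))
  expect_true(point_in_polygon(c(2, 1), tri))       # centroid-ish
  expect_false(point_in_polygon(c(100, 100), tri))  # far outside
  expect_true(point_in_polygon(c(2, 0), tri))       # edge midpoint
  expect_true(point_in_polygon(c(0, 0), tri))       # vertex
  expect_false(point_in_polygon(c(2, -0.001), tri))
  expect_error(point_in_polygon(c(0, 0), tri[1:2, ]), "degenerate")
})

test_that("ray casting agrees with the winding-number oracle", {
  set.seed(17)
  for (rep in 1:20) {
    hull <- convex_hull(cbind(rnorm(12), rnorm(12)))
    pts <- cbind(runif(40, -3, 3), runif(40, -3, 3))
    for (k in seq_len(nrow(pts))) {
      expect_equal(point_in_polygon(pts[k, ], hull),
                   winding_inside(pts[k, ], hull))
    }
  }
})

test_that("vectorized membership equals the scalar routine", {
  set.seed(5)
  hull <- convex_hull(cbind(rnorm(8), rnorm(8)))
  px <- runif(100, -3, 3)
  py <- runif(100, -3, 3)
  vec <- preyselect:::points_in_polygon(px, py, hull)
  sc <- vapply(seq_along(px), function(i) {
    point_in_polygon(c(px[i], py[i]), hull)
  }, logical(1))
  expect_equal(vec, sc)
})

wide_sources <- function() {
  # well-separated sources with modest spread: the hull dwarfs the jitter
  data.frame(source = c("s1", "s2", "s3", "s4"),
             mean_d13C = c(-24, -14, -14, -24),
             sd_d13C = 0.3,
             mean_d15N = c(6, 6, 16, 16),
             sd_d15N = 0.3)
}

test_that("mixing-region probabilities behave at the extremes", {
  src <- wide_sources()
  tef <- gom_tef()
  centre <- data.frame(
    specimen_id = "c",
    d13C = mean(src$mean_d13C) + tef$mean_d13C,
    d15N = mean(src$mean_d15N) + tef$mean_d15N
  )
  res <- simulate_mixing_region(src, tef, centre, iterations = 500, seed = 1)
  expect_gt(res$prob, 0.99)
  far <- data.frame(specimen_id = "f", d13C = 100, d15N = -100)
  res2 <- simulate_mixing_region(src, tef, far, iterations = 500, seed = 1)
  expect_equal(res2$prob, 0)
  expect_false(res2$retained)
  expect_error(simulate_mixing_region(src[1:2, ], tef, centre), ">= 3")
  expect_error(simulate_mixing_region(src, tef, centre, iterations = 0),
               ">= 1")
})

test_that("mixing region is seeded and retained flag follows the 5% rule", {
  src <- gom_prey_sources()
  cons <- gom_consumers(seed = 2)
  a <- simulate_mixing_region(src, gom_tef(), cons, iterations = 300,
                              seed = 11)
  b <- simulate_mixing_region(src, gom_tef(), cons, iterations = 300,
                              seed = 11)
  expect_identical(a, b)
  expect_equal(a$retained, a$prob >= 0.05)
})

test_that("inflating TEF SDs weakly increases inside-probabilities", {
  # per-source TEF draws: larger TEF SD inflates every vertex's spread, so
  # an off-centre consumer is reached by more polygons
  src <- gom_prey_sources()
  cons <- gom_consumers(seed = 3)
  probs <- sapply(c(1, 2, 4), function(f) {
    tef <- tef_spec(1.29, 0.56 * f, 2.73, 0.58 * f)
    mean(simulate_mixing_region(src, tef, cons, iterations = 800,
                                seed = 13, tef_shared = FALSE)$prob)
  })
  expect_true(all(diff(probs) > -0.02))  # monotone up to MC jitter
})

test_that("probabilities are stable between 1500 and 15000 iterations", {
  src <- gom_prey_sources()
  cons <- gom_consumers(seed = 4)
  p1 <- simulate_mixing_region(src, gom_tef(), cons, iterations = 1500,
                               seed = 8)$prob
  p2 <- simulate_mixing_region(src, gom_tef(), cons, iterations = 15000,
                               seed = 9)$prob
  expect_lt(max(abs(p1 - p2)), 0.03)
})

test_that("probability surface spans the corrected polygon", {
  src <- wide_sources()
  cons <- gom_consumers(seed = 6)
  res <- simulate_mixing_region(src, gom_tef(), cons, iterations = 150,
                                seed = 2, grid_n = 25)
  s <- attr(res, "surface")
  expect_equal(dim(s$z), c(25, 25))
  expect_true(all(s$z >= 0 & s$z <= 1))
  expect_gt(max(s$z), 0.9)   # grid cells near the centroid almost always in
  expect_equal(min(s$z), 0)  # margin cells outside every polygon
})
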