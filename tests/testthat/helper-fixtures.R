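# Shared fixtures built in code.

toy_catch <- function() {
  # 3 hauls, 3 species, mixed presence; hand-checkable totals
  data.frame(
    haul_id = rep(c("h1", "h2", "h3"), each = 3),
    species = rep(c("A", "B", "C"), times = 3),
    count = c(10L, 0L, 2L, 5L, 4L, 0L, 0L, 6L, 3L),
    biomass_kg = c(1.0, 0, 0.5, 0.25, 2.0, 0, 0, 1.0, 0.25)
  )
}

two_sources <- function() {
  data.frame(source = c("A", "B"),
             mean_d13C = c(-20, -16), sd_d13C = c(0.1, 0.1),
             mean_d15N = c(10, 14), sd_d15N = c(0.1, 0.1))
}

tef_zero <- function() tef_spec(0, 0, 0, 0)

quick_cfg <- function(...) {
  mixing_config(draws = 6000L, burnin = 3000L, ...)
}

# Brute-force convex hull: a point is a hull vertex iff it is not strictly
# inside the hull, i.e. there exists a directed line through two points
# with all other points strictly on one side making it extreme. O(n^3).
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    side <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    others <- setdiff(seq_len(n), c(i, j))
    if (all(side[others] < 0)) keep[c(i, j)] <- TRUE
  }
  pts[keep, , drop = FALSE]
}

# Winding-number point-in-polygon (strictly inside or on boundary)
winding_inside <- function(point, hull) {
  n <- nrow(hull)
  ang <- 0
  for (i in seq_len(n)) {
    a <- hull[i, ] - point
    b <- hull[if (i == n) 1 else i + 1, ] - point
    if (sqrt(sum(a^2)) < 1e-12 || sqrt(sum(b^2)) < 1e-12) return(TRUE)
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi  # ~2*pi inside, ~0 outside; boundary handled by caller tol
}
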