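#' Convex hull of points in the tracer plane
#'
#' Andrew's monotone-chain construction. Returns the hull vertices in
#' counter-clockwise order with collinear interior points excluded.
#'
#' @param points Two-column numeric matrix (d13C, d15N) with >= 3 rows.
#' @return Two-column matrix of hull vertices, counter-clockwise, first
#'   vertex not repeated.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need >= 3 points", call. = FALSE)
  pts <- unique(points[order(points[, 1], points[, 2]), , drop = FALSE])
  n <- nrow(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- pts[c(lower[-length(lower)], upper[-length(upper)]), ,
              drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate hull: all points collinear",
                            call. = FALSE)
  dimnames(hull) <- NULL
  hull
}

#' Point-in-polygon test with on-edge counted inside
#'
#' Ray-casting membership test against a convex-hull vertex list; a point
#' exactly on a polygon edge (or vertex) is counted as inside, matching
#' the mixing-polygon convention that consumers on the edge of the source
#' polygon are admissible.
#'
#' @param point Length-2 numeric.
#' @param hull Vertex matrix as returned by [convex_hull()].
#' @param tol Absolute tolerance for the on-edge test.
#' @return Logical.
#' @export
point_in_polygon <- function(point, hull, tol = 1e-9) {
  hull <- as.matrix(hull)
  if (nrow(hull) < 3L) stop("degenerate hull", call. = FALSE)
  n <- nrow(hull)
  x <- point[1]; y <- point[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- hull[i, 1]; yi <- hull[i, 2]
    xj <- hull[j, 1]; yj <- hull[j, 2]
    # on-edge: zero cross product and within the segment's bounding box
    cr <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cr) <= tol &&
        x >= min(xi, xj) - tol && x <= max(xi, xj) + tol &&
        y >= min(yi, yj) - tol && y <= max(yi, yj) + tol) {
      return(TRUE)
    }
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Vectorized ray casting over many points; on-edge counts as inside.
points_in_polygon <- function(px, py, hull, tol = 1e-9) {
  n <- nrow(hull)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- hull[i, 1]; yi <- hull[i, 2]
    xj <- hull[j, 1]; yj <- hull[j, 2]
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onedge <- onedge | (abs(cr) <= tol &
                          px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
                          py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol)
    crossing <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crossing[is.na(crossing)] <- FALSE
    inside <- xor(inside, crossing)
    j <- i
  }
  inside | onedge
}

#' Monte-Carlo mixing-polygon validation
#'
#' Simulates the mixing polygon: on each iteration every TEF-corrected
#' source vertex is drawn as
#' \eqn{N(\mu_{it} + \lambda_t, \sqrt{\sigma_{it}^2 + \tau_t^2})} per
#' tracer, the convex hull of the drawn vertices is built, and each
#' consumer is tested for membership (on-edge counts as inside). The
#' per-consumer probability is the fraction of iterations whose polygon
#' contains it; consumers with probability >= 0.05 lie within the 95%
#' mixing region and can reasonably be kept in the mixing model.
#'
#' By default a single TEF deviate per tracer is shared by all sources
#' within an iteration (one consumer-level enrichment per iteration);
#' `tef_shared = FALSE` draws it independently per source. With
#' `se_scale = TRUE` source means are drawn with their standard error
#' \eqn{\sigma/\sqrt{n}} instead of \eqn{\sigma}.
#'
#' @param sources Source summary table (>= 3 rows; see
#'   [summarize_sources()]). Needs an `n` column when `se_scale = TRUE`.
#' @param tef A [tef_spec()].
#' @param consumers Data frame with `d13C`, `d15N` (and optionally
#'   `specimen_id`).
#' @param iterations Number of simulated polygons (default 1500).
#' @param seed Integer seed.
#' @param tef_shared Share one TEF draw per tracer across sources within an
#'   iteration (default TRUE).
#' @param se_scale Draw source means with sigma/sqrt(n) (default FALSE).
#' @param grid_n Optional: when > 0, also evaluate the inside-probability
#'   surface on a `grid_n` x `grid_n` grid spanning the hull extremes
#'   plus a 1 per-mil margin (for 5%/10%-contour plots). Default 0 (off).
#' @return Data frame of class `mixing_region` with `consumer`, `prob`,
#'   `retained` (prob >= 0.05); when `grid_n > 0`, attribute `surface` is a
#'   list with `x`, `y` and probability matrix `z`.
#' @export
simulate_mixing_region <- function(sources, tef, consumers,
                                   iterations = 1500L, seed = 1L,
                                   tef_shared = TRUE, se_scale = FALSE,
                                   grid_n = 0L) {
  check_source_table(sources)
  check_tef(tef)
  m <- nrow(sources)
  if (m < 3L) stop("need >= 3 sources for a mixing polygon", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  n_c <- nrow(consumers)
  sd_src <- cbind(sources$sd_d13C, sources$sd_d15N)
  if (se_scale) {
    if (is.null(sources$n)) stop("`se_scale` needs a source n column",
                                 call. = FALSE)
    sd_src <- sd_src / sqrt(sources$n)
  }
  mu_src <- cbind(sources$mean_d13C, sources$mean_d15N)
  lam <- c(tef$mean_d13C, tef$mean_d15N)
  tau <- c(tef$sd_d13C, tef$sd_d15N)
  hits <- numeric(n_c)
  surface <- NULL
  if (grid_n > 0L) {
    base_hull <- convex_hull(sweep(mu_src, 2, lam, `+`))
    gx <- seq(min(base_hull[, 1]) - 1, max(base_hull[, 1]) + 1,
              length.out = grid_n)
    gy <- seq(min(base_hull[, 2]) - 1, max(base_hull[, 2]) + 1,
              length.out = grid_n)
    gpts <- expand.grid(x = gx, y = gy)
    ghits <- numeric(nrow(gpts))
  }
  set.seed(child_seed(seed, "mixing-region"))
  for (it in seq_len(iterations)) {
    if (tef_shared) {
      lam_draw <- rnorm(2, lam, tau)
      vx <- rnorm(m, mu_src[, 1], sd_src[, 1]) + lam_draw[1]
      vy <- rnorm(m, mu_src[, 2], sd_src[, 2]) + lam_draw[2]
    } else {
      vx <- rnorm(m, mu_src[, 1] + lam[1], sqrt(sd_src[, 1]^2 + tau[1]^2))
      vy <- rnorm(m, mu_src[, 2] + lam[2], sqrt(sd_src[, 2]^2 + tau[2]^2))
    }
    hull <- tryCatch(convex_hull(cbind(vx, vy)), error = function(e) NULL)
    if (is.null(hull)) next
    hits <- hits + points_in_polygon(consumers$d13C, consumers$d15N, hull)
    if (grid_n > 0L) {
      ghits <- ghits + points_in_polygon(gpts$x, gpts$y, hull)
    }
  }
  prob <- hits / iterations
  ids <- consumers$specimen_id %||% sprintf("consumer_%03d", seq_len(n_c))
  res <- data.frame(consumer = ids, prob = prob, retained = prob >= 0.05)
  if (grid_n > 0L) {
    attr(res, "surface") <- list(
      x = gx, y = gy,
      z = matrix(ghits / iterations, grid_n, grid_n)
    )
  }
  class(res) <- c("mixing_region", "data.frame")
  res
}

#' Contour plot of the simulated mixing region
#'
#' Draws the inside-probability surface (5% outermost contour, then every
#' 10%) with consumers and TEF-corrected source means overlaid. Requires
#' the result to have been computed with `grid_n > 0`.
#'
#' @param x A `mixing_region` result carrying a surface attribute.
#' @param consumers,sources,tef Optional: overlay the consumer points and
#'   corrected source means.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.mixing_region <- function(x, consumers = NULL, sources = NULL,
                               tef = NULL, ...) {
  s <- attr(x, "surface")
  if (is.null(s)) stop("re-run simulate_mixing_region() with grid_n > 0",
                       call. = FALSE)
  contour(s$x, s$y, s$z, levels = c(0.05, seq(0.1, 0.9, by = 0.1)),
          xlab = expression(delta^13 * C), ylab = expression(delta^15 * N),
          ...)
  if (!is.null(consumers)) points(consumers$d13C, consumers$d15N, pch = 16)
  if (!is.null(sources) && !is.null(tef)) {
    points(sources$mean_d13C + tef$mean_d13C,
           sources$mean_d15N + tef$mean_d15N, pch = 4, cex = 1.3)
  }
  invisible(x)
}
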