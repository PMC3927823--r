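test_that("locality CSV reading validates structure and coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("a", "b", "c"),
                       longitude = c(29.1, 29.2, 29.3),
                       latitude = c(-29.1, -29.2, -29.3)),
            f, row.names = FALSE)
  loc <- read_localities(f)
  expect_equal(nrow(loc), 3)
  expect_named(loc, c("species", "longitude", "latitude", "precision_m",
                      "source"))

  write.csv(data.frame(species = "a", longitude = 29, latitude = 95),
            f, row.names = FALSE)
  expect_error(read_localities(f), "invalid locality row")

  write.csv(data.frame(species = character(0), longitude = numeric(0),
                       latitude = numeric(0)), f, row.names = FALSE)
  expect_warning(empty <- read_localities(f), "no rows")
  expect_equal(nrow(empty), 0)

  write.csv(data.frame(species = "a", lat = 1), f, row.names = FALSE)
  expect_error(read_localities(f), "missing required column")
})

test_that("equirectangular projection matches the closed form", {
  loc <- data.frame(species = "a", longitude = c(0, 1), latitude = c(0, 0))
  p <- project_localities(loc)
  # one degree of longitude at the equator: R * pi / 180 km
  expect_equal(diff(p$x), 6371 * pi / 180, tolerance = 1e-10)
  expect_equal(diff(p$x), 111.19, tolerance = 1e-4)
  expect_equal(p$y, c(0, 0))

  # point at the reference origin projects to (0, 0)
  p0 <- project_localities(data.frame(longitude = 12, latitude = -5),
                           reference_latitude = -5,
                           reference_longitude = 12)
  expect_equal(unlist(p0[c("x", "y")]), c(x = 0, y = 0))

  # translation invariance: shifting all longitudes preserves distances
  loc2 <- data.frame(species = "a", longitude = runif(5, 20, 21),
                     latitude = runif(5, -30, -29))
  loc3 <- loc2; loc3$longitude <- loc3$longitude + 40
  d2 <- dist(project_localities(loc2)[, c("x", "y")])
  d3 <- dist(project_localities(loc3)[, c("x", "y")])
  expect_equal(as.numeric(d2), as.numeric(d3), tolerance = 1e-9)

  expect_error(project_localities(data.frame(longitude = numeric(0),
                                             latitude = numeric(0))),
               "empty")
})

test_that("convex hulls are minimal, CCW, and handle degenerate inputs", {
  sq <- build_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)),
                   "sq")
  expect_equal(nrow(sq$vertices), 4)
  expect_equal(sq$area, 1)
  expect_false(sq$degenerate)
  # counter-clockwise: positive shoelace signed area
  v <- sq$vertices
  j <- c(nrow(v), seq_len(nrow(v) - 1))
  expect_gt(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2, 0)

  col <- build_hull(rbind(c(0, 0), c(1, 1), c(2, 2)), "line")
  expect_true(col$degenerate)
  expect_equal(col$area, 0)

  pt <- build_hull(rbind(c(3, 4)), "pt")
  expect_true(pt$degenerate)

  # adding interior points never changes the hull polygon
  set.seed(11)
  base <- matrix(rnorm(40), ncol = 2)
  h1 <- build_hull(base, "h")
  centroid <- colMeans(h1$vertices)
  interior <- t(replicate(30, centroid + 0.1 * runif(1) *
                            (base[sample(20, 1), ] - centroid)))
  h2 <- build_hull(rbind(base, interior), "h")
  expect_equal(h1$vertices, h2$vertices)
  expect_true(all(points_in_convex(base, h1$vertices)))
})

test_that("hull area agrees with the Monte-Carlo membership oracle", {
  set.seed(21)
  theta <- runif(200) * 2 * pi
  r <- sqrt(runif(200))
  disc <- build_hull(cbind(r * cos(theta), r * sin(theta)), "disc")
  mc <- mc_polygon_area(disc$vertices, n = 1e6)
  expect_lt(abs(disc$area - mc$area) / mc$area, 0.01)
  expect_lt(abs(disc$area - mc$area), 3 * mc$se)
})

test_that("intersection areas are exact on analytic cases and match MC", {
  a <- square_range(0, 0)
  expect_equal(intersection_area(a, a), 1)
  b <- square_range(0.5, 0)
  expect_equal(intersection_area(a, b), 0.5)
  far <- square_range(5, 5)
  expect_equal(intersection_area(a, far), 0)
  expect_error(intersection_area(a, build_hull(rbind(c(0, 0)), "p")),
               "non-degenerate")

  set.seed(31)
  for (i in 1:5) {
    pa <- random_convex_poly(10)
    pb <- random_convex_poly(5)
    got <- intersection_area(build_hull(pa, "a"), build_hull(pb, "b"))
    mc <- mc_intersection_area(pa, pb, n = 4e5)
    expect_lt(abs(got - mc$area), 3 * mc$se + 1e-12)
  }
})

test_that("overlap proportion implements the min-area and degenerate rules", {
  big <- square_range(0, 0, side = 4)
  small <- square_range(1, 1, side = 1)
  expect_equal(overlap_proportion(big, small), 1)   # embedded range
  expect_equal(overlap_proportion(small, big), 1)   # symmetric
  expect_equal(overlap_proportion(square_range(0, 0), square_range(0.5, 0)),
               0.5)
  expect_equal(overlap_proportion(square_range(0, 0), square_range(9, 9)), 0)

  # degenerate vs polygon: fraction of localities inside-or-on the hull
  deg <- build_hull(rbind(c(0.5, 0.5), c(2, 2), c(3.5, 3.5), c(9, 9)), "d")
  expect_true(deg$degenerate)
  expect_equal(overlap_proportion(deg, big), 0.75)
  expect_equal(overlap_proportion(big, deg), 0.75)

  # degenerate vs degenerate: coincidence within 1e-6 km
  d1 <- build_hull(rbind(c(0, 0), c(1, 1)), "d1")
  d2 <- build_hull(rbind(c(1, 1 + 1e-8), c(2, 2)), "d2")
  d3 <- build_hull(rbind(c(5, 5), c(6, 6)), "d3")
  expect_equal(overlap_proportion(d1, d2), 1)
  expect_equal(overlap_proportion(d1, d3), 0)
})

test_that("overlap matrix is symmetric in [0,1] with unit diagonal", {
  set.seed(41)
  ranges <- lapply(1:10, function(i) {
    build_hull(matrix(rnorm(16, mean = runif(1, -2, 2)), ncol = 2),
               paste0("sp", i))
  })
  M <- overlap_matrix(ranges)
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(unname(diag(M)), rep(1, 10))
  # element-wise recomputation oracle
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(M[i, j], overlap_proportion(ranges[[i]], ranges[[j]]))

  expect_error(overlap_matrix(ranges[c(1, 1)]), "duplicate")

  disjoint <- list(square_range(0, 0, id = "a"), square_range(5, 0, id = "b"),
                   square_range(0, 5, id = "c"))
  expect_equal(sum(overlap_matrix(disjoint)) - 3, 0)
  same <- list(square_range(0, 0, id = "a"), square_range(0, 0, id = "b"))
  expect_equal(unname(overlap_matrix(same)[1, 2]), 1)
})

test_that("scaling coordinates scales areas by c^2 and fixes proportions", {
  set.seed(51)
  pts1 <- matrix(rnorm(24), ncol = 2)
  pts2 <- matrix(rnorm(24, mean = 0.5), ncol = 2)
  c0 <- 3.7
  a1 <- build_hull(pts1, "a"); b1 <- build_hull(pts2, "b")
  a2 <- build_hull(pts1 * c0, "a"); b2 <- build_hull(pts2 * c0, "b")
  expect_equal(a2$area, c0^2 * a1$area, tolerance = 1e-12)
  expect_equal(overlap_proportion(a1, b1), overlap_proportion(a2, b2),
               tolerance = 1e-12)
})
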