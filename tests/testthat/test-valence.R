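test_that("bond clouds carry the Voronoi neighbour structure to the origin", {
  cl <- bondCloud(hexPartition)
  # interior hexagonal particle: 6 bonds of equal length at 2pi/6 arcs
  v1 <- cl[[1]]
  expect_equal(nrow(v1), 6L)
  len <- sqrt(rowSums(v1^2))
  expect_equal(len, rep(hexagonalSpacing(1), 6), tolerance = 1e-9)
  ang <- sort(atan2(v1[, 2], v1[, 1]))
  expect_equal(diff(ang), rep(pi / 3, 5), tolerance = 1e-9)

  # point-count conservation against the coordination numbers
  k <- coordination(hexPartition)
  expect_equal(sum(vapply(cl, nrow, integer(1))), sum(k, na.rm = TRUE))

  expect_warning(empty <- bondCloud(hexPartition, coordinationFilter = 5),
                 "no particles")
  expect_length(empty, 0L)
  expect_length(bondCloud(hexPartition, coordinationFilter = 6),
                sum(!is.na(k)))
})

test_that("orientation rotates the reference bond to +y rigidly", {
  v <- tessellate(smallCsr)
  cl <- bondCloud(v)
  for (rule in c("longest_facet", "first_ccw")) {
    or <- orientClouds(cl, rule = rule)
    for (k in seq_along(or)) {
      a <- atan2(or[[k]][, 2], or[[k]][, 1])
      expect_lt(min(abs(a - pi / 2)), 1e-9)
      # intra-set angle multiset preserved by the rigid rotation
      circGaps <- function(x) {
        s <- sort(x %% (2 * pi))
        sort(diff(c(s, s[1] + 2 * pi)))
      }
      a0 <- atan2(cl[[k]][, 2], cl[[k]][, 1])
      expect_equal(circGaps(a), circGaps(a0), tolerance = 1e-9)
    }
  }
})

test_that("probability maps normalize, conserve counts and localize peaks", {
  p2 <- pointPattern(c(0.5, 0.5), c(0.3, 0.7), unitSquare)
  cl2 <- bondCloud(tessellate(p2), excludeEdge = FALSE)
  m <- probabilityMap(cl2, nBins = 16, halfWidth = 1)
  expect_equal(sum(m@grid), 1)
  expect_equal(sum(m@grid > 0), 2L)  # one bond up, one bond down

  cl <- bondCloud(hexPartition)
  m6 <- probabilityMap(orientClouds(cl), nBins = 64,
                       halfWidth = 1.5 * hexagonalSpacing(1))
  expect_equal(sum(m6@grid), 1)
  expect_equal(m6@nOutOfRange, 0L)
  # six sharp spots: a small number of bins carries all the mass
  expect_lte(sum(m6@grid > 0), 24L)
  expect_gte(sum(m6@grid > 0), 6L)
  # one of the spots sits on the +y axis (centre columns, upper half)
  spots <- which(m6@grid > 0, arr.ind = TRUE)
  onY <- abs(spots[, 1] - 32.5) <= 2 & spots[, 2] > 32
  expect_true(any(onY))

  expect_error(probabilityMap(cl, nBins = 64, halfWidth = 1e-6), "outside")
})

test_that("unoriented hexagonal maps have 6-fold rotational symmetry", {
  cl <- bondCloud(hexPartition)
  # odd bin count keeps the lattice spots off bin boundaries (a spot on a
  # boundary would hop bins under the 1-ulp noise of the rotation)
  m0 <- probabilityMap(cl, nBins = 95, halfWidth = 1.37 * hexagonalSpacing(1))
  rot <- lapply(cl, function(v) {
    a <- pi / 3
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    w <- v %*% R
    attributes(w)[c("facetLengths", "particle")] <-
      attributes(v)[c("facetLengths", "particle")]
    w
  })
  attr(rot, "coordinationFilter") <- NULL
  m60 <- probabilityMap(rot, nBins = 95,
                        halfWidth = 1.37 * hexagonalSpacing(1))
  expect_gt(cor(as.vector(m0@grid), as.vector(m60@grid)), 0.99)
})

test_that("maps do not depend on particle enumeration order", {
  v <- tessellate(smallCsr)
  cl <- bondCloud(v)
  perm <- rev(seq_along(cl))
  clp <- structure(cl[perm],
                   coordinationFilter = attr(cl, "coordinationFilter"))
  m1 <- probabilityMap(cl, nBins = 32, halfWidth = 3)
  m2 <- probabilityMap(clp, nBins = 32, halfWidth = 3)
  expect_identical(m1@grid, m2@grid)
})

test_that("CSR valence maps are angularly isotropic", {
  p <- csrPattern(1, obsWindow(0, 45, 0, 45), seed = 33)
  cl <- bondCloud(tessellate(p))
  pts <- do.call(rbind, cl)
  ang <- atan2(pts[, 2], pts[, 1])
  resultant <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  expect_lt(resultant, 0.05)
})

test_that("valence maps serialize as dense text matrices", {
  cl <- bondCloud(hexPartition, coordinationFilter = 6)
  m <- probabilityMap(orientClouds(cl), nBins = 16, halfWidth = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  writeValenceMap(m, f)
  lines <- readLines(f)
  expect_length(lines, 3L + 16L)
  grid <- as.matrix(read.table(f, skip = 3))
  expect_equal(unname(grid), unname(m@grid), tolerance = 1e-12)
})
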