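# shared fixtures, built in code at load time (all cheap)

unitSquare <- obsWindow(0, 1, 0, 1)

# window holding ~15 spacings of the unit-intensity hexagonal lattice
hexWindow <- obsWindow(0, 15, 0, 15)
hexFixture <- hexagonalLattice(1, hexWindow)
hexPartition <- tessellate(hexFixture)

squareFixture <- squareLattice(1, hexWindow)

smallCsr <- csrPattern(0.5, obsWindow(0, 10, 0, 10), seed = 42)

# rigid rotation of a pattern about its window centre (window unchanged)
rotatePattern <- function(pattern, angle) {
  w <- patternWindow(pattern)
  cx <- c((w@xmin + w@xmax) / 2, (w@ymin + w@ymax) / 2)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- sweep(coordinates(pattern), 2, cx) %*% R
  xy <- sweep(xy, 2, cx, "+")
  pointPattern(xy[, 1], xy[, 2], window = w)
}

# distance of each point to the nearest window side
borderDistance <- function(pattern) {
  xy <- coordinates(pattern)
  w <- patternWindow(pattern)
  pmin(pmin(xy[, 1] - w@xmin, w@xmax - xy[, 1]),
       pmin(xy[, 2] - w@ymin, w@ymax - xy[, 2]))
}
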