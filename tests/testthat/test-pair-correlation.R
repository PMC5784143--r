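test_that("a single pair lands in exactly the bin containing its distance", {
  p <- pointPattern(c(0.2, 0.8), c(0.5, 0.5), unitSquare)
  expect_warning(g <- pairCorrelation(p, binWidth = 0.05, rMax = 1),
                 "half the shorter window side")
  nz <- which(grValues(g) > 0)
  expect_length(nz, 1L)
  expect_lt(abs(binCentres(g)[nz] - 0.6), 0.025 + 1e-12)
})

test_that("g(r) matches an independent brute-force pair count exactly", {
  for (n in c(10, 50)) {
    w <- obsWindow(0, 5, 0, 5)
    p <- csrPattern(n / 25, w, seed = n)
    bw <- 0.1
    rmax <- 2.5
    g <- pairCorrelation(p, binWidth = bw, rMax = rmax)
    oracle <- bruteForceGr(coordinates(p), w, bw, rmax)
    expect_equal(grValues(g), oracle$g, tolerance = 1e-12)

    # pair-count conservation: binned ordered pairs = all ordered pairs
    # within range (exact integer identity)
    nHat <- grValues(g) * 2 * pi * binCentres(g) * bw *
      intensity(p) * nPoints(p)
    d <- dist(coordinates(p))
    expect_equal(round(sum(nHat)), sum(nHat), tolerance = 1e-9)
    expect_equal(sum(nHat), 2 * sum(d <= rmax))
  }
})

test_that("g(r) is invariant under rigid motions of pattern and window", {
  p <- smallCsr
  g0 <- pairCorrelation(p, binWidth = 0.2, rMax = 4)

  # translation (window moves along)
  xy <- coordinates(p)
  w <- patternWindow(p)
  pT <- pointPattern(xy[, 1] + 3, xy[, 2] - 2,
                     obsWindow(w@xmin + 3, w@xmax + 3, w@ymin - 2, w@ymax - 2))
  expect_equal(grValues(pairCorrelation(pT, binWidth = 0.2, rMax = 4)),
               grValues(g0))

  # rotation about the window centre of an interior-dominated pattern
  ctr <- c(5, 5)
  inDisk <- sqrt(colSums((t(xy) - ctr)^2)) < 4.9
  pd <- pointPattern(xy[inDisk, 1], xy[inDisk, 2], w)
  gd <- pairCorrelation(pd, binWidth = 0.2, rMax = 4)
  pr <- rotatePattern(pd, 0.61)
  expect_equal(grValues(pairCorrelation(pr, binWidth = 0.2, rMax = 4)),
               grValues(gd), tolerance = 1e-12)
})

test_that("large CSR flattens to g = 1 beyond two mean spacings", {
  p <- csrPattern(1, obsWindow(0, 60, 0, 60), seed = 17)
  spacing <- 0.5                      # Poisson mean NN distance 1/(2 sqrt(lambda))
  # the isotropic correction removes the window-truncation decay the
  # uncorrected estimator shows at several spacings; quarter-unit bins
  # keep per-bin counting noise well inside the band
  g <- pairCorrelation(p, binWidth = 0.25, rMax = 5, edgeCorrection = TRUE)
  sel <- binCentres(g) >= 2 * spacing & binCentres(g) <= 10 * spacing
  expect_true(all(abs(grValues(g)[sel] - 1) < 0.05))

  # the uncorrected estimator sits strictly below the corrected one at
  # large r (neighbours outside the window are simply missing)
  g0 <- pairCorrelation(p, binWidth = 0.25, rMax = 5)
  tail <- binCentres(g) >= 3
  expect_true(mean(grValues(g0)[tail]) < mean(grValues(g)[tail]))
})

test_that("normalization state machine rescales once and only once", {
  g <- pairCorrelation(hexFixture, binWidth = 0.05, rMax = 3)
  gn <- normalizeDistance(g, 1)
  expect_equal(binCentres(gn), binCentres(g))       # spacing 1: unchanged
  expect_error(normalizeDistance(gn, 2), "already")

  gh <- normalizeHeight(g)
  expect_equal(max(grValues(gh)), 1)
  expect_equal(grValues(normalizeHeight(gh)), grValues(gh))  # idempotent
  expect_equal(normalizationState(normalizeHeight(gn)), "both")

  flat <- normalizeDistance(g, 1)
  zero <- tryCatch(normalizeHeight(
    differenceSpectrum(normalizeHeight(gn), normalizeHeight(gn))),
    error = function(e) e)
  expect_s3_class(zero, "error")      # all-zero spectrum cannot be rescaled
})

test_that("hexagonal lattice g(r) peaks at the shell distances, split second shell included", {
  g <- pairCorrelation(hexagonalLattice(1, obsWindow(0, 33, 0, 33)),
                       binWidth = 0.02, rMax = 3.3)
  gn <- normalizeHeight(normalizeDistance(g, hexagonalSpacing(1)))
  v <- grValues(gn)
  ctr <- binCentres(gn)
  pk <- which(v > 0.03)
  cl <- split(pk, cumsum(c(1, diff(pk) > 1)))
  pos <- vapply(cl, function(ix) sum(ctr[ix] * v[ix]) / sum(v[ix]), numeric(1))
  expect_equal(pos[1:5], c(1, sqrt(3), 2, sqrt(7), 3), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("the impulse reference matches a brute-force lattice enumeration", {
  bw <- 0.02
  ref <- hexagonalReferenceGr(binWidth = bw, rMax = 3.05)
  nz <- which(grValues(ref) > 0)
  sh <- latticeShells(k = 20, rMax = 3.05)
  # peak positions agree with the enumerated shell distances to half a bin
  expect_equal(binCentres(ref)[nz], sh$distance, tolerance = bw,
               ignore_attr = TRUE)
  # peak masses reproduce the shell multiplicities through the Eq-style
  # shell-area scaling
  mult <- grValues(ref)[nz] * 2 * pi * binCentres(ref)[nz] * bw * (2 / sqrt(3))
  expect_equal(mult, sh$multiplicity, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(binCentres(ref)[nz][1], 1, tolerance = bw)
})

test_that("difference spectra rank patterns by their disorder", {
  refN <- normalizeHeight(hexagonalReferenceGr(binWidth = 0.02, rMax = 3.2))
  normOf <- function(p) {
    sp <- meanSpacing(p)
    normalizeHeight(normalizeDistance(
      pairCorrelation(p, binWidth = sp / 50, rMax = 3.3 * sp), sp))
  }
  w <- obsWindow(0, 22, 0, 22)
  hex <- hexagonalLattice(1, w)
  gHex <- normOf(hex)

  expect_true(all(grValues(differenceSpectrum(gHex, gHex)) == 0))
  expect_error(differenceSpectrum(gHex, hexagonalReferenceGr()), "both")

  dHex <- deltaRms(differenceSpectrum(gHex, refN), c(0.5, 3))
  dHexatic <- deltaRms(differenceSpectrum(
    normOf(hexaticEnsemble(hex, 0.02, 1, seed = 3)[[1]]), refN), c(0.5, 3))
  dCsr <- deltaRms(differenceSpectrum(
    normOf(csrPattern(1, w, seed = 2)), refN), c(0.5, 3))
  expect_true(dCsr > dHexatic && dHexatic > dHex)
})

test_that("delta-rms reduces to simple closed forms", {
  mk <- function(vals) new("RadialDistribution",
                           binCentres = seq(0.55, by = 0.1,
                                            length.out = length(vals)),
                           values = vals, binWidth = 0.1, density = 1,
                           normalization = "both", kind = "difference")
  expect_equal(deltaRms(mk(rep(0, 20))), 0)
  expect_equal(deltaRms(mk(rep(-0.3, 20))), 0.3)
  expect_error(deltaRms(mk(rep(1, 5)), c(10, 20)), "empty")
})

test_that("delta-rms against the hexagonal reference grows with jitter", {
  sp <- hexagonalSpacing(1)
  refN <- normalizeHeight(hexagonalReferenceGr(binWidth = 0.02, rMax = 3.2))
  rms <- vapply(c(0.01, 0.05, 0.10), function(f) {
    p <- hexaticEnsemble(hexFixture, f * sp, 1, seed = 31)[[1]]
    g <- normalizeHeight(normalizeDistance(
      pairCorrelation(p, binWidth = sp / 50, rMax = 3.3 * sp),
      meanSpacing(p)))
    deltaRms(differenceSpectrum(g, refN), c(0.5, 3))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("bootstrap smoothing reduces to g(r) at sigma 0 and converges in sigma", {
  p <- hexaticEnsemble(hexFixture, 0.05, 1, seed = 41)[[1]]
  g0 <- pairCorrelation(p, binWidth = 0.05, rMax = 3)
  expect_identical(grValues(bootstrapPairCorrelation(p, 0, 10, seed = 1,
                                                     binWidth = 0.05,
                                                     rMax = 3)),
                   grValues(g0))
  gTiny <- bootstrapPairCorrelation(p, 1e-8, 20, seed = 1,
                                    binWidth = 0.05, rMax = 3)
  expect_lt(max(abs(grValues(gTiny) - grValues(g0))), 0.05)
})

test_that("bootstrap smoothing suppresses single-bin spikes and is seed-stable", {
  base <- hexagonalLattice(1, hexWindow)   # ~230 points
  p <- hexaticEnsemble(base, 0.05, 1, seed = 9)[[1]]
  g0 <- pairCorrelation(p)
  gb1 <- bootstrapPairCorrelation(p, sigma = 0.03,
                                  nRealizations = 200, seed = 10)
  spike <- function(v) max(abs(diff(diff(v))))
  expect_lt(spike(grValues(gb1)), spike(grValues(g0)))

  gb2 <- bootstrapPairCorrelation(p, sigma = 0.03,
                                  nRealizations = 200, seed = 11)
  expect_lt(mean(abs(grValues(gb1) - grValues(gb2))),
            0.05 * max(grValues(gb1)))
  expect_identical(grValues(bootstrapPairCorrelation(
    p, 0.1, 5, seed = 12)), grValues(bootstrapPairCorrelation(
    p, 0.1, 5, seed = 12)))
})

test_that("first-peak width of hexatic patterns grows with the jitter scale", {
  sp <- hexagonalSpacing(1)
  fwhm <- vapply(c(0.01, 0.10), function(f) {
    g <- bootstrapPairCorrelation(
      hexaticEnsemble(hexFixture, f * sp, 1, seed = 51)[[1]],
      sigma = f * sp, nRealizations = 50, seed = 52,
      binWidth = sp / 50, rMax = 2 * sp)
    v <- grValues(g)
    pk <- which.max(v)
    sum(v >= v[pk] / 2 & seq_along(v) > pk - 20 & seq_along(v) < pk + 20)
  }, numeric(1))
  expect_gt(fwhm[2], fwhm[1])
})
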