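# Independent oracles, deliberately written along different code paths
# than the package implementation.

# g(r) by an explicit double loop over ordered pairs with the same binning
# convention (bin b covers ((b-1)*dr, b*dr], r at bin centres).
bruteForceGr <- function(xy, window, binWidth, rMax) {
  n <- nrow(xy)
  nb <- ceiling(rMax / binWidth - 1e-9)
  counts <- integer(nb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (d > nb * binWidth) next
      b <- min(max(ceiling(d / binWidth), 1L), nb)
      counts[b] <- counts[b] + 1L
    }
  }
  rho <- n / windowArea(window)
  centres <- (seq_len(nb) - 0.5) * binWidth
  list(centres = centres, counts = counts,
       g = (counts / n) / (2 * pi * centres * binWidth * rho))
}

# associated Legendre P_l^m(x) by the standard three-term recurrence
# (Condon-Shortley phase), independent of pracma
legendrePlm <- function(l, m, x) {
  if (m > l) return(0)
  pmm <- 1
  if (m > 0) {
    somx2 <- sqrt((1 - x) * (1 + x))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- 0
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# orthonormalized spherical harmonic Y_lm(theta, phi) as a complex number
sphericalY <- function(l, m, theta, phi) {
  am <- abs(m)
  norm <- sqrt((2 * l + 1) / (4 * pi) *
               exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  y <- norm * legendrePlm(l, am, cos(theta)) * exp(1i * am * phi)
  if (m < 0) y <- (-1)^am * Conj(y)
  y
}

# q_l by direct summation of the defining m-sum over weighted bond
# harmonics at the equator
bruteForceQl <- function(phi, wts, ell) {
  tot <- 0
  for (m in -ell:ell) {
    s <- sum(wts * vapply(phi, function(p)
      sphericalY(ell, m, pi / 2, p), complex(1)))
    tot <- tot + Mod(s)^2
  }
  sqrt(4 * pi / (2 * ell + 1) * tot)
}

# shell distances and multiplicities of an explicit (2k+1)^2-site
# triangular lattice, measured from its central site
latticeShells <- function(k = 15, rMax = 3.05) {
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- ij$i + ij$j / 2
  y <- ij$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  d <- d[d > 1e-12 & d <= rMax + 1e-9]
  tab <- table(round(d, 9))
  list(distance = as.numeric(names(tab)), multiplicity = as.integer(tab))
}
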