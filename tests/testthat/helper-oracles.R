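# Independent oracles used across the test suite. These deliberately take
# different computational routes than the package code.

# Rodrigues axis-angle rotation of vector v about unit axis k by angle th
rotateAxisAngle <- function(v, k, th) {
  k <- k / sqrt(sum(k^2))
  v * cos(th) + pracma::cross(k, v) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
}

# Liang-Barsky: length of segment (x1,y1)-(x2,y2) inside [lo,hi] x [lo,hi]
clipLengthOracle <- function(x1, y1, x2, y2, lo, hi) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (s in list(c(-dx, x1 - lo), c(dx, hi - x1),
                 c(-dy, y1 - lo), c(dy, hi - y1))) {
    p <- s[1]; q <- s[2]
    if (p == 0) { if (q < 0) return(0) }
    else { r <- q / p; if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r) }
  }
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

# brute-force detector: intersect a ray with every crystal front-face
# segment and return the 0-based id of the first segment hit (NA if none)
detectOracle <- function(scanner, origin, direction) {
  C <- crystalCenters(scanner)
  K <- scanner@crystalsPerSide
  side <- (seq_len(nrow(C)) - 1) %/% K
  alpha <- 2 * pi * side / scanner@nSides
  # segment endpoints: center +/- (w/2) along the side tangent
  tx <- -sin(alpha); ty <- cos(alpha)
  w2 <- scanner@crystalWidth / 2
  e1x <- C[, 1] - w2 * tx; e1y <- C[, 2] - w2 * ty
  e2x <- C[, 1] + w2 * tx; e2y <- C[, 2] + w2 * ty
  # solve origin + t*d = e1 + s*(e2-e1)
  sx <- e2x - e1x; sy <- e2y - e1y
  den <- direction[1] * (-sy) - direction[2] * (-sx)
  qx <- e1x - origin[1]; qy <- e1y - origin[2]
  t <- (qx * (-sy) - qy * (-sx)) / den
  s <- (direction[1] * qy - direction[2] * qx) / den
  ok <- is.finite(t) & t > 1e-9 & s >= 0 & s < 1
  if (!any(ok)) return(NA_integer_)
  which.min(ifelse(ok, t, Inf)) - 1L
}

# dense-grid FWHM of a function evaluated on a fine axis
denseFwhmOracle <- function(f, lim, n = 2e5) {
  x <- seq(-lim, lim, length.out = n)
  v <- f(x)
  half <- max(v) / 2
  above <- which(v >= half)
  x[max(above)] - x[min(above)]
}

# CDFs for Kolmogorov-Smirnov checks
prayleigh <- function(q, sigma) 1 - exp(-q^2 / (2 * sigma^2))
phalfnorm <- function(q, sigma) 2 * stats::pnorm(q, 0, sigma) - 1
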