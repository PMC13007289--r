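# Angular samplers, densities, and the deviated-direction construction.

test_that("fwhmToSigma is the 2*sqrt(2*log(2)) conversion", {
  expect_equal(fwhmToSigma(2.354820045), 1, tolerance = 1e-8)
  expect_identical(fwhmToSigma(0), 0)
  expect_equal(fwhmToSigma(0.58), 0.246304, tolerance = 1e-5)
  expect_error(fwhmToSigma(-1), "nonnegative")
})

test_that("model validity rejects bad kinds and widths", {
  expect_error(apaModel("GaussBoth"))
  expect_error(new("ApaModel", kind = "GaussDev", acoFwhmDeg = -0.1),
               "nonnegative")
})

test_that("zero acollinearity gives identically zero deviations", {
  for (kind in c("GaussDev", "GaussMag")) {
    d <- sampleDeviation(apaModel(kind, acoFwhmDeg = 0), 100)
    expect_true(all(d$phi == 0 & d$psi == 0 & d$theta == 0))
  }
})

test_that("theta is the Euclidean magnitude of (phi, psi)", {
  set.seed(42)
  for (kind in c("GaussDev", "GaussMag")) {
    d <- sampleDeviation(apaModel(kind), 5e4)
    expect_lt(max(abs(d$theta - sqrt(d$phi^2 + d$psi^2))), 1e-12)
    expect_true(all(d$theta >= 0))
  }
})

test_that("magnitude laws: Rayleigh for GaussDev, half-normal for GaussMag", {
  set.seed(7)
  sigma <- fwhmToSigma(0.58 * pi / 180)
  dd <- sampleDeviation(apaModel("GaussDev"), 1e5)
  dm <- sampleDeviation(apaModel("GaussMag"), 1e5)
  # closed-form means
  expect_equal(mean(dd$theta), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(mean(dm$theta), sigma * sqrt(2 / pi), tolerance = 0.01)
  # distributional shape
  expect_gt(stats::ks.test(dd$theta^2 / sigma^2, stats::pchisq,
                           df = 2)$p.value, 0.01)
  expect_gt(stats::ks.test(dm$theta, phalfnorm, sigma = sigma)$p.value,
            0.01)
})

test_that("deviationToDirection reproduces the frame formula and preserves angle", {
  # identity
  p <- c(0.6, 0.8, 0)
  expect_equal(deviationToDirection(p, 0, 0), p)
  # direct evaluation of the sampling-code formula at p = z-hat
  expect_equal(deviationToDirection(c(0, 0, 1), 0.01, 0),
               c(sin(0.01), 0, cos(0.01)), tolerance = 1e-12)
  # rotation-matrix oracle: rotating p about the in-frame axis
  set.seed(3)
  for (i in 1:200) {
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    phi <- rnorm(1, 0, 0.02); psi <- rnorm(1, 0, 0.02)
    out <- deviationToDirection(p, phi, psi)
    th <- sqrt(phi^2 + psi^2)
    expect_equal(acos(min(1, sum(p * out))), th, tolerance = 1e-9)
    expect_equal(sum(out^2), 1, tolerance = 1e-9)
    # oracle: axis = normalize(p x out) rotation of p by theta equals out
    ax <- pracma::cross(p, out)
    if (sqrt(sum(ax^2)) > 1e-12)
      expect_equal(rotateAxisAngle(p, ax, th), out, tolerance = 1e-9)
  }
  expect_error(deviationToDirection(c(0, 0, 0), 0.1, 0.1), "norm")
})

test_that("magnitude densities are correct and normalized", {
  gd <- apaModel("GaussDev"); gm <- apaModel("GaussMag")
  sigma <- fwhmToSigma(0.58 * pi / 180)
  expect_identical(magnitudePdf(gd, 0), 0)
  expect_error(magnitudePdf(gd, -0.1), ">= 0")
  # Rayleigh mode at theta = sigma (0.246 deg)
  opt <- optimize(function(t) magnitudePdf(gd, t), c(0, 5 * sigma),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, sigma, tolerance = 1e-4)
  expect_equal(opt$maximum * 180 / pi, 0.246304, tolerance = 1e-3)
  for (m in list(gd, gm))
    expect_equal(integrate(function(t) magnitudePdf(m, t), 0, Inf)$value,
                 1, tolerance = 1e-6)
})

test_that("deviation density satisfies f(theta) = 2*pi*theta*g and symmetry", {
  gd <- apaModel("GaussDev"); gm <- apaModel("GaussMag")
  sigma <- fwhmToSigma(0.58 * pi / 180)
  th <- seq(0.05, 5, length.out = 50) * sigma
  for (m in list(gd, gm)) {
    f <- magnitudePdf(m, th)
    g <- deviationPdf(m, th, 0)
    expect_lt(max(abs(f - 2 * pi * th * g) / f), 1e-10)
  }
  # isotropy of the GaussDev deviation
  expect_equal(deviationPdf(gd, 0.001, 0.002),
               deviationPdf(gd, -0.001, 0.002))
  expect_equal(deviationPdf(gd, 0.001, 0.002),
               deviationPdf(gd, 0.002, 0.001))
  # Gaussian-over-norm sharpening near the origin
  r <- deviationPdf(gm, sigma / 10, 0) / deviationPdf(gm, sigma, 0)
  expect_equal(r, 10 * exp((1 - 0.01) / 2), tolerance = 1e-10)
  expect_error(deviationPdf(gm, 0, 0), "singular")
})

test_that("pair generation is back-to-back up to the sampled deviation", {
  set.seed(11)
  p0 <- makePair(c(0, 0), apaModel("GaussDev", acoFwhmDeg = 0), 100)
  expect_equal(p0$dirB, -p0$dirA)
  sigma <- fwhmToSigma(0.58 * pi / 180)
  for (mode in c("in_plane", "isotropic3d")) {
    pd <- makePair(c(0, 0), apaModel("GaussDev"), 1e5, mode = mode)
    ang <- acos(pmin(1, -rowSums(pd$dirA * pd$dirB)))
    expect_lt(max(abs(ang - pd$theta)), 1e-9)
    expect_gt(stats::ks.test(ang, prayleigh, sigma = sigma)$p.value, 0.01)
  }
  pm <- makePair(c(0, 0), apaModel("GaussMag"), 1e5)
  ang <- acos(pmin(1, -rowSums(pm$dirA * pm$dirB)))
  expect_gt(stats::ks.test(ang, phalfnorm, sigma = sigma)$p.value, 0.01)
})

test_that("Rayleigh scale is recovered from a GaussDev theta histogram", {
  set.seed(13)
  d <- sampleDeviation(apaModel("GaussDev"), 1e6)
  h <- thetaHistogram(d$theta, binWidthDeg = 0.01)
  fit <- fitMagnitudeHistogram(h, "rayleigh")
  expect_equal(fit@scale, 0.246304, tolerance = 0.01)
})
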