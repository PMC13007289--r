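# Resolution metrics and fits.

test_that("theoretical blur coefficient matches the known values", {
  expect_equal(theoreticalFwhm(0.58, 405), 2.0499, tolerance = 1e-4)
  expect_equal(theoreticalFwhm(0.58, 1) , 0.0051, tolerance = 0.01)
  expect_equal(theoreticalFwhm(0.50, 1) , 0.0044, tolerance = 0.01)
  expect_identical(theoreticalFwhm(0.58, 0), 0)
})

test_that("displacement samples have the model's radial law", {
  expect_true(all(sampleBlurDisplacements(
    apaModel("GaussDev", acoFwhmDeg = 0), 405, 100, seed = 1) == 0))
  sd1 <- sampleBlurDisplacements(apaModel("GaussDev"), 405, 1e6, seed = 51)
  # per-axis std x 2.35482 equals the analytic FWHM for the Gaussian case
  expect_equal(stddevBlur(sd1, factor = 2.35482),
               theoreticalFwhm(0.58, 405), tolerance = 0.01)
  sm1 <- sampleBlurDisplacements(apaModel("GaussMag"), 405, 1e5, seed = 52)
  r <- sqrt(rowSums(sm1^2))
  sigmaD <- fwhmToSigma(theoreticalFwhm(0.58, 405))
  expect_gt(stats::ks.test(r, phalfnorm, sigma = sigmaD)$p.value, 0.01)
})

test_that("FWHM equivalent and stddev metrics reproduce the whole-body values", {
  # reference mass fraction: chi-3 CDF at half the FWHM
  expect_equal(stats::pchisq((2.35482 / 2)^2, df = 3), 0.292,
               tolerance = 0.005)
  s <- sampleBlurDisplacements(apaModel("GaussMag"), 405, 1e6, seed = 53)
  fe <- fwhmEquivalent(s)
  # closed form: 2 * sqrt(2) * sigma_d * erfinv(0.292)
  sigmaD <- fwhmToSigma(theoreticalFwhm(0.58, 405))
  closed <- 2 * sigmaD * qnorm((1 + 0.292) / 2)
  expect_equal(fe, 0.652, tolerance = 0.01)
  expect_equal(fe, closed, tolerance = 0.01)
  expect_equal(stddevBlur(s), 1.4496, tolerance = 0.01)
  # homogeneity of degree one
  expect_equal(fwhmEquivalent(3 * s), 3 * fe, tolerance = 1e-12)
  expect_equal(stddevBlur(3 * s), 3 * stddevBlur(s), tolerance = 1e-12)
  # rotation invariance
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sr <- s %*% R
  expect_equal(fwhmEquivalent(sr), fe, tolerance = 1e-9)
  expect_equal(stddevBlur(sr), stddevBlur(s), tolerance = 1e-9)
  expect_identical(stddevBlur(matrix(0, 1e4, 2)), 0)
  expect_error(fwhmEquivalent(s[1:100, ]), "1e4")
})

test_that("blur curve is monotone, proportional, and correctly ordered", {
  d <- c(200, 400, 810, 1000)
  curve <- blurCurve(d, n = 2e5, seed = 54)
  for (col in 2:4) expect_true(all(diff(curve[[col]]) > 0))
  # proportional to diameter
  for (col in 2:4)
    expect_equal(curve[[col]][2] / curve[[col]][1], 2, tolerance = 0.01)
  # FWHM equivalent < std x 2.355 < Gaussian-deviation FWHM
  expect_true(all(curve$gaussmag_fwhm_equiv_mm < curve$gaussmag_std235_mm))
  expect_true(all(curve$gaussmag_std235_mm < curve$gaussdev_fwhm_mm))
  expect_equal(curve$gaussdev_fwhm_mm[3], 2.05, tolerance = 0.001)
})

test_that("quadrature resolution combines components root-sum-square", {
  expect_identical(quadratureResolution(c(3, 4)), 5)
  expect_identical(quadratureResolution(7.3), 7.3)
  expect_equal(quadratureResolution(c(2.76 / 2, theoreticalFwhm(0.58, 393))),
               2.42, tolerance = 0.005)
  expect_error(quadratureResolution(c(-1, 2)))
})

test_that("profile FWHM matches closed forms and a dense-grid oracle", {
  x <- seq(-10, 10, by = 0.3125)
  sig <- 1.3
  g <- exp(-x^2 / (2 * sig^2))
  expect_equal(profileFwhm(g, x = x), 2.35482 * sig, tolerance = 0.3125 / 10)
  # triangle of half-width w has FWHM w
  w <- 3
  tri <- pmax(0, 1 - abs(x) / w)
  expect_equal(profileFwhm(tri, x = x), w, tolerance = 1e-9)
  # cusp: Gaussian over norm, compared with a dense-grid oracle
  cuspF <- function(t) exp(-t^2 / (2 * 0.87^2)) / pmax(abs(t), 0.3125 / 2)
  cusp <- cuspF(x + 1e-9)
  oracle <- denseFwhmOracle(function(t) cuspF(t + 1e-9), 10)
  expect_equal(profileFwhm(cusp, x = x), oracle, tolerance = 0.3125)
  expect_error(profileFwhm(rep(1, 10), x = 1:10), "crossing")
  expect_error(profileFwhm(rep(1, 10), x = 1:10, background = 2), "peak")
})

test_that("Gaussian profile fit recovers sigma and background", {
  set.seed(55)
  x <- seq(-8, 8, by = 0.3125)
  y <- 5 * exp(-(x - 0.2)^2 / (2 * 0.87^2)) + 2 + rnorm(length(x), 0, 0.02)
  f <- fitGaussianProfile(x, y)
  expect_equal(f$fwhm, 2.35482 * 0.87, tolerance = 0.02)
  expect_equal(f$background, 2, tolerance = 0.02)
  expect_equal(f$mu, 0.2, tolerance = 0.02)
})

test_that("magnitude-histogram fits recover scales and select the family", {
  set.seed(56)
  sigma <- 0.246304
  thR <- sigma * sqrt(-2 * log(runif(1e6)))      # Rayleigh, degrees
  hR <- data.frame(binCenterDeg = NA, count = NA)
  hR <- thetaHistogram(thR * pi / 180, binWidthDeg = 0.01)
  fR <- fitMagnitudeHistogram(hR, "rayleigh")
  expect_equal(fR@scale, sigma, tolerance = 0.01)
  thG <- abs(rnorm(1e6, 0, sigma))
  hG <- thetaHistogram(thG * pi / 180, binWidthDeg = 0.01)
  fG <- fitMagnitudeHistogram(hG, "gaussian")
  expect_equal(fG@scale, sigma, tolerance = 0.01)
  expect_equal(fG@fwhm, 0.58, tolerance = 0.01)
  # the wrong family fits Rayleigh data at least 5x worse
  wrong <- fitMagnitudeHistogram(hR, "gaussian")
  expect_gt(wrong@rss, 5 * fR@rss)
  # verdicts
  expect_identical(t19Check(thR * pi / 180)$verdict, "GaussDev")
  expect_identical(t19Check(thG * pi / 180)$verdict, "GaussMag")
})

test_that("bilinear interpolation is exact on an affine image", {
  v <- outer(1:8, 1:6, function(i, j) 2 * i - 3 * j + 30)
  img <- activityImage(v, pixelSize = 0.5, origin = c(0, 0))
  set.seed(57)
  pts <- cbind(runif(50, 0.5, 3), runif(50, 0.5, 2))
  got <- bilinearAt(img, pts)
  expected <- 2 * (pts[, 1] / 0.5 + 1) - 3 * (pts[, 2] / 0.5 + 1) + 30
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("Rayleigh-criterion scoring matches a dense-profile oracle", {
  # synthetic two-Gaussian "spot pair" images across separations
  sig <- 1
  mkSpec <- function(sep) {
    new("PhantomSpec", kind = "hot_spot", point = c(0, 0), bgFraction = 0,
        fovRadius = 20, diameters = sep / 2,
        centers = list(rbind(c(-sep / 2, 0), c(sep / 2, 0))),
        ratio = 4, phantomRadius = 20)
  }
  mkImg <- function(sep) {
    x <- seq(-15, 15, by = 0.25)
    v <- outer(x, x, function(ix, iy)
      exp(-((ix + sep / 2)^2 + iy^2) / (2 * sig^2)) +
        exp(-((ix - sep / 2)^2 + iy^2) / (2 * sig^2)))
    activityImage(v + 1e-9, 0.25, c(-15, -15))
  }
  verdicts <- vapply(c(0, 2, 2.5, 3, 4), function(sep) {
    r <- resolvability(mkImg(sep), mkSpec(max(sep, 0.5)))
    r$n_resolved[1] == r$n_pairs[1] & r$n_pairs[1] >= 1
  }, logical(1))
  # oracle: exact two-Gaussian values at the centers and the midpoint
  oracleRes <- vapply(c(0, 2, 2.5, 3, 4), function(sep) {
    if (sep == 0) return(FALSE)
    peak <- 1 + exp(-sep^2 / 2)
    valley <- 2 * exp(-sep^2 / 8)
    valley <= 0.735 * peak
  }, logical(1))
  expect_identical(verdicts, oracleRes)
  # the resolved/unresolved transition lies between separations 2 and 3
  expect_false(oracleRes[2])
  expect_true(oracleRes[4])
})
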