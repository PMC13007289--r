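# Phantom construction, rasterization, and emission sampling.

test_that("default point position is a 0.3125 mm pixel center", {
  ph <- pointPhantom()
  expect_equal(ph@point, c(0.15625, 0.15625))
  # pixel edges at multiples of the pixel size
  expect_equal(ph@point %% 0.3125, c(0.15625, 0.15625))
  expect_error(pointPhantom(position = c(11, 0), fovRadius = 10), "inside")
})

test_that("point phantom emission split follows bgFraction", {
  set.seed(31)
  ph0 <- pointPhantom(bgFraction = 0)
  e0 <- sampleEmission(ph0, 1000)
  expect_true(all(e0[, 1] == 0.15625 & e0[, 2] == 0.15625))
  ph <- pointPhantom(bgFraction = 0.7)
  e <- sampleEmission(ph, 1e5)
  atPoint <- e[, 1] == 0.15625 & e[, 2] == 0.15625
  # binomial 3-sigma band
  expect_equal(mean(!atPoint), 0.7, tolerance = 3 * sqrt(0.21 / 1e5) / 0.7)
})

test_that("uniform disk sampling has the right radial profile", {
  set.seed(32)
  ph <- pointPhantom(bgFraction = 1, fovRadius = 10)
  e <- sampleEmission(ph, 1e6)
  r <- sqrt(rowSums(e^2))
  expect_equal(mean(r), 2 / 3 * 10, tolerance = 0.01)
  expect_lt(max(r), 10 + 1e-9)
})

test_that("hot-spot centers respect sector margins and lattice spacing", {
  ph <- hotSpotPhantom(phantomRadius = 40)
  for (k in seq_along(ph@diameters)) {
    cen <- ph@centers[[k]]
    expect_gt(nrow(cen), 0)
    r <- sqrt(rowSums(cen^2))
    ang <- atan2(cen[, 2], cen[, 1]) %% (2 * pi)
    lo <- (k - 1) * pi / 3
    dAng <- (ang - lo) %% (2 * pi)
    expect_true(all(dAng >= 0 & dAng <= pi / 3))
    # >= 2 mm from both bounding radii and the rim
    expect_true(all(r * sin(dAng) >= 2 - 1e-9))
    expect_true(all(r * sin(pi / 3 - dAng) >= 2 - 1e-9))
    expect_true(all(r <= 40 - 2 + 1e-9))
    # nearest-neighbour spacing is twice the diameter
    if (nrow(cen) > 1) {
      D <- as.matrix(dist(cen)); diag(D) <- Inf
      expect_gte(min(D), 2 * ph@diameters[k] - 1e-9)
      expect_equal(min(D), 2 * ph@diameters[k], tolerance = 1e-9)
    }
  }
})

test_that("spot count matches a brute-force lattice enumeration", {
  ph <- hotSpotPhantom(diameters = rep(2.5, 6), phantomRadius = 40)
  # independent enumeration for sector 1 (bisector at 30 deg), spacing 5
  s <- 5; margin <- 2
  cnt <- 0L
  for (i in -25:25) for (j in -25:25) {
    p <- i * s * c(cos(pi / 6), sin(pi / 6)) +
      j * s * c(cos(pi / 2), sin(pi / 2))
    r <- sqrt(sum(p^2)); if (r == 0) next
    ang <- atan2(p[2], p[1]) %% (2 * pi)
    if (ang > pi / 3) next
    if (r * sin(ang) < margin || r * sin(pi / 3 - ang) < margin) next
    if (r > 40 - margin) next
    cnt <- cnt + 1L
  }
  expect_identical(nrow(ph@centers[[1]]), cnt)
})

test_that("ground-truth raster reproduces densities and total activity", {
  ph <- hotSpotPhantom(phantomRadius = 20)
  gt <- groundTruth(ph, pixelSize = 0.3125)
  v <- imageValues(gt)
  # analytic total: disk + excess over spots
  aSpots <- sum(vapply(seq_along(ph@diameters), function(k)
    nrow(ph@centers[[k]]) * pi * (ph@diameters[k] / 2)^2, numeric(1)))
  analytic <- pi * 20^2 + (4 - 1) * aSpots
  expect_equal(sum(v) * gt@pixelSize^2, analytic, tolerance = 0.005)
  # the raster preserves each spot's excess activity (partial-volume
  # pixels carry the boundary mass) ...
  org <- imageOrigin(gt)
  h <- gt@pixelSize
  nx <- nrow(v)
  gx <- org[1] + (seq_len(nx) - 1) * h
  gy <- org[2] + (seq_len(ncol(v)) - 1) * h
  GX <- matrix(gx, nx, ncol(v)); GY <- matrix(gy, nx, ncol(v), byrow = TRUE)
  for (k in 2:6) {
    cen <- ph@centers[[k]]; d <- ph@diameters[k]
    for (q in seq_len(min(3, nrow(cen)))) {
      near <- sqrt((GX - cen[q, 1])^2 + (GY - cen[q, 2])^2) <= d / 2 + 2 * h
      excess <- sum((v[near] - 1)) * h^2
      expect_equal(excess, 3 * pi * (d / 2)^2, tolerance = 0.05)
    }
  }
  # ... and pixels fully inside a spot sit at ratio x background
  for (k in 4:6) {
    cen <- ph@centers[[k]]; d <- ph@diameters[k]
    inner <- sqrt((GX - cen[1, 1])^2 + (GY - cen[1, 2])^2) <=
      d / 2 - h * sqrt(2) / 2
    expect_gt(sum(inner), 0)
    expect_equal(mean(v[inner]), 4, tolerance = 0.02)
  }
})

test_that("hot-spot emissions land in spots with the analytic probability", {
  set.seed(33)
  ph <- hotSpotPhantom(phantomRadius = 20)
  n <- 1e6
  e <- sampleEmission(ph, n)
  cen <- do.call(rbind, ph@centers)
  dia <- unlist(lapply(seq_along(ph@diameters), function(k)
    rep(ph@diameters[k], nrow(ph@centers[[k]]))))
  inSpot <- rep(FALSE, n)
  for (j in seq_len(nrow(cen)))
    inSpot <- inSpot |
      ((e[, 1] - cen[j, 1])^2 + (e[, 2] - cen[j, 2])^2 <= (dia[j] / 2)^2)
  aSpots <- sum(pi * (dia / 2)^2)
  pSpot <- 4 * aSpots / (pi * 20^2 + 3 * aSpots)
  expect_equal(mean(inSpot), pSpot, tolerance = 0.01)
})

test_that("emission sampling matches the activity map on a coarse grid", {
  set.seed(34)
  ph <- hotSpotPhantom(phantomRadius = 20)
  n <- 2e5
  e <- sampleEmission(ph, n)
  gt <- groundTruth(ph, pixelSize = 0.5)
  v <- imageValues(gt); org <- imageOrigin(gt)
  # aggregate both to 4 mm cells
  cell <- function(x, y) {
    cx <- floor((x + 24) / 4); cy <- floor((y + 24) / 4)
    cx + 12 * cy
  }
  nxp <- nrow(v)
  px <- org[1] + (seq_len(nxp) - 1) * 0.5
  obs <- tabulate(cell(e[, 1], e[, 2]) + 1L, nbins = 144)
  G <- expand.grid(x = px, y = px)
  expv <- tapply(as.vector(v), cell(G$x, G$y), sum)
  expc <- numeric(144); expc[as.integer(names(expv)) + 1L] <- expv
  keep <- expc > 0
  p <- expc[keep] / sum(expc)
  expect_gt(stats::chisq.test(obs[keep], p = p / sum(p))$p.value, 0.01)
})
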