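test_that("Crick generator is deterministic and recovers its parameters", {
  p <- crickParams(5, 170, "left", n_residues = 100L)
  a <- generateCrickCoil(p)
  b <- generateCrickCoil(p)
  expect_identical(caCoords(a@chains[[1L]]), caCoords(b@chains[[1L]]))

  prof <- coiledCoilProfile(a)
  expect_lt(abs(mean(prof@radius) - 5) / 5, 0.02)
  expect_lt(abs(mean(prof@pitch, na.rm = TRUE) - 170) / 170, 0.05)
})

test_that("huge pitch degenerates to numerically parallel strands", {
  p <- crickParams(5, 1e6, "left", n_residues = 60L)
  prof <- coiledCoilProfile(generateCrickCoil(p))
  expect_true(all(abs(prof@rotation) < 0.5))
  expect_true(all(prof@handedness == "indeterminate"))
  expect_true(all(is.na(prof@pitch)))
})

test_that("ideal alpha-helix has the stated radius, spacing and equivariance", {
  h <- generateAlphaHelix(40L)
  ca <- caCoords(h)
  expect_equal(max(abs(sqrt(ca[, 1L]^2 + ca[, 2L]^2) - 2.26)), 0,
               tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))

  # arbitrary axis/origin: same radius, rise and spacing about the new axis
  rot <- randomRotation(11)
  axis2 <- as.numeric(rot %*% c(0, 0, 1))
  org2 <- c(3, -2, 7)
  h2 <- generateAlphaHelix(40L, axis = axis2, origin = org2)
  rel <- sweep(caCoords(h2), 2L, org2)
  proj <- as.numeric(rel %*% axis2)
  expect_equal(proj, 1.51 * (0:39), tolerance = 1e-9)
  perp <- rel - outer(proj, axis2)
  expect_equal(unname(sqrt(rowSums(perp^2))), rep(2.26, 40L),
               tolerance = 1e-9)

  expect_error(generateAlphaHelix(10L, axis = c(0, 0, 0)), "zero")
})

test_that("globular chains hit the target Rg and respect the seed", {
  g <- generateGlobularChain(100L, 25, seed = 1L)
  rg <- radiusOfGyration(caCoords(g))
  expect_true(rg >= 24.75 && rg <= 25.25)
  expect_identical(caCoords(generateGlobularChain(100L, 25, seed = 1L)),
                   caCoords(g))
  expect_false(identical(caCoords(generateGlobularChain(100L, 25, seed = 2L)),
                         caCoords(g)))
  expect_error(generateGlobularChain(100L, 2, seed = 1L), "packing")
})

test_that("globule walks are connected chains with excluded volume", {
  g <- generateGlobularChain(60L, 15, seed = 5L)
  ca <- caCoords(g)
  steps <- sqrt(rowSums(diff(ca)^2))
  # uniform bond length (the exact-Rg rescale preserves uniformity)
  expect_lt(diff(range(steps)) / mean(steps), 1e-9)
  d <- as.matrix(dist(ca))
  nonadj <- abs(row(d) - col(d)) > 1L
  # the 4.0 A exclusion scales with the 3.8 A step under the rescale
  expect_gt(min(d[nonadj]) / mean(steps), 4.0 / 3.8 * 0.999)
})

test_that("jittered ensembles reproduce the noise model", {
  coil <- makeTestCoil(n = 30L)
  ens0 <- perturbEnsemble(coil, 3L, 0, seed = 1L)
  for (k in 1:3)
    expect_identical(caCoords(ens0@frames[[k]]@chains[[1L]]),
                     caCoords(coil@chains[[1L]]))

  # a residue pair at 11 A jittered with sigma = 0.1 cannot cross the 12 A
  # cutoff (a > 7 sigma excursion) in 200 frames
  pair11 <- DimerStructure(chainFromCA("K1", matrix(c(0, 0, 0), 1L)),
                           chainFromCA("K10", matrix(c(11, 0, 0), 1L)))
  ensP <- perturbEnsemble(pair11, 200L, 0.1, seed = 2L)
  idxP <- globalIndexMap(ensP)
  mapsP <- lapply(ensP@frames, caContactMap, index = idxP)
  cpm <- aggregateContactProbability(mapsP, ensP, "per-frame")
  expect_equal(cpm@pairs$probability, 1.0)

  # mean 3-D displacement magnitude ~ sigma * sqrt(8/pi) (Maxwell)
  ens <- perturbEnsemble(coil, 200L, 0.1, seed = 2L)
  disp <- unlist(lapply(ens@frames, function(f)
    sqrt(rowSums((caCoords(f@chains[[1L]]) -
                    caCoords(coil@chains[[1L]]))^2))))
  expect_equal(mean(disp), 0.1 * sqrt(8 / pi), tolerance = 0.03)
})

test_that("assembled dimers reproduce the requested placement", {
  fx <- makeAnnotatedRod()
  g1 <- generateGlobularChain(30L, 12, seed = 3L, label = "K1")
  g10 <- generateGlobularChain(30L, 12, seed = 4L, label = "K10")

  dm <- suppressWarnings(
    assembleSyntheticDimer(fx$rod, list(K1 = g1, K10 = g10),
                           fx$annotation, d = 10, theta_r = 0, rho = 15))
  gp <- globulePosition(dm, fx$annotation, "K1", "V1", "head")
  expect_equal(gp@d, 10, tolerance = 0.1)
  expect_equal(gp@theta_r, 0, tolerance = 1)

  dm2 <- assembleSyntheticDimer(fx$rod, list(K1 = g1), fx$annotation,
                                d = 5, theta_r = 180, rho = 15)
  gp2 <- globulePosition(dm2, fx$annotation, "K1", "V1", "head")
  expect_equal(abs(gp2@theta_r), 180, tolerance = 1)

  dm3 <- suppressWarnings(
    assembleSyntheticDimer(fx$rod, list(K1 = g1), fx$annotation,
                           d = -20, theta_r = 90, rho = 15))
  gp3 <- globulePosition(dm3, fx$annotation, "K1", "V1", "head")
  expect_identical(classifyCategory(gp3), "III")
})
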