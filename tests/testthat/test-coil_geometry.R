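test_that("helix axis estimation recovers the true axis", {
  h <- generateAlphaHelix(50L)
  ap <- axisPoints(computeHelixAxis(h))
  expect_lt(max(sqrt(ap[, 1L]^2 + ap[, 2L]^2)), 0.05)

  # rigid-body equivariance
  rot <- randomRotation(3)
  shift <- c(5, -8, 2)
  h2 <- transformChain(h, rot, shift)
  ap2 <- axisPoints(computeHelixAxis(h2))
  expected <- sweep(ap %*% t(rot), 2L, -shift)
  expect_lt(max(abs(ap2 - expected)), 1e-6)

  # noisy helix stays near the true axis
  noisy <- perturbEnsemble(DimerStructure(h, generateAlphaHelix(
    50L, origin = c(30, 0, 0), label = "B")), 1L, 0.1, seed = 7L)
  apn <- axisPoints(computeHelixAxis(noisy@frames[[1L]]@chains[[1L]]))
  expect_lt(max(sqrt(apn[, 1L]^2 + apn[, 2L]^2)), 0.3)

  expect_error(computeHelixAxis(chainFromCA("A", diag(3))), "4 residues")
})

test_that("central axis is the pointwise midpoint", {
  h <- generateAlphaHelix(30L)
  a <- computeHelixAxis(h)
  expect_equal(computeCentralAxis(a, a), axisPoints(a))

  p1 <- matrix(c(rep(5, 10), rep(0, 10), 1:10), ncol = 3L)
  p2 <- matrix(c(rep(-5, 10), rep(0, 10), 1:10), ncol = 3L)
  rownames(p1) <- rownames(p2) <- 1:10
  P <- computeCentralAxis(p1, p2)
  expect_true(all(abs(P[, 1L]) < 1e-12))

  coil <- makeTestCoil()
  pa <- computeHelixAxis(coil@chains[[1L]])
  pb <- computeHelixAxis(coil@chains[[2L]])
  Pc <- computeCentralAxis(pa, pb)
  expect_lt(max(sqrt(Pc[, 1L]^2 + Pc[, 2L]^2)), 0.2)

  rownames(p2) <- 101:110
  expect_error(computeCentralAxis(p1, p2), "overlap")
})

test_that("local radius follows the geometry", {
  p1 <- matrix(c(rep(5, 10), rep(0, 10), 1:10), ncol = 3L)
  p2 <- matrix(c(rep(-5, 10), rep(0, 10), 1:10), ncol = 3L)
  rownames(p1) <- rownames(p2) <- 1:10
  P <- computeCentralAxis(p1, p2)
  R <- computeLocalRadius(p1, p2, P)
  expect_true(all(abs(R - 5) < 0.05))
  expect_true(all(computeLocalRadius(p1, p1, (p1 + p1) / 2) == 0))

  coil <- makeTestCoil()
  pa <- computeHelixAxis(coil@chains[[1L]])
  pb <- computeHelixAxis(coil@chains[[2L]])
  Pc <- computeCentralAxis(pa, pb)
  Rc <- computeLocalRadius(pa, pb, Pc)
  expect_lt(abs(mean(Rc) - 5) / 5, 0.02)
})

test_that("rotation angle: magnitude, sign and reflection behaviour", {
  # two parallel straight helices: no winding
  h1 <- generateAlphaHelix(30L)
  h2 <- generateAlphaHelix(30L, origin = c(10, 0, 0), label = "B")
  a1 <- computeHelixAxis(h1); a2 <- computeHelixAxis(h2)
  P <- computeCentralAxis(a1, a2)
  psi <- computeRotationAngle(a1, a2, P)
  expect_true(all(abs(psi) < 0.01))

  # closed form: |Psi| = 360 * rise / pitch
  coil <- makeTestCoil(pitch = 170)
  prof <- coiledCoilProfile(coil)
  expect_lt(abs(mean(abs(prof@rotation)) - 360 * 1.51 / 170) /
              (360 * 1.51 / 170), 0.05)
  expect_true(all(prof@rotation < 0))  # left-handed convention

  # mirror image flips the sign exactly
  mirror <- new("DimerStructure", chains = lapply(coil@chains, function(ch) {
    a <- ch@atoms; a$x <- -a$x; ChainStructure(ch@label, a)
  }), frame_id = 1L, source = "mirror")
  profM <- coiledCoilProfile(mirror)
  expect_equal(profM@rotation, -prof@rotation, tolerance = 1e-9)
  expect_true(all(profM@handedness == "right"))
  expect_equal(profM@radius, prof@radius, tolerance = 1e-9)
  expect_equal(profM@pitch, prof@pitch, tolerance = 1e-9)
})

test_that("local pitch recovers the generator and guards division", {
  coil <- makeTestCoil(pitch = 170)
  prof <- coiledCoilProfile(coil)
  expect_lt(abs(mean(prof@pitch) - 170) / 170, 0.05)

  coil2 <- makeTestCoil(pitch = 340)
  prof2 <- coiledCoilProfile(coil2)
  expect_equal(mean(prof2@pitch) / mean(prof@pitch), 2, tolerance = 0.05)

  # near-parallel strands are flagged indeterminate, not divergent
  h1 <- generateAlphaHelix(30L)
  h2 <- generateAlphaHelix(30L, origin = c(10, 0, 0), label = "B")
  prof3 <- coiledCoilProfile(DimerStructure(h1, h2))
  expect_true(all(is.na(prof3@pitch)))
  expect_true(all(prof3@handedness == "indeterminate"))
})

test_that("profile is equivariant under rigid-body motion", {
  coil <- makeTestCoil(n = 60L)
  prof <- coiledCoilProfile(coil)
  moved <- transformDimer(coil, randomRotation(9), c(-4, 12, 3))
  prof2 <- coiledCoilProfile(moved)
  expect_equal(prof2@radius, prof@radius, tolerance = 1e-9)
  expect_equal(prof2@rotation, prof@rotation, tolerance = 1e-9)
  expect_equal(prof2@pitch, prof@pitch, tolerance = 1e-9)
})

test_that("major axis anchors and direction behave as specified", {
  P <- matrix(c(rep(0, 20), seq(0, 19) * 1.5, rep(0, 20)), ncol = 3L)
  rownames(P) <- 1:20
  u <- computeMajorAxis(P, c(1, 20), "1A")
  expect_equal(u$vector, c(0, 1, 0), tolerance = 1e-6)
  expect_equal(u$start_anchor, P[2L, ], ignore_attr = TRUE)
  expect_equal(u$end_anchor, P[18L, ], ignore_attr = TRUE)

  # reversing residue order flips the sign
  Pr <- P[20:1, , drop = FALSE]
  expect_equal(computeMajorAxis(Pr, c(1, 20))$vector, c(0, -1, 0),
               tolerance = 1e-6)

  # gently bent path: axis approximates the chord
  half1 <- cbind(0, seq(0, 9) * 1.5, 0)
  dir2 <- c(sin(pi / 6), cos(pi / 6), 0)   # 150 deg interior bend
  half2 <- t(sapply(1:10, function(k) half1[10, ] + k * 1.5 * dir2))
  Pb <- rbind(half1, half2)
  rownames(Pb) <- 1:20
  ub <- computeMajorAxis(Pb, c(1, 20))
  chord <- Pb[18L, ] - Pb[2L, ]
  expect_equal(ub$vector, chord / sqrt(sum(chord^2)), tolerance = 1e-9)

  expect_error(computeMajorAxis(P, c(1, 4)), ">= 5")
})

test_that("hinge angle conventions", {
  u <- c(0, 1, 0)
  expect_equal(computeHingeAngle(u, u), 0)
  expect_equal(computeHingeAngle(u, c(1, 0, 0)), 90)
  expect_equal(computeHingeAngle(u, -u), 180)
  expect_equal(computeHingeAngle(u, -u, convention = "reflex"), 180)
  expect_equal(computeHingeAngle(u, c(1, 0, 0), convention = "reflex"), 270)
})

test_that("full parameter recovery across the generator design space", {
  for (r0 in c(3, 8)) for (pitch in c(100, 300))
    for (hand in c("left", "right")) {
      coil <- generateCrickCoil(crickParams(r0, pitch, hand,
                                            n_residues = 60L))
      prof <- coiledCoilProfile(coil)
      expect_lt(abs(mean(prof@radius) - r0) / r0, 0.02)
      expect_lt(abs(mean(prof@pitch, na.rm = TRUE) - pitch) / pitch, 0.05)
      expect_true(all(prof@handedness == hand))
    }
})
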