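twoResidueDimer <- function(gap) {
  DimerStructure(chainFromCA("K1", matrix(c(0, 0, 0), 1L), resnum = 1L),
                 chainFromCA("K10", matrix(c(gap, 0, 0), 1L), resnum = 1L))
}

test_that("C-alpha cutoff is strict and chain-classed", {
  m1 <- caContactMap(twoResidueDimer(11.9))
  expect_identical(nrow(m1@pairs), 1L)
  expect_identical(m1@pairs$class, "K1-K10")
  expect_identical(nrow(caContactMap(twoResidueDimer(12.1))@pairs), 0L)
  expect_identical(nrow(caContactMap(twoResidueDimer(12.0))@pairs), 0L)
})

test_that("production map equals the brute-force oracle and is monotone", {
  fx <- makeAnnotatedRod(n_rod = 60L, offset = 30L)
  g1 <- generateGlobularChain(25L, 11, seed = 6L, label = "K1")
  dm <- suppressWarnings(assembleSyntheticDimer(
    fx$rod, list(K1 = g1), fx$annotation, d = -5, theta_r = 40, rho = 10))
  jit <- perturbEnsemble(dm, 2L, 0.3, seed = 8L)
  for (fr in jit@frames) {
    prod <- caContactMap(fr)@pairs
    oracle <- bruteForceContacts(fr)
    expect_identical(nrow(prod), nrow(oracle))
    expect_identical(paste(prod$chain_i, prod$res_i, prod$chain_j,
                           prod$res_j),
                     paste(oracle$chain_i, oracle$res_i, oracle$chain_j,
                           oracle$res_j))
  }
  counts <- vapply(c(6, 9, 12, 15), function(cf)
    nrow(caContactMap(jit@frames[[1L]], cutoff = cf)@pairs), integer(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("intra-chain sequence exclusion drops near-diagonal pairs", {
  h <- generateAlphaHelix(10L, label = "K1")
  dm <- DimerStructure(h, generateAlphaHelix(10L, origin = c(50, 0, 0),
                                             label = "K10"))
  pairs <- caContactMap(dm)@pairs
  intra <- pairs[pairs$chain_i == pairs$chain_j, ]
  expect_true(all(abs(intra$res_i - intra$res_j) > 2L))
})

test_that("probability aggregation: fractions, bounds and truncation rule", {
  coil <- makeTestCoil(n = 40L)
  ens1 <- perturbEnsemble(coil, 1L, 0, seed = 1L)
  maps1 <- lapply(ens1@frames, caContactMap)
  cpm1 <- aggregateContactProbability(maps1, ens1)
  expect_true(all(cpm1@pairs$probability %in% c(0, 1)))

  # 10 of 20 equally weighted frames -> 0.5
  near <- twoResidueDimer(11.5)
  far <- twoResidueDimer(13)
  frames <- c(replicate(10L, near), replicate(10L, far))
  ens <- StructureEnsemble(frames, model_id = 1:20,
                           model_scope = rep("full", 20L))
  idx <- globalIndexMap(ens)
  maps <- lapply(ens@frames, caContactMap, index = idx)
  cpm <- aggregateContactProbability(maps, ens, "per-frame")
  expect_equal(cpm@pairs$probability, 0.5)
  expect_equal(aggregateContactProbability(maps, ens,
                                           "per-model")@pairs$probability,
               0.5)

  # pair present in every frame -> 1.0
  ensA <- StructureEnsemble(replicate(4L, near), model_id = 1:4,
                            model_scope = rep("full", 4L))
  mapsA <- lapply(ensA@frames, caContactMap,
                  index = globalIndexMap(ensA))
  expect_equal(aggregateContactProbability(mapsA, ensA)@pairs$probability, 1)

  # tail-region pairs are normalized over full models only
  full <- makeTestCoil(n = 50L)
  trunc <- DimerStructure(
    ChainStructure("K1",
                   full@chains[[1L]]@atoms[full@chains[[1L]]@atoms$resnum <=
                                             30L, ]),
    ChainStructure("K10",
                   full@chains[[2L]]@atoms[full@chains[[2L]]@atoms$resnum <=
                                             30L, ]))
  ensT <- StructureEnsemble(c(replicate(2L, full), replicate(3L, trunc)),
                            model_id = 1:5,
                            model_scope = c("full", "full", rep("truncated",
                                                                3L)))
  idxT <- globalIndexMap(ensT)
  mapsT <- lapply(ensT@frames, caContactMap, index = idxT)
  cpmT <- aggregateContactProbability(mapsT, ensT)
  tail_pairs <- cpmT@pairs[cpmT@pairs$res_i > 32L & cpmT@pairs$res_j > 32L, ]
  rod_pairs <- cpmT@pairs[cpmT@pairs$res_i < 28L & cpmT@pairs$res_j < 28L, ]
  expect_true(all(tail_pairs$n_eff == 2L))
  expect_true(all(rod_pairs$n_eff == 5L))

  # inconsistent cutoffs refuse to aggregate
  mix <- c(maps1, list(caContactMap(coil, cutoff = 10)))
  ens_mix <- StructureEnsemble(c(ens1@frames, list(coil)),
                               model_id = c(1L, 2L),
                               model_scope = c("full", "full"))
  expect_error(aggregateContactProbability(mix, ens_mix), "cutoff")
})

test_that("probability matrix is symmetric with values in [0, 1]", {
  coil <- makeTestCoil(n = 30L)
  ens <- perturbEnsemble(coil, 4L, 0.5, seed = 3L)
  idx <- globalIndexMap(ens)
  maps <- lapply(ens@frames, caContactMap, index = idx)
  cpm <- aggregateContactProbability(maps, ens, "per-frame")
  m <- contactMatrix(cpm, idx)
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("typed side-chain contacts follow the table and precedence", {
  glu <- mkResidueAtoms("GLU", 1L, c(0, 0, 0),
                        list(CD = c(1, 0, 0), OE1 = c(2, 0, 0),
                             OE2 = c(2, 1, 0)))
  lys <- mkResidueAtoms("LYS", 1L, c(6, 0, 0),
                        list(CE = c(6.5, 0, 0), NZ = c(5.5, 0, 0)))
  dm <- DimerStructure(mkChain("K1", glu), mkChain("K10", lys))
  sc <- detectSidechainContacts(dm)
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$class, "acid-base")
  expect_equal(sc$distance, 3.5)

  # ring centroids just beyond the aromatic cutoff: no contact
  ring <- function(cx) list(CG = c(cx, 0, 0), CD1 = c(cx, 1, 0),
                            CD2 = c(cx + 1, 0, 0), CE1 = c(cx, 2, 0),
                            CE2 = c(cx + 2, 0, 0), CZ = c(cx + 1, 2, 0))
  f1 <- mkResidueAtoms("PHE", 1L, c(0, -3, 0), ring(0))
  centroid_gap <- 7.1
  f2 <- mkResidueAtoms("PHE", 1L, c(centroid_gap, -3, 0),
                       lapply(ring(0), function(v) v + c(centroid_gap, 0, 0)))
  dmF <- DimerStructure(mkChain("K1", f1), mkChain("K10", f2))
  expect_identical(nrow(detectSidechainContacts(dmF)), 0L)
  # and just inside: one aromatic contact (not hydrophobic, by precedence)
  f2b <- mkResidueAtoms("PHE", 1L, c(6.5, -3, 0),
                        lapply(ring(0), function(v) v + c(6.5, 0, 0)))
  scF <- detectSidechainContacts(DimerStructure(mkChain("K1", f1),
                                                mkChain("K10", f2b)))
  expect_identical(scF$class, "aromatic")

  # leucine pair: hydrophobic via closest side-chain carbons
  leu1 <- mkResidueAtoms("LEU", 1L, c(0, 5, 0), list(CD1 = c(0, 6, 0)))
  leu2 <- mkResidueAtoms("LEU", 1L, c(5, 5, 0), list(CD1 = c(4, 6, 0)))
  scL <- detectSidechainContacts(DimerStructure(mkChain("K1", leu1),
                                                mkChain("K10", leu2)))
  expect_identical(scL$class, "hydrophobic")

  # polar pair with only the second candidate site in range still counts
  asn <- mkResidueAtoms("ASN", 1L, c(0, 0, 0),
                        list(OD1 = c(0, 8, 0), ND2 = c(1, 0, 0)))
  gln <- mkResidueAtoms("GLN", 1L, c(4, 0, 0),
                        list(OE1 = c(3.5, 0, 0), NE2 = c(4, 8, 0)))
  scP <- detectSidechainContacts(DimerStructure(mkChain("K1", asn),
                                                mkChain("K10", gln)))
  expect_identical(scP$class, "hydrogen-bond")
  expect_equal(scP$distance, 2.5)

  # missing reference atoms: skipped with a warning, not an error
  bare <- mkResidueAtoms("GLU", 1L, c(0, 0, 0))
  expect_warning(
    scB <- detectSidechainContacts(DimerStructure(mkChain("K1", bare),
                                                  mkChain("K10", lys))),
    "skipped")
  expect_identical(nrow(scB), 0L)
})

test_that("typed census is rigid-motion invariant and label-consistent", {
  glu <- mkResidueAtoms("GLU", 1L, c(0, 0, 0),
                        list(CD = c(1, 0, 0), OE1 = c(2, 0, 0)))
  lys <- mkResidueAtoms("LYS", 1L, c(6, 0, 0), list(NZ = c(5.5, 0, 0)))
  dm <- DimerStructure(mkChain("K1", glu), mkChain("K10", lys))
  sc <- detectSidechainContacts(dm)
  moved <- transformDimer(dm, randomRotation(12), c(3, 3, 3))
  scM <- detectSidechainContacts(moved)
  expect_identical(scM$class, sc$class)
  expect_equal(scM$distance, sc$distance, tolerance = 1e-9)

  swapped <- DimerStructure(mkChain("K10", glu), mkChain("K1", lys))
  scS <- detectSidechainContacts(swapped)
  expect_identical(scS$class, sc$class)
  expect_identical(scS$chain_class, "K10-K1")
})

test_that("contact summaries average over frames correctly", {
  glu <- mkResidueAtoms("GLU", 1L, c(0, 0, 0),
                        list(OE1 = c(2, 0, 0)))
  lys <- mkResidueAtoms("LYS", 1L, c(6, 0, 0), list(NZ = c(5.5, 0, 0)))
  near <- DimerStructure(mkChain("K1", glu), mkChain("K10", lys))
  lys_far <- mkResidueAtoms("LYS", 1L, c(30, 0, 0),
                            list(NZ = c(29, 0, 0)))
  far <- DimerStructure(mkChain("K1", glu), mkChain("K10", lys_far))
  ens <- StructureEnsemble(list(near, far), model_id = c(1L, 1L),
                           model_scope = c("full", "full"))
  s <- summarizeContacts(ens)
  expect_equal(s$total, 0.5)
  expect_equal(unname(s$pair_probs$probability), 0.5)

  ens2 <- StructureEnsemble(list(near, near), model_id = c(1L, 1L),
                            model_scope = c("full", "full"))
  expect_equal(summarizeContacts(ens2)$total, 1.0)
})

test_that("summed probabilities match construction frequencies on jitter", {
  # a pair engineered near the cutoff has an intermediate, predictable
  # contact frequency under isotropic jitter
  fx <- makeTestCoil(n = 30L)
  ens <- perturbEnsemble(fx, 150L, 0.6, seed = 13L)
  idx <- globalIndexMap(ens)
  maps <- lapply(ens@frames, caContactMap, index = idx)
  cpm <- aggregateContactProbability(maps, ens, "per-frame")
  ref <- caContactMap(fx, index = idx)@pairs
  key <- paste(cpm@pairs$i, cpm@pairs$j)
  refkey <- paste(ref$i, ref$j)
  # pairs comfortably inside the cutoff in the reference stay near 1
  d0 <- ref[abs(ref$res_i - ref$res_j) == 3L & ref$chain_i == ref$chain_j, ]
  p <- cpm@pairs$probability[key %in% paste(d0$i, d0$j)]
  expect_true(all(p > 0.95))
})

test_that("heptad register and ideal a/d contact counts", {
  reg <- heptadRegister(1:14)
  expect_identical(unname(reg[1:7]),
                   c("a", "b", "c", "d", "e", "f", "g"))
  one <- heptadRegister(1:7)
  expect_identical(idealAdContacts(one, one), 4L)
  expect_identical(idealAdContacts(character(), character()), 0L)

  # stuttered register equals a brute-force enumeration of the same rule
  regS <- heptadRegister(1:21, stutters = 10L)
  bf <- 0L
  a <- unname(regS); b <- unname(regS)
  for (k in seq_along(a)) {
    if (a[k] == "a" && b[k] == "a") bf <- bf + 1L
    if (a[k] == "d" && b[k] == "d") bf <- bf + 1L
    if (a[k] == "a" && k + 3L <= length(b) && b[k + 3L] == "d")
      bf <- bf + 1L
    if (a[k] == "d" && k - 3L >= 1L && b[k - 3L] == "a") bf <- bf + 1L
  }
  expect_identical(idealAdContacts(regS, regS), bf)
  # the stutter breaks the a..g cycle where annotated
  expect_identical(unname(regS[10:11]), c("c", "g"))

  reg_bad <- c(a = "a", b = NA_character_)
  expect_error(idealAdContacts(reg_bad, reg_bad), "unassigned")
})

test_that("hydrogen-bond criteria: distance, adjacency and helix count", {
  don <- mkResidueAtoms("SER", 1L, c(0, 0, 0), list(OG = c(1, 0, 0)))
  acc <- mkResidueAtoms("SER", 5L, c(4, 0, 0),
                        list(OG = c(1, 2.9, 0), CB = c(1, 3.9, 0)))
  dm <- DimerStructure(mkChain("K1", don), mkChain("K10", acc))
  hb <- countHbonds(dm)
  expect_identical(unname(hb$counts["sidechain-sidechain"]), 1L)

  acc_far <- mkResidueAtoms("SER", 5L, c(4, 0, 0),
                            list(OG = c(1, 3.6, 0), CB = c(1, 4.6, 0)))
  dm2 <- DimerStructure(mkChain("K1", don), mkChain("K10", acc_far))
  expect_identical(sum(countHbonds(dm2)$counts), 0L)

  h <- generateAlphaHelix(20L, full_backbone = TRUE)
  hbh <- countHbonds(DimerStructure(h))
  expect_identical(unname(hbh$counts["backbone-backbone"]), 16L)
  expect_true(all(hbh$pairs$separation == 4L))
})
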