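# Grafting, rotamer packing and the decomposed energy.

test_that("rotamer library covers all residues within the size budget", {
  lib <- rotamerLibrary()
  expect_setequal(names(lib), larkscreen:::AA1)
  sizes <- vapply(lib, length, 0L)
  expect_true(all(sizes >= 1L & sizes <= 9L))
  expect_equal(unname(sizes[c("G", "A", "P")]), c(1L, 1L, 1L))
  expect_equal(length(lib$G[[1L]]), 0L)
})

test_that("grafting places the expected number of heavy atoms", {
  fa <- expandFibril(TEMPLATES$ZIPPER_P1, 5, 2)
  # independent per-residue heavy-atom counts (backbone 4 + side chain)
  counts <- c(G = 4, A = 5, S = 6, C = 6, T = 7, V = 7, P = 7, I = 8,
              L = 8, N = 8, D = 8, M = 8, E = 9, Q = 9, K = 9, H = 10,
              R = 11, F = 11, Y = 12, W = 14)
  for (win in c("SGMGGI", "GGGGGG", "WYRKHP")) {
    m <- graftSequence(fa, win)
    expected <- sum(counts[strsplit(win, "")[[1L]]]) * 10L
    expect_equal(nrow(m@atoms), expected)
  }
  # glycine carries no side-chain atoms at all
  mg <- graftSequence(fa, "GGGGGG")
  expect_true(all(mg@atoms$atom %in% c("N", "CA", "C", "O")))
})

test_that("grafting rejects malformed sequences", {
  fa <- expandFibril(TEMPLATES$ZIPPER_P1, 3, 1)
  expect_error(graftSequence(fa, "GGGGGGG"), "length")
  expect_error(graftSequence(fa, "GGXGGG"), "X")
  expect_error(graftSequence(fa, "GGBGGG"), "non-standard")
})

test_that("packing an all-glycine model changes nothing", {
  fa <- expandFibril(TEMPLATES$LARKS_STGGYS, 5, 2)
  m <- packSideChains(graftSequence(fa, "GGGGGG"))
  expect_equal(m@changedCycles, 0L)
  expect_true(m@converged)
})

test_that("packing energy is non-increasing and reaches the brute-force optimum", {
  w <- defaultEnergyWeights()
  # toy 3-residue template: full enumeration over the rotamer product
  t2 <- truncate_template(TEMPLATES$ZIPPER_P1, 3L)
  for (win in c("SCG", "TVS", "CTV", "VSC")) {
    m <- threadWindow(win, t2, weights = w)
    expect_true(all(diff(m@energyPath) <= 1e-9))
    oracle <- exhaustive_pack_min(t2, win, w)
    expect_equal(totalEnergy(m), oracle, tolerance = 1e-9)
  }
})

test_that("the energy breakdown identity holds to machine precision", {
  for (win in c("SGMGGI", "STGGYS")) {
    for (tmpl in TEMPLATES[c("LARKS_STGGYS", "ZIPPER_P1")]) {
      m <- threadWindow(win, tmpl)
      e <- m@energy
      expect_identical(e@total,
                       sum(e@weights[c("rep", "att", "solv", "hb")] *
                           c(e@rep, e@att, e@solv, e@hb)))
      expect_gte(e@rep, 0)
      expect_lte(e@att, 0)
      expect_lte(e@hb, 0)
    }
  }
})

test_that("a forced clash dominates the energy", {
  # collapsing the two sheets onto each other stacks backbones atop one
  # another at sub-vdW separations
  clash <- BackboneTemplate("clash", "zipper", idealBetaDihedrals(6),
                            rise = 4.8, sheetSep = 0.5, sheetStagger = 0)
  m <- graftSequence(expandFibril(clash, 2, 2), "GGGGGG")
  e <- m@energy
  expect_gt(e@rep, 0)
  expect_gt(e@weights["rep"] * e@rep, abs(e@weights["att"] * e@att))
  expect_gt(totalEnergy(m), 0)
})

test_that("threading is deterministic and rigid-motion invariant", {
  e1 <- totalEnergy(threadWindow("STGGYS", TEMPLATES$LARKS_STGGYS))
  e2 <- totalEnergy(threadWindow("STGGYS", TEMPLATES$LARKS_STGGYS))
  expect_identical(e1, e2)
  # rotate + translate the realized template coordinates; the energy
  # depends only on internal geometry
  set.seed(7)
  tr <- larkscreen:::random_rigid()
  tmpl <- TEMPLATES$LARKS_STGGYS
  tmpl@coords <- lapply(tmpl@coords, function(m) {
    out <- larkscreen:::apply_rigid(m, tr$R, tr$t)
    rownames(out) <- rownames(m)
    out
  })
  e3 <- totalEnergy(threadWindow("STGGYS", tmpl))
  expect_lt(abs(e3 - e1), 1e-6)
})

test_that("bulky cores cannot be accommodated on kinked backbones", {
  eG <- totalEnergy(packSideChains(graftSequence(
    expandFibril(TEMPLATES$LARKS_STGGYS, 5, 2), "GGGGGG")))
  eW <- totalEnergy(threadWindow("WWWWWW", TEMPLATES$LARKS_STGGYS))
  expect_gte(eW, eG)
})

test_that("the native kinked segment fits its own template at least as well as the zipper", {
  e_self <- totalEnergy(threadWindow("STGGYS", TEMPLATES$LARKS_STGGYS,
                                     weights = CONFIG@weights))
  e_zip <- totalEnergy(threadWindow("STGGYS", TEMPLATES$ZIPPER_P1,
                                    weights = CONFIG@weights))
  expect_lte(e_self, e_zip)
})

test_that("proline at a kink-incompatible position incurs a strain penalty", {
  # zipper phi (-120) lies outside the proline-compatible range
  ePG <- totalEnergy(threadWindow("GGPGGG", TEMPLATES$ZIPPER_P1))
  eGG <- totalEnergy(threadWindow("GGGGGG", TEMPLATES$ZIPPER_P1))
  expect_gt(ePG, eGG)
})
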