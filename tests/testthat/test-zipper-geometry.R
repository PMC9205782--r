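# Strand/sheet detection, zipper classification, conformation labels and
# buried interface area.

test_that("strand assignment recovers the two sheets of an ideal assembly", {
  z <- makeIdealZipperStructure(1, "SAVGYT", seed = 3,
                                nStrandsPerSheet = 5L)
  ss <- assignStrands(z$structure)
  expect_equal(sort(as.integer(table(ss@strands$sheet))), c(5L, 5L))
})

test_that("distant chains form singleton sheets and need >= 2 chains", {
  z <- makeIdealZipperStructure(1, "SAVGYT", seed = 1,
                                nStrandsPerSheet = 2L, sheetSep = 20)
  ss <- assignStrands(z$structure)
  # strands within a sheet still cluster; the two sheets stay separate
  expect_equal(length(unique(ss@strands$sheet)), 2L)
  one <- z$structure
  one@atoms <- one@atoms[one@atoms$chain == "A", ]
  expect_error(assignStrands(one), "single polymer chain")
})

test_that("reversing residue order flips the strand direction vector", {
  z <- makeIdealZipperStructure(1, "SAVGYT", seed = 2)
  ss <- assignStrands(z$structure)
  st <- z$structure
  a <- st@atoms
  aA <- a[a$chain == "A", ]
  aA$resno <- max(aA$resno) + min(aA$resno) - aA$resno
  aA <- aA[order(aA$resno), ]
  st2 <- StructureModel(rbind(aA, a[a$chain != "A", ]))
  ss2 <- assignStrands(st2)
  d1 <- as.numeric(ss@strands[ss@strands$chain == "A", c("dx", "dy", "dz")])
  d2 <- as.numeric(ss2@strands[ss2@strands$chain == "A",
                               c("dx", "dy", "dz")])
  expect_equal(d1, -d2, tolerance = 1e-9)
})

test_that("within-sheet orientation distinguishes parallel from antiparallel", {
  zp <- makeIdealZipperStructure(1, "SAVGYT", seed = 1)
  sp <- assignStrands(zp$structure)
  expect_equal(withinSheetOrientation(zp$structure, sp, 1L), "parallel")
  za <- makeIdealZipperStructure(5, "SAVGYT", seed = 1)
  sa <- assignStrands(za$structure)
  expect_equal(withinSheetOrientation(za$structure, sa, 1L),
               "antiparallel")
  # the G62C mutant assembly is a parallel sheet
  sx <- standinStructure("7K3X")
  ssx <- assignStrands(sx)
  expect_equal(withinSheetOrientation(sx, ssx, 1L), "parallel")
})

test_that("the classifier recovers every planted class across seeds", {
  for (cls in 1:8) {
    for (seed in 1:3) {
      z <- makeIdealZipperStructure(cls, "SAVGYT", seed = seed)
      got <- classifyZipper(z$structure)
      expect_equal(got@classNumber, cls)
      expect_equal(got@withinSheet, z$truth$within)
      expect_equal(got@facePacking, z$truth$face)
      expect_equal(got@sheetPolarity, z$truth$polarity)
    }
  }
})

test_that("classification is invariant to chain relabeling", {
  z <- makeIdealZipperStructure(7, "SGMGGIT", seed = 5)
  a <- z$structure@atoms
  relabel <- stats::setNames(rev(sort(unique(a$chain))),
                             sort(unique(a$chain)))
  a$chain <- unname(relabel[a$chain])
  got <- classifyZipper(StructureModel(a))
  expect_equal(got@classNumber, 7L)
})

test_that("the stand-in assemblies classify as their described classes", {
  expect_equal(classifyZipper(standinStructure("7K3C"))@classNumber, 7L)
  expect_equal(classifyZipper(standinStructure("7K3X"))@classNumber, 2L)
  expect_equal(classifyZipper(standinStructure("7K3Y"))@classNumber, 6L)
})

test_that("conformation labels partition the phi/psi plane as configured", {
  expect_equal(classifyBackboneConformation(-179, 179), "extended")
  expect_equal(classifyBackboneConformation(-120, 120), "pleated")
  expect_equal(classifyBackboneConformation(75, 20), "kinked")
  expect_equal(classifyBackboneConformation(-120, 20), "kinked")
  expect_equal(classifyBackboneConformation(-70, 160), "other")
})

test_that("pleat profiles label the interior residues of each chain", {
  z <- makeIdealZipperStructure(1, "SAVGYT", seed = 1)
  pp <- pleatProfile(z$structure, "A")
  expect_length(pp, 4L)  # n - 2 for terminal exclusion
  expect_true(all(pp == "pleated"))
  # the wild-type stand-in has the two central glycines extended
  ppc <- pleatProfile(standinStructure("7K3C"), "A")
  expect_equal(unname(ppc[c("61", "62")]), c("extended", "extended"))
  # ... and the G62C mutant is pleated at residue 62
  ppx <- pleatProfile(standinStructure("7K3X"), "A")
  expect_equal(unname(ppx["62"]), "pleated")
})

test_that("single-atom solvent-accessible area matches the closed form", {
  a <- shrakeRupleySasa(matrix(c(0, 0, 0), 1L), "C")
  expect_equal(a, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  # two distant atoms are additive; a close pair buries area
  far <- shrakeRupleySasa(matrix(c(0, 0, 0, 50, 0, 0), 2L, byrow = TRUE),
                          c("C", "C"))
  expect_equal(sum(far), 2 * 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  near <- shrakeRupleySasa(matrix(c(0, 0, 0, 2, 0, 0), 2L, byrow = TRUE),
                           c("C", "C"))
  expect_lt(sum(near), sum(far))
})

test_that("buried interface area behaves physically", {
  # no contact at 50 A separation
  z0 <- makeIdealZipperStructure(1, "AAAAAA", seed = 1, sheetSep = 50)
  expect_equal(buriedInterfaceArea(z0$structure), 0)
  # bigger side chains bury more area
  za <- makeIdealZipperStructure(1, "AAAAAA", seed = 1)
  zf <- makeIdealZipperStructure(1, "FFFFFF", seed = 1)
  ba <- buriedInterfaceArea(za$structure)
  bf <- buriedInterfaceArea(zf$structure)
  expect_gt(ba, 0)
  expect_gt(bf, ba)
  # sphere-point convergence: doubling the density moves the result < 2%
  b2 <- buriedInterfaceArea(zf$structure, nPoints = 1920L)
  expect_lt(abs(b2 - bf) / b2, 0.02)
})

test_that("geometry outputs are invariant under global rigid motion", {
  z <- makeIdealZipperStructure(3, "SAVGYT", seed = 9)
  a <- z$structure@atoms
  set.seed(99)
  tr <- larkscreen:::random_rigid()
  xyz <- larkscreen:::apply_rigid(as.matrix(a[, c("x", "y", "z")]),
                                  tr$R, tr$t)
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  moved <- StructureModel(a)
  expect_equal(classifyZipper(moved)@classNumber, 3L)
  # the sphere-point lattice is fixed in space, so rotation changes the
  # numerical SASA within its sampling error
  expect_equal(buriedInterfaceArea(moved, nPoints = 960L),
               buriedInterfaceArea(z$structure, nPoints = 960L),
               tolerance = 0.05)
})
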