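# Backbone construction from dihedral tables and fibril expansion.

test_that("built backbones reproduce their input dihedrals exactly", {
  for (tab in list(idealBetaDihedrals(6),
                   idealBetaDihedrals(7, phi = -179, psi = 179),
                   TEMPLATES$LARKS_STGGYS@dihedrals)) {
    bb <- buildBackbone(tab)
    pp <- measurePhiPsi(bb)
    expect_lt(max(abs(pp[-1L, "phi"] - tab[-1L, "phi"])), 0.5)
    n <- nrow(tab)
    expect_lt(max(abs(pp[-n, "psi"] - tab[-n, "psi"])), 0.5)
  }
})

test_that("dihedral measurement agrees with the bio3d torsion oracle", {
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4L, 3L)
    mine <- larkscreen:::dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("an extended strand has CA-CA distances in the trans-peptide range", {
  bb <- buildBackbone(idealBetaDihedrals(7, phi = -179, psi = 179))
  cas <- t(vapply(bb, function(m) m["CA", ], numeric(3)))
  d <- sqrt(rowSums(diff(cas)^2))
  expect_true(all(d > 3.7 & d < 3.9))
})

test_that("dihedral table length must match the declared sequence length", {
  expect_error(buildBackbone(idealBetaDihedrals(5), 6), "5 rows")
})

test_that("rebuilding from measured dihedrals is a fixed point", {
  tab <- TEMPLATES$LARKS_SYSGYS@dihedrals
  bb1 <- buildBackbone(tab)
  pp <- measurePhiPsi(bb1)
  tab2 <- tab
  tab2[-1L, "phi"] <- pp[-1L, "phi"]
  tab2[-nrow(tab), "psi"] <- pp[-nrow(tab), "psi"]
  bb2 <- buildBackbone(tab2)
  a <- do.call(rbind, bb1)
  b <- do.call(rbind, bb2)
  expect_lt(larkscreen:::superpose_rmsd(a, b), 1e-3)
})

test_that("template validity enforces omega, rise and category constraints", {
  bad_omega <- idealBetaDihedrals(6)
  bad_omega[3L, "omega"] <- 140
  expect_error(BackboneTemplate("t", "zipper", bad_omega), "omega")
  expect_error(BackboneTemplate("t", "zipper", idealBetaDihedrals(6),
                                rise = 12), "rise")
  expect_error(BackboneTemplate("t", "nonsense", idealBetaDihedrals(6)),
               "category")
})

test_that("the built-in set is three kinked LARKS templates plus one zipper", {
  expect_named(TEMPLATES, c("LARKS_STGGYS", "LARKS_SYSGYS", "LARKS_GYNGFG",
                            "ZIPPER_P1"))
  cats <- vapply(TEMPLATES, function(t) t@category, "")
  expect_equal(sum(cats == "LARKS"), 3L)
  expect_equal(sum(cats == "zipper"), 1L)
  # zipper: every residue pleated; LARKS: at least one kinked residue
  zd <- TEMPLATES$ZIPPER_P1@dihedrals
  labs <- classifyBackboneConformation(zd[, "phi"], zd[, "psi"])
  expect_true(all(labs == "pleated"))
  for (t in TEMPLATES[1:3]) {
    d <- t@dihedrals
    labs <- classifyBackboneConformation(d[-1L, "phi"],
                                         d[-nrow(d), "psi"])
    expect_true("kinked" %in% labs)
  }
})

test_that("fibril expansion produces exact rigid strand copies", {
  tmpl <- TEMPLATES$ZIPPER_P1
  fa <- expandFibril(tmpl, 5, 2)
  expect_equal(nrow(fa@strandInfo), 10L)
  ref <- do.call(rbind, tmpl@coords)
  for (bb in assemblyBackbones(fa)) {
    expect_lt(larkscreen:::superpose_rmsd(do.call(rbind, bb), ref), 1e-6)
  }
  # identity expansion
  fa1 <- expandFibril(tmpl, 1, 1)
  bb1 <- assemblyBackbones(fa1)[[1L]]
  expect_equal(do.call(rbind, bb1), ref, tolerance = 1e-12)
})

test_that("stacked strands of the pleated template are hydrogen-bond capable", {
  # adjacent in-sheet N...O distances must fall in the hydrogen-bond range
  # carbonyls alternate along a beta-strand, so each stacking interface
  # carries hydrogen bonds in both axial directions
  fa <- expandFibril(TEMPLATES$ZIPPER_P1, 5, 1)
  bbs <- assemblyBackbones(fa)
  in_range <- function(donor_strand, acceptor_strand) {
    sum(vapply(seq_along(bbs[[acceptor_strand]]), function(i) {
      O <- bbs[[acceptor_strand]][[i]]["O", ]
      d <- min(vapply(seq_along(bbs[[donor_strand]]), function(j)
        sqrt(sum((bbs[[donor_strand]][[j]]["N", ] - O)^2)), 0))
      d >= 2.6 && d <= 3.3
    }, logical(1)))
  }
  nn <- 0L
  for (s in 1:4) nn <- nn + in_range(s + 1L, s) + in_range(s, s + 1L)
  expect_gte(nn, 16L)  # at least two bonds per direction per interface
})
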