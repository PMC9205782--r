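# Seeded generators: proteomes, variant tables, idealized assemblies.

test_that("proteome generation is a pure function of (spec, seed)", {
  spec <- SyntheticSpec(seed = 3, nProteins = 4L)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  writeProteinFasta(generateSyntheticProteome(spec)$proteins, f1)
  writeProteinFasta(generateSyntheticProteome(spec)$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted windows are recorded and sit inside their proteins", {
  spec <- SyntheticSpec(seed = 4, nProteins = 10L, nPlantedPerProtein = 3L)
  pr <- generateSyntheticProteome(spec)
  expect_equal(nrow(pr$truth), 30L)
  for (i in seq_len(nrow(pr$truth))) {
    w <- pr$truth[i, ]
    p <- pr$proteins[[w$protein_id]]
    expect_equal(substr(p@sequence, w$start, w$end), w$sequence)
    expect_equal(substr(p@sequence, w$kink_pos, w$kink_pos), "G")
  }
})

test_that("LCD composition matches the profile within sampling error", {
  spec <- SyntheticSpec(seed = 6, nProteins = 20L)
  pr <- generateSyntheticProteome(spec)
  # pool non-planted LCD positions across proteins
  pool <- character(0)
  for (i in seq_len(nrow(pr$lcd))) {
    row <- pr$lcd[i, ]
    p <- pr$proteins[[row$protein_id]]
    idx <- seq(row$lcd_start, row$lcd_end)
    pw <- pr$truth[pr$truth$protein_id == row$protein_id, ]
    for (j in seq_len(nrow(pw))) idx <- setdiff(idx, pw$start[j]:pw$end[j])
    pool <- c(pool, strsplit(p@sequence, "")[[1L]][idx])
  }
  target <- sum(spec@composition[c("G", "S", "Y")])
  obs <- mean(pool %in% c("G", "S", "Y"))
  se <- sqrt(target * (1 - target) / length(pool))
  expect_lt(abs(obs - target), 3 * se)
})

test_that("generated variant tables are valid and internally consistent", {
  spec <- SyntheticSpec(seed = 8)
  pr <- generateSyntheticProteome(spec)
  vr <- generateSyntheticVariants(pr, spec)
  f <- tempfile(fileext = ".tsv")
  writeVariantTable(vr$variants, f)
  expect_identical(nrow(readVariantTable(f)), nrow(vr$variants))
  # every row's wild type matches the sequence
  for (i in seq_len(nrow(vr$variants))) {
    v <- vr$variants[i, ]
    p <- pr$proteins[[v$protein_id]]
    expect_equal(substr(p@sequence, v$position, v$position), v$wt)
  }
  # planted fraction reaches the configured target
  patho <- vr$truth[vr$truth$significance == "pathogenic", ]
  expect_gte(mean(patho$planted), spec@pathogenicInPlantedFrac)
  # reproducibility
  vr2 <- generateSyntheticVariants(generateSyntheticProteome(spec), spec)
  expect_identical(vr$variants, vr2$variants)
})

test_that("the eight zipper classes have distinct attribute triples", {
  triples <- vapply(1:8, function(cls) {
    z <- makeIdealZipperStructure(cls, "SAVGYT", seed = 1L)
    paste(z$truth$within, z$truth$face, z$truth$polarity)
  }, "")
  expect_equal(length(unique(triples)), 8L)
  z1 <- makeIdealZipperStructure(1, "SAVGYT", seed = 1L)
  expect_equal(z1$truth$within, "parallel")
  expect_error(makeIdealZipperStructure(9, "SAVGYT"), "1..8")
  expect_error(makeIdealZipperStructure(1, "SAV"), "6 or 7")
})

test_that("idealized assemblies are seeded-reproducible", {
  a <- makeIdealZipperStructure(4, "SGMGGI", seed = 10L)$structure
  b <- makeIdealZipperStructure(4, "SGMGGI", seed = 10L)$structure
  expect_identical(a@atoms, b@atoms)
  c <- makeIdealZipperStructure(4, "SGMGGI", seed = 11L)$structure
  expect_false(identical(a@atoms$x, c@atoms$x))
})
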