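# Window extraction, mutation application, scanning, variant mapping,
# zipper pairs, heat map and summaries.

test_that("window extraction honours the numbering offset", {
  krt8 <- FIXTURES$proteins$KRT8
  expect_equal(extractWindow(krt8, 58, 64)@sequence, "SGMGGIT")
  expect_equal(extractWindow(krt8, 52, 58)@sequence, "GGYGGAS")
  expect_error(extractWindow(krt8, 1, 7), "outside the numbered range")
})

test_that("mutations apply at the stated residue and guard the wild type", {
  krt8 <- FIXTURES$proteins$KRT8
  w1 <- extractWindow(krt8, 58, 64)
  m1 <- applyMutation(w1, data.frame(position = 62, wt = "G", mut = "C"))
  expect_equal(m1@sequence, "SGMGCIT")
  w2 <- extractWindow(krt8, 52, 58)
  m2 <- applyMutation(w2, data.frame(position = 55, wt = "G", mut = "A"))
  expect_equal(m2@sequence, "GGYAGAS")
  expect_error(applyMutation(w1, data.frame(position = 62, wt = "A",
                                            mut = "C")),
               "wild-type mismatch")
})

test_that("scanning evaluates every sliding window", {
  krt8 <- FIXTURES$proteins$KRT8
  calls <- scanLarks(krt8, TEMPLATES, CONFIG)
  expect_equal(nrow(calls), 84L)       # L - k + 1 = 89 - 6 + 1
  expect_equal(calls$start[1L], 2L)    # numbering starts at the offset
  expect_true(all(calls$accepted == (calls$E_larks <= CONFIG@tauL)))
  expect_gte(sum(calls$accepted & calls$start %in% 52:59), 1L)
})

test_that("windows containing X are skipped with a warning", {
  p <- ProteinRecord("PX", "GGGGGXGGGGG")
  expect_warning(calls <- scanLarks(p, TEMPLATES, CONFIG), "skipped")
  expect_equal(nrow(calls), 0L)   # every 6-mer covers the central X
})

test_that("an all-tryptophan sequence yields no accepted windows", {
  p <- ProteinRecord("POLYW", strrep("W", 30L))
  calls <- scanLarks(p, TEMPLATES, CONFIG)
  expect_equal(nrow(calls), 25L)
  expect_equal(sum(calls$accepted), 0L)
})

test_that("variant mapping is interval containment with set semantics", {
  calls <- data.frame(protein_id = "P", start = c(10L, 12L, 30L),
                      end = c(15L, 17L, 35L),
                      sequence = c("GGGGGG", "GGGGGG", "GGGGGG"),
                      best_template = "LARKS_STGGYS",
                      E_larks = c(-5, -4, 100),
                      accepted = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  v <- data.frame(protein_id = "P", position = c(13L, 33L, 50L),
                  wt = "G", mut = "V", significance = "other",
                  source = "x", stringsAsFactors = FALSE)
  m <- mapVariantsToLarks(v, calls)
  expect_length(m, 1L)                       # 33 only hits a rejected
  expect_equal(attr(m, "n_unmatched"), 2L)   # window; 50 hits nothing
  expect_equal(nrow(m[[1L]]$windows), 2L)
  m2 <- mapVariantsToLarks(v, calls[c(3, 1, 2), ])
  expect_equal(nrow(m2[[1L]]$windows), 2L)   # order of calls irrelevant
})

test_that("zipper pairs have exact delta identity and antisymmetry", {
  krt8 <- FIXTURES$proteins$KRT8
  w <- extractWindow(krt8, 58, 63)
  v <- data.frame(position = 62, wt = "G", mut = "C")
  p <- scoreZipperPair(v, w, TEMPLATES$ZIPPER_P1, CONFIG)
  expect_identical(p$delta, p$E_zip_mut - p$E_zip_wt)
  expect_lt(p$delta, 0)
  # swapping roles flips the sign exactly
  wm <- applyMutation(w, v)
  vb <- data.frame(position = 62, wt = "C", mut = "G")
  pb <- scoreZipperPair(vb, wm, TEMPLATES$ZIPPER_P1, CONFIG)
  expect_equal(pb$delta, -p$delta, tolerance = 1e-12)
  # a window scored against itself can never convert
  self <- scoreZipperPair(data.frame(position = 58, wt = "S", mut = "S"),
                          w, TEMPLATES$ZIPPER_P1, CONFIG)
  expect_identical(self$delta, 0)
  expect_false(self$converted)
})

test_that("the mutation heat map counts transitions with a zero diagonal", {
  v <- data.frame(wt = c("G", "G", "P"), mut = c("V", "V", "L"))
  m <- mutationHeatmap(v)
  expect_equal(m["G", "V"], 2L)
  expect_equal(m["P", "L"], 1L)
  expect_equal(sum(m), 3L)
  expect_true(all(diag(m) == 0L))
  expect_equal(sum(mutationHeatmap(v[0, ])), 0L)
})

test_that("glycine dominates the heat map of a pathogenic-like table", {
  spec <- SyntheticSpec(seed = 5)
  pr <- generateSyntheticProteome(spec)
  vr <- generateSyntheticVariants(pr, spec)
  patho <- vr$variants[vr$variants$significance == "pathogenic", ]
  m <- mutationHeatmap(patho)
  expect_equal(unname(which.max(rowSums(m))), match("G", rownames(m)))
})

test_that("residue-context enrichment is a frequency ratio", {
  v <- data.frame(wt = rep("G", 5L), mut = rep("V", 5L))
  bg <- stats::setNames(rep(0.05, 20L), larkscreen:::AA1)
  e <- residueContextEnrichment(v, bg)
  expect_equal(e$wt_enrichment[e$residue == "G"], 20)
  expect_equal(e$mut_enrichment[e$residue == "V"], 20)
  # duplicating the table changes nothing
  e2 <- residueContextEnrichment(rbind(v, v), bg)
  expect_equal(e$wt_enrichment, e2$wt_enrichment)
  # empty input, empty table
  expect_equal(nrow(residueContextEnrichment(v[0, ], bg)), 0L)
  # zero background flagged
  bg0 <- bg; bg0["G"] <- 0
  expect_warning(e3 <- residueContextEnrichment(v, bg0), "zero background")
  expect_true(is.na(e3$wt_enrichment[e3$residue == "G"]))
})

test_that("group comparison reports medians, fractions and a scatter table", {
  pairs <- data.frame(E_zip_mut = c(-5, -1, 3), delta = c(-2, -1, 1),
                      converted = c(TRUE, TRUE, FALSE))
  out <- comparePathogenicBenign(pairs, pairs)
  expect_equal(out$summary$median_delta, c(-1, -1))
  expect_equal(diff(out$summary$fraction_converted), 0)
  expect_equal(nrow(out$scatter), 6L)
  expect_error(comparePathogenicBenign(pairs, pairs[0, ]), "non-empty")
})

test_that("the full screen matches the KRT8 variants and is deterministic", {
  krt8 <- FIXTURES$proteins["KRT8"]
  vars <- FIXTURES$variants[FIXTURES$variants$protein_id == "KRT8", ]
  r1 <- runScreen(krt8, vars, CONFIG)
  expect_equal(nrow(r1@calls), 3L)             # all three variants matched
  expect_true(all(r1@calls$delta < 0))
  expect_equal(r1@unmatched, 0L)
  r2 <- runScreen(krt8, vars, CONFIG)
  expect_identical(r1@calls, r2@calls)
  # heat-map totals conserve the variant count
  expect_equal(sum(r1@heatmap), nrow(vars))
})

test_that("an impossible LARKS threshold empties the screen with a warning", {
  krt8 <- FIXTURES$proteins["KRT8"]
  vars <- FIXTURES$variants[FIXTURES$variants$protein_id == "KRT8", ]
  cfg <- ScreenConfig(tauL = -Inf)
  expect_warning(r <- runScreen(krt8, vars, cfg), "no variant")
  expect_equal(nrow(r@calls), 0L)
})

test_that("variants contradicting the sequence are quarantined", {
  krt8 <- FIXTURES$proteins["KRT8"]
  vars <- data.frame(protein_id = "KRT8", position = c(62L, 62L),
                     wt = c("G", "A"), mut = c("C", "C"),
                     significance = "pathogenic", source = "x",
                     stringsAsFactors = FALSE)
  r <- runScreen(krt8, vars, CONFIG)
  expect_equal(nrow(r@calls), 1L)
  expect_equal(nrow(r@rejected), 1L)
  expect_equal(r@rejected$wt, "A")
})

test_that("screen reports are written as TSV and JSON", {
  krt8 <- FIXTURES$proteins["KRT8"]
  vars <- FIXTURES$variants[FIXTURES$variants$protein_id == "KRT8", ]
  r <- runScreen(krt8, vars, CONFIG)
  stem <- tempfile()
  writeScreenReport(r, stem)
  expect_true(file.exists(paste0(stem, "_calls.tsv")))
  j <- jsonlite::read_json(paste0(stem, ".json"))
  expect_length(j$calls, 3L)
})

test_that("LARKS ranking orders accepted windows by ascending energy", {
  krt8 <- FIXTURES$proteins$KRT8
  calls <- scanLarks(krt8, TEMPLATES, CONFIG)
  top <- rankLarks(calls, 5)
  expect_equal(nrow(top), 5L)
  expect_true(all(diff(top$E_larks) >= 0))
  expect_true(all(top$accepted))
  expect_equal(top$rank, 1:5)
})
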