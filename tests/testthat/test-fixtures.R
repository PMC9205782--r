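# Bundled reference material: sequences, segment pairs, mutation table.

test_that("the bundled sequences carry their hallmark regions", {
  fx <- FIXTURES
  expect_true(grepl("GGITAVTVNQ", fx$proteins$KRT8@sequence, fixed = TRUE))
  expect_true(grepl("QVTNVGGAVVTGVTAV", fx$proteins$ASYN@sequence,
                    fixed = TRUE))
  expect_equal(fx$proteins$KRT8@offset, 2L)
  expect_equal(proteinLength(fx$proteins$ASYN), 140L)
})

test_that("the crystallized segment entries follow the two-pairs-plus-one shape", {
  sp <- FIXTURES$segment_pairs
  expect_equal(nrow(sp), 3L)
  expect_equal(sum(sp$wt_crystallized & sp$mut_crystallized), 1L)  # G62C
  expect_equal(sum(!sp$wt_crystallized & sp$mut_crystallized), 1L) # G55A
  expect_equal(sum(!sp$wt_crystallized & !sp$mut_crystallized), 1L) # Y54H
  expect_equal(sp$mut_segment[sp$variant == "G62C"], "SGMGCIT")
})

test_that("every KRT8 row of the mutation table is consistent with the sequence", {
  krt8 <- FIXTURES$proteins$KRT8
  tab <- FIXTURES$mutation_table
  rows <- tab[tab$protein == "KRT8", ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    # locate the wild-type window in the numbered sequence
    hit <- regexpr(r$wt_window, krt8@sequence, fixed = TRUE)[1L]
    expect_gt(hit, 0L)
    start <- hit + krt8@offset - 1L
    w <- extractWindow(krt8, start, start + 5L)
    expect_equal(w@sequence, r$wt_window)
    m <- applyMutation(w, data.frame(position = r$position, wt = r$wt,
                                     mut = r$mut))
    expect_equal(m@sequence, r$mut_window)
  }
})

test_that("mutation-table rows are single substitutions of the stated residues", {
  tab <- FIXTURES$mutation_table
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    a <- strsplit(r$wt_window, "")[[1L]]
    b <- strsplit(r$mut_window, "")[[1L]]
    diffpos <- which(a != b)
    expect_length(diffpos, 1L)
    expect_equal(a[diffpos], r$wt)
    expect_equal(b[diffpos], r$mut)
  }
})

test_that("the beta-sheet background frequencies are a distribution", {
  bg <- FIXTURES$beta_frequencies
  expect_setequal(names(bg), larkscreen:::AA1)
  expect_equal(sum(bg), 1)
  expect_true(all(bg > 0))
})
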