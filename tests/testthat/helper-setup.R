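# Shared objects for the test suite.  Threading results are memoized inside
# the package, so repeated scoring of the same window is cheap across tests.

TEMPLATES <- builtinTemplates()
CONFIG <- ScreenConfig()
FIXTURES <- referenceFixtures()

larks_energy <- function(window, config = CONFIG) {
  min(vapply(TEMPLATES[1:3], function(t)
    larkscreen:::threaded_energy(window, t, config), 0))
}

zipper_energy <- function(window, config = CONFIG) {
  larkscreen:::threaded_energy(window, TEMPLATES$ZIPPER_P1, config)
}

# Exhaustive-enumeration packing oracle: minimum weighted energy over the
# full rotamer product space (independent of the iterative packer).
exhaustive_pack_min <- function(template, sequence, weights,
                                nStrands = 5L, nSheets = 2L) {
  asm <- expandFibril(template, nStrands, nSheets)
  eng <- larkscreen:::build_engine(asm, sequence)
  nr <- vapply(eng$blocks, length, 0L)
  grid <- expand.grid(lapply(nr, seq_len))
  min(apply(grid, 1L, function(r) {
    raw <- larkscreen:::engine_full_raw(eng, as.integer(r))
    sum(weights[c("rep", "att", "solv", "hb")] *
        raw[c("rep", "att", "solv", "hb")])
  }))
}

# a template truncated to its first n residues
truncate_template <- function(template, n) {
  BackboneTemplate(paste0(template@name, "_trunc"), template@category,
                   template@dihedrals[seq_len(n), , drop = FALSE],
                   rise = template@rise, sheetSep = template@sheetSep,
                   sheetStagger = template@sheetStagger,
                   packing = template@packing)
}
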