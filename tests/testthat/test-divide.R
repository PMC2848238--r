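test_that("identical sequences align gap-free with score 100", {
  s <- c(a = strrep("ACGTTGCA", 100), b = strrep("ACGTTGCA", 100))
  aln <- anchorAlign(s, anchorAlignControl(segmentThreshold = 100))
  expect_equal(width(aln), 800L)
  expect_false(any(grepl("-", alignedRows(aln), fixed = TRUE)))
  expect_equal(spMean(spIdentityScore(aln)), 100)
})

test_that("pipeline output always degaps to the inputs and assembles by blocks", {
  fam <- evolveFamily(3000, 5, subRate = 0.01, indelRate = 0.002,
                      rngSeed = 13)
  aln <- anchorAlign(fam$sequences, anchorAlignControl(segmentThreshold = 500))
  expect_identical(unname(degapRows(aln)),
                   unname(toupper(as.character(fam$sequences))))
  st <- aln@stats
  expect_gt(st$topAnchors, 0)
  expect_equal(st$perDepth$segments[1], st$perDepth$anchors[1] + 1L)
})

test_that("a sequence with an empty interval gets an all-gap row there", {
  # anchors chosen so the middle segment is empty for sequence b
  s <- c(a = paste0("AAAA", "ACGTACG", "TTTTT", "GGGGGCC", "AAAA"),
         b = paste0("CC", "ACGTACG", "GGGGGCC", "TT"))  # empty mid interval
  anc <- new("AnchorSet", ktuple = c("ACGTACG", "GGGGGCC"), k = c(7L, 7L),
             positions = rbind(c(5L, 3L), c(17L, 10L)),
             exactSeqs = c(2L, 2L), seqnames = c("a", "b"),
             seqlengths = nchar(s))
  aln <- seedsOnlyAlignment(s, anc)
  expect_identical(unname(degapRows(aln)), unname(s))
  # middle segment: a has TTTTT (5 bp), b is empty -> 5 gap columns in b
  rows <- alignedRows(aln)
  expect_identical(substr(rows[["b"]], 12, 16), "-----")
  expect_identical(substr(rows[["a"]], 12, 16), "TTTTT")
})

test_that("seeds-only padding left-justifies to the widest interval", {
  s <- c(a = "CCACGTACGTACGTAAA", b = "GGGGGACGTACGTACGTAAAAA")
  anc <- resolveConflicts(locateSeeds(s, "ACGTACGTACGT"))
  aln <- seedsOnlyAlignment(s, anc)
  expect_identical(unname(degapRows(aln)), unname(s))
  # leading segment widths {2,5}: first row is "CC---"
  expect_identical(substr(alignedRows(aln)[["a"]], 1, 5), "CC---")
  # width = left block + anchor k + right block = 5 + 12 + 5
  expect_equal(width(aln), 22L)
})

test_that("max depth limits anchoring rounds and seeds-only never sub-aligns", {
  fam <- evolveFamily(4000, 4, subRate = 0.002, indelRate = 0, rngSeed = 31)
  # T = 5 leaves long inter-anchor segments so recursion actually happens
  deep <- anchorAlign(fam$sequences,
                      anchorAlignControl(T = 5, segmentThreshold = 300))
  shallow <- anchorAlign(fam$sequences,
                         anchorAlignControl(T = 5, segmentThreshold = 300,
                                            maxDepth = 1))
  expect_gt(max(deep@stats$perDepth$depth), 1)
  expect_equal(max(shallow@stats$perDepth$depth), 1L)
  # identical top-level anchors regardless of depth policy
  expect_equal(deep@stats$topAnchors, shallow@stats$topAnchors)

  rough <- anchorAlign(fam$sequences,
                       anchorAlignControl(seedsOnly = TRUE, maxDepth = 1))
  expect_equal(rough@stats$subAlignerCalls, 0L)
  expect_identical(unname(degapRows(rough)),
                   unname(toupper(as.character(fam$sequences))))
})

test_that("runs are deterministic", {
  fam <- evolveFamily(2500, 4, subRate = 0.01, indelRate = 0.003,
                      rngSeed = 55)
  ctl <- anchorAlignControl(segmentThreshold = 400)
  a1 <- anchorAlign(fam$sequences, ctl)
  a2 <- anchorAlign(fam$sequences, ctl)
  expect_identical(alignedRows(a1), alignedRows(a2))
})

test_that("zero anchors routes the whole set to the sub-aligner", {
  # two short unrelated sequences: no shared unique k-tuples of any length
  s <- c(a = "ACACACACACAC", b = "GTGTGTGTGT")
  aln <- anchorAlign(s, anchorAlignControl())
  expect_identical(unname(degapRows(aln)), unname(s))
  expect_equal(aln@stats$topAnchors, 0L)
  expect_equal(aln@stats$subAlignerCalls, 1L)
})

test_that("anchored alignment scores at least close to whole-set alignment", {
  fam <- evolveFamily(1500, 5, subRate = 0.01, indelRate = 0.002,
                      rngSeed = 17)
  anchored <- anchorAlign(fam$sequences,
                          anchorAlignControl(segmentThreshold = 250))
  whole <- builtinAlign(fam$sequences)
  expect_gte(spMean(spIdentityScore(anchored)),
             spMean(spIdentityScore(whole)) - 1)
})
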