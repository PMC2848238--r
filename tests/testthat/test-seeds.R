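test_that("planted motifs are located at their planted positions", {
  set.seed(77)
  motif <- "ACGTACGTACGT"
  at <- c(31L, 11L, 51L, 21L, 41L)
  seqs <- vapply(seq_len(5), function(i) {
    s <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
    paste(s, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:5)
  planted <- seqs
  for (i in 1:5)
    substr(planted[[i]], at[[i]], at[[i]] + 11L) <- motif
  # keep only replicates where the plant is genuinely unique (random
  # backgrounds may contain accidental near-matches)
  orc <- oracle_locate(planted, motif)
  if (all(lengths(orc) == 1L)) {
    seeds <- locateSeeds(planted, motif)
    expect_length(seeds, 1)
    expect_equal(unname(seedPositions(seeds)[1, ]), at)
    expect_equal(seeds@exactSeqs, 5L)
  }
  # independently: oracle and locateSeeds agree on arbitrary candidates
  cand <- c("ACGTACGTACGT", "TTTTTTTTTTTT", "ACGTACGTACGA")
  seeds2 <- locateSeeds(planted, cand)
  for (kt in cand) {
    o <- oracle_locate(planted, kt)
    if (all(lengths(o) == 1L)) {
      expect_true(kt %in% seedKtuples(seeds2))
      expect_equal(unname(seedPositions(seeds2)[match(kt, seedKtuples(seeds2)), ]),
                   unname(unlist(o)))
    } else {
      expect_false(kt %in% seedKtuples(seeds2))
    }
  }
})

test_that("candidates occurring twice in one sequence are dropped", {
  seqs <- c(s1 = "AATTTACGTCTTTTT", s2 = "GGGGGACGTCGGGGACGTCGG")
  expect_length(locateSeeds(seqs, "ACGTC"), 0)   # twice in s2
  seqs2 <- c(s1 = "AATTTACGTCTTTTT", s2 = "GGGGGACGTCGGGGGGG")
  s <- locateSeeds(seqs2, "ACGTC")
  expect_length(s, 1)
  expect_equal(unname(seedPositions(s)[1, ]), c(6L, 6L))
})

test_that("ranking orders by k, exactness, position and is cap- and permutation-stable", {
  # k = 12 exact everywhere beats k = 8 with a mismatched window
  s <- new("SeedSet",
           ktuple = c("ACGTACGT", "ACGTACGTACGT"), k = c(8L, 12L),
           positions = matrix(c(100L, 300L, 100L, 300L), 2, 2),
           exactSeqs = c(1L, 2L), seqnames = c("a", "b"),
           seqlengths = c(1000L, 1000L))
  r <- rankSeeds(s, 600)
  expect_equal(seedKtuples(r), c("ACGTACGTACGT", "ACGTACGT"))

  # 700 non-overlapping seeds, T = 600 -> exactly 600, permutation-invariant
  P <- matrix(rep(seq(1L, by = 20L, length.out = 700L), 3), 700, 3)
  big <- make_seedset(P, k = 5, seqlen = 20000L)
  r600 <- rankSeeds(big, 600)
  expect_length(r600, 600)
  perm <- sample(700)
  shuffled <- AnchorAlign:::.subset_seeds(big, perm)
  expect_identical(seedKtuples(rankSeeds(shuffled, 600)),
                   seedKtuples(r600))
  expect_identical(seedPositions(rankSeeds(shuffled, 600)),
                   seedPositions(r600))
})

test_that("overlap-aware selection spreads seeds instead of clustering", {
  # 50 seeds at consecutive positions, k = 5: pure rank order would pick
  # mutually overlapping ones; selection must keep only spaced seeds
  P <- matrix(rep(1:50, 2), 50, 2)
  s <- make_seedset(P, k = 5, seqlen = 100L)
  r <- rankSeeds(s, 600)
  pos <- sort(seedPositions(r)[, 1])
  expect_true(all(diff(pos) >= 5))
})

test_that("incompatibility distance counts the minority, overlaps against both", {
  # same order in all 5 sequences -> 0
  a_then_b <- make_seedset(rbind(rep(10L, 5), rep(100L, 5)), k = 5)
  expect_equal(incompatibilityDistance(a_then_b, 1, 2), 0L)
  # 3 sequences a<b, 2 sequences b<a -> distance 2
  mixed <- make_seedset(rbind(c(10L, 10L, 10L, 200L, 200L),
                              c(100L, 100L, 100L, 20L, 20L)), k = 5)
  expect_equal(incompatibilityDistance(mixed, 1, 2), 2L)
  # N = 4 tie (2 vs 2) -> distance 2
  tie <- make_seedset(rbind(c(10L, 10L, 200L, 200L),
                            c(100L, 100L, 20L, 20L)), k = 5)
  expect_equal(incompatibilityDistance(tie, 1, 2), 2L)
  # overlap in one sequence counts against both orders
  ovl <- make_seedset(rbind(c(10L, 10L), c(12L, 100L)), k = 5)
  expect_equal(incompatibilityDistance(ovl, 1, 2), 1L)
  # symmetry, everywhere
  set.seed(11)
  for (i in 1:20) {
    P <- matrix(sample(1000L, 8), 2, 4)
    s <- make_seedset(P, k = 3)
    expect_equal(incompatibilityDistance(s, 1, 2),
                 incompatibilityDistance(s, 2, 1))
  }
})

test_that("the matrix matches pairwise distances, is symmetric, zero diagonal", {
  set.seed(5)
  P <- matrix(sample(5000L, 6 * 8), 6, 8)
  s <- make_seedset(P, k = 4)
  m <- incompatibilityMatrix(s)
  expect_true(validObject(m))
  for (a in 1:6) for (b in 1:6)
    if (a != b)
      expect_equal(m@D[a, b], incompatibilityDistance(s, a, b))
})

test_that("conflict resolution removes minimally on worked cases", {
  # 3 mutually compatible seeds -> all kept, in coordinate order
  compat <- make_seedset(rbind(rep(300L, 4), rep(10L, 4), rep(150L, 4)),
                         k = 5)
  a <- resolveConflicts(compat)
  expect_s4_class(a, "AnchorSet")
  expect_length(a, 3)
  expect_equal(unname(seedPositions(a)[, 1]), c(10L, 150L, 300L))

  # one seed conflicting with two that agree -> the conflicting one removed
  conflicted <- make_seedset(rbind(
    c(10L, 10L, 10L, 10L),      # A
    c(100L, 100L, 100L, 100L),  # B, compatible with A
    c(200L, 200L, 5L, 5L)),     # C, conflicts with both
    k = 5)
  res <- resolveConflicts(conflicted)
  expect_length(res, 2)
  expect_equal(oracle_min_removals(conflicted), 1L)
  expect_equal(3L - length(res), oracle_min_removals(conflicted))
  expect_true(all(incompatibilityMatrix(res)@D == 0))

  # all pairs mutually incompatible -> exactly one anchor survives
  allbad <- make_seedset(rbind(
    c(10L, 200L, 10L),
    c(100L, 100L, 100L),
    c(200L, 10L, 200L)), k = 5)
  D <- incompatibilityMatrix(allbad)@D
  expect_true(all(D[upper.tri(D)] > 0))
  expect_length(resolveConflicts(allbad), 1)
})

test_that("resolved anchor sets are always collinear and conflict-free", {
  set.seed(99)
  for (i in 1:25) {
    S <- sample(3:10, 1)
    N <- sample(2:6, 1)
    P <- matrix(sample(2000L, S * N, replace = TRUE), S, N)
    s <- make_seedset(P, k = 4, seqlen = 3000L)
    a <- resolveConflicts(s)
    expect_gte(length(a), 1)
    expect_true(validObject(a))          # collinearity + non-overlap validity
    if (length(a) > 1) {
      expect_true(all(incompatibilityMatrix(a)@D == 0))
      pos <- seedPositions(a)
      for (col in seq_len(N))
        expect_true(all(diff(pos[, col]) >= a@k[-length(a@k)]))
    }
  }
})

test_that("anchor reports serialize positions for every sequence", {
  s <- make_seedset(rbind(rep(10L, 3), rep(100L, 3)), k = 5)
  a <- resolveConflicts(s)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAnchors(a, f)
  rep <- read.delim(f)
  expect_equal(nrow(rep), 2)
  expect_equal(ncol(rep), 2 + 3)
  expect_equal(rep$start.s1, c(10L, 100L))
})
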