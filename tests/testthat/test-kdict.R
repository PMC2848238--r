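test_that("exact counts follow overlap semantics on worked examples", {
  d <- buildDictionary(c(s1 = "ACGT"), M = 2)
  st <- ktupleStats(d, c("AC", "CG", "GT", "A", "C", "G", "T"))
  expect_equal(st$exact_count, rep(1L, 7))
  expect_equal(st$seq_count, rep(1L, 7))

  d2 <- buildDictionary(c(s1 = "AAAA"), M = 2)
  st2 <- ktupleStats(d2, c("AA", "A"))
  expect_equal(st2$exact_count, c(3L, 4L))   # overlapping windows count
  expect_equal(st2$seq_count, c(1L, 1L))
})

test_that("windows overlapping non-ACGT characters are skipped", {
  d <- buildDictionary(c(s1 = "ACNGT"), M = 2)
  st <- ktupleStats(d, c("AC", "GT", "CG", "CA"))
  expect_equal(st$exact_count, c(1L, 1L, 0L, 0L))
  # conservation: per-k totals equal the windows free of ambiguity codes
  expect_equal(sum(d@tables[[2]]$exact), 2L)  # AC and GT only
  expect_equal(sum(d@tables[[1]]$exact), 4L)  # A, C, G, T (not N)
})

test_that("one-substitution neighbourhood has size 3k and drives inexact counts", {
  d <- addInexactCounts(buildDictionary(c(s1 = "AAC", s2 = "AAG"), M = 3))
  st <- ktupleStats(d, "AAC")
  expect_equal(st$exact_count, 1L)
  expect_equal(st$inexact_count, 2L)   # AAC + its neighbour AAG
  # neighbourhood combinatorics for k = 2: exactly 6 neighbours of AA
  d2 <- addInexactCounts(buildDictionary(
    c(s1 = "CAGATAACAGAT"), M = 2))
  nb <- c("CA", "GA", "TA", "AC", "AG", "AT")
  got <- ktupleStats(d2, "AA")
  expect_equal(got$inexact_count,
               got$exact_count + sum(ktupleStats(d2, nb)$exact_count))
})

test_that("exact and inexact counts match the brute-force oracle", {
  set.seed(404)
  for (rep in 1:22) {
    n <- sample(2:5, 1)
    len <- sample(60:140, 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (rep %% 3 == 0) s[sample(len, 2)] <- "N"  # some ambiguity
      paste(s, collapse = "")
    }, "")
    names(seqs) <- paste0("s", seq_len(n))
    M <- sample(3:6, 1)
    d <- addInexactCounts(buildDictionary(seqs, M))
    for (k in unique(c(1L, M))) {
      orc <- oracle_kmer_counts(seqs, k)
      tab <- d@tables[[k]]
      kts <- AnchorAlign:::.decode_codes(tab$code, k)
      expect_setequal(kts, names(orc$exact))
      m <- match(kts, names(orc$exact))
      expect_equal(tab$exact, as.integer(orc$exact[m]))
      expect_equal(tab$seqcount, as.integer(orc$seqcount[names(orc$exact)[m]]))
      expect_equal(tab$lastseq, unname(orc$lastseq[names(orc$exact)[m]]))
      # inexact counts, spot-checked on a handful of k-tuples
      for (kt in head(kts, 5))
        expect_equal(ktupleStats(d, kt)$inexact_count,
                     oracle_inexact_count(seqs, kt))
    }
    # monotonicity holds everywhere
    for (k in seq_len(M))
      expect_true(all(d@tables[[k]]$inexact >= d@tables[[k]]$exact))
  }
})

test_that("counting reads through the residues exactly once per sequence", {
  seqs <- c(a = random_dna(500, 1), b = random_dna(400, 2),
            c = random_dna(300, 3))
  AnchorAlign:::.reset_pass_counter()
  buildDictionary(seqs, M = 8)
  expect_identical(AnchorAlign:::.get_pass_counter(), 3L)
})

test_that("candidate prefilter uses inexact == N and defers per-sequence checks", {
  # ACGTC occurs twice in s1, nowhere (even inexactly) in s2:
  # aggregate inexact count is 2 == N, so it is a candidate, but the
  # location pass must reject it
  seqs <- c(s1 = "TTTACGTCTTTTACGTCTTT", s2 = "TTTTTTTTTTTTTTTTTTTT")
  d <- addInexactCounts(buildDictionary(seqs, M = 5))
  cand <- candidateSeeds(d)
  expect_true("ACGTC" %in% cand)
  seeds <- locateSeeds(seqs, "ACGTC")
  expect_length(seeds, 0)
})

test_that("oversized M is refused and the dump round-trips", {
  expect_error(buildDictionary(c(a = "ACGT"), M = 15), "cap")
  d <- addInexactCounts(buildDictionary(c(a = "ACGTACGT"), M = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDictionary(d, f)
  dump <- read.delim(f)
  expect_true(all(c("ktuple", "k", "exact_count", "inexact_count")
                  %in% names(dump)))
  expect_equal(sum(dump$k == 1), 4L)
})
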