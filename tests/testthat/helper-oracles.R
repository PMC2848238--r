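# Independent oracles used to check the package implementations.  These are
# deliberately naive (quadratic scans, plain-loop DP) and share no code with
# the package internals.

# brute-force exact k-mer statistics: scan every window of every sequence
oracle_kmer_counts <- function(seqs, k) {
  perseq <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- substring(s, 1:(L - k + 1), k:L)
    w[grepl("^[ACGT]+$", w)]
  })
  exact <- table(unlist(perseq, use.names = FALSE))
  seqc <- table(unlist(lapply(perseq, unique), use.names = FALSE))
  lastseq <- sapply(names(exact), function(kt)
    max(which(vapply(perseq, function(w) kt %in% w, TRUE))))
  list(exact = exact, seqcount = seqc, lastseq = lastseq)
}

# brute-force inexact count of one k-tuple: windows at Hamming distance <= 1
oracle_inexact_count <- function(seqs, kt) {
  k <- nchar(kt)
  target <- strsplit(kt, "")[[1]]
  tot <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    w <- substring(s, 1:(L - k + 1), k:L)
    w <- w[grepl("^[ACGT]+$", w)]
    if (!length(w)) next
    wm <- matrix(unlist(strsplit(w, "")), ncol = k, byrow = TRUE)
    mism <- rowSums(wm != matrix(target, nrow(wm), k, byrow = TRUE))
    tot <- tot + sum(mism <= 1L)
  }
  tot
}

# per-sequence Hamming<=1 match positions of one k-tuple (for seed checks)
oracle_locate <- function(seqs, kt) {
  k <- nchar(kt)
  target <- strsplit(kt, "")[[1]]
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(integer(0))
    w <- substring(s, 1:(L - k + 1), k:L)
    ok <- grepl("^[ACGT]+$", w)
    pos <- which(ok)
    if (!length(pos)) return(integer(0))
    wm <- matrix(unlist(strsplit(w[ok], "")), ncol = k, byrow = TRUE)
    mism <- rowSums(wm != matrix(target, nrow(wm), k, byrow = TRUE))
    pos[mism <= 1L]
  })
}

# plain-loop Gotoh DP optimum score; gap of length g costs open + g * extend
oracle_nw_affine <- function(s1, s2, match = 1, mismatch = -1,
                             gapOpen = -4, gapExtend = -1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(-Inf, n + 1, m + 1)
  U <- matrix(-Inf, n + 1, m + 1)
  V <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) {
    U[i, 1] <- gapOpen + gapExtend * (i - 1)
    H[i, 1] <- U[i, 1]
  }
  if (m > 0) for (j in 2:(m + 1)) {
    V[1, j] <- gapOpen + gapExtend * (j - 1)
    H[1, j] <- V[1, j]
  }
  if (n > 0 && m > 0) for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    U[i, j] <- max(H[i - 1, j] + gapOpen + gapExtend,
                   U[i - 1, j] + gapExtend)
    V[i, j] <- max(H[i, j - 1] + gapOpen + gapExtend,
                   V[i, j - 1] + gapExtend)
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    H[i, j] <- max(H[i - 1, j - 1] + s, U[i, j], V[i, j])
  }
  H[n + 1, m + 1]
}

# affine score of a GIVEN pairwise alignment under the same gap convention
score_pairwise_alignment <- function(r1, r2, match = 1, mismatch = -1,
                                     gapOpen = -4, gapExtend = -1) {
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(r2, "")[[1]]
  stopifnot(length(a) == length(b))
  sc <- 0
  inA <- FALSE; inB <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-" && b[i] == "-") stop("both-gap column in pairwise alignment")
    if (a[i] == "-") {
      sc <- sc + gapExtend + if (!inA) gapOpen else 0
      inA <- TRUE; inB <- FALSE
    } else if (b[i] == "-") {
      sc <- sc + gapExtend + if (!inB) gapOpen else 0
      inB <- TRUE; inA <- FALSE
    } else {
      sc <- sc + if (a[i] == b[i]) match else mismatch
      inA <- FALSE; inB <- FALSE
    }
  }
  sc
}

# independent column-by-column sum-of-pairs identity scorer
oracle_sp_score <- function(rows) {
  ch <- strsplit(rows, "")
  N <- length(rows)
  L <- length(ch[[1]])
  scores <- c()
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    m <- 0L
    for (col in seq_len(L))
      if (ch[[i]][col] != "-" && ch[[i]][col] == ch[[j]][col])
        m <- m + 1L
    scores <- c(scores, 100 * m / L)
  }
  mean(scores)
}

# build a SeedSet directly from a positions matrix (rows = seeds)
make_seedset <- function(positions, k = 5L, exactSeqs = NULL,
                         seqlen = 10000L) {
  S <- nrow(positions)
  N <- ncol(positions)
  kts <- vapply(seq_len(S), function(s)
    paste(c("A", "C", "G", "T")[(s + seq_len(k)) %% 4 + 1], collapse = ""),
    "")
  new("SeedSet", ktuple = kts, k = rep(as.integer(k), S),
      positions = matrix(as.integer(positions), S, N),
      exactSeqs = if (is.null(exactSeqs)) rep(N, S) else exactSeqs,
      seqnames = paste0("s", seq_len(N)),
      seqlengths = rep(as.integer(seqlen), N))
}

# exhaustive minimal-removal oracle: smallest number of seeds whose removal
# leaves an all-compatible set (checked over all subsets; tiny inputs only)
oracle_min_removals <- function(seeds) {
  S <- length(seeds)
  D <- incompatibilityMatrix(seeds)@D
  for (r in 0:(S - 1)) {
    for (drop in combn(S, r, simplify = FALSE)) {
      keep <- setdiff(seq_len(S), drop)
      if (length(keep) && all(D[keep, keep] == 0)) return(r)
    }
  }
  S - 1L
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
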