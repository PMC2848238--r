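## Seed location, ranking, incompatibility analysis and conflict resolution.
##
## A seed is a k-tuple with exactly one match, allowing at most one
## substitution, in every sequence.  Seeds are ranked, capped at T, scored
## pairwise by the incompatibility distance (number of sequences whose
## relative order of the two seeds departs from the majority order), and the
## seed contributing the most incompatibility is removed iteratively until a
## mutually order-compatible anchor set remains.

.empty_seedset <- function(seqnames, seqlengths, class = "SeedSet") {
  new(class, ktuple = character(0), k = integer(0),
      positions = matrix(integer(0), 0L, length(seqnames)),
      exactSeqs = integer(0), seqnames = seqnames, seqlengths = seqlengths)
}

.subset_seeds <- function(x, idx, as_class = class(x)) {
  new(as_class, ktuple = x@ktuple[idx], k = x@k[idx],
      positions = x@positions[idx, , drop = FALSE],
      exactSeqs = x@exactSeqs[idx],
      seqnames = x@seqnames, seqlengths = x@seqlengths)
}

#' Locate candidate seeds and verify per-sequence uniqueness
#'
#' Second read through the sequence data: every candidate k-tuple is matched
#' against all windows of every sequence at Hamming distance at most one
#' (substitutions only).  A candidate is kept as a seed if and only if every
#' sequence contains exactly one such window; its start there becomes the
#' seed's position.  Candidates failing verification are silently dropped.
#'
#' @param seqs sequences ([Biostrings::DNAStringSet] or named character), the
#'   same set the dictionary was built from.
#' @param candidates character vector of candidate k-tuples, typically from
#'   [candidateSeeds()].
#' @return a [SeedSet-class] in candidate order.
#' @examples
#' seqs <- c(a = "TTTTACGTACGTACGTTTTT", b = "AAAAACGTACGTACGTAAAA")
#' locateSeeds(seqs, "ACGTACGTACGT")
#' @export
locateSeeds <- function(seqs, candidates) {
  s <- .as_named_chars(seqs)
  N <- length(s)
  lens <- nchar(s)
  if (length(candidates) == 0L)
    return(.empty_seedset(names(s), lens))
  candidates <- toupper(candidates)
  klens <- nchar(candidates)
  ncand <- length(candidates)

  hits <- matrix(0L, ncand, N)        # inexact matches per sequence (capped at 2)
  P    <- matrix(NA_integer_, ncand, N)
  EX   <- matrix(FALSE, ncand, N)     # was the unique match exact?

  enc <- lapply(s, .encode_residues)  # the "second read" through the residues

  code <- ci <- pos <- exact <- NULL  # data.table NSE
  for (kk in unique(klens)) {
    sel <- which(klens == kk)
    selfcodes <- .encode_ktuples(candidates[sel])
    if (anyNA(selfcodes)) stop("candidates must be over the ACGT alphabet")
    # expand each candidate to itself plus its 3k one-substitution neighbours
    nbs <- vector("list", 3L * kk + 1L)
    nbs[[1L]] <- data.table(code = selfcodes, ci = sel, exact = TRUE)
    slot <- 2L
    for (j in seq_len(kk) - 1L) {
      p <- as.integer(4^j)
      d <- (selfcodes %/% p) %% 4L
      for (delta in 1:3) {
        nb <- selfcodes + (((d + delta) %% 4L) - d) * p
        nbs[[slot]] <- data.table(code = nb, ci = sel, exact = FALSE)
        slot <- slot + 1L
      }
    }
    expd <- rbindlist(nbs)
    setkey(expd, code)
    for (i in seq_len(N)) {
      if (lens[[i]] < kk) {
        hits[sel, i] <- 0L
        next
      }
      b <- enc[[i]]
      L <- lens[[i]]
      wc <- b[seq_len(L - kk + 1L)]
      if (kk > 1L) for (j in 2:kk)
        wc <- wc * 4L + b[j:(L - kk + j)]
      keep <- which(!is.na(wc))
      if (length(keep) == 0L) next
      win <- data.table(code = wc[keep], pos = keep, key = "code")
      mg <- expd[win, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(mg) == 0L) next
      agg <- mg[, list(n = .N, p1 = pos[1L], e1 = exact[1L]), by = ci]
      hits[agg$ci, i] <- pmin(agg$n, 2L)
      one <- agg$n == 1L
      P[agg$ci[one], i] <- agg$p1[one]
      EX[agg$ci[one], i] <- agg$e1[one]
    }
  }

  alive <- rowSums(hits == 1L) == N
  if (!any(alive)) return(.empty_seedset(names(s), lens))
  idx <- which(alive)
  new("SeedSet",
      ktuple = candidates[idx], k = klens[idx],
      positions = P[idx, , drop = FALSE],
      exactSeqs = as.integer(rowSums(EX[idx, , drop = FALSE])),
      seqnames = names(s), seqlengths = lens)
}

#' Rank seeds and select the top T
#'
#' Seeds are ordered by a deterministic ranking key: longer k-tuples first,
#' then seeds matching exactly in more sequences, then smaller start in
#' sequence 1, then k-tuple string as a final tiebreak.  Up to `T` seeds are
#' then selected greedily in that order; with `overlapFree = TRUE` (the
#' default) a seed whose window overlaps an already-selected seed's window in
#' any sequence is skipped, so that the selected seeds spread along the
#' sequences instead of clustering.
#'
#' @param seeds a [SeedSet-class] from [locateSeeds()].
#' @param T maximum number of seeds to keep (default 600).
#' @param overlapFree skip seeds overlapping already-selected ones.
#' @return a [SeedSet-class] of at most `T` seeds, in ranking order.
#' @export
rankSeeds <- function(seeds, T = 600L, overlapFree = TRUE) {
  stopifnot(is(seeds, "SeedSet"))
  S <- length(seeds)
  if (S == 0L) return(seeds)
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  ord <- order(-seeds@k, -seeds@exactSeqs, seeds@positions[, 1L],
               seeds@ktuple, method = "radix")
  if (!overlapFree)
    return(.subset_seeds(seeds, ord[seq_len(min(T, S))]))
  N <- length(seeds@seqnames)
  selS <- matrix(0L, T, N)
  selE <- matrix(0L, T, N)
  chosen <- integer(T)
  nsel <- 0L
  for (idx in ord) {
    p <- seeds@positions[idx, ]
    e <- p + seeds@k[[idx]] - 1L
    if (nsel > 0L) {
      a <- selS[seq_len(nsel), , drop = FALSE]
      b <- selE[seq_len(nsel), , drop = FALSE]
      if (any(a <= rep(e, each = nsel) & b >= rep(p, each = nsel))) next
    }
    nsel <- nsel + 1L
    selS[nsel, ] <- p
    selE[nsel, ] <- e
    chosen[nsel] <- idx
    if (nsel == T) break
  }
  .subset_seeds(seeds, chosen[seq_len(nsel)])
}

#' Incompatibility distance between two seeds
#'
#' The number of sequences whose relative order of seeds `a` and `b` differs
#' from the majority order: with n_AB sequences placing a strictly before b
#' (windows non-overlapping), n_BA the reverse, and overlaps counting against
#' both orders, the distance is N - max(n_AB, n_BA).  When n_AB == n_BA the
#' majority is taken as the order in sequence 1 (the distance itself is
#' unaffected).  Two seeds in the same order everywhere have distance 0.
#'
#' @param x a [SeedSet-class].
#' @param a,b seed indices in `x`.
#' @return non-negative integer distance (symmetric in `a`, `b`).
#' @export
incompatibilityDistance <- function(x, a, b) {
  stopifnot(is(x, "SeedSet"))
  N <- length(x@seqnames)
  pa <- x@positions[a, ]; ea <- pa + x@k[[a]] - 1L
  pb <- x@positions[b, ]; eb <- pb + x@k[[b]] - 1L
  nAB <- sum(ea < pb)
  nBA <- sum(eb < pa)
  as.integer(N - max(nAB, nBA))
}

#' Build the T x T incompatibility-distance matrix
#'
#' @param seeds a [SeedSet-class], typically the output of [rankSeeds()]
#'   (the matrix rows follow its order).
#' @return an [IncompatibilityMatrix-class].
#' @export
incompatibilityMatrix <- function(seeds) {
  stopifnot(is(seeds, "SeedSet"))
  S <- length(seeds)
  N <- length(seeds@seqnames)
  if (S == 0L)
    return(new("IncompatibilityMatrix", seeds = seeds,
               D = matrix(integer(0), 0L, 0L)))
  P <- seeds@positions
  E <- P + seeds@k - 1L   # k recycles down columns: P is S x N
  nAB <- matrix(0, S, S)
  for (i in seq_len(N))
    nAB <- nAB + outer(E[, i], P[, i], "<")
  D <- N - pmax(nAB, t(nAB))
  diag(D) <- 0
  storage.mode(D) <- "integer"
  new("IncompatibilityMatrix", seeds = seeds, D = D)
}

#' Resolve seed conflicts into an anchor set
#'
#' Iteratively removes the seed with the largest incompatibility row sum
#' (ties broken by removing the worst-ranked seed) and re-derives the matrix
#' by deleting that row and column, until no incompatibility is left.  A
#' second identical removal loop on the window-overlap-violation matrix then
#' enforces pairwise non-overlap in every sequence.  If every pair of seeds
#' conflicts, exactly one seed survives.  The result is sorted by start in
#' sequence 1.
#'
#' @param x an [IncompatibilityMatrix-class], or a [SeedSet-class] (the
#'   matrix is then computed first).
#' @return an [AnchorSet-class] of mutually compatible, non-overlapping
#'   anchors; empty only if `x` was empty.
#' @export
resolveConflicts <- function(x) {
  if (is(x, "SeedSet")) x <- incompatibilityMatrix(x)
  stopifnot(is(x, "IncompatibilityMatrix"))
  seeds <- x@seeds
  S <- length(seeds)
  if (S == 0L)
    return(.empty_seedset(seeds@seqnames, seeds@seqlengths, "AnchorSet"))

  keep <- .removal_loop(x@D)
  # enforce non-overlap in every sequence with the same removal scheme
  sub <- .subset_seeds(seeds, keep)
  O <- .overlap_matrix(sub)
  keep2 <- .removal_loop(O)
  final <- .subset_seeds(sub, keep2)
  ord <- order(final@positions[, 1L])
  .subset_seeds(final, ord, as_class = "AnchorSet")
}

# iterative max-row-sum removal; ties remove the worst rank (largest index,
# rows assumed in best-first rank order); returns surviving indices
.removal_loop <- function(D) {
  keep <- seq_len(nrow(D))
  rs <- rowSums(D)
  while (any(rs > 0)) {
    worst <- max(which(rs == max(rs)))
    rs <- rs - D[, worst]
    D <- D[-worst, -worst, drop = FALSE]
    rs <- rs[-worst]
    keep <- keep[-worst]
  }
  keep
}

# number of sequences in which the windows of seeds a and b intersect
.overlap_matrix <- function(seeds) {
  S <- length(seeds)
  N <- length(seeds@seqnames)
  P <- seeds@positions
  E <- P + seeds@k - 1L
  O <- matrix(0, S, S)
  for (i in seq_len(N))
    O <- O + (outer(P[, i], E[, i], "<=") & outer(E[, i], P[, i], ">="))
  diag(O) <- 0
  storage.mode(O) <- "integer"
  O
}

#' Write an anchor report as TSV
#'
#' One row per anchor: the k-tuple, its length k, and its (1-based) start in
#' every sequence, in sequence order.
#'
#' @param anchors an [AnchorSet-class] (a [SeedSet-class] is accepted).
#' @param path output path.
#' @export
writeAnchors <- function(anchors, path) {
  stopifnot(is(anchors, "SeedSet"))
  df <- data.frame(ktuple = anchors@ktuple, k = anchors@k,
                   anchors@positions, check.names = FALSE)
  if (length(anchors@seqnames))
    colnames(df)[-(1:2)] <- paste0("start.", anchors@seqnames)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
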