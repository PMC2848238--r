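## S4 classes for the anchoring pipeline.
##
## All coordinates are 1-based, intervals closed (IRanges convention).
## Sequence index = 1-based position in input order, everywhere.

setOldClass("data.table")

#' k-tuple dictionary over a sequence set
#'
#' Sparse dictionary of every k-tuple (k = 1..M) occurring in a sequence set,
#' with, per k-tuple: the exact occurrence count over the whole dataset, the
#' number of distinct sequences containing it, the index of the last sequence
#' where it was seen (the bookkeeping that makes the sequence count computable
#' in a single read through the data), and -- after [addInexactCounts()] --
#' the one-substitution inexact occurrence count.
#'
#' k-tuples are stored by their 2-bit integer encoding (A=0, C=1, G=2, T=3,
#' most significant digit first); [ktupleStats()] translates back to strings.
#' Windows overlapping any non-ACGT character are skipped entirely: a strict
#' 4-letter alphabet is assumed for counting.
#'
#' @slot M maximum k-tuple length indexed.
#' @slot N number of sequences indexed.
#' @slot seqnames,seqlengths names and lengths of the indexed sequences.
#' @slot tables list of length M; element k is a `data.table` keyed by `code`
#'   with columns `code`, `exact`, `seqcount`, `lastseq` and, once inexact
#'   counts have been added, `inexact`.
#' @slot hasInexact whether [addInexactCounts()] has run.
#' @exportClass KmerDictionary
setClass("KmerDictionary",
  representation(
    M          = "integer",
    N          = "integer",
    seqnames   = "character",
    seqlengths = "integer",
    tables     = "list",
    hasInexact = "logical"
  )
)

setValidity("KmerDictionary", function(object) {
  msg <- character()
  if (length(object@M) != 1L || object@M < 1L)
    msg <- c(msg, "M must be a single integer >= 1")
  if (length(object@tables) != object@M)
    msg <- c(msg, "tables must have one element per k in 1..M")
  if (object@N != length(object@seqnames) ||
      object@N != length(object@seqlengths))
    msg <- c(msg, "N must match seqnames and seqlengths")
  if (length(msg)) msg else TRUE
})

#' Verified seeds with one location per sequence
#'
#' A set of k-tuples each verified to match exactly once -- allowing at most
#' one substitution -- in every input sequence, together with the (1-based)
#' start of that unique match in each sequence.  `exactSeqs` records in how
#' many sequences the match is exact (zero mismatches); it is the second
#' component of the seed ranking key.
#'
#' @slot ktuple the seed k-tuples (character).
#' @slot k their lengths.
#' @slot positions integer matrix, one row per seed, one column per sequence;
#'   `positions[s, i]` is the start of seed s in sequence i.
#' @slot exactSeqs number of sequences in which each seed matches exactly.
#' @slot seqnames,seqlengths names and lengths of the sequences located in.
#' @exportClass SeedSet
setClass("SeedSet",
  representation(
    ktuple     = "character",
    k          = "integer",
    positions  = "matrix",
    exactSeqs  = "integer",
    seqnames   = "character",
    seqlengths = "integer"
  )
)

setValidity("SeedSet", function(object) {
  S <- length(object@ktuple)
  N <- length(object@seqnames)
  msg <- character()
  if (length(object@k) != S || length(object@exactSeqs) != S)
    msg <- c(msg, "k and exactSeqs must parallel ktuple")
  if (S > 0L && (nrow(object@positions) != S || ncol(object@positions) != N))
    msg <- c(msg, "positions must be S x N")
  if (any(object@k != nchar(object@ktuple)))
    msg <- c(msg, "k must equal nchar(ktuple)")
  if (S > 0L && N > 0L) {
    lo <- object@positions < 1L
    hi <- object@positions > rep(object@seqlengths, each = S) - object@k + 1L
    if (any(lo | hi))
      msg <- c(msg, "seed positions out of sequence bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Order-compatible, non-overlapping anchor set
#'
#' A `SeedSet` whose seeds appear in the same relative order in every
#' sequence, with no two seed windows overlapping in any sequence.  Anchors
#' are stored sorted by their start in sequence 1; by collinearity this is
#' their order in every sequence.  These are the split points of the
#' divide-and-conquer alignment.
#'
#' @exportClass AnchorSet
setClass("AnchorSet", contains = "SeedSet")

setValidity("AnchorSet", function(object) {
  S <- length(object@ktuple)
  if (S < 2L) return(TRUE)
  P <- object@positions
  # consecutive anchors must satisfy start_p + k_p <= start_{p+1} in EVERY
  # sequence: same order everywhere and no window overlap
  ok <- P[-S, , drop = FALSE] + object@k[-S] <= P[-1L, , drop = FALSE]
  if (all(ok)) TRUE else "anchors are not collinear and non-overlapping in every sequence"
})

#' Seed incompatibility-distance matrix
#'
#' Symmetric matrix over a `SeedSet`; entry (a, b) is the number of sequences
#' whose relative order of seeds a and b differs from the majority order,
#' with a window overlap in a sequence counting against both orders.
#'
#' @slot seeds the `SeedSet` the matrix is over (in ranking order).
#' @slot D the integer distance matrix, zero diagonal.
#' @exportClass IncompatibilityMatrix
setClass("IncompatibilityMatrix",
  representation(seeds = "SeedSet", D = "matrix")
)

setValidity("IncompatibilityMatrix", function(object) {
  S <- length(object@seeds@ktuple)
  msg <- character()
  if (nrow(object@D) != S || ncol(object@D) != S)
    msg <- c(msg, "D must be S x S")
  if (S > 0L) {
    if (any(object@D != t(object@D))) msg <- c(msg, "D must be symmetric")
    if (any(diag(object@D) != 0L)) msg <- c(msg, "diagonal of D must be zero")
    if (any(object@D < 0L)) msg <- c(msg, "D must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Gapped multiple alignment
#'
#' Equal-width gapped rows ('-' is the only gap character) in input sequence
#' order.  The central contract of the package is the round-trip invariant:
#' removing the gaps from any row reproduces the corresponding input sequence
#' exactly.  Use [degapRows()] to check, [writeAlignment()] to serialize.
#'
#' @slot ids sequence identifiers, in input order.
#' @slot rows gapped sequence strings, all the same width.
#' @slot stats run statistics recorded by [anchorAlign()] (per-depth seed and
#'   segment counts, number of sub-aligner invocations); empty list otherwise.
#' @exportClass AnchorAlignment
setClass("AnchorAlignment",
  representation(ids = "character", rows = "character", stats = "list")
)

setValidity("AnchorAlignment", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows must have equal length")
  if (length(object@rows) > 0L) {
    w <- nchar(object@rows)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "all rows must have identical width")
  }
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate ids")
  if (any(!nzchar(object@ids))) msg <- c(msg, "empty id")
  if (any(grepl("[[:space:]]", object@rows))) msg <- c(msg, "whitespace in rows")
  if (length(msg)) msg else TRUE
})

#' Sum-of-pairs identity score report
#'
#' Pairwise identity scores S_ij = 100 * M_ij / L for all sequence pairs of
#' an alignment (M_ij = columns where rows i and j carry the same non-gap
#' residue, L = alignment width including gaps) and their unweighted mean.
#'
#' @slot pairs data.frame with columns `i`, `j`, `matches`, `identity`.
#' @slot mean arithmetic mean identity over all pairs.
#' @slot L alignment width.
#' @exportClass ScoreReport
setClass("ScoreReport",
  representation(pairs = "data.frame", mean = "numeric", L = "integer")
)

## ---- generics -------------------------------------------------------------

#' @describeIn KmerDictionary-accessors maximum k indexed
#' @export
setGeneric("maxK", function(x) standardGeneric("maxK"))

#' @describeIn KmerDictionary-accessors number of sequences indexed
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname seedPositions
#' @export
setGeneric("seedPositions", function(x) standardGeneric("seedPositions"))

#' @rdname seedPositions
#' @export
setGeneric("seedKtuples", function(x) standardGeneric("seedKtuples"))

#' @rdname spIdentityScore
#' @export
setGeneric("spMean", function(x) standardGeneric("spMean"))

#' @rdname spIdentityScore
#' @export
setGeneric("spPairs", function(x) standardGeneric("spPairs"))

#' @rdname AnchorAlignment-accessors
#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))

#' @rdname AnchorAlignment-accessors
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))

## ---- accessors ------------------------------------------------------------

#' Accessors for KmerDictionary objects
#'
#' @param x a [KmerDictionary-class] object.
#' @name KmerDictionary-accessors
#' @aliases maxK,KmerDictionary-method nSequences,KmerDictionary-method
NULL

#' @export
setMethod("maxK", "KmerDictionary", function(x) x@M)

#' @export
setMethod("nSequences", "KmerDictionary", function(x) x@N)

#' Seed accessors
#'
#' `seedPositions()` returns the S x N matrix of 1-based match starts;
#' `seedKtuples()` the seed k-tuple strings.
#'
#' @param x a [SeedSet-class] (or [AnchorSet-class]) object.
#' @name seedPositions
#' @aliases seedKtuples
NULL

#' @export
setMethod("seedPositions", "SeedSet", function(x) {
  p <- x@positions
  dimnames(p) <- list(x@ktuple, x@seqnames)
  p
})

#' @export
setMethod("seedKtuples", "SeedSet", function(x) x@ktuple)

#' @export
setMethod("length", "SeedSet", function(x) length(x@ktuple))

#' @export
setMethod("nSequences", "SeedSet", function(x) length(x@seqnames))

#' Accessors for AnchorAlignment objects
#'
#' `alignedRows()` returns the gapped rows named by id; `alignmentIds()` the
#' ids; `width()` the common row width.
#'
#' @param x an [AnchorAlignment-class] object.
#' @name AnchorAlignment-accessors
NULL

#' @export
setMethod("alignedRows", "AnchorAlignment", function(x) {
  r <- x@rows
  names(r) <- x@ids
  r
})

#' @export
setMethod("alignmentIds", "AnchorAlignment", function(x) x@ids)

#' @export
setMethod("nSequences", "AnchorAlignment", function(x) length(x@rows))

#' @importMethodsFrom BiocGenerics width
#' @export
setMethod("width", "AnchorAlignment", function(x) {
  if (length(x@rows) == 0L) 0L else nchar(x@rows[[1L]])
})

#' @export
setMethod("spMean", "ScoreReport", function(x) x@mean)

#' @export
setMethod("spPairs", "ScoreReport", function(x) x@pairs)

## ---- show methods ---------------------------------------------------------

setMethod("show", "KmerDictionary", function(object) {
  nent <- sum(vapply(object@tables, nrow, 0L))
  cat(sprintf("KmerDictionary: %d sequences, k = 1..%d, %d distinct k-tuples%s\n",
              object@N, object@M, nent,
              if (object@hasInexact) " (with inexact counts)" else ""))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("%s: %d seed(s) over %d sequence(s)\n",
              class(object), length(object@ktuple), length(object@seqnames)))
  if (length(object@ktuple)) {
    n <- min(5L, length(object@ktuple))
    for (s in seq_len(n))
      cat(sprintf("  %s (k=%d, exact in %d/%d)\n", object@ktuple[s],
                  object@k[s], object@exactSeqs[s], length(object@seqnames)))
    if (length(object@ktuple) > n) cat(sprintf("  ... and %d more\n",
                                               length(object@ktuple) - n))
  }
})

setMethod("show", "IncompatibilityMatrix", function(object) {
  cat(sprintf("IncompatibilityMatrix over %d seed(s); total incompatibility %d\n",
              length(object@seeds@ktuple), sum(object@D) %/% 2L))
})

setMethod("show", "AnchorAlignment", function(object) {
  cat(sprintf("AnchorAlignment: %d rows, width %d\n",
              length(object@rows), width(object)))
  n <- min(4L, length(object@rows))
  for (i in seq_len(n)) {
    r <- object@rows[[i]]
    cat(sprintf("  %-12s %s%s\n", object@ids[[i]],
                substr(r, 1L, 50L), if (nchar(r) > 50L) "..." else ""))
  }
  if (length(object@rows) > n)
    cat(sprintf("  ... and %d more rows\n", length(object@rows) - n))
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport: mean SP identity %.3f over %d pair(s), L = %d\n",
              object@mean, nrow(object@pairs), object@L))
})
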