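## Pipeline orchestration: find anchors, divide the sequences at them, align
## the inter-anchor segments (recursively, via the sub-aligner, or by gap
## padding in seeds-only mode) and concatenate the partial alignments.

#' Pipeline configuration
#'
#' @param M maximum k-tuple length for the dictionary (default 12).
#' @param T maximum number of seeds entering conflict resolution
#'   (default 600).
#' @param maxDepth maximum number of recursive anchoring rounds; the top
#'   level is depth 1.  `Inf` (default) means unlimited.
#' @param segmentThreshold segments whose longest interval is at most this
#'   many bp go straight to the sub-aligner instead of recursing
#'   (default 2000).
#' @param aligner a sub-aligner specification ([builtinAligner()],
#'   [mafftAligner()], [clustalwAligner()] or [externalAligner()]).
#' @param seedsOnly if TRUE, produce a rough alignment in which only anchor
#'   blocks are aligned and inter-anchor segments are left-justified and
#'   gap-padded; no sub-aligner is ever invoked.  With zero anchors this
#'   raises a condition of class `anchoralign_no_seeds` -- the recommended
#'   triage for possibly unalignable data.
#' @param anchorsOut optional path for a TSV report of the top-level anchors.
#' @return a validated configuration list for [anchorAlign()].
#' @export
anchorAlignControl <- function(M = 12L, T = 600L, maxDepth = Inf,
                               segmentThreshold = 2000L,
                               aligner = builtinAligner(),
                               seedsOnly = FALSE, anchorsOut = NULL) {
  stopifnot(M >= 1L, T >= 1L, segmentThreshold >= 1L,
            is.infinite(maxDepth) || maxDepth >= 1L,
            inherits(aligner, "aligner_spec"),
            isTRUE(seedsOnly) || isFALSE(seedsOnly))
  list(M = as.integer(M), T = as.integer(T), maxDepth = maxDepth,
       segmentThreshold = as.integer(segmentThreshold), aligner = aligner,
       seedsOnly = seedsOnly, anchorsOut = anchorsOut)
}

#' Anchor-based divide-and-conquer multiple alignment
#'
#' The full pipeline: build the k-tuple dictionary (k = 1..M) with
#' one-substitution inexact counts, extract candidate k-tuples with one
#' inexact match per sequence, verify and locate them ([locateSeeds()]),
#' rank and cap at T ([rankSeeds()]), resolve order conflicts into an anchor
#' set ([resolveConflicts()]), split the sequences at the anchors and align
#' each inter-anchor segment -- recursively while segments are long and the
#' depth budget allows, otherwise with the configured sub-aligner -- and
#' concatenate anchor blocks and partial alignments into the final
#' alignment.  If no anchors are found at the top level the whole dataset is
#' handed to the sub-aligner (or, in seeds-only mode, a
#' `anchoralign_no_seeds` condition is raised: on real data that is a strong
#' indication the sequences are very hard or impossible to align).
#'
#' Every emitted alignment satisfies the round-trip invariant: degapping any
#' row reproduces the corresponding input sequence exactly.  This is
#' asserted on every run.
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector of at
#'   least 2 unaligned nucleotide sequences.
#' @param control a configuration from [anchorAlignControl()].
#' @return an [AnchorAlignment-class]; its `stats` slot records per-depth
#'   candidate/seed/anchor/segment counts and the number of sub-aligner
#'   invocations.
#' @examples
#' fam <- evolveFamily(ancestorLength = 600, n = 4, subRate = 0.01,
#'                     indelRate = 0.002, rngSeed = 7)
#' aln <- anchorAlign(fam$sequences,
#'                    anchorAlignControl(segmentThreshold = 200))
#' spMean(spIdentityScore(aln))
#' @export
anchorAlign <- function(seqs, control = anchorAlignControl()) {
  s <- .as_named_chars(seqs)
  if (length(s) < 2L) stop("need at least 2 sequences")
  st <- new.env(parent = emptyenv())
  st$levels <- list()
  st$subCalls <- 0L
  st$topAnchors <- NULL
  aln <- .align_recursive(s, control, depth = 1L, st)
  deg <- degapRows(aln)
  if (!identical(unname(deg), unname(s)))
    stop("internal error: round-trip invariant violated")
  if (!is.null(control$anchorsOut) && !is.null(st$topAnchors))
    writeAnchors(st$topAnchors, control$anchorsOut)
  aln@stats <- list(
    perDepth = if (length(st$levels)) do.call(rbind, st$levels)
               else data.frame(),
    subAlignerCalls = st$subCalls,
    topAnchors = if (is.null(st$topAnchors)) 0L else length(st$topAnchors))
  aln
}

# one anchoring round at the given depth, then divide and recurse
.align_recursive <- function(s, cfg, depth, st) {
  N <- length(s)
  anchors <- NULL
  if (all(nchar(s) > 0L)) {
    dict <- addInexactCounts(buildDictionary(s, cfg$M))
    cand <- candidateSeeds(dict)
    seeds <- locateSeeds(s, cand)
    ranked <- rankSeeds(seeds, cfg$T)
    anchors <- resolveConflicts(ranked)
    st$levels[[length(st$levels) + 1L]] <- data.frame(
      depth = depth, candidates = length(cand), verified = length(seeds),
      ranked = length(ranked), anchors = length(anchors),
      segments = length(anchors) + 1L,
      maxSegLen = NA_integer_)
    lev <- length(st$levels)
  } else {
    # a sequence with an empty interval can never contain a seed
    anchors <- .empty_seedset(names(s), nchar(s), "AnchorSet")
    lev <- NA_integer_
  }
  if (depth == 1L) st$topAnchors <- anchors

  if (length(anchors) == 0L) {
    if (cfg$seedsOnly) {
      if (depth == 1L)
        stop(structure(class = c("anchoralign_no_seeds", "error", "condition"),
                       list(message = paste(
                         "no seeds found: the data is very hard or",
                         "impossible to align"), call = NULL)))
      return(.pad_block(s))
    }
    st$subCalls <- st$subCalls + 1L
    return(.run_sub_aligner(cfg$aligner, s))
  }

  blocks <- .divide_at_anchors(s, anchors)
  if (!is.na(lev))
    st$levels[[lev]]$maxSegLen <-
      max(vapply(blocks$segments, function(x) max(nchar(x)), 0L))

  parts <- vector("list", 2L * length(anchors) + 1L)
  for (p in seq_along(blocks$segments)) {
    parts[[2L * p - 1L]] <- .align_segment(blocks$segments[[p]], cfg,
                                           depth, st)
  }
  for (a in seq_along(blocks$anchorBlocks)) {
    parts[[2L * a]] <- blocks$anchorBlocks[[a]]
  }
  rows <- do.call(paste0, lapply(parts, function(x)
    if (is(x, "AnchorAlignment")) x@rows else x))
  new("AnchorAlignment", ids = names(s), rows = rows, stats = list())
}

# align one inter-anchor segment set at the current depth
.align_segment <- function(seg, cfg, depth, st) {
  maxlen <- max(nchar(seg))
  if (maxlen == 0L)
    return(new("AnchorAlignment", ids = names(seg),
               rows = rep("", length(seg)), stats = list()))
  if (depth >= cfg$maxDepth || maxlen <= cfg$segmentThreshold) {
    if (cfg$seedsOnly) return(.pad_block(seg))
    st$subCalls <- st$subCalls + 1L
    return(.run_sub_aligner(cfg$aligner, seg))
  }
  .align_recursive(seg, cfg, depth + 1L, st)
}

# left-justify and right-pad a segment to its longest interval (seeds-only)
.pad_block <- function(s) {
  w <- max(nchar(s))
  rows <- paste0(s, strrep("-", w - nchar(s)))
  new("AnchorAlignment", ids = names(s), rows = unname(rows), stats = list())
}

# split sequences at the anchors: m anchor blocks (gap-free, width k_a) and
# m + 1 segment sets (intervals strictly between consecutive anchor windows)
.divide_at_anchors <- function(s, anchors) {
  m <- length(anchors)
  N <- length(s)
  P <- anchors@positions
  k <- anchors@k
  anchorBlocks <- vector("list", m)
  for (a in seq_len(m))
    anchorBlocks[[a]] <- substr(s, P[a, ], P[a, ] + k[[a]] - 1L)
  segments <- vector("list", m + 1L)
  for (p in 0:m) {
    from <- if (p == 0L) rep(1L, N) else P[p, ] + k[[p]]
    to   <- if (p == m) nchar(s) else P[p + 1L, ] - 1L
    seg <- substr(s, from, to)   # empty when from > to
    names(seg) <- names(s)
    segments[[p + 1L]] <- seg
  }
  list(anchorBlocks = anchorBlocks, segments = segments)
}

#' Seeds-only rough alignment from a given anchor set
#'
#' Places the anchor windows as aligned gap-free blocks and renders every
#' inter-anchor segment without alignment: each interval is left-justified
#' and right-padded with gaps to the longest interval of its segment.  The
#' round-trip invariant still holds.  This is the fast triage output -- no
#' sub-aligner runs.
#'
#' @param seqs the sequences the anchors were located in.
#' @param anchors an [AnchorSet-class].
#' @return an [AnchorAlignment-class].
#' @export
seedsOnlyAlignment <- function(seqs, anchors) {
  s <- .as_named_chars(seqs)
  stopifnot(is(anchors, "AnchorSet"))
  if (length(anchors) == 0L)
    stop(structure(class = c("anchoralign_no_seeds", "error", "condition"),
                   list(message = "no seeds found: nothing to anchor",
                        call = NULL)))
  blocks <- .divide_at_anchors(s, anchors)
  parts <- vector("list", 2L * length(anchors) + 1L)
  for (p in seq_along(blocks$segments))
    parts[[2L * p - 1L]] <- .pad_block(blocks$segments[[p]])@rows
  for (a in seq_along(blocks$anchorBlocks))
    parts[[2L * a]] <- blocks$anchorBlocks[[a]]
  rows <- do.call(paste0, parts)
  out <- new("AnchorAlignment", ids = names(s), rows = unname(rows),
             stats = list())
  stopifnot(identical(unname(degapRows(out)), unname(s)))
  out
}
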