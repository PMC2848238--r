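## Sequence simulation: uniform random sequence sets (the unalignability
## demonstration) and homologous families evolved from a common ancestor by
## substitutions and indels, with the ground truth recorded.

# run code with a private, restored RNG state seeded deterministically
.with_rng <- function(seed, code) {
  if (exists(".Random.seed", globalenv()))
    old <- get(".Random.seed", globalenv())
  else old <- NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Generate uniform random sequences
#'
#' i.i.d. uniform over A, C, G, T; fully reproducible from `rngSeed` (the
#' generator runs on a private RNG state and does not disturb the session's).
#' Random sequence sets of this kind are unalignable by construction and are
#' the standard negative control for seed finding: the pipeline should
#' detect zero seeds on them.
#'
#' @param n number of sequences.
#' @param length length of each sequence in bp.
#' @param rngSeed integer seed.
#' @return a [Biostrings::DNAStringSet] named `s1..sn`.
#' @examples
#' randomSequences(3, 50, rngSeed = 1)
#' @export
randomSequences <- function(n, length, rngSeed = 1L) {
  stopifnot(n >= 1L, length >= 1L)
  .with_rng(rngSeed, {
    s <- vapply(seq_len(n), function(i)
      paste(.BASES[sample.int(4L, length, replace = TRUE)], collapse = ""),
      "")
    names(s) <- paste0("s", seq_len(n))
    Biostrings::DNAStringSet(s)
  })
}

#' Evolve a homologous family from a common ancestor
#'
#' Simulates independent descent (star phylogeny) of `n` descendants from
#' one uniform random ancestor.  Each site substitutes with probability
#' `subRate` (uniformly to a different base); each site independently hosts
#' an indel event with probability `indelRate` (insertion or deletion with
#' equal probability), with lengths 1 + Geometric, mean `meanIndelLen`.
#' Deletions starting inside an earlier deletion are skipped.  For every
#' descendant the full edit list and the monotone ancestor-to-descendant
#' coordinate map are recorded, so tests can verify recovered anchors
#' against their true homologous coordinates.
#'
#' @param ancestorLength ancestor length in bp.
#' @param n number of descendants (>= 2).
#' @param subRate per-site substitution probability in [0, 1).
#' @param indelRate per-site indel event probability in [0, 1).
#' @param meanIndelLen mean indel length in bp (default 3).
#' @param rngSeed integer seed.
#' @return a list with elements:
#'   \describe{
#'     \item{sequences}{[Biostrings::DNAStringSet] of the descendants
#'       (`d1..dn`).}
#'     \item{ancestor}{the ancestor sequence (character).}
#'     \item{truths}{one list per descendant with `edits` (data.frame of
#'       `type` = sub/ins/del, `pos` = 1-based ancestor coordinate, `len`,
#'       `bases`) and `map` (integer vector: descendant coordinate of every
#'       ancestor base, NA where deleted).}
#'   }
#' @examples
#' fam <- evolveFamily(200, 3, subRate = 0.01, indelRate = 0.005, rngSeed = 42)
#' fam$sequences
#' @export
evolveFamily <- function(ancestorLength, n, subRate, indelRate,
                         meanIndelLen = 3, rngSeed = 1L) {
  stopifnot(ancestorLength >= 1L, n >= 2L,
            subRate >= 0, subRate < 1, indelRate >= 0, indelRate < 1,
            meanIndelLen >= 1)
  .with_rng(rngSeed, {
    anc <- .BASES[sample.int(4L, ancestorLength, replace = TRUE)]
    L <- ancestorLength
    seqs <- character(n)
    truths <- vector("list", n)
    for (d in seq_len(n)) {
      base <- anc
      # substitutions: uniform over the three other bases
      subsites <- which(runif(L) < subRate)
      if (length(subsites)) {
        cur <- match(base[subsites], .BASES)
        newb <- (cur - 1L + sample.int(3L, length(subsites),
                                       replace = TRUE)) %% 4L + 1L
        base[subsites] <- .BASES[newb]
      }
      # indel events, applied left to right on ancestor coordinates
      evsites <- which(runif(L) < indelRate)
      edits <- list()
      if (length(subsites))
        edits[[1L]] <- data.frame(type = "sub", pos = subsites, len = 1L,
                                  bases = base[subsites])
      deleted <- rep(FALSE, L)
      ins_after <- vector("list", L + 1L)  # insertions after ancestor pos 0..L
      for (ev in evsites) {
        if (deleted[ev]) next  # inside an earlier deletion
        elen <- rgeom(1L, prob = 1 / meanIndelLen) + 1L
        if (runif(1L) < 0.5) {
          ib <- .BASES[sample.int(4L, elen, replace = TRUE)]
          ins_after[[ev + 1L]] <- c(ins_after[[ev + 1L]], ib)
          edits[[length(edits) + 1L]] <-
            data.frame(type = "ins", pos = ev, len = elen,
                       bases = paste(ib, collapse = ""))
        } else {
          to <- min(L, ev + elen - 1L)
          deleted[ev:to] <- TRUE
          edits[[length(edits) + 1L]] <-
            data.frame(type = "del", pos = ev, len = to - ev + 1L,
                       bases = "")
        }
      }
      # assemble descendant and the ancestor -> descendant coordinate map
      pieces <- vector("list", L + 1L)
      pieces[[1L]] <- ins_after[[1L]]
      map <- integer(L)
      cursor <- length(ins_after[[1L]])
      for (i in seq_len(L)) {
        if (deleted[[i]]) {
          map[[i]] <- NA_integer_
        } else {
          cursor <- cursor + 1L
          map[[i]] <- cursor
        }
        nins <- length(ins_after[[i + 1L]])
        cursor <- cursor + nins
        pieces[[i + 1L]] <- c(if (!deleted[[i]]) base[[i]],
                              ins_after[[i + 1L]])
      }
      seqs[[d]] <- paste(unlist(pieces), collapse = "")
      truths[[d]] <- list(
        edits = if (length(edits)) do.call(rbind, edits)
                else data.frame(type = character(0), pos = integer(0),
                                len = integer(0), bases = character(0)),
        map = map)
    }
    names(seqs) <- paste0("d", seq_len(n))
    names(truths) <- names(seqs)
    list(sequences = Biostrings::DNAStringSet(seqs),
         ancestor = paste(anc, collapse = ""), truths = truths)
  })
}

#' Plant a conserved motif at a homologous position across a family
#'
#' Emulates a perfectly conserved functional site embedded in diverged
#' flanks: a random k-mer with no occurrence (allowing one substitution)
#' anywhere in the family is sampled, written at the same coordinate into
#' every sequence, and the `flank` positions on each side are re-randomized
#' independently per sequence so that no window overlapping the motif is
#' shared across sequences.  The motif is then, by construction, a seed:
#' present exactly once in every sequence.  Motifs are rejection-sampled
#' until the planted result verifies.
#'
#' @param seqs [Biostrings::DNAStringSet] or named character vector (e.g.
#'   from [evolveFamily()] without indels, so that coordinates are
#'   homologous).
#' @param k motif length (default 12).
#' @param at 1-based coordinate to plant at; must leave room for the flanks.
#' @param flank number of positions on each side to re-randomize per
#'   sequence (default k - 1, so no overlapping window is conserved).
#' @param rngSeed integer seed.
#' @return list with `sequences` (the modified set), `motif`, `at`.
#' @export
plantConservedMotif <- function(seqs, k = 12L, at, flank = k - 1L,
                                rngSeed = 1L) {
  s <- .as_named_chars(seqs)
  stopifnot(at - flank >= 1L, all(at + k - 1L + flank <= nchar(s)))
  .with_rng(rngSeed, {
    for (try in 1:50) {
      motif <- paste(.BASES[sample.int(4L, k, replace = TRUE)],
                     collapse = "")
      planted <- s
      for (i in seq_along(planted)) {
        left <- paste(.BASES[sample.int(4L, flank, replace = TRUE)],
                      collapse = "")
        right <- paste(.BASES[sample.int(4L, flank, replace = TRUE)],
                       collapse = "")
        substr(planted[[i]], at - flank, at + k - 1L + flank) <-
          paste0(left, motif, right)
      }
      ver <- locateSeeds(planted, motif)
      if (length(ver) == 1L &&
          all(seedPositions(ver)[1L, ] == at))
        return(list(sequences = Biostrings::DNAStringSet(planted),
                    motif = motif, at = at))
    }
    stop("could not plant a clash-free motif in 50 attempts")
  })
}

#' Apply a recorded edit list to an ancestor sequence
#'
#' Reconstructs a descendant from the ancestor and the edit list produced by
#' [evolveFamily()]; used to verify that the recorded ground truth is
#' internally consistent.
#'
#' @param ancestor ancestor sequence (character scalar).
#' @param edits the `edits` data.frame of one descendant truth record.
#' @return the reconstructed descendant sequence (character scalar).
#' @export
applyEdits <- function(ancestor, edits) {
  base <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  L <- length(base)
  deleted <- rep(FALSE, L)
  ins_after <- vector("list", L + 1L)
  for (r in seq_len(nrow(edits))) {
    type <- edits$type[[r]]
    pos <- edits$pos[[r]]
    if (type == "sub") {
      base[[pos]] <- edits$bases[[r]]
    } else if (type == "ins") {
      ib <- strsplit(edits$bases[[r]], "", fixed = TRUE)[[1L]]
      ins_after[[pos + 1L]] <- c(ins_after[[pos + 1L]], ib)
    } else if (type == "del") {
      deleted[pos:(pos + edits$len[[r]] - 1L)] <- TRUE
    } else stop("unknown edit type: ", type)
  }
  pieces <- vector("list", L + 1L)
  pieces[[1L]] <- ins_after[[1L]]
  for (i in seq_len(L))
    pieces[[i + 1L]] <- c(if (!deleted[[i]]) base[[i]], ins_after[[i + 1L]])
  paste(unlist(pieces), collapse = "")
}
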