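## k-tuple dictionary: single-read counting of exact occurrences, sequence
## counts and last-sequence indices for all k in 1..M, plus one-substitution
## inexact counts.
##
## k-tuples are handled as 2-bit integer codes (A=0, C=1, G=2, T=3, most
## significant digit first); a window overlapping any non-ACGT character
## encodes to NA and is skipped.

# char -> 2-bit code lookup, NA for anything outside ACGT
.CODE_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut
})
.BASES <- c("A", "C", "G", "T")

# single instrumented read through the residues of one sequence
.encode_residues <- function(s) {
  .bump_pass_counter()
  .CODE_LUT[utf8ToInt(s)]
}

# codes of all length-k windows for k = 1..M, derived arithmetically from the
# base codes (no further residue reads); element k has length max(0, L-k+1)
.window_codes <- function(b, M) {
  L <- length(b)
  out <- vector("list", M)
  cur <- b
  out[[1L]] <- cur
  for (k in seq_len(M)[-1L]) {
    if (L < k) {
      cur <- integer(0)
    } else {
      cur <- cur[seq_len(L - k + 1L)] * 4L + b[k:L]
    }
    out[[k]] <- cur
  }
  out
}

.decode_codes <- function(codes, k) {
  if (length(codes) == 0L) return(character(0))
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    p <- as.integer(4^(k - j))
    cols[[j]] <- .BASES[(codes %/% p) %% 4L + 1L]
  }
  do.call(paste0, cols)
}

.encode_ktuples <- function(kt) {
  k <- nchar(kt)
  vapply(seq_along(kt), function(i) {
    b <- .CODE_LUT[utf8ToInt(kt[[i]])]
    if (anyNA(b)) return(NA_integer_)
    as.integer(sum(b * 4^((k[[i]] - 1L):0L)))
  }, 0L)
}

#' Build the k-tuple dictionary for a sequence set
#'
#' Counts, for every k in 1..M and every k-tuple over \{A,C,G,T\} occurring in
#' the data, its total number of occurrences (overlapping windows counted),
#' the number of distinct sequences containing it, and the index of the last
#' sequence where it was seen.  All statistics are collected from a single
#' read through the residues: each sequence is integer-encoded once and all
#' window codes are derived arithmetically from that encoding.
#'
#' Windows overlapping a non-ACGT character (N and other ambiguity codes) are
#' skipped entirely.
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector of
#'   unaligned sequences.
#' @param M maximum k-tuple length (default 12).
#' @param maxM hard cap on M (default 14): larger M makes the 4^M code space
#'   impractical and is refused.
#' @return a [KmerDictionary-class] object (without inexact counts; see
#'   [addInexactCounts()]).
#' @examples
#' d <- buildDictionary(c(s1 = "ACGTACGT", s2 = "ACGTTCGT"), M = 4)
#' ktupleStats(d, c("ACGT", "CGT"))
#' @export
buildDictionary <- function(seqs, M = 12L, maxM = 14L) {
  s <- .as_named_chars(seqs)
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (M > maxM)
    stop("M = ", M, " exceeds the cap of ", maxM,
         ": the 4^M k-tuple code space would be impractical. ",
         "Raise maxM explicitly if you really want this.")
  if (any(nchar(s) == 0L)) stop("zero-length sequence: ",
                                names(s)[which(nchar(s) == 0L)[1L]])
  N <- length(s)
  lens <- nchar(s)

  # per-k accumulators of (code, seq) across sequences
  acc <- replicate(M, vector("list", N), simplify = FALSE)
  for (i in seq_len(N)) {
    wc <- .window_codes(.encode_residues(s[[i]]), M)
    for (k in seq_len(M)) acc[[k]][[i]] <- wc[[k]]
  }

  tables <- vector("list", M)
  for (k in seq_len(M)) {
    nlens <- lengths(acc[[k]])
    codes <- unlist(acc[[k]], use.names = FALSE)
    seqidx <- rep.int(seq_len(N), nlens)
    keep <- !is.na(codes)
    tables[[k]] <- .aggregate_codes(codes[keep], seqidx[keep])
  }

  new("KmerDictionary", M = M, N = N, seqnames = names(s),
      seqlengths = lens, tables = tables, hasInexact = FALSE)
}

# aggregate (code, sequence-index) pairs into per-code exact count, distinct
# sequence count and last sequence index by a single radix sort: within a
# sorted code group, sequence indices are ascending, so the group's last
# element is the last sequence and consecutive-duplicate removal yields the
# per-sequence presence count
.aggregate_codes <- function(codes, seqidx) {
  n <- length(codes)
  if (n == 0L)
    return(data.table(code = integer(0), exact = integer(0),
                      seqcount = integer(0), lastseq = integer(0),
                      key = "code"))
  o <- order(codes, seqidx, method = "radix")
  c2 <- codes[o]
  s2 <- seqidx[o]
  grpEnd <- if (n > 1L) c(c2[-1L] != c2[-n], TRUE) else TRUE
  ends <- which(grpEnd)
  exact <- diff(c(0L, ends))
  pairNew <- if (n > 1L) c(TRUE, c2[-1L] != c2[-n] | s2[-1L] != s2[-n])
             else TRUE
  cp <- c2[pairNew]
  np <- length(cp)
  gp <- if (np > 1L) c(cp[-1L] != cp[-np], TRUE) else TRUE
  seqcount <- diff(c(0L, which(gp)))
  data.table(code = c2[ends], exact = exact, seqcount = seqcount,
             lastseq = s2[ends], key = "code")
}

#' Add one-substitution inexact counts to a dictionary
#'
#' For every k-tuple t in the dictionary, the inexact count is its own exact
#' count plus the exact counts of all 3k one-substitution neighbours of t
#' (neighbours absent from the data contribute zero).  Insertions, deletions
#' and double substitutions are not part of the neighbourhood.
#'
#' @param dict a [KmerDictionary-class] from [buildDictionary()].
#' @return the dictionary with an `inexact` column in every k-table.
#' @export
addInexactCounts <- function(dict) {
  stopifnot(is(dict, "KmerDictionary"))
  for (k in seq_len(dict@M)) {
    tab <- dict@tables[[k]]
    cds <- tab$code
    e <- tab$exact
    inx <- e
    if (length(cds)) {
      dense_ok <- k <= 12L
      if (dense_ok) {
        dense <- integer(4L^k)
        dense[cds + 1L] <- e
      }
      for (j in seq_len(k) - 1L) {
        p <- as.integer(4^j)
        d <- (cds %/% p) %% 4L
        for (delta in 1:3) {
          nb <- cds + (((d + delta) %% 4L) - d) * p
          if (dense_ok) {
            inx <- inx + dense[nb + 1L]
          } else {
            m <- match(nb, cds)
            hit <- !is.na(m)
            inx[hit] <- inx[hit] + e[m[hit]]
          }
        }
      }
    }
    newtab <- data.table::copy(tab)
    newtab[, "inexact" := inx]
    dict@tables[[k]] <- newtab
  }
  dict@hasInexact <- TRUE
  dict
}

#' Candidate seed k-tuples
#'
#' Returns every k-tuple whose one-substitution inexact count equals N, the
#' number of sequences -- the aggregate prefilter for "one inexact match in
#' every sequence".  This is a necessary condition only: per-sequence
#' exactly-once verification is done by [locateSeeds()] in a second read
#' through the data (a k-tuple with all N inexact matches in one sequence
#' passes here and is rejected there).
#'
#' Candidates are ordered by the seed ranking rule as far as it is decidable
#' before location: longer k first, then higher exact count, then code order
#' for determinism.
#'
#' @param dict a [KmerDictionary-class] with inexact counts.
#' @return character vector of candidate k-tuples.
#' @export
candidateSeeds <- function(dict) {
  stopifnot(is(dict, "KmerDictionary"))
  if (!dict@hasInexact) stop("run addInexactCounts() first")
  out <- character(0)
  inexact <- exact <- NULL  # data.table NSE
  for (k in rev(seq_len(dict@M))) {
    tab <- dict@tables[[k]]
    hit <- tab[inexact == dict@N]
    if (nrow(hit)) {
      hit <- hit[order(-exact, code)]
      out <- c(out, .decode_codes(hit$code, k))
    }
  }
  out
}

#' Look up dictionary statistics for given k-tuples
#'
#' @param dict a [KmerDictionary-class].
#' @param ktuples character vector of k-tuples (ACGT alphabet).
#' @return data.frame with columns `ktuple`, `k`, `exact_count`, `seq_count`,
#'   `last_seq_index`, `inexact_count` (NA before [addInexactCounts()]);
#'   k-tuples absent from the data get zero counts.
#' @export
ktupleStats <- function(dict, ktuples) {
  stopifnot(is(dict, "KmerDictionary"))
  ktuples <- toupper(ktuples)
  k <- nchar(ktuples)
  if (any(k < 1L | k > dict@M))
    stop("k-tuple length outside 1..M")
  codes <- .encode_ktuples(ktuples)
  if (anyNA(codes)) stop("k-tuples must be over the ACGT alphabet")
  res <- data.frame(ktuple = ktuples, k = k, exact_count = 0L,
                    seq_count = 0L, last_seq_index = NA_integer_,
                    inexact_count = if (dict@hasInexact) 0L else NA_integer_)
  for (kk in unique(k)) {
    sel <- which(k == kk)
    tab <- dict@tables[[kk]]
    m <- match(codes[sel], tab$code)
    hit <- !is.na(m)
    res$exact_count[sel][hit] <- tab$exact[m[hit]]
    res$seq_count[sel][hit] <- tab$seqcount[m[hit]]
    res$last_seq_index[sel][hit] <- tab$lastseq[m[hit]]
    if (dict@hasInexact) res$inexact_count[sel][hit] <- tab$inexact[m[hit]]
  }
  # an absent k-tuple can still have inexact matches from its neighbours
  if (dict@hasInexact && any(res$exact_count == 0L)) {
    for (idx in which(res$exact_count == 0L)) {
      kk <- k[[idx]]
      tab <- dict@tables[[kk]]
      cds <- codes[[idx]]
      tot <- 0L
      for (j in seq_len(kk) - 1L) {
        p <- as.integer(4^j)
        d <- (cds %/% p) %% 4L
        for (delta in 1:3) {
          nb <- cds + (((d + delta) %% 4L) - d) * p
          m <- match(nb, tab$code)
          if (!is.na(m)) tot <- tot + tab$exact[[m]]
        }
      }
      res$inexact_count[[idx]] <- tot
    }
  }
  res
}

#' Dump a dictionary as TSV
#'
#' Writes one row per materialized k-tuple with columns `ktuple`, `k`,
#' `exact_count`, `seq_count`, `inexact_count`; intended for debugging and
#' for seeds-only diagnostic reports.  Large dictionaries produce large
#' files; restrict `k` for megabase inputs.
#'
#' @param dict a [KmerDictionary-class].
#' @param path output path.
#' @param k which k values to dump (default all).
#' @export
writeDictionary <- function(dict, path, k = seq_len(dict@M)) {
  stopifnot(is(dict, "KmerDictionary"))
  parts <- lapply(k, function(kk) {
    tab <- dict@tables[[kk]]
    data.frame(ktuple = .decode_codes(tab$code, kk), k = kk,
               exact_count = tab$exact, seq_count = tab$seqcount,
               inexact_count = if (dict@hasInexact) tab$inexact
                               else NA_integer_)
  })
  write.table(do.call(rbind, parts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
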