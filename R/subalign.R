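## Segment aligners: a builtin progressive affine-gap profile aligner (so the
## pipeline runs with zero external binaries) and an adapter shelling out to
## any FASTA-in/FASTA-out multiple aligner.

#' Sub-aligner specifications
#'
#' `builtinAligner()` selects the package's progressive profile aligner with
#' the given affine-gap nucleotide scoring.  `externalAligner()` wraps any
#' command-line aligner taking plain multi-FASTA in and producing aligned
#' multi-FASTA out; the template must contain `{in}` and `{out}`
#' placeholders.  `mafftAligner()` and `clustalwAligner()` are canonical
#' templates for the two conventional choices.
#'
#' @param match,mismatch,gapOpen,gapExtend builtin scoring parameters
#'   (defaults 1, -1, -4, -1).  A gap of length g costs
#'   `gapOpen + g * gapExtend`.
#' @param maxTotal cap on the summed length of the sequences handed to the
#'   builtin aligner (default 200000); beyond it the aligner refuses and
#'   suggests an external tool.
#' @param template external command template with `{in}` and `{out}`.
#' @return an aligner specification usable as the `aligner` element of
#'   [anchorAlignControl()].
#' @name aligner-specs
#' @export
builtinAligner <- function(match = 1, mismatch = -1, gapOpen = -4,
                           gapExtend = -1, maxTotal = 200000L) {
  structure(list(kind = "builtin",
                 scoring = list(match = match, mismatch = mismatch,
                                gapOpen = gapOpen, gapExtend = gapExtend),
                 maxTotal = as.integer(maxTotal)),
            class = c("builtin_aligner", "aligner_spec"))
}

#' @rdname aligner-specs
#' @export
externalAligner <- function(template) {
  if (!grepl("{in}", template, fixed = TRUE) ||
      !grepl("{out}", template, fixed = TRUE))
    stop("external aligner template must contain {in} and {out} placeholders")
  structure(list(kind = "external", template = template),
            class = c("external_aligner", "aligner_spec"))
}

#' @rdname aligner-specs
#' @export
mafftAligner <- function() externalAligner("mafft --auto --quiet {in} > {out}")

#' @rdname aligner-specs
#' @export
clustalwAligner <- function()
  externalAligner("clustalw -infile={in} -outfile={out} -output=fasta -align")

# dispatch a segment to the configured sub-aligner
.run_sub_aligner <- function(spec, seqs) {
  if (inherits(spec, "builtin_aligner")) {
    builtinAlign(seqs, match = spec$scoring$match,
                 mismatch = spec$scoring$mismatch,
                 gapOpen = spec$scoring$gapOpen,
                 gapExtend = spec$scoring$gapExtend,
                 maxTotal = spec$maxTotal)
  } else if (inherits(spec, "external_aligner")) {
    externalAlign(seqs, spec)
  } else stop("unknown aligner spec")
}

# char codes for profile columns: A,C,G,T = 0..3, other residue = 4, gap = 5
.PROF_LUT <- local({
  lut <- rep(4L, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt("-")] <- 5L
  lut
})

#' Progressive profile multiple alignment (builtin)
#'
#' Self-contained progressive aligner: sequences are taken longest first and
#' each is aligned to the growing profile by affine-gap global dynamic
#' programming over profile columns, a column being scored by the mean
#' substitution score against its residues (gaps in a column score as gap
#' extensions).  Tie-breaking is deterministic (diagonal preferred, then
#' column-gap, then residue-gap).  For two sequences this is exactly Gotoh's
#' optimal global affine alignment.
#'
#' Ambiguity codes are carried through unchanged but score as mismatches
#' against everything.
#'
#' @param seqs [Biostrings::DNAStringSet] or named character vector; empty
#'   strings are allowed and become all-gap rows.
#' @param match,mismatch,gapOpen,gapExtend affine scoring
#'   (defaults 1, -1, -4, -1).
#' @param maxTotal refuse inputs whose summed length exceeds this (default
#'   200000); an external aligner is the right tool there.
#' @return an [AnchorAlignment-class] in input order.
#' @examples
#' builtinAlign(c(a = "ACGT", b = "AGT"))
#' @export
builtinAlign <- function(seqs, match = 1, mismatch = -1, gapOpen = -4,
                         gapExtend = -1, maxTotal = 200000L) {
  s <- .as_named_chars(seqs)
  if (sum(nchar(s)) > maxTotal)
    stop("builtin aligner input totals ", sum(nchar(s)), " bp > cap of ",
         maxTotal, " bp; use an external aligner (e.g. mafftAligner()) ",
         "for segments this large")
  N <- length(s)
  if (N == 0L) stop("no sequences")
  ord <- order(-nchar(s))  # stable: ties keep input order
  chars <- strsplit(s[ord], "", fixed = TRUE)

  alnM <- matrix(chars[[1L]], nrow = 1L)  # rows x width character matrix
  if (N > 1L) for (i in 2:N) {
    W <- ncol(alnM)
    codeM <- matrix(.PROF_LUT[utf8ToInt(paste(t(alnM), collapse = ""))],
                    nrow = nrow(alnM), byrow = TRUE)
    prof <- matrix(0L, 6L, W)
    if (W > 0L) for (x in 0:5)
      prof[x + 1L, ] <- .colSums(codeM == x, nrow(alnM), W)
    sq <- chars[[i]]
    scodes <- if (length(sq)) pmin(.PROF_LUT[utf8ToInt(s[ord][[i]])], 4L)
              else integer(0)
    ops <- .profile_align_cpp(prof, scodes, match, mismatch, gapOpen,
                              gapExtend)
    nops <- length(ops)
    takecol <- ops != 2L
    takeres <- ops != 1L
    colidx <- cumsum(takecol)
    residx <- cumsum(takeres)
    newM <- matrix("-", nrow(alnM) + 1L, nops)
    if (any(takecol))
      newM[seq_len(nrow(alnM)), takecol] <- alnM[, colidx[takecol],
                                                 drop = FALSE]
    if (any(takeres))
      newM[nrow(alnM) + 1L, takeres] <- sq[residx[takeres]]
    alnM <- newM
  }
  rows <- apply(alnM, 1L, paste, collapse = "")
  if (ncol(alnM) == 0L) rows <- rep("", nrow(alnM))
  rows <- rows[order(ord)]  # back to input order
  out <- new("AnchorAlignment", ids = names(s), rows = unname(rows),
             stats = list())
  stopifnot(identical(unname(degapRows(out)), unname(s)))
  out
}

#' Align a segment with an external command-line aligner
#'
#' Writes the sequences as multi-FASTA, runs the template command, parses the
#' aligned FASTA it produces, restores input order regardless of any
#' reordering by the tool, and enforces the round-trip invariant (each
#' degapped output row must equal its input).  The working directory is
#' removed on success and retained on failure for inspection.
#'
#' @param seqs [Biostrings::DNAStringSet] or named character vector.
#' @param spec an [externalAligner()] specification.
#' @param workdir directory for the temporary FASTA files (default: a fresh
#'   tempdir subdirectory).
#' @return an [AnchorAlignment-class] in input order.
#' @export
externalAlign <- function(seqs, spec, workdir = NULL) {
  stopifnot(inherits(spec, "external_aligner"))
  s <- .as_named_chars(seqs)
  if (is.null(workdir))
    workdir <- tempfile("subalign_")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  fin <- file.path(workdir, "segment.fa")
  fout <- file.path(workdir, "segment.aln.fa")
  writeFasta(s, fin)
  cmd <- gsub("{out}", shQuote(fout),
              gsub("{in}", shQuote(fin), spec$template, fixed = TRUE),
              fixed = TRUE)
  res <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("external aligner failed (exit ", status, "); workdir kept at ",
         workdir, "\n", paste(res, collapse = "\n"))
  if (!file.exists(fout))
    stop("external aligner produced no output file; workdir kept at ", workdir)
  aln <- readAlignment(fout)
  m <- match(names(s), aln@ids)
  if (anyNA(m))
    stop("external aligner output is missing sequence(s): ",
         paste(names(s)[is.na(m)], collapse = ", "),
         "; workdir kept at ", workdir)
  out <- new("AnchorAlignment", ids = names(s), rows = aln@rows[m],
             stats = list())
  if (!identical(unname(degapRows(out)), unname(s)))
    stop("external aligner violated the round-trip invariant ",
         "(degapped output differs from input); workdir kept at ", workdir)
  unlink(workdir, recursive = TRUE)
  out
}
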