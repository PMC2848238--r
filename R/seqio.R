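## FASTA input/output and sequence normalization.
##
## Unaligned input and gapped aligned output are both plain multi-FASTA.
## '-' is the only gap character accepted or emitted; '.' is rejected.

#' Read a multi-FASTA nucleotide file
#'
#' Reads unaligned nucleotide sequences, uppercases them and maps U to T.
#' Characters outside A/C/G/T (IUPAC ambiguity codes such as N) are kept but
#' never participate in k-tuple counting downstream.  Record ids are the
#' FASTA headers up to the first whitespace and must be unique and non-empty;
#' zero-length records and gap characters in the input are errors.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] in file order, named by id.
#' @seealso [writeFasta()], [anchorAlign()]
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt", ">s2", "ACGTAC"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("[[:space:]].*$", "", names(x))
  if (any(!nzchar(ids)))
    stop("record ", which(!nzchar(ids))[1L], " has an empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  s <- toupper(as.character(x))
  s <- chartr("U", "T", s)
  if (any(nchar(s) == 0L))
    stop("zero-length record: ", ids[which(nchar(s) == 0L)[1L]])
  bad <- grepl("[.]", s, fixed = FALSE)
  if (any(bad))
    stop("record ", ids[which(bad)[1L]],
         " contains '.'; only '-' gaps are supported, and only in alignments")
  if (any(grepl("-", s, fixed = TRUE)))
    stop("gap characters in unaligned input (record ",
         ids[which(grepl("-", s, fixed = TRUE))[1L]],
         "); use readAlignment() for aligned FASTA")
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  out
}

#' Write sequences as multi-FASTA
#'
#' @param x a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line width for the sequence body (default 60).
#' @export
writeFasta <- function(x, path, width = 60L) {
  s <- .as_named_chars(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(s)[i]), con)
    n <- nchar(s[[i]])
    if (n > 0L) {
      starts <- seq.int(1L, n, by = width)
      writeLines(substring(s[[i]], starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Write a gapped alignment as aligned multi-FASTA
#'
#' Refuses to write unequal-width rows.  When `check` is supplied, the
#' round-trip invariant is enforced: degapping every row must reproduce the
#' corresponding input sequence exactly.
#'
#' @param aln an [AnchorAlignment-class] object.
#' @param path output path.
#' @param check optional `DNAStringSet`/named character of the original
#'   unaligned sequences to verify the round-trip invariant against.
#' @param width line width (default 60).
#' @export
writeAlignment <- function(aln, path, check = NULL, width = 60L) {
  stopifnot(is(aln, "AnchorAlignment"))
  validObject(aln)
  if (!is.null(check)) {
    orig <- .as_named_chars(check)
    deg <- degapRows(aln)
    if (!identical(unname(deg), unname(orig[aln@ids])))
      stop("round-trip violation: degapped rows do not reproduce the inputs")
  }
  r <- aln@rows
  names(r) <- aln@ids
  writeFasta(r, path, width = width)
}

#' Read an aligned multi-FASTA file
#'
#' @param path path to an aligned FASTA file with '-' gaps.
#' @return an [AnchorAlignment-class] object.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("[[:space:]].*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  s <- chartr("U", "T", toupper(as.character(x)))
  if (any(grepl(".", s, fixed = TRUE)))
    stop("'.' gaps are not supported; use '-'")
  if (length(unique(nchar(s))) > 1L)
    stop("rows have unequal widths; not an alignment")
  new("AnchorAlignment", ids = ids, rows = unname(s), stats = list())
}

#' Remove gaps from alignment rows
#'
#' @param aln an [AnchorAlignment-class] object (or character vector of
#'   gapped rows).
#' @return character vector of ungapped sequences, named by id when available.
#' @export
degapRows <- function(aln) {
  if (is(aln, "AnchorAlignment")) {
    out <- gsub("-", "", aln@rows, fixed = TRUE)
    names(out) <- aln@ids
    out
  } else {
    gsub("-", "", as.character(aln), fixed = TRUE)
  }
}

# normalize any supported sequence container to a named character vector
.as_named_chars <- function(x) {
  if (is(x, "XStringSet")) {
    s <- as.character(x)
  } else if (is.character(x)) {
    s <- x
  } else stop("unsupported sequence container: ", class(x)[1L])
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("sequences must be named")
  toupper(s)
}
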