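## Sum-of-pairs identity scoring of a gapped multiple alignment.

#' Sum-of-pairs identity score
#'
#' For every pair of rows (i, j) the pairwise identity is
#' \deqn{S_{ij} = 100 \, M_{ij} / L} where \eqn{M_{ij}} is the number of
#' alignment columns in which rows i and j carry the same non-gap residue
#' (a column gapped in either row, including both, never counts as a match)
#' and L is the full alignment width including gaps.  The report's mean is
#' the unweighted arithmetic mean of \eqn{S_{ij}} over all N(N-1)/2 pairs.
#'
#' Comparison is by literal character equality after uppercasing, so equal
#' ambiguity codes (e.g. N vs N) count as matches.  A width-0 alignment
#' scores 0 with a warning.
#'
#' @param aln an [AnchorAlignment-class] (or named character vector of
#'   equal-width gapped rows).
#' @return a [ScoreReport-class]; see [spMean()] and [spPairs()].
#' @examples
#' spIdentityScore(c(a = "AC-G", b = "ACTG"))  # M = 3, L = 4, S = 75
#' @export
spIdentityScore <- function(aln) {
  if (!is(aln, "AnchorAlignment")) {
    rows <- toupper(as.character(aln))
    ids <- names(rows)
    if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
    aln <- new("AnchorAlignment", ids = ids, rows = unname(rows),
               stats = list())
  }
  validObject(aln)
  N <- length(aln@rows)
  if (N < 2L) stop("need at least 2 rows to score")
  L <- width(aln)
  pairs <- t(utils::combn(N, 2L))
  if (L == 0L) {
    warning("width-0 alignment; score defined as 0")
    df <- data.frame(i = pairs[, 1L], j = pairs[, 2L], matches = 0L,
                     identity = 0)
    return(new("ScoreReport", pairs = df, mean = 0, L = 0L))
  }
  C <- matrix(utf8ToInt(paste(toupper(aln@rows), collapse = "")),
              nrow = N, byrow = TRUE)
  gap <- utf8ToInt("-")
  # M_ij via per-character indicator cross-products (gap excluded)
  Mcnt <- matrix(0, N, N)
  for (ch in setdiff(unique(as.vector(C)), gap)) {
    X <- (C == ch) * 1
    Mcnt <- Mcnt + tcrossprod(X)
  }
  m <- Mcnt[cbind(pairs[, 1L], pairs[, 2L])]
  df <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                   matches = as.integer(m), identity = 100 * m / L)
  new("ScoreReport", pairs = df, mean = mean(df$identity), L = L)
}

#' Write a pairwise score report as TSV
#'
#' One row per pair (`id_i`, `id_j`, `matches`, `identity`), followed by the
#' mean on a trailing comment line when written to a file, or printed to
#' stdout when `path` is empty.
#'
#' @param report a [ScoreReport-class].
#' @param ids row identifiers (in alignment order) used to label pairs.
#' @param path output path, or `""` for stdout.
#' @export
writeScoreReport <- function(report, ids, path = "") {
  stopifnot(is(report, "ScoreReport"))
  df <- report@pairs
  out <- data.frame(id_i = ids[df$i], id_j = ids[df$j],
                    matches = df$matches,
                    identity = sprintf("%.6g", df$identity))
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# mean\t%.6g", report@mean), con)
  invisible(report)
}
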