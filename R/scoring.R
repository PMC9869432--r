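# Alignment scoring parameters.

.SCORE_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                     "P","S","T","W","Y","V","B","J","Z","X","*")

#' Default substitution matrix for protein-to-genome alignment
#'
#' BLOSUM62 (from Biostrings) restricted to the 20 amino acids plus B/J/Z/X
#' and `*`, with two overrides suited to translated-genome alignment:
#' `s(X, .) = 0` (ambiguous translations are neutral) and `s(*, x) = -30`,
#' `s(*, *) = 1` (in-frame stops are strongly discouraged inside exons).
#'
#' @return an integer matrix with residue dimnames.
#' @export
default_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- env$BLOSUM62[.SCORE_ALPHABET, .SCORE_ALPHABET]
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat["*", ] <- -30L
  mat[, "*"] <- -30L
  mat["*", "*"] <- 1L
  storage.mode(mat) <- "integer"
  mat
}

#' Scoring parameters for the alignment DP
#'
#' @param matrix integer substitution matrix with residue dimnames covering
#'   the 20 amino acids, `X` and `*`; defaults to [default_matrix()].
#' @param q gap-open penalty (a gap of length g costs `q + e*g`).
#' @param e gap-extension penalty.
#' @param f frameshift penalty (per 1-2 nt frameshift event).
#' @param r intron-open penalty.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = default_matrix(), q = 11L, e = 1L,
                           f = 17L, r = 29L) {
  stopifnot(q >= 0, e >= 0, f >= 0, r >= 0, is.matrix(matrix),
            identical(rownames(matrix), colnames(matrix)))
  structure(list(matrix = matrix, q = as.integer(q), e = as.integer(e),
                 f = as.integer(f), r = as.integer(r)),
            class = "scoring_params")
}

#' Read an NCBI-style substitution matrix file
#'
#' Parses the whitespace-separated matrix text format used by BLAST
#' (`#` comment lines, a header row of residue letters, one labelled row per
#' residue).
#'
#' @param path path to the matrix file.
#' @return an integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1L]))
  if (any(lengths(vals) != length(header))) stop("ragged matrix rows")
  mat <- do.call(rbind, vals)
  dimnames(mat) <- list(labs, header)
  mat
}

# map residues to 0-based indices of a scoring matrix; unknown letters -> X
.residue_indices <- function(residues, alphabet) {
  residues <- toupper(residues)
  idx <- match(residues, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}
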