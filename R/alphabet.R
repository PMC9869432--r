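#' @useDynLib splicealigner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# SE-B(14)-style amino-acid reduction with N and D merged: 14 groups plus the
# stop symbol and X.  Code 9 is deliberately unassigned so that groups that
# differ only in the lowest bit tend to be biochemically similar.
.REDUCTION <- c(
  A = 0L, S = 1L, T = 1L, R = 2L, K = 2L, H = 3L, N = 4L, D = 4L,
  E = 5L, Q = 5L, C = 6L, P = 7L, G = 8L, I = 10L, V = 10L,
  L = 11L, M = 11L, F = 12L, Y = 12L, W = 13L, `*` = 14L, X = 15L,
  # ambiguity/rare letters collapse to X
  B = 15L, Z = 15L, J = 15L, U = 15L, O = 15L
)

#' Reduce an amino acid to its 4-bit group code
#'
#' Maps each of the 20 standard amino acids, the stop symbol `*` and `X` to a
#' 4-bit integer group code: A=0, S/T=1, R/K=2, H=3, N/D=4, E/Q=5, C=6, P=7,
#' G=8, I/V=10, L/M=11, F/Y=12, W=13, `*`=14, X=15.  Code 9 is never produced.
#' Ambiguity letters (B, Z, J, U, O) are treated as X; lower case is accepted.
#'
#' @param residue character vector of single residues.
#' @return integer vector of group codes in `[0, 15]`.
#' @examples
#' reduce_aa(c("A", "N", "D", "W", "*", "X"))
#' @export
reduce_aa <- function(residue) {
  residue <- toupper(as.character(residue))
  if (any(nchar(residue) != 1L))
    stop("residues must be single characters")
  out <- .REDUCTION[residue]
  if (anyNA(out))
    stop("invalid residue: ", paste(unique(residue[is.na(out)]), collapse = ", "))
  unname(out)
}

# reduce a residue string to a code vector (internal, vectorised)
.reduce_string <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  out <- .REDUCTION[ch]
  if (anyNA(out)) stop("invalid residue in peptide")
  unname(out)
}

# codon -> amino acid lookup built from the standard genetic code
.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Translate a single codon under the standard genetic code
#'
#' Codons are 3-nt strings over A/C/G/T/N (case-insensitive).  Stop codons
#' return `*`; any codon containing N (or another non-ACGT letter) returns `X`.
#'
#' @param codon character vector of 3-nt codons.
#' @return character vector of single amino-acid letters.
#' @examples
#' translate_codon(c("ATG", "TAA", "ANG"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (any(nchar(codon) != 3L)) stop("codons must have length 3")
  aa <- .CODON_TABLE[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# translate an nt character vector in frame `frame` (0..2); returns aa vector
.translate_frame <- function(chars, frame) {
  n <- length(chars)
  len <- (n - frame) %/% 3L
  if (len < 1L) return(character(0))
  idx <- frame + seq_len(len * 3L)
  m <- matrix(chars[idx], nrow = 3L)
  codons <- paste0(m[1L, ], m[2L, ], m[3L, ])
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Encode a peptide k-mer as a 4k-bit integer
#'
#' The code is the big-endian base-16 concatenation of the residue group codes:
#' `phi(P) = phi(P[1..k-1]) * 16 + phi(P[k])`.
#'
#' @param peptide a single residue string of length k (k <= 13 so the code is
#'   exactly representable as a double).
#' @return the k-mer code (numeric, integral-valued).
#' @examples
#' encode_kmer("AW")  # 0*16 + 13
#' @export
encode_kmer <- function(peptide) {
  codes <- .reduce_string(peptide)
  k <- length(codes)
  if (k < 1L || k > 13L) stop("k must be in [1, 13]")
  sum(codes * 16^((k - 1L):0L))
}

#' Decode a k-mer code back to its group-code sequence
#'
#' @param code k-mer code as produced by [encode_kmer()].
#' @param k k-mer length.
#' @return integer vector of k group codes (first residue first).
#' @export
decode_kmer <- function(code, k) {
  out <- integer(k)
  for (t in k:1) {
    out[t] <- as.integer(code %% 16)
    code <- code %/% 16
  }
  out
}

# rolling k-mer codes for a peptide code vector; returns numeric vector of
# length length(codes)-k+1 (window starting positions)
.rolling_kmers <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  if (k == 1L) return(as.numeric(codes))
  drop(stats::embed(codes, k) %*% 16^(0:(k - 1L)))
}

#' Invertible k-mer hash
#'
#' A Wang-style integer mixer restricted to `4k` bits (masked after every
#' step), a bijection on `[0, 2^(4k))`.  Used to subsample indexed k-mers:
#' only codes whose hashed value has lowest bit 0 are kept, retaining 50% of
#' k-mers on average.
#'
#' @param code numeric vector of k-mer codes in `[0, 2^(4k))`.
#' @param k k-mer length in residues.
#' @return numeric vector of hashed codes in the same range.
#' @seealso [unhash_kmer()] for the inverse.
#' @export
hash_kmer <- function(code, k) {
  .hash_mix_cpp(as.numeric(code), 4L * as.integer(k), FALSE)
}

#' @rdname hash_kmer
#' @export
unhash_kmer <- function(code, k) {
  .hash_mix_cpp(as.numeric(code), 4L * as.integer(k), TRUE)
}

# reverse complement for plain character strings (N-safe)
.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}
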