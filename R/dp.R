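# Alignment DP wrappers around the C++ core, plus extended-CIGAR helpers.
#
# Extended CIGAR conventions (op, len):
#   M  aligned codons (len in residues, 3 nt each)
#   I  inserted residues (protein only)
#   D  deleted codons (len in residues/codons, 3 nt each)
#   F  frameshift substitution '$': a 1-2 nt genomic "codon" aligned to one
#      residue (len in nt; one residue per F op)
#   G  frameshift insertion '+': 1-2 extra genomic bases, no residue
#   N  Phase-0 intron (len = intron nt)
#   U  Phase-1 intron (len = intron nt + 3: includes the split codon's one
#      upstream and two downstream bases; consumes one residue)
#   V  Phase-2 intron (len = intron nt + 3: two upstream, one downstream base;
#      consumes one residue)
# Genome nt consumed = 3*(M+D) + F + G + N + U + V (summing lens);
# residues consumed = M + I + one per F, U and V op.

.OP_LETTERS <- c("M", "I", "D", "F", "G", "N", "U", "V")

# ops matrix (code, len) -> data.frame(op, len)
.ops_df <- function(opmat) {
  data.frame(op = .OP_LETTERS[opmat[, 1L]], len = opmat[, 2L],
             stringsAsFactors = FALSE)
}

#' Genome and protein spans implied by an extended CIGAR
#'
#' @param cigar data.frame with columns `op`, `len`.
#' @return list with `genome` (nt) and `protein` (residues) consumed.
#' @export
cigar_spans <- function(cigar) {
  g <- sum(ifelse(cigar$op %in% c("M", "D"), 3L * cigar$len,
           ifelse(cigar$op == "I", 0L, cigar$len)))
  p <- sum(ifelse(cigar$op %in% c("M", "I"), cigar$len,
           ifelse(cigar$op %in% c("F", "U", "V"), 1L, 0L)))
  list(genome = as.integer(g), protein = as.integer(p))
}

#' @rdname cigar_spans
#' @export
cigar_string <- function(cigar) paste0(cigar$len, cigar$op, collapse = "")

# parse "12M87N3I" into a data.frame(op, len)
.parse_cigar <- function(s) {
  m <- gregexpr("[0-9]+[MIDFGNUV]", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  data.frame(op = sub("^[0-9]+", "", parts),
             len = as.integer(sub("[A-Z]$", "", parts)),
             stringsAsFactors = FALSE)
}

#' Global affine-gap alignment score between two peptides
#'
#' The three-state affine formulation: `I/D` gap states with open `q` and
#' extension `e` (a gap of length g costs `q + e*g`), `H` the running best.
#' Used as the residue-level reference for the spliced DP's gap logic.
#'
#' @param a,b residue strings.
#' @param params a [scoring_params()].
#' @return the optimal global score (integer).
#' @export
affine_align <- function(a, b, params = scoring_params()) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  stopifnot(n >= 1L, m >= 1L)
  alph <- rownames(params$matrix)
  ai <- .residue_indices(av, alph) + 1L
  bi <- .residue_indices(bv, alph) + 1L
  q <- params$q; e <- params$e; S <- params$matrix
  NEG <- -1e9
  Hp <- c(0, -(q + e * seq_len(m)))          # row i-1
  Ip <- rep(NEG, m + 1L)
  Dc <- rep(NEG, m + 1L)
  for (i in seq_len(n)) {
    H <- numeric(m + 1L); I <- rep(NEG, m + 1L)
    H[1L] <- -(q + e * i)
    Dc[1L] <- max(Hp[1L] - q, Dc[1L]) - e
    for (j in seq_len(m)) {
      I[j + 1L] <- max(H[j] - q, I[j]) - e
      Dc[j + 1L] <- max(Hp[j + 1L] - q, Dc[j + 1L]) - e
      H[j + 1L] <- max(Hp[j] + S[ai[i], bi[j]], I[j + 1L], Dc[j + 1L])
    }
    Hp <- H
  }
  Hp[m + 1L]
}

# shared driver for the C++ spliced DP
.run_dp <- function(dna, protein, params, splice, use_introns, free_genome_ends) {
  dna <- toupper(dna); protein <- toupper(protein)
  n <- nchar(dna); m <- nchar(protein)
  stopifnot(n >= 1L, m >= 1L)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  alph <- rownames(params$matrix)
  tcode <- rep(-1L, n)
  if (n >= 3L) {
    codons <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
    aa <- .CODON_TABLE[codons]
    aa[is.na(aa)] <- "X"
    tcode[3:n] <- .residue_indices(unname(aa), alph)
  }
  pcode <- .residue_indices(strsplit(protein, "", fixed = TRUE)[[1]], alph)
  if (use_introns) {
    if (is.list(splice) && !inherits(splice, "splice_model")) {
      dvec <- as.integer(splice$dvec); avec <- as.integer(splice$avec)
      stopifnot(length(dvec) == n, length(avec) == n)
    } else {
      cv <- .splice_cost_vectors(splice, dna)
      dvec <- cv$dvec; avec <- cv$avec
    }
  } else {
    dvec <- avec <- rep.int(0L, n)
  }
  res <- .spliced_dp_cpp(tcode, pcode, params$matrix, params$q, params$e,
                         params$f, params$r, dvec, avec, use_introns,
                         free_genome_ends)
  cigar <- .ops_df(res$ops)
  introns <- if (nrow(res$introns)) {
    data.frame(start = res$introns[, 1L], end = res$introns[, 2L],
               phase = res$introns[, 3L])
  } else data.frame(start = integer(0), end = integer(0), phase = integer(0))
  exons <- .exons_from_introns(res$gstart, res$gend, introns)
  list(score = res$score, cigar = cigar, introns = introns, exons = exons,
       gstart = res$gstart, gend = res$gend)
}

# exon intervals between introns within [gstart, gend]
.exons_from_introns <- function(gstart, gend, introns) {
  if (!nrow(introns))
    return(data.frame(start = gstart, end = gend))
  starts <- c(gstart, introns$end + 1L)
  ends <- c(introns$start - 1L, gend)
  data.frame(start = starts, end = ends)
}

#' Protein-to-DNA alignment with frameshifts
#'
#' Aligns a protein to a DNA sequence without splicing: codon matches scored
#' by the substitution matrix on the translated codon, residue insertions
#' and codon deletions under affine costs, and four frameshift transitions
#' with penalty `f` (1-2 nt codons aligned to a residue, or 1-2 nt genomic
#' insertions).
#'
#' @param dna nucleotide string.
#' @param protein residue string.
#' @param params a [scoring_params()].
#' @param free_genome_ends if `TRUE` (default) genome flanks outside the
#'   aligned region are free; if `FALSE` the whole DNA must be consumed.
#' @return list with `score`, `cigar` (data.frame op/len), `gstart`, `gend`.
#' @export
protein_dna_align <- function(dna, protein, params = scoring_params(),
                              free_genome_ends = TRUE) {
  out <- .run_dp(dna, protein, params, NULL, FALSE, free_genome_ends)
  out[c("score", "cigar", "gstart", "gend")]
}

#' Spliced protein-to-genome alignment
#'
#' The six-state DP: in addition to match/insertion/deletion/frameshift, three
#' intron states model Phase-0/1/2 introns entered at the intron-open cost
#' plus the donor-signal cost and left at the acceptor-signal cost, with the
#' signal costs coming from the splice model.  Split codons bridging
#' Phase-1/2 introns are not scored.
#' The protein is aligned globally; genome flanks are free by default.
#'
#' @param dna nucleotide string (one genome window, the strand being aligned).
#' @param protein residue string.
#' @param params a [scoring_params()].
#' @param splice a [splice_model()], or a list with precomputed integer cost
#'   vectors `dvec` (intron starting at i) and `avec` (intron ending at i).
#' @param free_genome_ends free genome flanks (default `TRUE`).
#' @return list with `score`, `cigar`, `introns` (start/end/phase),
#'   `exons`, `gstart`, `gend` (all 1-based inclusive window coordinates).
#' @export
spliced_align <- function(dna, protein, params = scoring_params(),
                          splice = splice_model("default"),
                          free_genome_ends = TRUE) {
  .run_dp(dna, protein, params, splice, TRUE, free_genome_ends)
}
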