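# Six-frame ORF enumeration and the binned k-mer index.

#' Enumerate open reading frames of a nucleotide sequence
#'
#' ORFs are maximal stop-free translated stretches in each of the three
#' forward frames (stop codons and sequence ends delimit; no start codon is
#' required, so internal exons remain visible).  Codons containing N
#' translate to X and do not break an ORF.  Apply to the reverse complement
#' as well to obtain all six frames.
#'
#' @param seq nucleotide string over A/C/G/T/N (case-insensitive).
#' @param min_len minimum ORF length in residues.
#' @return a data.frame with columns `frame` (0..2), `start` (1-based offset
#'   of the first codon base), and `peptide`.
#' @export
enumerate_orfs <- function(seq, min_len = 30L) {
  stopifnot(min_len >= 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- vector("list", 3L)
  for (fr in 0:2) {
    aa <- .translate_frame(chars, fr)
    if (!length(aa)) next
    stops <- aa == "*"
    seg <- cumsum(c(TRUE, diff(stops) != 0L))
    runs <- which(!stops)
    if (!length(runs)) next
    starts_aa <- tapply(runs, seg[runs], min)
    ends_aa <- tapply(runs, seg[runs], max)
    keep <- (ends_aa - starts_aa + 1L) >= min_len
    if (!any(keep)) next
    starts_aa <- as.integer(starts_aa[keep]); ends_aa <- as.integer(ends_aa[keep])
    peps <- vapply(seq_along(starts_aa), function(t)
      paste(aa[starts_aa[t]:ends_aa[t]], collapse = ""), character(1))
    out[[fr + 1L]] <- data.frame(frame = fr,
                                 start = fr + 3L * (starts_aa - 1L) + 1L,
                                 peptide = peps, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# normalize genome input to a named character vector of upper-case sequences
.as_seq_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- toupper(as.character(genome))
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    seqs <- toupper(as.character(Biostrings::readDNAStringSet(genome)))
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  if (!length(seqs)) return(stats::setNames(character(0), character(0)))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gsub("[^ACGT]", "N", seqs)
}

#' Build the reduced-alphabet k-mer index of a genome
#'
#' Each genome record and its reverse complement are treated as independent
#' sequences.  ORFs of at least `min_orf` residues are enumerated in all
#' three frames of each; every k-mer window whose hashed code has lowest bit
#' 0 (50% of k-mers on average) contributes one entry keyed by the hashed
#' code, valued by `(sequence id, floor(x/bin))` where `x` is the 0-based
#' genome coordinate of the k-mer's first codon base.  Binning keeps
#' positions within 32 bits for genomes up to `2^32 * bin / 2` bp.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param k k-mer length in residues (default 6; `4*k` must be <= 52).
#' @param bin positions per bin (default 256).
#' @param min_orf minimum ORF length in residues (default 30).
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome, k = 6L, bin = 256L, min_orf = 30L) {
  k <- as.integer(k); bin <- as.integer(bin); min_orf <- as.integer(min_orf)
  stopifnot(k >= 1L, 4L * k <= 52L, bin >= 1L, min_orf >= 1L)
  seqs <- .as_seq_set(genome)
  if (!length(seqs)) stop("no sequences in genome")

  meta <- data.frame(
    sid = seq_len(2L * length(seqs)),
    record = rep(names(seqs), each = 2L),
    strand = rep(c("+", "-"), length(seqs)),
    length = rep(unname(nchar(seqs)), each = 2L),
    stringsAsFactors = FALSE)
  doubled <- character(2L * length(seqs))
  for (t in seq_along(seqs)) {
    doubled[2L * t - 1L] <- seqs[[t]]
    doubled[2L * t] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seqs[[t]])))
  }

  keys <- sids <- bins <- vector("list", length(doubled))
  for (sid in seq_along(doubled)) {
    orfs <- enumerate_orfs(doubled[sid], min_orf)
    if (!nrow(orfs)) next
    kk <- vector("list", nrow(orfs)); bb <- vector("list", nrow(orfs))
    for (t in seq_len(nrow(orfs))) {
      codes <- .reduce_string(orfs$peptide[t])
      vals <- .rolling_kmers(codes, k)
      if (!length(vals)) next
      hashed <- hash_kmer(vals, k)
      sel <- hashed %% 2 == 0 & .windows_without_x(codes, k)
      if (!any(sel)) next
      pos <- orfs$start[t] + 3L * (which(sel) - 1L)    # first codon base, 1-based
      kk[[t]] <- hashed[sel]
      bb[[t]] <- (pos - 1L) %/% bin
    }
    kk <- unlist(kk); bb <- unlist(bb)
    if (!length(kk)) next
    keys[[sid]] <- kk; bins[[sid]] <- bb; sids[[sid]] <- rep.int(sid, length(kk))
  }
  keys <- unlist(keys); bins <- unlist(bins); sids <- unlist(sids)

  table <- new.env(parent = emptyenv(), size = max(16L, length(keys)))
  if (length(keys)) {
    dup <- duplicated(paste(keys, sids, bins))
    keys <- keys[!dup]; bins <- bins[!dup]; sids <- sids[!dup]
    ord <- order(keys, sids, bins)
    keys <- keys[ord]; bins <- bins[ord]; sids <- sids[ord]
    grp <- split(seq_along(keys), format(keys, scientific = FALSE, trim = TRUE))
    for (key in names(grp)) {
      idx <- grp[[key]]
      assign(key, cbind(sid = sids[idx], bin = as.integer(bins[idx])), envir = table)
    }
  }
  structure(list(meta = meta, seqs = doubled, k = k, bin = bin,
                 min_orf = min_orf, table = table, n_keys = length(ls(table))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d record(s), k=%d, bin=%d, min_orf=%d, %d keys\n",
              nrow(x$meta) / 2L, x$k, x$bin, x$min_orf, x$n_keys))
  invisible(x)
}

#' Query the index with a peptide k-mer
#'
#' Returns the stored `(sid, bin)` entries for a k-mer, or an empty matrix
#' when the k-mer's hashed code has lowest bit 1 (such k-mers are never
#' indexed) or the key is absent.
#'
#' @param index a `genome_index`.
#' @param peptide_kmer residue string of length `k`.
#' @return integer matrix with columns `sid`, `bin`.
#' @export
query_index <- function(index, peptide_kmer) {
  stopifnot(inherits(index, "genome_index"))
  if (nchar(peptide_kmer) != index$k) stop("k-mer must have length k")
  h <- hash_kmer(encode_kmer(peptide_kmer), index$k)
  if (h %% 2 != 0) return(cbind(sid = integer(0), bin = integer(0)))
  key <- format(h, scientific = FALSE, trim = TRUE)
  if (!exists(key, envir = index$table, inherits = FALSE))
    return(cbind(sid = integer(0), bin = integer(0)))
  get(key, envir = index$table, inherits = FALSE)
}

# TRUE for k-mer windows free of X (code 15); ambiguous k-mers are neither
# indexed nor used as seeds
.windows_without_x <- function(codes, k) {
  cs <- cumsum(codes == 15L)
  n <- length(codes) - k + 1L
  (cs[seq_len(n) + k - 1L] - c(0L, cs)[seq_len(n)]) == 0L
}

# all anchors of a query protein against the index: data.frame(sid, x=bin,
# y=last residue position of the k-mer)
.collect_anchors <- function(index, protein) {
  k <- index$k
  codes <- .reduce_string(protein)
  vals <- .rolling_kmers(codes, k)
  if (!length(vals))
    return(data.frame(sid = integer(0), x = integer(0), y = integer(0)))
  hashed <- hash_kmer(vals, k)
  sel <- which(hashed %% 2 == 0 & .windows_without_x(codes, k))
  out <- vector("list", length(sel))
  for (t in seq_along(sel)) {
    key <- format(hashed[sel[t]], scientific = FALSE, trim = TRUE)
    if (!exists(key, envir = index$table, inherits = FALSE)) next
    hits <- get(key, envir = index$table, inherits = FALSE)
    out[[t]] <- data.frame(sid = hits[, "sid"], x = hits[, "bin"],
                           y = sel[t] + k - 1L)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(sid = integer(0), x = integer(0), y = integer(0)))
  do.call(rbind, out)
}
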