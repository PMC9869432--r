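# Readers and writers: FASTA in; GFF3 and PAF (extended CIGAR) out.

#' Read a genome / protein FASTA
#'
#' Thin wrappers over Biostrings readers returning named upper-case character
#' vectors (gzip-transparent).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_genome <- function(path) .as_seq_set(path)

#' @rdname read_genome
#' @export
read_proteins <- function(path) unlist(.as_protein_set(path))

# GFF3 phases of exons given in genome order, for one transcript
.gff_phases <- function(exons, strand) {
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  lens <- exons$end - exons$start + 1L
  cum <- c(0L, cumsum(lens[ord]))[seq_len(nrow(exons))]
  ph <- (3L - cum %% 3L) %% 3L
  out <- integer(nrow(exons))
  out[ord] <- ph
  out
}

.gff_escape <- function(x) gsub("([;=&,\t])", "", x)

#' Write alignments as GFF3 gene models
#'
#' One `mRNA` feature plus ordered `CDS` features per alignment; coordinates
#' are 1-based inclusive, CDS phases follow the cumulative coding length in
#' transcription order.  Attributes carry identity and both DP scores.
#'
#' @param alns a `spliced_alignment_list` (or list of `spliced_alignment`).
#' @param file output path or connection.
#' @param source value of the GFF source column.
#' @return `invisible(file)`.
#' @export
write_gff3 <- function(alns, file, source = "splicealigner") {
  lines <- "##gff-version 3"
  for (t in seq_along(alns)) {
    a <- alns[[t]]
    id <- sprintf("%s.aln%d", .gff_escape(a$qname), t)
    attr_m <- sprintf("ID=%s;Query=%s;Identity=%.4f;ms=%d;us=%d;Rank=%d",
                      id, .gff_escape(a$qname), a$identity,
                      a$score_spliced, a$score_unspliced,
                      if (isTRUE(a$is_secondary)) 2L else 1L)
    lines <- c(lines, paste(a$target, source, "mRNA", a$tstart, a$tend,
                            a$score_spliced, a$strand, ".", attr_m, sep = "\t"))
    ph <- .gff_phases(a$exons, a$strand)
    for (u in seq_len(nrow(a$exons))) {
      attr_c <- sprintf("ID=%s.cds%d;Parent=%s", id, u, id)
      lines <- c(lines, paste(a$target, source, "CDS", a$exons$start[u],
                              a$exons$end[u], ".", a$strand, ph[u], attr_c,
                              sep = "\t"))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Write alignments as PAF with extended CIGAR
#'
#' Query coordinates are in residues, target coordinates in nucleotides, both
#' 0-based half-open on the forward strand.  Tags: `tp:A` primary/secondary,
#' `ms:i` spliced DP score, `us:i` unspliced re-score, `cg:Z` extended CIGAR
#' with ops M/I/D/F/G/N/U/V (see [cigar_spans()] for the conventions).
#'
#' @inheritParams write_gff3
#' @return `invisible(file)`.
#' @export
write_paf <- function(alns, file) {
  lines <- character(0)
  for (a in alns) {
    lines <- c(lines, paste(
      a$qname, a$qlen, 0L, a$qlen, a$strand, a$target, a$tlen,
      a$tstart - 1L, a$tend, a$nmatch, a$tend - a$tstart + 1L,
      if (isTRUE(a$is_secondary)) 0L else 60L,
      sprintf("tp:A:%s", if (isTRUE(a$is_secondary)) "S" else "P"),
      sprintf("ms:i:%d", a$score_spliced),
      sprintf("us:i:%d", a$score_unspliced),
      sprintf("cg:Z:%s", cigar_string(a$cigar)),
      sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}

# exon/intron intervals (forward coordinates) implied by a cigar anchored at
# tstart (1-based, forward) on the given strand
.cigar_structure <- function(cigar, tstart, tend, strand) {
  introns <- data.frame(start = integer(0), end = integer(0), phase = integer(0))
  g <- if (strand == "+") tstart else tend   # alignment-orientation cursor
  step <- if (strand == "+") 1L else -1L
  for (t in seq_len(nrow(cigar))) {
    op <- cigar$op[t]; len <- cigar$len[t]
    adv <- switch(op, M = 3L * len, D = 3L * len, I = 0L, F = len, G = len,
                  N = len, U = len, V = len)
    if (op %in% c("N", "U", "V")) {
      off1 <- switch(op, N = 0L, U = 1L, V = 2L)     # split bases before intron
      off2 <- switch(op, N = 0L, U = 2L, V = 1L)     # split bases after
      is1 <- g + step * off1; is2 <- g + step * (adv - 1L - off2)
      introns <- rbind(introns, data.frame(
        start = min(is1, is2), end = max(is1, is2),
        phase = switch(op, N = 0L, U = 1L, V = 2L)))
    }
    g <- g + step * adv
  }
  introns <- introns[order(introns$start), , drop = FALSE]
  list(introns = introns,
       exons = .exons_from_introns(tstart, tend, introns))
}

#' Parse a PAF file written by [write_paf()]
#'
#' @param file PAF path.
#' @return a data.frame (one row per record) with list-columns `cigar`,
#'   `exons` and `introns` reconstructed from the extended CIGAR.
#' @export
read_paf <- function(file) {
  lines <- readLines(file)
  recs <- lapply(lines, function(ln) {
    fld <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tags <- fld[-(1:12)]
    getv <- function(tag) sub(paste0("^", tag, ":[AiZ]:"), "",
                              grep(paste0("^", tag, ":"), tags, value = TRUE)[1])
    cg <- .parse_cigar(getv("cg"))
    tstart <- as.integer(fld[8]) + 1L; tend <- as.integer(fld[9])
    st <- .cigar_structure(cg, tstart, tend, fld[5])
    list(qname = fld[1], qlen = as.integer(fld[2]), strand = fld[5],
         target = fld[6], tlen = as.integer(fld[7]), tstart = tstart,
         tend = tend, nmatch = as.integer(fld[10]),
         ms = as.integer(getv("ms")), us = as.integer(getv("us")),
         cigar = cg, exons = st$exons, introns = st$introns)
  })
  out <- data.frame(
    qname = vapply(recs, `[[`, character(1), "qname"),
    qlen = vapply(recs, `[[`, integer(1), "qlen"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    target = vapply(recs, `[[`, character(1), "target"),
    tlen = vapply(recs, `[[`, integer(1), "tlen"),
    tstart = vapply(recs, `[[`, integer(1), "tstart"),
    tend = vapply(recs, `[[`, integer(1), "tend"),
    nmatch = vapply(recs, `[[`, integer(1), "nmatch"),
    ms = vapply(recs, `[[`, integer(1), "ms"),
    us = vapply(recs, `[[`, integer(1), "us"),
    stringsAsFactors = FALSE)
  out$cigar <- lapply(recs, `[[`, "cigar")
  out$exons <- lapply(recs, `[[`, "exons")
  out$introns <- lapply(recs, `[[`, "introns")
  out
}

# normalize a GFF3 source (path, GRanges from rtracklayer, or internal
# data.frame) to a flat data.frame: seqid,type,start,end,strand,id,parent
.gff_df <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "gff3")
    md <- S4Vectors::mcols(gr)
    parent <- if ("Parent" %in% names(md)) {
      vapply(as.list(md$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else rep(NA_character_, length(gr))
    data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
               type = as.character(md$type),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
               parent = parent, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    need <- c("seqid", "type", "start", "end", "strand", "id", "parent")
    if (!all(need %in% names(x))) stop("data.frame GFF needs columns: ",
                                       paste(need, collapse = ", "))
    x[, need]
  } else stop("unsupported GFF input")
}
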