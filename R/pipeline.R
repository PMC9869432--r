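# End-to-end mapping: seed -> chain -> refine -> spliced DP -> ranking.

#' Aligner parameters
#'
#' Bundles the tunables of the full pipeline.
#'
#' @param scoring a [scoring_params()].
#' @param splice a [splice_model()].
#' @param chain a [chain_params()]; its `bin` is taken from the index.
#' @param intron_pad genome padding (bp, capped at `G`) added around chain
#'   extents when cutting the refinement/DP window, so introns adjacent to
#'   terminal exons stay inside the window.
#' @param max_secondary maximum number of secondary alignments reported.
#' @return a list of class `aligner_params`.
#' @export
aligner_params <- function(scoring = scoring_params(),
                           splice = splice_model("default"),
                           chain = chain_params(),
                           intron_pad = 5000L,
                           max_secondary = 5L) {
  structure(list(scoring = scoring, splice = splice, chain = chain,
                 intron_pad = as.integer(intron_pad),
                 max_secondary = as.integer(max_secondary)),
            class = "aligner_params")
}

# walk a cigar over window/protein to count aligned and identical residues
.cigar_identity <- function(cigar, win, protein, gstart) {
  wch <- strsplit(toupper(win), "", fixed = TRUE)[[1]]
  pch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  g <- gstart; p <- 1L; nmatch <- 0L; naln <- 0L
  for (t in seq_len(nrow(cigar))) {
    op <- cigar$op[t]; len <- cigar$len[t]
    if (op == "M") {
      for (u in seq_len(len)) {
        codon <- paste0(wch[g], wch[g + 1L], wch[g + 2L])
        aa <- .CODON_TABLE[codon]; if (is.na(aa)) aa <- "X"
        if (identical(unname(aa), pch[p])) nmatch <- nmatch + 1L
        naln <- naln + 1L; g <- g + 3L; p <- p + 1L
      }
    } else if (op == "I") { p <- p + len
    } else if (op == "D") { g <- g + 3L * len
    } else if (op == "F") { g <- g + len; p <- p + 1L; naln <- naln + 1L
    } else if (op == "G") { g <- g + len
    } else if (op == "N") { g <- g + len
    } else if (op %in% c("U", "V")) { g <- g + len; p <- p + 1L; naln <- naln + 1L }
  }
  list(nmatch = nmatch, naln = naln)
}

#' Penalise single-exon alignments when ranking
#'
#' Processed pseudogenes are intron-less copies of spliced genes; the raw
#' spliced DP score favours them because they pay no intron penalties.  The
#' ranking score is therefore the alignment's intron-free re-score
#' (`score_unspliced`, a frameshift-aware DP between the query and the
#' concatenated exon sequence), and single-exon alignments are additionally
#' penalised by the intron-open score `r`.
#'
#' @param aln a `spliced_alignment`.
#' @param r intron-open penalty.
#' @return the adjusted ranking score (numeric).
#' @export
pseudogene_adjust <- function(aln, r) {
  s <- aln$score_unspliced
  if (aln$n_exons == 1L) s <- s - r
  s
}

#' Map one protein to an indexed genome
#'
#' Runs the full pipeline: collect sampled k-mer anchors, round-1 chaining on
#' binned positions, round-2 base-resolution re-chaining with 5-mers inside
#' each top chain's window, one spliced DP over the refined window (free
#' genome flanks, global on the protein), intron-free re-scoring and
#' single-exon adjustment, then ranking.
#'
#' @param index a [build_index()] result.
#' @param protein query protein string (length >= k).
#' @param qname query name carried into output.
#' @param params an [aligner_params()].
#' @return list of `spliced_alignment` objects, best first (empty if the
#'   query seeds nowhere).
#' @export
map_protein <- function(index, protein, qname = "query",
                        params = aligner_params()) {
  stopifnot(inherits(index, "genome_index"))
  protein <- toupper(gsub("\\s", "", protein))
  qlen <- nchar(protein)
  if (qlen < index$k) stop("query shorter than k")
  cp <- params$chain; cp$bin <- index$bin
  ipad <- min(cp$G, params$intron_pad)

  anchors <- .collect_anchors(index, protein)
  if (!nrow(anchors)) return(.empty_alignments())
  chains <- list()
  for (sid in unique(anchors$sid)) {
    sub <- anchors[anchors$sid == sid, , drop = FALSE]
    for (ch in chain_anchors(sub, span = index$k, params = cp, binned = TRUE)) {
      ch$sid <- sid
      chains[[length(chains) + 1L]] <- ch
    }
  }
  if (!length(chains)) return(.empty_alignments())
  chains <- chains[order(-vapply(chains, `[[`, numeric(1), "score"))]
  chains <- .filter_chains_locus(chains, cp$top_n, index$bin)

  alns <- list()
  for (ch in chains) {
    sid <- ch$sid
    seqd <- index$seqs[sid]
    L <- index$meta$length[sid]
    y1 <- min(ch$anchors$y); y2 <- max(ch$anchors$y)
    gs <- min(ch$anchors$x) * index$bin + 1L
    ge <- (max(ch$anchors$x) + 1L) * index$bin
    w1s <- max(1L, gs - (3L * y1 + ipad))
    w1e <- min(L, ge + 3L * (qlen - y2) + ipad)
    window1 <- substr(seqd, w1s, w1e)

    rc <- rechain_local(window1, protein, cp,
                        prefer_range = c(gs - w1s + 1L, ge - w1s + 1L))
    if (!is.null(rc)) {
      cs <- max(1L, min(rc$anchors$x) - 3L * cp$round2_k + 1L)
      ce <- max(rc$anchors$x)
      ry1 <- min(rc$anchors$y) - cp$round2_k; ry2 <- max(rc$anchors$y)
      padl <- if (ry1 > 0L) 3L * ry1 + ipad else 30L
      padr <- if (qlen - ry2 > 0L) 3L * (qlen - ry2) + ipad else 30L
      ds <- max(1L, cs - padl)
      de <- min(nchar(window1), ce + padr)
    } else {
      ds <- 1L; de <- nchar(window1)
    }
    win <- substr(window1, ds, de)
    if (nchar(win) < 3L) next
    al <- tryCatch(spliced_align(win, protein, params$scoring, params$splice),
                   error = function(e) NULL)
    if (is.null(al)) next
    offset <- w1s + ds - 2L   # window coord + offset = doubled-seq coord

    strand <- index$meta$strand[sid]
    rec <- index$meta$record[sid]
    t1 <- al$gstart + offset; t2 <- al$gend + offset
    exons_d <- al$exons + offset
    introns_d <- al$introns
    if (nrow(introns_d)) {
      introns_d$start <- introns_d$start + offset
      introns_d$end <- introns_d$end + offset
    }
    if (strand == "+") {
      tstart <- t1; tend <- t2
      exons <- exons_d
      introns <- introns_d
    } else {
      tstart <- L - t2 + 1L; tend <- L - t1 + 1L
      exons <- data.frame(start = rev(L - exons_d$end + 1L),
                          end = rev(L - exons_d$start + 1L))
      introns <- if (nrow(introns_d)) {
        data.frame(start = rev(L - introns_d$end + 1L),
                   end = rev(L - introns_d$start + 1L),
                   phase = rev(introns_d$phase))
      } else introns_d
    }
    idy <- .cigar_identity(al$cigar, win, protein, al$gstart)
    exon_seq <- paste(vapply(seq_len(nrow(al$exons)), function(t)
      substr(win, al$exons$start[t], al$exons$end[t]), character(1)),
      collapse = "")
    uns <- protein_dna_align(exon_seq, protein, params$scoring)$score

    aln <- structure(list(
      qname = qname, qlen = qlen, target = rec, strand = strand,
      tlen = L, tstart = as.integer(tstart), tend = as.integer(tend),
      exons = exons, introns = introns, n_exons = nrow(exons),
      cigar = al$cigar, score_spliced = al$score, score_unspliced = uns,
      nmatch = idy$nmatch,
      identity = if (idy$naln > 0) idy$nmatch / idy$naln else 0,
      rank_score = NA_real_, is_secondary = NA), class = "spliced_alignment")
    alns[[length(alns) + 1L]] <- aln
  }
  if (!length(alns)) return(.empty_alignments())

  key <- vapply(alns, function(a) paste(a$target, a$strand, a$tstart, a$tend),
                character(1))
  alns <- alns[!duplicated(key)]
  r <- params$scoring$r
  rank <- vapply(alns, pseudogene_adjust, numeric(1), r = r)
  ord <- order(-rank, vapply(alns, function(a) as.numeric(a$n_exons), numeric(1)),
               vapply(alns, function(a) as.numeric(a$tstart), numeric(1)))
  alns <- alns[ord]; rank <- rank[ord]
  alns <- alns[seq_len(min(length(alns), 1L + params$max_secondary))]
  for (t in seq_along(alns)) {
    alns[[t]]$rank_score <- rank[t]
    alns[[t]]$is_secondary <- t > 1L
  }
  class(alns) <- "spliced_alignment_list"
  alns
}

.empty_alignments <- function() structure(list(), class = "spliced_alignment_list")

# overlap filter that only collapses chains competing for the same genomic
# locus: >50% protein overlap with a better chain on the same sequence with
# overlapping genome extents; distinct loci (e.g. a pseudogene copy) are kept
.filter_chains_locus <- function(chains, top_n, bin) {
  kept <- list()
  for (ch in chains) {
    y1 <- min(ch$anchors$y); y2 <- max(ch$anchors$y)
    g1 <- min(ch$anchors$x); g2 <- max(ch$anchors$x)
    ok <- TRUE
    for (kc in kept) {
      if (kc$sid != ch$sid) next
      gov <- min(g2, max(kc$anchors$x)) - max(g1, min(kc$anchors$x))
      if (gov <= 1) next   # disjoint or merely abutting bins: distinct loci
      ov <- min(y2, max(kc$anchors$y)) - max(y1, min(kc$anchors$y)) + 1L
      if (ov > 0.5 * (y2 - y1 + 1L)) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- ch
    if (length(kept) >= top_n) break
  }
  kept
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> %s (%d aa) -> %s:%d-%d (%s), %d exon(s), score %d (unspliced %d), identity %.1f%%%s\n",
              x$qname, x$qlen, x$target, x$tstart, x$tend, x$strand,
              x$n_exons, x$score_spliced, x$score_unspliced,
              100 * x$identity, if (isTRUE(x$is_secondary)) " [secondary]" else ""))
  invisible(x)
}

#' @export
print.spliced_alignment_list <- function(x, ...) {
  cat(sprintf("<spliced_alignment_list> %d alignment(s)\n", length(x)))
  for (a in x) print(a)
  invisible(x)
}

#' Align a set of proteins to a genome
#'
#' Convenience wrapper: builds (or reuses) the index and maps every query.
#'
#' @param genome FASTA path, `DNAStringSet`, named character vector, or a
#'   prebuilt `genome_index`.
#' @param proteins FASTA path, `AAStringSet`, or named character vector.
#' @param params an [aligner_params()].
#' @param k,bin,min_orf index parameters (ignored when `genome` is an index).
#' @return a `spliced_alignment_list` over all queries (each query's
#'   alignments ranked, primaries first within a query).
#' @export
align_proteins <- function(genome, proteins, params = aligner_params(),
                           k = 6L, bin = 256L, min_orf = 30L) {
  index <- if (inherits(genome, "genome_index")) genome
           else build_index(genome, k = k, bin = bin, min_orf = min_orf)
  prots <- .as_protein_set(proteins)
  out <- list()
  for (t in seq_along(prots)) {
    alns <- tryCatch(map_protein(index, prots[[t]], qname = names(prots)[t],
                                 params = params),
                     error = function(e) .empty_alignments())
    out <- c(out, alns)
  }
  class(out) <- "spliced_alignment_list"
  out
}

.as_protein_set <- function(proteins) {
  if (inherits(proteins, "AAStringSet")) {
    p <- toupper(as.character(proteins))
  } else if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins)) {
    p <- toupper(as.character(Biostrings::readAAStringSet(proteins)))
  } else if (is.character(proteins)) {
    p <- toupper(proteins)
  } else stop("proteins must be an AAStringSet, named character vector, or FASTA path")
  if (is.null(names(p))) names(p) <- paste0("query", seq_along(p))
  names(p) <- sub("\\s.*$", "", names(p))
  as.list(p)
}
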