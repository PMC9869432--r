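# Annotation-accuracy metrics: confirmed / non-overlapping splice junctions,
# base-level sensitivity and specificity against a reference annotation.

# junction set (seq, strand, start, end of intron) from a GFF source:
# introns between consecutive CDS of each transcript, deduplicated
.gff_introns <- function(x) {
  df <- .gff_df(x)
  cds <- df[df$type == "CDS", , drop = FALSE]
  out <- list()
  for (tx in unique(cds$parent)) {
    sub <- cds[cds$parent %in% tx, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      seq = sub$seqid[-nrow(sub)], strand = sub$strand[-nrow(sub)],
      start = sub$end[-nrow(sub)] + 1L, end = sub$start[-1L] - 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seq = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  unique(do.call(rbind, out))
}

#' Splice junctions of a GFF3 annotation or alignment set
#'
#' @param x GFF3 path, internal GFF data.frame, or a
#'   `spliced_alignment_list`.
#' @return data.frame with columns `seq`, `strand`, `start`, `end` (intron
#'   intervals, deduplicated).
#' @export
junctions <- function(x) {
  if (inherits(x, "spliced_alignment_list") || inherits(x, "spliced_alignment")) {
    alns <- if (inherits(x, "spliced_alignment")) list(x) else x
    out <- lapply(alns, function(a) {
      if (!nrow(a$introns)) return(NULL)
      data.frame(seq = a$target, strand = a$strand,
                 start = a$introns$start, end = a$introns$end,
                 stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
      return(data.frame(seq = character(0), strand = character(0),
                        start = integer(0), end = integer(0)))
    return(unique(do.call(rbind, out)))
  }
  .gff_introns(x)
}

#' Junction-level accuracy
#'
#' A predicted junction is *confirmed* when an annotated intron has exactly
#' the same boundaries (same sequence and strand); it is *non-overlapping*
#' when its intron interval overlaps no annotated intron at all.
#'
#' @param pred,anno junction sets as returned by [junctions()].
#' @return list with `n_pred`, `n_confirmed`, `n_nonoverlap`,
#'   `pct_confirmed` (0 when nothing is predicted).
#' @export
junction_stats <- function(pred, anno) {
  pred <- unique(pred); anno <- unique(anno)
  n_pred <- nrow(pred)
  if (!n_pred)
    return(list(n_pred = 0L, n_confirmed = 0L, n_nonoverlap = 0L,
                pct_confirmed = 0))
  keyp <- paste(pred$seq, pred$strand, pred$start, pred$end)
  keya <- paste(anno$seq, anno$strand, anno$start, anno$end)
  n_conf <- sum(keyp %in% keya)
  if (nrow(anno)) {
    gp <- GenomicRanges::GRanges(pred$seq, IRanges::IRanges(pred$start, pred$end))
    ga <- GenomicRanges::GRanges(anno$seq, IRanges::IRanges(anno$start, anno$end))
    n_nov <- sum(GenomicRanges::countOverlaps(gp, ga, ignore.strand = TRUE) == 0L)
  } else n_nov <- n_pred
  list(n_pred = n_pred, n_confirmed = n_conf, n_nonoverlap = n_nov,
       pct_confirmed = 100 * n_conf / n_pred)
}

# CDS intervals of the longest transcript (by coding length) per gene
.longest_tx_cds <- function(x) {
  df <- .gff_df(x)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("annotation contains no CDS features")
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  gene_of <- stats::setNames(mrna$parent, mrna$id)
  cds$gene <- gene_of[cds$parent]
  cds$gene[is.na(cds$gene)] <- cds$parent[is.na(cds$gene)]
  lens <- tapply(cds$end - cds$start + 1L, cds$parent, sum)
  tx_gene <- cds$gene[match(names(lens), cds$parent)]
  keep_tx <- unlist(lapply(split(seq_along(lens), tx_gene), function(idx) {
    names(lens)[idx][which.max(lens[idx])]
  }))
  cds[cds$parent %in% keep_tx, c("seqid", "start", "end"), drop = FALSE]
}

# aligned CDS intervals from alignments or a GFF source
.aligned_cds <- function(x) {
  if (inherits(x, "spliced_alignment_list") || inherits(x, "spliced_alignment")) {
    alns <- if (inherits(x, "spliced_alignment")) list(x) else x
    out <- lapply(alns, function(a)
      data.frame(seqid = a$target, start = a$exons$start, end = a$exons$end,
                 stringsAsFactors = FALSE))
    if (!length(out))
      return(data.frame(seqid = character(0), start = integer(0), end = integer(0)))
    return(do.call(rbind, out))
  }
  df <- .gff_df(x)
  df <- df[df$type == "CDS", c("seqid", "start", "end"), drop = FALSE]
  df
}

#' Base-level sensitivity and specificity
#'
#' Sensitivity: percentage of annotated coding bases (longest transcript per
#' gene, intervals unioned) covered by alignments.  Specificity: percentage
#' of aligned genomic bases covered by annotated coding regions.
#'
#' @param pred alignments (`spliced_alignment_list`) or a GFF3 prediction.
#' @param anno reference annotation (GFF3 path or internal data.frame).
#' @return list with `sn` and `sp`, both in percent.
#' @export
base_sn_sp <- function(pred, anno) {
  acds <- .longest_tx_cds(anno)
  pcds <- .aligned_cds(pred)
  ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
    acds$seqid, IRanges::IRanges(acds$start, acds$end)))
  if (!nrow(pcds))
    return(list(sn = 0, sp = 0))
  gp <- GenomicRanges::reduce(GenomicRanges::GRanges(
    pcds$seqid, IRanges::IRanges(pcds$start, pcds$end)))
  ov <- sum(IRanges::width(GenomicRanges::intersect(ga, gp, ignore.strand = TRUE)))
  list(sn = 100 * ov / sum(IRanges::width(ga)),
       sp = 100 * ov / sum(IRanges::width(gp)))
}

#' Evaluate predicted gene models against a reference annotation
#'
#' Mirrors the standard accuracy summary for protein-to-genome aligners:
#' junction counts (predicted / confirmed / non-overlapping, percent
#' confirmed) and base-level SN/SP.
#'
#' @param pred predictions: `spliced_alignment_list` or GFF3 path.
#' @param anno reference annotation: GFF3 path or internal data.frame.
#' @return list of metrics; also of class `aligner_eval` for printing.
#' @export
evaluate_annotation <- function(pred, anno) {
  js <- junction_stats(junctions(pred), junctions(anno))
  bs <- base_sn_sp(pred, anno)
  structure(c(js, bs), class = "aligner_eval")
}

#' @export
print.aligner_eval <- function(x, ...) {
  cat(sprintf("No. of predicted junc.   %d\n", x$n_pred))
  cat(sprintf("No. of non-ovlp. junc.   %d\n", x$n_nonoverlap))
  cat(sprintf("No. of confirmed junc.   %d\n", x$n_confirmed))
  cat(sprintf("%% confirmed junc.        %.2f\n", x$pct_confirmed))
  cat(sprintf("%% base SN                %.2f\n", x$sn))
  cat(sprintf("%% base SP                %.2f\n", x$sp))
  invisible(x)
}
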