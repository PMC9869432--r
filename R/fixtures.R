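# Synthetic-locus generator: genomes with implanted multi-exon genes,
# diverged query proteins, optional frameshifted copies and processed
# pseudogenes, plus the matching truth annotation.  This is the test
# substrate for the whole aligner; it emulates gene *structure* (GT..AG
# introns at random phases, realistic exon/intron sizes), not realistic
# codon usage or branch-site sequence.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","K","L","M","F","P","S",
           "T","W","Y","V")

.CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

.random_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# reverse-translate a protein with uniformly random synonymous codons
.reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) {
    cods <- .CODONS_OF[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Specification of one synthetic gene locus
#'
#' @param n_exons number of exons (>= 1).
#' @param exon_len range of exon lengths in residues.
#' @param intron_len range of intron lengths in nt (>= 20).
#' @param canonical_frac fraction of introns carrying GT..AG signals; the
#'   rest get random terminal dinucleotides.
#' @param divergence per-residue substitution rate applied to the query
#'   protein relative to the encoded protein.
#' @param indel_rate per-residue insertion/deletion rate on the query.
#' @param frameshifts number of 1-2 nt insertions implanted into genomic
#'   exons (the encoded gene is then frameshifted relative to the query).
#' @param pseudogene also implant an intron-less (processed-pseudogene) copy
#'   of the coding sequence downstream of the gene.
#' @return a list of class `locus_spec`.
#' @export
locus_spec <- function(n_exons = 3L, exon_len = c(30L, 100L),
                       intron_len = c(60L, 2000L), canonical_frac = 1,
                       divergence = 0.05, indel_rate = 0.01,
                       frameshifts = 0L, pseudogene = FALSE) {
  stopifnot(n_exons >= 1L, exon_len[1] >= 1L, intron_len[1] >= 20L,
            canonical_frac >= 0, canonical_frac <= 1,
            divergence >= 0, divergence <= 1, indel_rate >= 0, indel_rate <= 1)
  structure(list(n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 canonical_frac = canonical_frac, divergence = divergence,
                 indel_rate = indel_rate, frameshifts = as.integer(frameshifts),
                 pseudogene = pseudogene), class = "locus_spec")
}

# canonical introns carry the consensus signal context (GTR..YAG), the
# majority classes observed in real donors/acceptors; non-canonical introns
# get random terminal dinucleotides
.make_intron <- function(len, canonical) {
  if (canonical) {
    body <- if (len > 6L) .random_nt(len - 6L) else ""
    paste0("GT", sample(c("A", "G"), 1L), body, sample(c("C", "T"), 1L), "AG")
  } else {
    body <- if (len > 4L) .random_nt(len - 4L) else ""
    paste0(.random_nt(2L), body, .random_nt(2L))
  }
}

.mutate_protein <- function(protein, divergence, indel_rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sub_at <- which(stats::runif(n) < divergence)
  for (t in sub_at) aa[t] <- sample(setdiff(.AA20, aa[t]), 1L)
  n_ind <- stats::rbinom(1L, n, indel_rate)
  for (u in seq_len(n_ind)) {
    pos <- sample.int(length(aa), 1L)
    if (stats::runif(1) < 0.5 && length(aa) > 10L) aa <- aa[-pos]
    else aa <- append(aa, sample(.AA20, 1L), after = pos)
  }
  paste(aa, collapse = "")
}

#' Generate one synthetic locus
#'
#' Draws a random protein, reverse-translates it with random synonymous
#' codons, splits the coding sequence into exons at random positions (intron
#' phases arise uniformly over 0/1/2), inserts introns, and derives the
#' query protein by mutating the encoded one at the specified rates.  Uses
#' the current RNG stream (seed the bundle, not each locus).
#'
#' @param spec a [locus_spec()].
#' @return list with `seq` (locus nucleotide string), `exons` and `introns`
#'   (locus coordinates; introns carry `phase`), `protein` (query),
#'   `protein_true` (encoded, pre-mutation), `cds`, and `pseudo` (interval of
#'   the implanted pseudogene copy or `NULL`).
#' @export
make_locus <- function(spec = locus_spec()) {
  stopifnot(inherits(spec, "locus_spec"))
  r_ex <- sample(seq(spec$exon_len[1], spec$exon_len[2]), spec$n_exons,
                 replace = TRUE)
  protein_true <- paste(sample(.AA20, sum(r_ex), replace = TRUE), collapse = "")
  cds <- .reverse_translate(protein_true)
  ncds <- nchar(cds)
  if (spec$frameshifts > 0L) {
    for (u in seq_len(spec$frameshifts)) {
      pos <- sample.int(nchar(cds) - 3L, 1L)
      cds <- paste0(substr(cds, 1L, pos), .random_nt(sample(1:2, 1L)),
                    substr(cds, pos + 1L, nchar(cds)))
    }
    ncds <- nchar(cds)
  }
  n_int <- spec$n_exons - 1L
  cuts <- integer(0)
  if (n_int > 0L) {
    base_cuts <- 3L * cumsum(r_ex)[seq_len(n_int)]
    base_cuts <- pmin(base_cuts, ncds - 3L)
    cuts <- base_cuts + sample(0:2, n_int, replace = TRUE)
    if (spec$frameshifts == 0L && ncds %% 3L != 0L) stop("internal: bad CDS")
  }
  ilens <- if (n_int > 0L)
    sample(seq(spec$intron_len[1], spec$intron_len[2]), n_int, replace = TRUE)
  else integer(0)
  canon <- stats::runif(n_int) < spec$canonical_frac

  pieces <- character(0)
  exons <- data.frame(start = integer(0), end = integer(0))
  introns <- data.frame(start = integer(0), end = integer(0), phase = integer(0))
  prev <- 0L; gpos <- 0L
  bounds <- c(cuts, ncds)
  for (t in seq_along(bounds)) {
    ex_nt <- substr(cds, prev + 1L, bounds[t])
    pieces <- c(pieces, ex_nt)
    exons <- rbind(exons, data.frame(start = gpos + 1L,
                                     end = gpos + nchar(ex_nt)))
    gpos <- gpos + nchar(ex_nt)
    if (t <= n_int) {
      intr <- .make_intron(ilens[t], canon[t])
      pieces <- c(pieces, intr)
      introns <- rbind(introns, data.frame(
        start = gpos + 1L, end = gpos + nchar(intr),
        phase = bounds[t] %% 3L))
      gpos <- gpos + nchar(intr)
    }
    prev <- bounds[t]
  }
  seq <- paste(pieces, collapse = "")
  pseudo <- NULL
  if (spec$pseudogene) {
    sp <- .random_nt(300L)
    pseudo <- data.frame(start = nchar(seq) + nchar(sp) + 1L,
                         end = nchar(seq) + nchar(sp) + ncds)
    seq <- paste0(seq, sp, cds)
  }
  protein <- .mutate_protein(protein_true, spec$divergence, spec$indel_rate)
  list(seq = seq, exons = exons, introns = introns, protein = protein,
       protein_true = protein_true, cds = cds, pseudo = pseudo)
}

#' Generate a full synthetic fixture bundle
#'
#' Concatenates `n_loci` loci with random intergenic spacers into one
#' chromosome, placing each locus on a random strand, and returns the genome,
#' the query proteins and the truth annotation (gene/mRNA/CDS with exact
#' intron coordinates and phases).  A single RNG stream drives the whole
#' bundle, so a fixed seed gives a byte-identical bundle.
#'
#' @param n_loci number of gene loci.
#' @param spec a [locus_spec()] applied to every locus.
#' @param spacer range of intergenic spacer lengths in nt.
#' @param seed RNG seed.
#' @param seqname chromosome name.
#' @return list with `genome` (named character), `proteins` (named character,
#'   one query per locus), `truth` (GFF-like data.frame with `phase`),
#'   `junctions` (truth intron set), and `loci` (per-locus detail).
#' @export
make_genome <- function(n_loci = 20L, spec = locus_spec(),
                        spacer = c(500L, 2000L), seed = 1L,
                        seqname = "chrS") {
  set.seed(seed)
  chrom <- character(0); pos <- 0L
  truth <- NULL; prot <- character(0); loci <- list()
  for (t in seq_len(n_loci)) {
    sp <- .random_nt(sample(seq(spacer[1], spacer[2]), 1L))
    chrom <- c(chrom, sp); pos <- pos + nchar(sp)
    loc <- make_locus(spec)
    strand <- sample(c("+", "-"), 1L)
    Ll <- nchar(loc$seq)
    ins <- if (strand == "+") loc$seq else .revcomp(loc$seq)
    flip <- function(d) {
      if (strand == "+") data.frame(start = pos + d$start, end = pos + d$end)
      else data.frame(start = pos + Ll - d$end + 1L, end = pos + Ll - d$start + 1L)
    }
    ex <- flip(loc$exons); ex <- ex[order(ex$start), , drop = FALSE]
    gid <- sprintf("gene%03d", t); mid <- sprintf("mRNA%03d", t)
    ph <- .gff_phases(ex, strand)
    truth <- rbind(truth,
      data.frame(seqid = seqname, type = "gene", start = min(ex$start),
                 end = max(ex$end), strand = strand, id = gid,
                 parent = NA_character_, phase = NA_integer_),
      data.frame(seqid = seqname, type = "mRNA", start = min(ex$start),
                 end = max(ex$end), strand = strand, id = mid, parent = gid,
                 phase = NA_integer_),
      data.frame(seqid = seqname, type = "CDS", start = ex$start, end = ex$end,
                 strand = strand, id = sprintf("%s.cds%d", mid, seq_len(nrow(ex))),
                 parent = mid, phase = ph))
    intr <- if (nrow(loc$introns)) {
      fi <- flip(loc$introns)
      data.frame(start = fi$start, end = fi$end,
                 phase = loc$introns$phase)[order(fi$start), , drop = FALSE]
    } else NULL
    loci[[t]] <- list(strand = strand, offset = pos, length = Ll,
                      exons = ex, introns = intr, spec_introns = loc$introns,
                      pseudo = if (!is.null(loc$pseudo)) flip(loc$pseudo) else NULL,
                      protein_true = loc$protein_true)
    prot[gid] <- loc$protein
    chrom <- c(chrom, ins); pos <- pos + Ll
  }
  sp <- .random_nt(sample(seq(spacer[1], spacer[2]), 1L))
  chrom <- c(chrom, sp)
  genome <- stats::setNames(paste(chrom, collapse = ""), seqname)
  if (is.null(truth))
    truth <- data.frame(seqid = character(0), type = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), id = character(0),
                        parent = character(0), phase = integer(0))
  junc <- NULL
  for (lc in loci) if (!is.null(lc$introns))
    junc <- rbind(junc, data.frame(seq = seqname, strand = lc$strand,
                                   start = lc$introns$start,
                                   end = lc$introns$end))
  if (is.null(junc))
    junc <- data.frame(seq = character(0), strand = character(0),
                       start = integer(0), end = integer(0))
  list(genome = genome, proteins = prot, truth = truth, junctions = junc,
       loci = loci)
}

#' Write a fixture bundle to FASTA / GFF3 files
#'
#' @param bundle a [make_genome()] result.
#' @param prefix output path prefix; writes `<prefix>.fa`,
#'   `<prefix>.prot.fa`, `<prefix>.truth.gff3`.
#' @return invisible character vector of the three paths.
#' @export
write_fixture_bundle <- function(bundle, prefix) {
  fa <- paste0(prefix, ".fa"); pfa <- paste0(prefix, ".prot.fa")
  gff <- paste0(prefix, ".truth.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$genome), fa)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bundle$proteins), pfa)
  tr <- bundle$truth
  lines <- "##gff-version 3"
  for (t in seq_len(nrow(tr))) {
    attrs <- if (is.na(tr$parent[t])) sprintf("ID=%s", tr$id[t])
             else sprintf("ID=%s;Parent=%s", tr$id[t], tr$parent[t])
    lines <- c(lines, paste(tr$seqid[t], "fixture", tr$type[t], tr$start[t],
                            tr$end[t], ".", tr$strand[t],
                            if (is.na(tr$phase[t])) "." else tr$phase[t],
                            attrs, sep = "\t"))
  }
  writeLines(lines, gff)
  invisible(c(fa, pfa, gff))
}
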