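jset <- function(starts, ends, seq = "chr", strand = "+") {
  data.frame(seq = rep_len(seq, length(starts)),
             strand = rep_len(strand, length(starts)),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

test_that("junction stats: identity, boundary shifts, and free regions", {
  anno <- jset(c(100, 500), c(200, 700))
  self <- junction_stats(anno, anno)
  expect_equal(self$pct_confirmed, 100)
  expect_equal(self$n_nonoverlap, 0L)
  # +1 nt shift: no longer confirmed, still overlapping
  shift <- junction_stats(jset(c(101, 501), c(201, 701)), anno)
  expect_equal(shift$n_confirmed, 0L)
  expect_equal(shift$n_nonoverlap, 0L)
  # predictions in an annotation-free region are all non-overlapping
  far <- junction_stats(jset(5000, 5100), anno)
  expect_equal(far$n_nonoverlap, 1L)
  # empty predictions report zeros
  none <- junction_stats(jset(integer(0), integer(0)), anno)
  expect_equal(none$pct_confirmed, 0)
  expect_equal(none$n_pred, 0L)
})

gff_cds <- function(starts, ends, tx = "t1", gene = "g1", seq = "chr") {
  rbind(
    data.frame(seqid = seq, type = "mRNA", start = min(starts), end = max(ends),
               strand = "+", id = tx, parent = gene, stringsAsFactors = FALSE),
    data.frame(seqid = seq, type = "CDS", start = starts, end = ends,
               strand = "+", id = paste0(tx, ".c", seq_along(starts)),
               parent = tx, stringsAsFactors = FALSE))
}

test_that("base SN/SP: identity, half coverage, intergenic predictions", {
  anno <- gff_cds(c(101, 401), c(200, 500))
  expect_equal(base_sn_sp(anno, anno), list(sn = 100, sp = 100))
  half <- gff_cds(c(101, 401), c(150, 450), tx = "p1", gene = "p1")
  bs <- base_sn_sp(half, anno)
  expect_equal(bs$sn, 50)
  expect_equal(bs$sp, 100)
  inter <- gff_cds(2000, 2500, tx = "p2", gene = "p2")
  expect_equal(base_sn_sp(inter, anno), list(sn = 0, sp = 0))
})

test_that("SN/SP are invariant to ordering and to splitting into abutting pieces", {
  anno <- gff_cds(c(101, 401), c(200, 500))
  whole <- gff_cds(c(101, 401), c(200, 500), tx = "p", gene = "p")
  split2 <- gff_cds(c(401, 101, 151), c(500, 150, 200), tx = "p", gene = "p")
  expect_equal(base_sn_sp(whole, anno), base_sn_sp(split2, anno))
})

test_that("the longest transcript per gene defines the reference base set", {
  anno <- rbind(gff_cds(c(101, 401), c(200, 500), tx = "t1", gene = "g1"),
                gff_cds(110, 130, tx = "t2", gene = "g1"))
  # only t1 (longer coding length) counts: covering t2 alone gives low SN
  pred <- gff_cds(110, 130, tx = "p", gene = "p")
  bs <- base_sn_sp(pred, anno)
  expect_equal(bs$sp, 100)
  expect_equal(bs$sn, 100 * 21 / 200)
})

test_that("single-exon truth yields no junctions and trivially perfect stats", {
  b <- make_genome(n_loci = 2, spec = locus_spec(n_exons = 1), seed = 301)
  tj <- junctions(b$truth)
  expect_equal(nrow(tj), 0L)
  st <- junction_stats(tj, tj)
  expect_equal(st$n_pred, 0L)
})
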