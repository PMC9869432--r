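test_that("a fixed seed gives a byte-identical bundle", {
  b1 <- make_genome(n_loci = 3, seed = 7)
  b2 <- make_genome(n_loci = 3, seed = 7)
  expect_identical(b1, b2)
})

test_that("translating the truth CDS reproduces the pre-mutation protein", {
  b <- make_genome(n_loci = 4, spec = locus_spec(divergence = 0.08,
                                                 indel_rate = 0.02), seed = 8)
  g <- Biostrings::DNAString(unname(b$genome))
  for (t in seq_along(b$loci)) {
    lc <- b$loci[[t]]
    pieces <- lapply(seq_len(nrow(lc$exons)), function(u)
      g[lc$exons$start[u]:lc$exons$end[u]])
    cds <- do.call(Biostrings::xscat, pieces)
    if (lc$strand == "-") cds <- Biostrings::reverseComplement(cds)
    aa <- as.character(Biostrings::translate(cds))
    expect_equal(aa, lc$protein_true)
  }
})

test_that("intron phases are near-uniform over 0/1/2 across seeds", {
  ph <- integer(0)
  for (s in 1:25) {
    b <- make_genome(n_loci = 2, spec = locus_spec(intron_len = c(60, 200)),
                     seed = 400 + s)
    for (lc in b$loci) ph <- c(ph, lc$spec_introns$phase)
  }
  tab <- table(factor(ph, levels = 0:2))
  expect_gte(length(ph), 90)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("strands are balanced and truth junctions live on both strands", {
  strands <- character(0)
  for (s in 1:10) {
    b <- make_genome(n_loci = 4, seed = 500 + s)
    strands <- c(strands, vapply(b$loci, `[[`, character(1), "strand"))
  }
  n <- length(strands); k <- sum(strands == "-")
  expect_gt(stats::binom.test(k, n)$p.value, 1e-4)
})

test_that("zero loci give a pure-spacer genome and empty truth", {
  b <- make_genome(n_loci = 0, seed = 9)
  expect_equal(nrow(b$truth), 0L)
  expect_equal(nrow(b$junctions), 0L)
  expect_gt(nchar(b$genome), 0L)
})

test_that("infeasible locus specs are rejected", {
  expect_error(locus_spec(n_exons = 0), "n_exons")
  expect_error(locus_spec(intron_len = c(5, 10)))
  expect_error(locus_spec(divergence = 1.5))
})

test_that("the bundle writer emits valid FASTA and GFF3 that re-read cleanly", {
  b <- make_genome(n_loci = 2, seed = 10)
  prefix <- tempfile()
  paths <- write_fixture_bundle(b, prefix)
  g <- read_genome(paths[1])
  expect_equal(unname(nchar(g)), unname(nchar(b$genome)))
  p <- read_proteins(paths[2])
  expect_equal(unname(p), unname(b$proteins))
  tj1 <- junctions(paths[3])          # via rtracklayer
  tj2 <- junctions(b$truth)
  key <- function(d) sort(paste(d$seq, d$strand, d$start, d$end))
  expect_equal(key(tj1), key(tj2))
})
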