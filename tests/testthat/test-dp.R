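test_that("affine alignment: diagonal, single extension, oracle equality", {
  sp <- scoring_params()
  set.seed(30)
  p <- random_protein(5)
  expect_equal(affine_align(p, p), diag_score(p))
  expect_equal(affine_align("A", "AA"), sp$matrix["A", "A"] - sp$q - sp$e)
  for (t in 1:12) {
    a <- random_protein(sample(2:6, 1)); b <- random_protein(sample(2:6, 1))
    pars <- scoring_params(q = sample(3:12, 1), e = sample(1:2, 1))
    expect_equal(affine_align(a, b, pars), oracle_affine(a, b, pars))
  }
})

test_that("protein-to-DNA alignment: exact coding is all-M at diagonal score", {
  set.seed(31)
  p <- random_protein(30)
  dna <- code_for(p)
  al <- protein_dna_align(dna, p)
  expect_equal(al$score, diag_score(p))
  expect_equal(cigar_string(al$cigar), "30M")
  expect_equal(c(al$gstart, al$gend), c(1L, 90L))
})

test_that("a single inserted base costs one frameshift and emits a G op", {
  set.seed(32)
  p <- random_protein(30)
  dna <- code_for(p)
  shifted <- paste0(substr(dna, 1, 45), "A", substr(dna, 46, 90))
  al <- protein_dna_align(shifted, p)
  expect_equal(al$score, diag_score(p) - scoring_params()$f)
  expect_equal(sum(al$cigar$op == "G"), 1L)
  expect_equal(al$cigar$len[al$cigar$op == "G"], 1L)
})

test_that("frameshift DP equals exhaustive enumeration without introns", {
  set.seed(33)
  for (t in 1:30) {
    n <- sample(6:18, 1); m <- sample(2:5, 1)
    dna <- random_dna(n); p <- random_protein(m)
    pars <- scoring_params(q = sample(3:10, 1), e = sample(1:2, 1),
                           f = sample(2:15, 1))
    got <- protein_dna_align(dna, p, pars)$score
    expect_equal(got, oracle_spliced(dna, p, pars, use_introns = FALSE))
  }
})

test_that("two exact exons over a canonical intron score sum - r - signals", {
  set.seed(34)
  p <- random_protein(60)
  cds <- code_for(p)
  half <- 3 * 30
  # GT/AG-free interior so the junction placement is unambiguous; long enough
  # that deleting the intron as codons cannot compete with splicing it
  intron <- paste0("GTA", strrep("C", 296), "CAG")
  dna <- paste0(substr(cds, 1, half), intron, substr(cds, half + 1, nchar(cds)))
  sp <- scoring_params()
  al <- spliced_align(dna, p)
  expect_equal(al$score, diag_score(p) - sp$r)          # d = a = 0
  expect_equal(al$cigar$op, c("M", "N", "M"))
  expect_equal(al$introns$start, half + 1L)
  expect_equal(al$introns$end, half + nchar(intron))
  expect_equal(al$introns$phase, 0L)

  # mutating the terminal signals to CT..AC costs exactly the table penalties
  bad <- paste0(substr(cds, 1, half), "CT", strrep("C", 297), "AC",
                substr(cds, half + 1, nchar(cds)))
  al2 <- spliced_align(bad, p)
  expect_equal(nrow(al2$introns), 1L)
  expect_equal(al$score - al2$score, (30 - 0) + (21 - 0))
})

test_that("spliced DP equals the parse-enumeration oracle on random instances", {
  set.seed(35)
  for (t in 1:40) {
    n <- sample(10:30, 1); m <- sample(2:6, 1)
    dna <- random_dna(n); p <- random_protein(m)
    pars <- scoring_params(q = sample(4:12, 1), e = sample(1:2, 1),
                           f = sample(3:20, 1), r = sample(3:25, 1))
    spl <- if (stats::runif(1) < 0.5) splice_model("simple", p = sample(0:20, 1))
           else splice_model("default")
    expect_equal(spliced_align(dna, p, pars, spl)$score,
                 oracle_spliced(dna, p, pars, spl))
  }
})

test_that("state reductions: no intron -> frameshift DP; no frameshift -> affine", {
  set.seed(36)
  for (t in 1:10) {
    dna <- random_dna(sample(12:24, 1)); p <- random_protein(sample(2:5, 1))
    # with a prohibitive intron cost the 6-state DP collapses to the 3+frameshift DP
    pars <- scoring_params(r = 5000)
    expect_equal(spliced_align(dna, p, pars)$score,
                 protein_dna_align(dna, p, pars)$score)
  }
  for (t in 1:10) {
    m <- sample(3:6, 1)
    p1 <- random_protein(m); p2 <- random_protein(m)
    dna <- code_for(p1)
    # prohibitive frameshift + whole-DNA consumption reduces to codon-level affine
    pars <- scoring_params(f = 5000, r = 5000)
    expect_equal(protein_dna_align(dna, p2, pars, free_genome_ends = FALSE)$score,
                 affine_align(p1, p2, pars))
  }
})

test_that("extended CIGAR spans match the aligned intervals for every traceback", {
  set.seed(37)
  for (t in 1:25) {
    n <- sample(20:60, 1); m <- sample(3:10, 1)
    dna <- random_dna(n); p <- random_protein(m)
    pars <- scoring_params(q = sample(4:12, 1), f = sample(3:20, 1),
                           r = sample(3:25, 1))
    al <- spliced_align(dna, p, pars)
    sp <- cigar_spans(al$cigar)
    expect_equal(sp$genome, al$gend - al$gstart + 1L)
    expect_equal(sp$protein, m)
    # exons partition the genome span around the introns
    expect_equal(sum(al$exons$end - al$exons$start + 1L) +
                 sum(al$introns$end - al$introns$start + 1L),
                 al$gend - al$gstart + 1L)
  }
})

test_that("raising the intron-open cost never adds introns", {
  set.seed(38)
  p <- random_protein(40)
  cds <- code_for(p)
  dna <- paste0(substr(cds, 1, 60), "GTAAG", random_dna(40), "CAG",
                substr(cds, 61, 90), "GTGAG", random_dna(60), "TAG",
                substr(cds, 91, nchar(cds)))
  counts <- vapply(c(1, 10, 25, 60, 200, 1000), function(r) {
    nrow(spliced_align(dna, p, scoring_params(r = r))$introns)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 2)
})
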