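test_that("ORF enumeration yields maximal stop-free stretches per frame", {
  seq <- paste0("ATG", strrep("GCT", 30), "TAA")
  orfs <- enumerate_orfs(seq, min_len = 30L)
  expect_equal(nrow(orfs[orfs$frame == 0, ]), 1L)
  o <- orfs[orfs$frame == 0, ]
  expect_equal(o$start, 1L)
  expect_equal(o$peptide, paste0("M", strrep("A", 30)))  # 31 residues
  # below the threshold nothing is reported for that frame
  orfs32 <- enumerate_orfs(seq, min_len = 32L)
  expect_equal(nrow(orfs32[orfs32$frame == 0, ]), 0L)
})

test_that("ORF length is floor(nt/3); 89 nt gives 29 residues, excluded at 30", {
  set.seed(10)
  repeat {  # 89 nt without a stop in frame 0
    s <- random_dna(89)
    aa <- translate_codon(substring(s, seq(1, 87, 3), seq(3, 89, 3)))
    if (!any(aa == "*")) break
  }
  orfs <- enumerate_orfs(s, min_len = 1L)
  expect_equal(nchar(orfs$peptide[orfs$frame == 0]), 29L)
  expect_equal(nrow(enumerate_orfs(s, min_len = 30L)[enumerate_orfs(s, min_len = 30L)$frame == 0, ]), 0L)
})

test_that("ORFs tolerate N codons (X) but stops delimit", {
  seq <- paste0(strrep("GCT", 20), "NNN", strrep("GCT", 20))
  orfs <- enumerate_orfs(seq, min_len = 41L)
  expect_equal(nrow(orfs[orfs$frame == 0, ]), 1L)
  expect_true(grepl("X", orfs$peptide[orfs$frame == 0]))
})

test_that("hashed-lowest-bit sampling retains about half of genome ORF k-mers", {
  set.seed(42)
  g <- random_dna(10000)
  kept <- total <- 0
  for (s in c(g, as.character(Biostrings::reverseComplement(Biostrings::DNAString(g))))) {
    orfs <- enumerate_orfs(s, 30L)
    for (p in orfs$peptide) {
      codes <- reduce_aa(strsplit(p, "")[[1]])
      if (length(codes) < 6) next
      vals <- drop(stats::embed(codes, 6) %*% 16^(0:5))
      h <- hash_kmer(vals, 6)
      kept <- kept + sum(h %% 2 == 0); total <- total + length(h)
    }
  }
  expect_gt(total, 500)
  expect_lt(abs(kept / total - 0.5), 0.02)
})

test_that("index stores first-codon-base bins and query retrieves them", {
  set.seed(3)
  pep <- random_protein(40)
  cds <- code_for(pep)
  flank1 <- random_dna(100); flank3 <- random_dna(400 - 100 - nchar(cds))
  # same CDS at 0-based offsets 100 and 400: bins 0 and 1 for its first k-mer
  g <- paste0(flank1, cds, flank3, cds, random_dna(200))
  idx <- build_index(c(chr = g), k = 6, bin = 256, min_orf = 10)
  # find a sampled k-mer of the peptide
  hit <- NULL
  for (j in 1:(nchar(pep) - 5)) {
    km <- substr(pep, j, j + 5)
    res <- query_index(idx, km)
    if (nrow(res)) { hit <- list(j = j, res = res) ; break }
  }
  expect_false(is.null(hit))
  fwd <- hit$res[hit$res[, "sid"] == 1L, , drop = FALSE]
  exp_bins <- c((100 + 3 * (hit$j - 1)) %/% 256, (400 + 3 * (hit$j - 1)) %/% 256)
  expect_true(all(exp_bins %in% fwd[, "bin"]))
})

test_that("identical records give identical key sets on distinct sequence ids", {
  set.seed(4)
  g <- random_dna(3000)
  idx <- build_index(c(a = g, b = g))
  keys <- ls(idx$table)
  for (key in keys) {
    hits <- get(key, envir = idx$table)
    s1 <- hits[hits[, "sid"] %in% c(1L, 2L), "bin"]
    s2 <- hits[hits[, "sid"] %in% c(3L, 4L), "bin"]
    expect_equal(sort(s1), sort(s2))
  }
})

test_that("query respects the sampling rule and missing keys", {
  set.seed(5)
  idx <- build_index(c(chr = random_dna(2000)))
  # a k-mer whose hash has lowest bit 1 is never indexed
  found_odd <- FALSE
  for (t in 1:50) {
    km <- random_protein(6)
    if (hash_kmer(encode_kmer(km), 6) %% 2 == 1) {
      expect_equal(nrow(query_index(idx, km)), 0L)
      found_odd <- TRUE
      break
    }
  }
  expect_true(found_odd)
  expect_error(build_index(character(0)), "no sequence")
  # an all-N record yields no index entries but no error either
  idxN <- build_index(c(n = strrep("N", 500)))
  expect_equal(idxN$n_keys, 0L)
})
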