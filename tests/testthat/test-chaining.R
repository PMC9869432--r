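test_that("binned gap size follows the three-branch rule", {
  expect_equal(binned_gap(1, 200), 3 * 200 - 256 * 2)   # 88, insertion branch
  expect_equal(binned_gap(5, 10), 30 - 256 * 4)         # -994, deletion branch
  expect_equal(binned_gap(2, 100), 0)                   # hidden by binning
  expect_error(binned_gap(-1, 5), "invalid")
  expect_error(binned_gap(1, 0), "invalid")
})

test_that("gap penalty: zero, infinite, and log-capped deletion branches", {
  expect_equal(gap_cost(0), 0)
  expect_equal(gap_cost(200000), Inf)
  expect_equal(gap_cost(-200000), Inf)
  expect_equal(gap_cost(30), 10 + 0.75 * log2(31))
  expect_equal(gap_cost(-30), min(10, 0.75 * log2(31)))
  # monotone in |g| on each branch
  gpos <- gap_cost(1:1000)
  gneg <- gap_cost(-(1:1000))
  expect_true(all(diff(gpos) >= 0))
  expect_true(all(diff(gneg) >= 0))
  # deletions are bounded by the log term
  expect_true(all(gneg <= 0.75 * log2(1:1000 + 1) + 1e-12))
})

test_that("chain scores: floor k, perfect extension, translation invariance", {
  one <- chain_anchors(data.frame(x = 10, y = 50), span = 6,
                       params = chain_params(min_score = 0))
  expect_equal(one[[1]]$score, 6)
  # two colinear anchors with zero gap: score 2k
  two <- chain_anchors(data.frame(x = c(0, 0), y = c(6, 12)), span = 6,
                       params = chain_params(min_score = 0))
  expect_equal(two[[1]]$score, 12)
  set.seed(20)
  a <- data.frame(x = sort(sample(0:50, 8)), y = sort(sample(1:200, 8)))
  s0 <- chain_anchors(a, 6, chain_params(min_score = 0))[[1]]$score
  a2 <- data.frame(x = a$x + 1000, y = a$y + 500)
  expect_equal(chain_anchors(a2, 6, chain_params(min_score = 0))[[1]]$score, s0)
})

test_that("chaining DP equals brute-force enumeration on small instances", {
  set.seed(21)
  for (t in 1:40) {
    n <- sample(2:9, 1)
    a <- data.frame(x = sort(sample(0:30, n, replace = TRUE)),
                    y = sample(1:120, n))
    pars <- chain_params(min_score = -Inf)
    got <- chain_anchors(a, 6, pars)[[1]]$score
    expect_equal(got, oracle_chain(a, 6, pars), tolerance = 1e-10)
  }
})

test_that("log gap penalty joins exons across a long intron", {
  # two exact 20-residue exons, 100 kb apart on the genome (base resolution)
  y <- c(6:20, 26:40)
  x <- c(3 * (6:20), 100000 + 3 * (26:40))
  pars <- chain_params(min_score = 0)
  chains <- chain_anchors(data.frame(x = x, y = y), span = 6, pars,
                          binned = FALSE)
  expect_equal(length(chains), 1L)             # one chain spans the intron
  expect_equal(nrow(chains[[1]]$anchors), 30L)
  # joined score beats the best single-exon chain
  solo <- chain_anchors(data.frame(x = 3 * (6:20), y = 6:20), span = 6, pars,
                        binned = FALSE)[[1]]$score
  expect_gt(chains[[1]]$score, solo)
})

test_that("base-resolution re-chaining recovers exact coding and introns", {
  set.seed(22)
  pep <- random_protein(60)
  cds <- code_for(pep)
  ch <- rechain_local(cds, pep, chain_params(min_score = 0))
  expect_false(is.null(ch))
  d <- ch$anchors
  expect_true(all(3 * diff(d$y) == diff(d$x)))   # all g' = 0
  # implant a 1 kb intron between two halves: junction gap about -1000
  half <- 3 * 30
  with_intron <- paste0(substr(cds, 1, half), "GT", random_dna(996), "AG",
                        substr(cds, half + 1, nchar(cds)))
  ch2 <- rechain_local(with_intron, pep, chain_params(min_score = 0))
  g <- 3 * diff(ch2$anchors$y) - diff(ch2$anchors$x)
  expect_equal(sum(g < -900), 1L)
  expect_true(all(g[g < -900] > -1100))
})

test_that("reported chain scores equal the recurrence over their anchors", {
  set.seed(23)
  pars <- chain_params(min_score = -Inf)
  for (t in 1:10) {
    pep <- random_protein(12)
    win <- paste0(random_dna(6), code_for(pep), random_dna(6))
    ch <- rechain_local(win, pep, pars)
    expect_false(is.null(ch))
    d <- ch$anchors
    g <- 3 * diff(d$y) - diff(d$x)
    recomputed <- 5 + sum(pmin(diff(d$y), 5) - gap_cost(g, pars$G, pars$beta))
    expect_equal(ch$score, recomputed, tolerance = 1e-9)
    # the chain score is at least the brute-force optimum over its anchors
    if (nrow(d) <= 9)
      expect_equal(ch$score, oracle_chain(d, 5, pars, binned = FALSE),
                   tolerance = 1e-9)
  }
})
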