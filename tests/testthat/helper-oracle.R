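# Independent oracles used by the test suite.
#
# oracle_spliced(): top-down enumeration (memoised on suffixes) of every
# parse of a DNA window against a protein into codon matches, 1-2 nt
# frameshift codons ('$'), 1-2 nt frameshift insertions ('+'), affine
# insertion/deletion runs, and Phase-0/1/2 introns with explicit spans and
# donor/acceptor costs.  It never uses the six intron states of the
# production DP; intron placement is enumerated directly, with intron
# length >= 1 nt and split codons unscored.  Protein is global, genome
# flanks free.

oracle_spliced <- function(dna, prot, params = scoring_params(),
                           splice = splice_model("default"),
                           use_introns = TRUE) {
  dna <- toupper(dna); prot <- toupper(prot)
  n <- nchar(dna); m <- nchar(prot)
  ch <- strsplit(dna, "", fixed = TRUE)[[1]]
  pa <- strsplit(prot, "", fixed = TRUE)[[1]]
  S <- params$matrix
  alph <- rownames(S)
  aa_at <- function(i) {       # residue of codon starting at i
    cod <- paste0(ch[i], ch[i + 1L], ch[i + 2L])
    a <- splicealigner::translate_codon(cod)
    if (!a %in% alph) a <- "X"
    a
  }
  pres <- ifelse(pa %in% alph, pa, "X")
  q <- params$q; e <- params$e; fp <- params$f; r <- params$r
  dc <- function(i) if (i >= 1 && i <= n) donor_cost(splice, dna, i - 1L) else Inf
  ac <- function(i) if (i >= 1 && i <= n) acceptor_cost(splice, dna, i) else Inf
  dcv <- vapply(seq_len(n), dc, numeric(1))
  acv <- vapply(seq_len(n), ac, numeric(1))

  memo <- array(NA_real_, dim = c(n + 2L, m + 1L))
  f <- function(i, j) {
    if (j == m + 1L) return(0)            # genome tail is free
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- -Inf
    # consume residue j
    if (i + 2L <= n)
      best <- max(best, S[aa_at(i), pres[j]] + f(i + 3L, j + 1L))
    if (i <= n)      best <- max(best, -fp + f(i + 1L, j + 1L))
    if (i + 1L <= n) best <- max(best, -fp + f(i + 2L, j + 1L))
    for (g in seq_len(m - j + 1L))        # insertion run
      best <- max(best, -(q + e * g) + f(i, j + g))
    # genome-only events
    if (i <= n)      best <- max(best, -fp + f(i + 1L, j))
    if (i + 1L <= n) best <- max(best, -fp + f(i + 2L, j))
    gmax <- (n - i + 1L) %/% 3L
    for (g in seq_len(gmax))              # deletion run (codons)
      best <- max(best, -(q + e * g) + f(i + 3L * g, j))
    if (use_introns) {
      if (i <= n && is.finite(dcv[i])) {  # Phase 0: intron i..x
        for (x in i:n) if (is.finite(acv[x]))
          best <- max(best, -(r + dcv[i] + acv[x]) + f(x + 1L, j))
      }
      if (i + 3L <= n && is.finite(dcv[min(i + 1L, n)])) {
        # Phase 1: codon base i | intron i+1..x | bases x+1,x+2; residue j unscored
        for (x in (i + 1L):(n - 2L)) if (is.finite(acv[x]))
          best <- max(best, -(r + dcv[i + 1L] + acv[x]) + f(x + 3L, j + 1L))
      }
      if (i + 3L <= n && i + 2L <= n && is.finite(dcv[min(i + 2L, n)])) {
        # Phase 2: bases i,i+1 | intron i+2..x | base x+1
        for (x in (i + 2L):(n - 1L)) if (is.finite(acv[x]))
          best <- max(best, -(r + dcv[i + 2L] + acv[x]) + f(x + 2L, j + 1L))
      }
    }
    memo[i, j] <<- best
    best
  }
  max(vapply(seq_len(n + 1L), function(i0) f(i0, 1L), numeric(1)))
}

# brute-force chaining: maximum over all strictly-increasing (in y,
# non-decreasing in x) anchor subsequences of span + sum(min(dy, span) -
# gap_cost(g)); gaps binned or base-resolution as in chain_anchors()
oracle_chain <- function(anchors, span, params = chain_params(),
                         binned = TRUE) {
  n <- nrow(anchors)
  ord <- order(anchors$x, anchors$y)
  x <- anchors$x[ord]; y <- anchors$y[ord]
  best <- -Inf
  rec <- function(last, score) {
    best <<- max(best, score)
    if (last >= n) return(invisible())
    for (j in (last + 1L):n) {
      if (x[j] < x[last] || y[j] <= y[last]) next
      g <- if (binned) binned_gap(x[j] - x[last], y[j] - y[last], params$bin)
           else 3 * (y[j] - y[last]) - (x[j] - x[last])
      sc <- score + min(y[j] - y[last], span) - gap_cost(g, params$G, params$beta)
      rec(j, sc)
    }
  }
  for (s in seq_len(n)) rec(s, span)
  best
}

# exhaustive protein-protein affine alignment by recursion (tiny inputs)
oracle_affine <- function(a, b, params = scoring_params()) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  S <- params$matrix; q <- params$q; e <- params$e
  n <- length(av); m <- length(bv)
  f <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) best <- max(best, S[av[i], bv[j]] + f(i + 1L, j + 1L))
    if (i <= n) for (g in seq_len(n - i + 1L))
      best <- max(best, -(q + e * g) + f(i + g, j))
    if (j <= m) for (g in seq_len(m - j + 1L))
      best <- max(best, -(q + e * g) + f(i, j + g))
    best
  }
  f(1L, 1L)
}
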