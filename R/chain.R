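# Two-round colinear anchor chaining.

#' Minimum possible gap between two binned anchors
#'
#' With anchor genome positions in bins of `bin` bp, the minimum gap in base
#' pairs implied by bin difference `dx` and residue difference `dy` is
#' `3*dy - bin*(dx-1)` when `3*dy < bin*(dx-1)` (a definitive deletion,
#' negative), `3*dy - bin*(dx+1)` when `3*dy > bin*(dx+1)` (a definitive
#' insertion to the genome, positive), and 0 otherwise (the binning hides any
#' gap).  Vectorised over `dx`/`dy`.
#'
#' @param dx genome bin difference (`x_j - x_i`, >= 0).
#' @param dy protein residue difference (`y_j - y_i`, > 0).
#' @param bin bin width in bp.
#' @return signed gap size in bp.
#' @export
binned_gap <- function(dx, dy, bin = 256L) {
  if (any(dx < 0) || any(dy <= 0)) stop("invalid anchor pair ordering")
  lo <- bin * (dx - 1); hi <- bin * (dx + 1); d3 <- 3 * dy
  ifelse(d3 < lo, d3 - lo, ifelse(d3 > hi, d3 - hi, 0))
}

#' Chaining gap penalty
#'
#' Zero for `g = 0`, infinite for `|g| >= G`; insertions to the genome
#' (`g > 0`) cost `g/3 + beta*log2(g+1)`; deletions (`g < 0`, introns seen
#' from the protein) cost `min(|g|/3, beta*log2(|g|+1))` so that the penalty
#' for spanning an intron grows only logarithmically, letting chains join
#' exons across introns.
#'
#' @param g signed gap in bp (vectorised).
#' @param G maximum intron length in bp.
#' @param beta weight of the logarithmic term.
#' @return non-negative penalty (possibly `Inf`).
#' @export
gap_cost <- function(g, G = 200000L, beta = 0.75) {
  a <- abs(g)
  out <- ifelse(g == 0, 0,
         ifelse(a >= G, Inf,
         ifelse(g > 0, g / 3 + beta * log2(g + 1),
                pmin(a / 3, beta * log2(a + 1)))))
  out
}

#' Chaining parameters
#'
#' @param G maximum intron length in bp (default 200 kb; 50 kb is a better
#'   fit for compact genomes).
#' @param beta log-gap weight (default 0.75).
#' @param bin bin width of round-1 anchors.
#' @param top_n chains carried into round-2 refinement.
#' @param max_dy maximum residue gap considered between chainable anchors.
#' @param min_score minimum chain score to report.
#' @param round2_k k-mer length for base-resolution re-chaining.
#' @return a list of class `chain_params`.
#' @export
chain_params <- function(G = 200000L, beta = 0.75, bin = 256L, top_n = 30L,
                         max_dy = 1000L, min_score = 15, round2_k = 5L) {
  stopifnot(G > 0, beta > 0, top_n >= 1L, max_dy >= 1L)
  structure(list(G = as.integer(G), beta = beta, bin = as.integer(bin),
                 top_n = as.integer(top_n), max_dy = as.integer(max_dy),
                 min_score = min_score, round2_k = as.integer(round2_k)),
            class = "chain_params")
}

#' Chain anchors by dynamic programming
#'
#' Computes `f(j) = max(max_i f(i) + alpha(i,j) - gamma(g(i,j)), span)` over
#' predecessors `i` with `x_i <= x_j`, `y_i < y_j`, where `alpha(i,j) =
#' min(y_j - y_i, span)` counts newly matched residues, and extracts disjoint
#' chains best-first (each anchor belongs to at most one chain).  With
#' `binned = TRUE` gaps come from [binned_gap()]; otherwise anchors are at
#' base resolution and `g = 3*dy - dx`.
#'
#' @param anchors data.frame with columns `x` (genome position, bins or bp)
#'   and `y` (protein residue position), one genome sequence at a time.
#' @param span matched residues per anchor (the seed length).
#' @param params a [chain_params()].
#' @param binned whether `x` is in bins.
#' @return list of chains, each `list(anchors=, score=)`, sorted by score.
#' @export
chain_anchors <- function(anchors, span, params = chain_params(), binned = TRUE) {
  n <- nrow(anchors)
  if (!n) return(list())
  ord <- order(anchors$x, anchors$y)
  x <- as.numeric(anchors$x[ord]); y <- as.numeric(anchors$y[ord])
  unit <- if (binned) params$bin else 1L
  reach <- params$G + 3 * params$max_dy + 2 * params$bin
  f <- rep(as.numeric(span), n)
  pred <- integer(n)
  best_g <- rep(Inf, n); best_dx <- rep(Inf, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    for (i in (j - 1L):1L) {
      dx <- x[j] - x[i]
      if (dx * unit > reach) break
      dy <- y[j] - y[i]
      if (dy <= 0 || dy > params$max_dy) next
      g <- if (binned) binned_gap(dx, dy, params$bin) else 3 * dy - dx
      cand <- f[i] + min(dy, span) - gap_cost(g, params$G, params$beta)
      if (cand > f[j] ||
          (cand == f[j] && pred[j] > 0L &&
           (abs(g) < best_g[j] || (abs(g) == best_g[j] && dx < best_dx[j])))) {
        f[j] <- cand; pred[j] <- i; best_g[j] <- abs(g); best_dx[j] <- dx
      }
    }
  }
  used <- logical(n)
  chains <- list()
  for (j in order(-f, x, y)) {
    if (used[j]) next
    path <- integer(0); t <- j; base <- 0
    while (t > 0L && !used[t]) { path <- c(path, t); used[t] <- TRUE; t <- pred[t] }
    if (t > 0L) base <- f[t]
    score <- f[j] - base
    if (score < params$min_score) next
    idx <- rev(path)
    chains[[length(chains) + 1L]] <-
      list(anchors = data.frame(x = x[idx], y = y[idx]), score = score)
  }
  chains[order(-vapply(chains, `[[`, numeric(1), "score"))]
}

# drop chains overlapping a better chain by >50% on the protein, keep top_n
.filter_chains <- function(chains, top_n) {
  kept <- list()
  for (ch in chains) {
    y1 <- min(ch$anchors$y); y2 <- max(ch$anchors$y)
    ok <- TRUE
    for (kc in kept) {
      ov <- min(y2, max(kc$anchors$y)) - max(y1, min(kc$anchors$y)) + 1L
      if (ov > 0.5 * (y2 - y1 + 1L)) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- ch
    if (length(kept) >= top_n) break
  }
  kept
}

#' Base-resolution re-chaining within a window
#'
#' Indexes all reduced-alphabet k-mers (default 5-mers) of the protein
#' without hashing or sampling, finds exact matches against all three frame
#' translations of the genome window (no ORF minimum), and chains them with
#' the base-resolution gap `g = 3*dy - dx` under the same penalty as round 1.
#' Anchor `x` is the window coordinate of the last base of the k-mer's last
#' codon; `y` is its last residue position.
#'
#' @param window nucleotide string (a genome subsequence).
#' @param protein query protein string.
#' @param params a [chain_params()].
#' @param prefer_range optional `c(start, end)` in window coordinates: when
#'   given, the best chain overlapping that range is preferred over a
#'   higher-scoring chain elsewhere in the window (used by the pipeline to
#'   keep each round-1 locus attached to its own refinement).
#' @return the best chain (`list(anchors=, score=)`) or `NULL` if no anchor.
#' @export
rechain_local <- function(window, protein, params = chain_params(),
                          prefer_range = NULL) {
  k <- params$round2_k
  pcodes <- .reduce_string(protein)
  pvals <- .rolling_kmers(pcodes, k)
  if (!length(pvals)) return(NULL)
  pok <- which(.windows_without_x(pcodes, k))
  if (!length(pok)) return(NULL)
  pmap <- split(pok + k - 1L, pvals[pok])   # code -> last residue positions
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  anch <- list()
  for (fr in 0:2) {
    aa <- .translate_frame(chars, fr)
    if (length(aa) < k) next
    gcodes <- unname(.REDUCTION[aa])
    gvals <- .rolling_kmers(gcodes, k)
    hit <- match(format(gvals, scientific = FALSE, trim = TRUE), names(pmap))
    hit[!.windows_without_x(gcodes, k)] <- NA
    idx <- which(!is.na(hit))
    if (!length(idx)) next
    rows <- lapply(idx, function(t) {
      ys <- pmap[[hit[t]]]
      data.frame(x = fr + 3L * (t + k - 1L), y = ys)
    })
    anch[[length(anch) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(anch)) return(NULL)
  anchors <- do.call(rbind, anch)
  chains <- chain_anchors(anchors, span = k, params = params, binned = FALSE)
  if (!length(chains)) return(NULL)
  if (!is.null(prefer_range)) {
    for (ch in chains) {
      if (max(ch$anchors$x) >= prefer_range[1] &&
          min(ch$anchors$x) <= prefer_range[2]) return(ch)
    }
  }
  chains[[1L]]
}
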