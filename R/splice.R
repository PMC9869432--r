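# Splice-signal cost models.
#
# Donor cost d(i) looks at the bases immediately after genome position i
# (the first intron bases when the intron starts at i+1); acceptor cost a(i)
# looks at the bases ending at position i (the last intron bases when the
# intron ends at i).  Costs are non-negative; canonical GT..AG signals cost 0.

#' Construct a splice-signal cost model
#'
#' Three named models are provided:
#' \describe{
#'   \item{`simple`}{GT/AG dinucleotide check: cost 0 for a canonical signal,
#'     `p` otherwise (default 30).}
#'   \item{`default`}{3-base tables: donors GTA/GTG cost 0, GTC/GTT 8, GC 15,
#'     AT 21, anything else 30; acceptors CAG/TAG cost 0, AAG/GAG 8, AC 21,
#'     anything else 30.  The weights follow the BLOSUM-style scaling of the
#'     observed signal frequencies (see [blosum_scaled_penalty()]).}
#'   \item{`human`}{a named hook for extended signals (last exon base G,
#'     poly-pyrimidine tract near the acceptor); currently identical to
#'     `default` because no weights for those signals are published here.}
#' }
#' Signal windows running off a sequence end cost the maximum (an intron
#' cannot extend past the contig).
#'
#' @param name one of `"simple"`, `"default"`, `"human"`.
#' @param p non-canonical penalty for the simple model.
#' @return an object of class `splice_model`.
#' @export
splice_model <- function(name = c("default", "simple", "human"), p = 30L) {
  name <- match.arg(name)
  stopifnot(p >= 0)
  structure(list(name = name, p = as.integer(p)), class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat("<splice_model>", x$name,
      if (x$name == "simple") sprintf("(non-canonical penalty p=%d)", x$p) else "", "\n")
  invisible(x)
}

#' Donor and acceptor splice-signal costs
#'
#' `donor_cost(model, seq, i)` scores a donor whose intron starts at position
#' `i + 1` (the signal window is the bases after `i`); `acceptor_cost(model,
#' seq, i)` scores an acceptor whose intron ends at position `i`.  Both are
#' vectorised over `i`; out-of-range windows cost the maximum.
#'
#' @param model a [splice_model()].
#' @param seq a nucleotide string (the strand being aligned).
#' @param i integer vector of genome positions (1-based).
#' @return integer vector of costs.
#' @export
donor_cost <- function(model, seq, i) {
  ch <- c(strsplit(toupper(seq), "", fixed = TRUE)[[1]], "?", "?", "?")
  n <- nchar(seq)
  b1 <- ch[pmin(pmax(i + 1L, 1L), n + 1L)]
  b2 <- ch[pmin(pmax(i + 2L, 1L), n + 2L)]
  b3 <- ch[pmin(pmax(i + 3L, 1L), n + 3L)]
  bad <- i + 2L > n | i < 0L
  if (model$name == "simple") {
    out <- ifelse(!bad & b1 == "G" & b2 == "T", 0L, model$p)
  } else {
    out <- rep.int(30L, length(i))
    gt <- !bad & b1 == "G" & b2 == "T"
    out[!bad & b1 == "G" & b2 == "C"] <- 15L
    out[!bad & b1 == "A" & b2 == "T"] <- 21L
    out[gt] <- 30L  # GT with a non-informative third base
    out[gt & i + 3L <= n & (b3 == "C" | b3 == "T")] <- 8L
    out[gt & i + 3L <= n & (b3 == "A" | b3 == "G")] <- 0L
  }
  as.integer(out)
}

#' @rdname donor_cost
#' @export
acceptor_cost <- function(model, seq, i) {
  ch <- c("?", "?", strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  n <- nchar(seq)
  at <- function(p) ch[pmin(pmax(p + 2L, 1L), n + 2L)]
  b1 <- at(i - 2L); b2 <- at(i - 1L); b3 <- at(i)
  bad <- i - 1L < 1L | i > n
  if (model$name == "simple") {
    out <- ifelse(!bad & b2 == "A" & b3 == "G", 0L, model$p)
  } else {
    out <- rep.int(30L, length(i))
    ag <- !bad & b2 == "A" & b3 == "G"
    out[!bad & b2 == "A" & b3 == "C"] <- 21L
    out[ag] <- 30L
    out[ag & i - 2L >= 1L & (b1 == "A" | b1 == "G")] <- 8L
    out[ag & i - 2L >= 1L & (b1 == "C" | b1 == "T")] <- 0L
  }
  as.integer(out)
}

#' BLOSUM-style scaled penalty from signal frequencies
#'
#' Converts the relative frequency of a major and a minor splice signal into
#' an integer cost: `round(2 * log2(freq_major / freq_minor))`.  For example
#' the observed 99.81% AG vs 0.10% AC acceptor frequencies give a penalty of
#' 20 for AC acceptors.
#'
#' @param freq_major,freq_minor frequencies (any common unit), both > 0.
#' @return integer penalty.
#' @examples
#' blosum_scaled_penalty(99.81, 0.10)
#' @export
blosum_scaled_penalty <- function(freq_major, freq_minor) {
  if (any(freq_major <= 0) || any(freq_minor <= 0))
    stop("frequencies must be positive")
  as.integer(round(2 * log2(freq_major / freq_minor)))
}

# per-position cost vectors over a window, in the indexing the DP uses:
# dvec[i] = cost of an intron *starting* at i = donor_cost(., i-1);
# avec[i] = cost of an intron *ending* at i  = acceptor_cost(., i).
.splice_cost_vectors <- function(model, seq) {
  n <- nchar(seq)
  i <- seq_len(n)
  list(dvec = donor_cost(model, seq, i - 1L),
       avec = acceptor_cost(model, seq, i))
}
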