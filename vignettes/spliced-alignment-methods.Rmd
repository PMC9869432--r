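---
title: "Methods: spliced protein-to-genome alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spliced protein-to-genome alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicealigner)
```

# Overview

`splicealigner` maps protein queries to a nucleotide genome through the
seed–chain–extend paradigm: a sampled k-mer index over six-frame ORF
translations, two rounds of colinear anchor chaining, and a six-state
dynamic program (DP) that aligns a protein against a genomic window while
jointly modelling affine gaps, frameshifts and Phase-0/1/2 introns with
explicit splice-signal costs. This vignette documents the model, its
parameters, the numerical choices made where the design was open, and what
the synthetic test substrate does and does not demonstrate.

# The alignment model

## States and transitions

For genome position $i$ (nucleotides) and protein position $j$ (residues)
the DP keeps six states: $H$ (best score), $I$ (residue insertion), $D$
(codon deletion) and $A/B/C$ (Phase-0/1/2 intron states):

$$
\begin{aligned}
I_{ij} &= \max\{H_{i,j-1}-q,\; I_{i,j-1}\} - e\\
D_{ij} &= \max\{H_{i-3,j}-q,\; D_{i-3,j}\} - e\\
A_{ij} &= \max\{H_{i-1,j}-r-d(i),\; A_{i-1,j}\}\\
B_{ij} &= \max\{H_{i-1,j-1}-r-d(i+1),\; B_{i-1,j}\}\\
C_{ij} &= \max\{H_{i-1,j-1}-r-d(i+2),\; C_{i-1,j}\}\\
H_{ij} &= \max\{H_{i-3,j-1}+s(i,j),\; I_{ij},\; D_{ij},\\
      &\qquad H_{i-1,j-1}-f,\; H_{i-2,j-1}-f,\; H_{i-1,j}-f,\; H_{i-2,j}-f,\\
      &\qquad A_{ij}-a(i),\; B_{i-3,j}-a(i-2),\; C_{i-3,j}-a(i-1)\}
\end{aligned}
$$

where $s(i,j)$ scores the translated codon ending at $i$ against residue
$j$, $d(\cdot)$/$a(\cdot)$ are donor/acceptor signal costs indexed by the
first/last intron base, the four $-f$ terms are frameshifts (1–2 nt codons
aligned to a residue, written `$` in alignments, and 1–2 nt genomic
insertions, written `+`), and $r$ opens an intron. A Phase-1 intron entered
at $i$ starts at $i+1$ and, when left at $i'$, ends at $i'-2$; the split
codon bridging it (one base upstream, two downstream) is consumed but not
scored, and likewise for Phase-2. Not scoring split codons is a known
weakness of this state machine: a substitution adjacent to a junction can
occasionally pull the junction to a nearby signal because hiding the
mismatched residue in the split codon is free.

Two deliberate normalisations of the recurrence as commonly typeset:

* the codon-match term reads $H_{i-3,j-1}+s(i,j)$ — a codon match consumes
  one residue, so the protein index must decrement;
* Phase-1/2 exits read the intron state three rows back
  ($B_{i-3,j}$, $C_{i-3,j}$), which enforces a minimum intron length of
  1 nt and guarantees every traceback has valid split-codon geometry.
  Without this the literal recurrence admits "introns" of non-positive
  length whenever $r$ is small relative to $f$.

Both choices are pinned by an independent oracle in the test suite: a
memoised top-down enumeration of every parse into codon matches,
frameshifts, gap runs and explicitly enumerated intron spans. The DP must
agree with it exactly on hundreds of random instances; the oracle, not the
recurrence's typesetting, is the correctness authority.

## Alignment mode and boundary conditions

The protein is aligned globally; genome flanks are free by default
(`free_genome_ends = TRUE`): $H_{i,0}=0$ for every $i$ and the score is
$\max_i H_{i,m}$. With `free_genome_ends = FALSE` the window must be
consumed entirely (leading/trailing genome is paid for through deletions
and frameshifts), which is the mode used to re-score concatenated exons.
Scores are integers throughout the DP; the $-\infty$ sentinel is $-2^{28}$,
far outside any reachable score, and candidate evaluation skips
sentinel-based paths so no overflow semantics arise. Traceback ties are
broken by a fixed candidate order — match, frameshifts, insertions,
deletions, then Phase-0/1/2 intron exits — so equal-scoring structures
resolve deterministically toward fewer/simpler events.

## Scoring defaults

| parameter | default | meaning |
|---|---|---|
| matrix | BLOSUM62 | `s(X,·) = 0`; `s(*,x) = −30`, `s(*,*) = 1` |
| `q`, `e` | 11, 1 | gap open/extend (gap of length $g$ costs $q+eg$) |
| `f` | 17 | per-event frameshift penalty |
| `r` | 29 | intron open |

BLOSUM62 with 11/1 gaps is the field's standard protein scoring; `f` and
`r` are set so that a single frameshift or intron is paid for by roughly
2–3 good residue matches — large enough not to hallucinate structure,
small enough that genuine introns (worth dozens of matches) always win.
The stop-codon override makes in-frame stops inside exons strongly
unfavourable while still allowing a terminal `*` to pair. All are
CLI-configurable (`-O/-E/-F/-J`).

## Splice-signal costs

The `default` model uses 3-base tables: donors GTA/GTG cost 0, GTC/GTT 8,
GC 15, AT 21, anything else 30; acceptors CAG/TAG 0, AAG/GAG 8, AC 21,
else 30. The weights come from frequency scaling,
$\mathrm{round}(2\log_2 f_{major}/f_{minor})$ — e.g. 99.81% AG vs 0.10% AC
acceptors gives ≈ 20 (`blosum_scaled_penalty()`). The `simple` model
charges 0 for GT..AG and a flat `p` (default 30) otherwise. Signal windows
that would run past a sequence end cost the maximum: an intron cannot
extend beyond the contig. Signals are evaluated on the strand being
aligned (each record and its reverse complement are independent
sequences). A `human` model name is reserved for extended signals (last
exon base G, poly-pyrimidine tract); it currently ships identical to
`default` because we have no published weights for those signals and
would rather expose the hook than invent numbers.

# Indexing and chaining

6-mers (4 bits/residue, 24-bit codes) from ORFs of ≥ 30 residues are
hashed with an invertible Wang-style mixer masked to the code width after
every step; a k-mer is indexed iff the hashed code's lowest bit is 0.
Because the mixer is a bijection, exactly half of all codes are retained;
over random k-mers the sampling rate is 50% up to binomial noise. K-mers
containing `X` are neither indexed nor used as seeds. Positions are stored
as 256-bp bins of the k-mer's first codon base, keeping entries in 32
bits. No open-reading-frame start codon is required — a stop-free stretch
in a fixed frame is enough, since internal exons rarely begin with
methionine. Stops delimit ORFs; `N` codons translate to `X` and do not.
Duplicate (key, sequence, bin) entries are stored once.

Round-1 chaining maximises $f(j) = \max(\max_i f(i) + \min(\Delta y, k) -
\gamma(g), k)$ with the binned minimum-gap estimate and the logarithmic
gap penalty (weight $\beta = 0.75$, max intron $G$, default 200 kb with
50 kb recommended for compact genomes). Predecessor search is capped at
$\Delta y \le 1000$ residues and a genome span of $G$ plus slack, making
chaining $O(nw)$; ties prefer the smaller implied gap, then the smaller
genome step. Chains are extracted best-first with used-anchor marking.
The "drop chains overlapping a better chain by > 50% on the protein" rule
is applied only among chains competing for the same genomic locus
(same strand-sequence, overlapping extents): a processed pseudogene copy
overlaps its parent 100% on the protein yet is a distinct locus and must
reach the DP stage for the pseudogene control to operate. Round 2
re-chains each kept chain's window with exact (unhashed, unsampled)
reduced-alphabet 5-mer matches at base resolution, $g' = 3\Delta y -
\Delta x$, preferring chains that overlap the round-1 locus so that two
neighbouring gene copies sharing one padded window stay separate.

# Pipeline geometry

Rather than closing each inter-anchor gap with a banded DP, the pipeline
runs one exact spliced DP over the whole refined-chain window. The C++
core makes this affordable at the problem sizes this package targets, and
an unbanded DP is exact — there is no band parameter to mis-set around an
unusually large intron. Windows are the chain extent padded by
$3\times(\text{unaligned residues})$ plus an intron allowance of
$\min(G, 5000)$ nt per side, enough for a terminal exon separated from
the chained region by an intron of the sizes the simulator produces
(60–2000 nt by default). Memory for the traceback is $O(nm)$ bytes per
state; the core refuses windows beyond $2.5\times10^8$ cells.

Internally all coordinates are 1-based inclusive — the R/Bioconductor
convention (IRanges, GFF3). PAF output converts to its native 0-based
half-open convention.

In the extended CIGAR, `M/I/D` are in residues, `F/G/N/U/V` in
nucleotides. `U`/`V` (Phase-1/2 introns) include their three split-codon
bases and consume one residue, keeping the CIGAR linear in genome order
while remaining exactly invertible: `read_paf()` reconstructs exon
intervals from the ops alone.

Every alignment is re-scored without introns (frameshift DP over the
concatenated exon sequence), and single-exon alignments are penalised by
`r` before ranking — the processed-pseudogene control. The penalty is
applied before primary/secondary selection, so a spliced gene outranks
its intron-less copy rather than shadowing it out of the output.

# The synthetic-locus generator

`make_genome()` emulates the *structure* spliced alignment must recover:
random proteins reverse-translated with uniform synonymous codons, split
into exons of 30–100 residues at uniformly random phases, with introns of
60–2000 nt, random intergenic spacers (500–2000 nt), and loci placed on
random strands of one chromosome; optional processed-pseudogene copies
and implanted 1–2 nt frameshifts. Query proteins diverge from the encoded
ones by per-residue substitutions (default 5%) and indels (default 1%).
One RNG stream drives a bundle, so a seed fixes it byte-for-byte.

Canonical introns carry the consensus signal context GTR..YAG — the
zero-cost classes of the default cost tables, matching the strong
consensus seen in real donors/acceptors. An earlier draft drew the bases
adjacent to GT..AG uniformly, which made half of all "canonical" introns
carry minority-variant signals (cost 8–16); chance zero-cost motifs
inside random intron interiors could then legitimately outscore the
implanted junction. That is faithful aligner behaviour on unrealistic
truth, so the generator, not the aligner, was corrected.

The generator does **not** model codon-usage bias, branch sites,
poly-pyrimidine tracts, repeats, paralogy or sequencing error. Passing
the end-to-end tests therefore shows that the implementation recovers
implanted structure under its own model assumptions — it does not certify
accuracy on real genomes, where splice-signal realism and repeat content
dominate difficulty.

# Test problem sizes

The suite was sized for quick, deterministic runs: oracle equivalence on
200 random ≤ 30 nt × ≤ 6 aa instances (the enumeration oracle is
exponential-ish in sequence length); chaining against brute force on 100
instances of ≤ 12 anchors; end-to-end recovery on 20-locus bundles
(~100–150 kb genomes); the pseudogene control across 20 seeds. At the
default conditions (5% divergence, 1% indels, canonical signals) the
pipeline recovers ≥ 95% of implanted junctions; residual misses are
junction slides where a chance consensus signal plus an unscored split
codon outscores the truth placement — the model's documented weakness,
not a search failure.

# Known limitations

* Split codons across Phase-1/2 introns are unscored; junctions can slide
  when a nearby signal ties or beats the true one.
* Very small introns (≲ 60 nt) with weak signals can be absorbed as codon
  deletions — the model prefers merging exons when the deletion is
  cheaper than `r` plus signal costs.
* The one-window DP is quadratic in window size; pathological
  chain-window combinations are refused rather than banded.
* One protein is aligned at a time; overlapping gene models from
  different queries are not merged or reconciled.
* The `human` extended-signal model is a named hook only.
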