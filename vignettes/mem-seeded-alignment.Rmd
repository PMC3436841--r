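---
title: "MEM-seeded long-read alignment: model, parameters and design"
author: "memalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEM-seeded long-read alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memalign)
```

# The problem and the approach

As sequencing reads grow to a few hundred bases, alignment must tolerate
several substitutions *and* gaps per read. `memalign` follows the
seed-and-extend strategy with **maximal exact matches (MEMs)** as seeds:
exact read–genome matches extendable in neither direction. Seeding finds the
candidate genomic neighborhoods cheaply; an affine-gap Smith–Waterman
alignment restricted to those neighborhoods produces the reported alignment.

The pipeline for a single-end read is:

1. estimate the minimal seed length $Q$ from the read length and an error
   model;
2. generate all MEM seeds of length $\ge Q$ on both strands with an FM-index;
3. convert each seed to a genomic window, merge overlapping windows, and
   score each window with Smith–Waterman;
4. rank windows by score, trace back the best one, and report it if it
   passes identity and coverage filters, with a mapping quality derived from
   the best and second-best window scores.

Paired-end alignment adds a seed-pairing stage under strand and insert-size
constraints and a mate-rescue stage.

# Index structures

The reference records are concatenated into one text $T$ over
$\{A,C,G,T\}$. A suffix array stores the lexicographic order of all
suffixes; the Burrows–Wheeler transform $B_T$ is the last column of the
sorted rotation matrix of $T\$$. Backward search over the FM-index
($C(\cdot)$ counts plus occurrence array $Occ(\cdot)$) finds the
suffix-array interval of a pattern $S$ in $O(|S|)$ steps, prepending one
character at a time; the interval width is the occurrence count.

Two reductions keep memory proportional to the genome, not to
$|T|\lceil\log_2|T|\rceil$:

* **Occurrence checkpoints.** $Occ(a, i)$ is stored only every $u$ positions
  (default $u = 128$); a query scans at most $u-1$ packed 2-bit symbols from
  the nearest checkpoint, making search $O(u\,|S|)$.
* **Sampled suffix array.** Only suffixes whose *text position* is a
  multiple of $v$ (default $v = 8$) retain their value. Locating walks
  last-to-first (LF) steps until a retained entry and adds the step count;
  text-position sampling bounds every walk by $v$ steps, which index-order
  sampling would not.

`predictIndexMemory()` evaluates the closed-form footprints; at human-genome
scale ($|T| = 3\times10^9$) the full suffix array alone is 12 GB and the
full index 60 GB, while the reduced structures total about 2.6 GB:

```{r memory}
round(sapply(c("full_sa", "full_index", "reduced_fm", "reduced_sa",
               "reduced_total"),
             function(v) predictIndexMemory(3e9, 128, 8, v) / 8 / 1e9), 2)
```

Only the forward strand is indexed; a read is queried as-is and as its
reverse complement. A second FM-index over the *reversed* text makes
left-to-right exact-match extension itself a backward search, so seeding
needs only unidirectional substring search. Positions that were `N` in the
input are stored as a placeholder with a mask; any seed or aligned match
overlapping a masked position is rejected, and `N` in a read matches
nothing.

# Seed-size estimation

Modeling per-base errors as independent with probability $p$ (default 2%),
the substitution count $w$ of a read of length $L$ is Binomial$(L, p)$. The
error budget is $e = \min\{z : P(w > z) < m\}$ with missing probability
$m = 0.04$ (exact binomial tail, strict inequality — the 100-bp case sits at
$P(w>4) = 0.0508$ vs $m = 0.04$, so any tail approximation can flip it). By
the pigeonhole principle over $e + 1$ non-overlapping $q$-grams, at least
one seed of length $\lfloor L/(e+1)\rfloor$ survives $e$ errors, so

$$Q = \mathrm{clamp}\left(\lfloor L/(e+1)\rfloor,\; Q_L = 13,\; Q_H = 49\right).$$

This yields $Q = 16$ for 100-bp and $Q = 22$ for 200-bp reads. Two caveats
are documented deliberately: $Q(L)$ is not globally monotone (it dips by up
to 3 wherever $e$ increments, e.g. between 63 and 64 bp), and the commonly
quoted value 35 for 500-bp reads is not derivable from this model (it gives
29); the model is implemented as stated rather than distorted to match.
Reads that produce no seed at $Q$ are retried once with
$Q_N = \lfloor(Q + Q_L)/2\rfloor$.

# MEM generation

The scan advances a start position $p$ through the read left to right and
finds the longest exact match (LEM) of the suffix at $p$. LEMs are
right-maximal by construction; a LEM is also left-maximal — hence a MEM —
when it is not contained in a previously recorded one, so a LEM is recorded
iff its end exceeds the last recorded end and its length is $\ge Q$. Up to
$h = 1024$ occurrences per MEM are kept (the smallest suffix-array indices,
a deterministic choice), guarding against repeat blow-ups.

# Region determination, extension and filtering

A seed at read offset $P$, genome position $G$, length $\ell$ pins the read
to the window
$[\,G - P - s,\; G + \ell + (L - P - \ell) + s\,)$, clamped to the seed's
record, where the slack
$s = \min(\lfloor (L - \text{minScore} - \text{gapOpen}) / \text{gapExtend}
\rfloor, 2L)$ is the largest total gap length any alignment scoring at least
`minScore` can contain under the scheme (match $+1$, mismatch $-3$, gap open
$-5$, gap extend $-2$ per base; a gap of length $g$ costs $5 + 2g$). Because
every penalty exceeds the match score, a positive-score local alignment can
never span more than $2L$ reference bases, which caps the slack and is
asserted at runtime. Overlapping same-strand windows are merged and each
merged window is aligned once.

Windows scoring below 30 are dropped; the rest are sorted by score with
positional tie-breaking for reproducibility. The best window's traceback is
reported when identity (matches / aligned columns) is $\ge 90\%$ and read
coverage (aligned read bases / read length) is $\ge 80\%$; unaligned read
ends are soft-clipped. The DP kernel contract is
implementation-agnostic: any kernel must reproduce the scalar
dynamic-programming scores exactly, and the tests hold it to a brute-force
oracle.

# Paired-end mapping and mapping quality

A pair is concordant when the mates align to opposite strands of the same
record in forward/reverse orientation with outer distance at most
$\bar{x} + k\sigma$ (insert mean $\bar{x}$, deviation $\sigma$, $k = 4$ —
covering > 99.99% of a normal insert distribution). If the independently
best alignments are already concordant they are kept (`distance_ok`).
Otherwise seed pairs are enumerated: opposite strands, same record, and
estimated ungapped outer distance (from $T_s = G - P$ per seed) within the
threshold plus a slack of both mates' indel slacks, since the ungapped
estimate can be off by at most the total gap length. Qualified pairs are
finalized in order of combined seed length (first qualified wins — a
deterministic choice where the alternative, best-scoring, costs one full DP
per candidate). Failing that, an aligned mate anchors a windowed rescue of
the other inside the genomic interval implied by the insert model; rescue
never overrides an existing concordant pairing.

Mapping quality follows the heuristic
$M_q = \lfloor 250\,(b_1 - b_2)/b_1 \cdot r \rfloor$ clamped to $[0, 250]$,
with $b_1, b_2$ the best and second-best region scores ($b_2 = 0$ when there
is no competitor) and $r$ the aligned-base fraction; $r$ counts read bases
consumed by M/I operations. Seed-paired and distance-concordant mates keep
their single-end $M_q$; a rescued mate gets
$\lfloor r \cdot M_{mq}\rfloor$ from its anchor's $M_q$. Flooring and the
250 clamp keep SAM validity and determinism.

# The synthetic-data generator and what it shows

`simulateGenome()` draws i.i.d. uniform bases — a deliberately
low-ambiguity stand-in for a real genome. `simulatePairs()` emulates
wgsim-style simulation: fragment starts uniform, fragment lengths
$N(\bar{x}, \sigma)$ rounded and clamped to $\ge 2L$, mate 1 from the left
fragment end forward, mate 2 the reverse complement of the right end. Each
base errs independently with the configured rate (default 2%); an error is
a substitution with probability 0.9, otherwise a one-base insertion or
deletion with equal probability (10% indels). Truth records the pre-error
origin. Both mates are corrupted anchored at their leftmost genome
coordinate (mate 2 in forward-strand space, then reverse-complemented): the
error process is orientation-blind, so this is statistically identical to
corrupting in read orientation, and it keeps the truth coordinate exact
under internal indels, as with haplotype-space indels in wgsim.

The defaults mirror the 200-bp study condition: 2,000 pairs of 200-bp reads
at 2% error, insert $N(1000, 50)$, on a 1-Mbp genome — sizes chosen so the
full benchmark runs in minutes on one CPU while leaving recall estimates
with a standard error well below the margins being tested. What passing
these tests does *not* show: behavior on repeat structure, compositional
bias, platform-specific error profiles (e.g. homopolymer errors) or
quality-value information, none of which the generator emulates. Random
genomes are a *lower-ambiguity* instance, which is why published
human-genome recalls serve as floors, not targets, for the synthetic
benchmark.

# Evaluation conventions

`evaluateAlignments()` counts a read correct when it maps to the true
record and strand within `maxDist` (default 5) of the truth. The reported
position is the *unclipped* leftmost coordinate (SAM POS minus the leading
soft clip): local alignment clips error-bearing read ends, shifting POS by
a few bases although the placement is correct, while truth refers to the
full-read origin. Recall divides correct reads by all reads; precision by
aligned reads passing the `minMapq` filter; zero aligned reads are reported
as precision 0 with a degeneracy flag.

A known limitation follows from the collapsed single-layer error model:
an indel among the first ~7 bases at a read's genome-left end is optimally
soft-clipped (k retained matches cannot pay the gap-open cost for k < 7),
which shifts even the unclipped position by the net indel length. At
default rates this affects roughly $7 \times 0.2\% \approx 1.4\%$ of reads,
so *exact*-position (maxDist = 0) precision plateaus near 0.985 regardless
of aligner quality; the 5-bp criterion is unaffected. A two-layer simulator
that tracks indels in reference coordinates would not have this ceiling.

# Numerical and degenerate-input choices

* Binomial tails via `pbinom(..., lower.tail = FALSE)` — exact, not a
  normal/Poisson approximation.
* Integer floors throughout ($Q_N$, mapping qualities, slack); clamps as
  stated above.
* Suffix arrays are built by prefix-doubling with counting sorts
  ($O(n\log n)$) — construction is a one-time cost at desk scale.
* DP tie-breaking: diagonal over gap moves, gap-open over gap-extend; the
  best cell is the first maximum in row-major order. Region ties break by
  position then strand. All outputs are deterministic for a fixed seed and
  worker count 1, and record *sets* are worker-count invariant.
* Empty intervals are represented as `lo > hi` and carry width 0; patterns
  or reads containing `N` never match; reads shorter than $Q$ yield no
  seeds; an empty rescue window yields no rescue.

# Parameter reference

| parameter | default | meaning |
|---|---|---|
| `errProb` | 0.02 | per-base error probability in the seed-size model |
| `missProb` | 0.04 | allowed chance of underestimating the error count |
| `qLow`, `qHigh` | 13, 49 | clamps on the minimal seed size |
| `maxOcc` | 1024 | occurrences kept per MEM |
| `u`, `v` | 128, 8 | occurrence / suffix-array sampling factors |
| match, mismatch, gap open, gap extend | 1, 3, 5, 2 | scoring scheme |
| `minScore` | 30 | minimal mapping-region score |
| `minIdentity`, `minCoverage` | 0.90, 0.80 | alignment acceptance filters |
| `insertMean`, `insertSd`, `insertK` | 1000, 50, 4 | insert-size model |

All of these are exposed in `alignerParams()` and on the command line
(`exec/memalign`), including `--min-seed-size` to bypass the estimate.
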