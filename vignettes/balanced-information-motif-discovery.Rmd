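---
title: "Balanced-information motif discovery with position-specific priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced-information motif discovery with position-specific priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priormotif)
```

## The problem

Transcription-factor binding sites are short (5–25 bp), degenerate DNA
elements hidden in sets of co-regulated sequences. Purely combinatorial
motif finders enumerate over-represented words but struggle with weak,
degenerate motifs; probabilistic finders (EM, Gibbs samplers) have long
benefited from *position-specific priors* (PSPs) — per-sequence,
per-position probabilities that a motif starts there, computed from
external evidence such as orthologous conservation, DNA duplex stability,
nucleosome occupancy, or ChIP-seq coverage. `priormotif` brings PSPs to the
combinatorial setting: an exhaustive enumerator proposes candidate
consensus words, and a greedy search refines them over the 15-letter IUPAC
alphabet, guided by an objective that fuses over-representation with any
number of priors.

## The Balanced Information Score

A width-$k$ IUPAC motif $m$ induces a $4 \times k$ column-stochastic PSSM:
the bases in each symbol's set share probability $1-\delta$ uniformly and
the remaining bases share $\delta$ (a four-base set is uniform $1/4$
regardless). Writing $P_m(w)$ for the probability of a DNA word $w$ under
that matrix, each sequence $f_i$ is annotated at the start $j_i$ maximising
the balanced per-sequence term, and the objective sums those maxima:

$$\mathrm{BIS}(m, f, S) \;=\; \sum_{i=1}^{N} \max_{j}\Big[\,
\lambda \log P_m\!\big(f_i[j \,..\, j+k-1]\big) \;+\;
(1-\lambda) \sum_{p=1}^{\ell} \alpha_p \log S_p[i, j] \,\Big]$$

with $\lambda \in (0, 1]$ balancing sequence against prior information and
convex weights $\alpha_p \ge 0$, $\sum_p \alpha_p = 1$ merging the $\ell$
priors. Both logs are of probabilities, so the score is non-positive; it
reaches $0$ exactly when an unsmoothed motif occurs with probability one at
every annotated position and no priors are present. The negated score is
the joint self-information of observing the motif, and the priors, at the
annotated positions — maximising BIS minimises that surprise. There are no
latent variables and no background model; over-representation enters only
through the annotated occurrence probabilities.

Two modelling points deserve emphasis:

* **One occurrence per sequence.** Every sequence contributes exactly one
  annotated start (the OOPS regime). Detecting the fraction of sequences
  that contain a site at all (a quorum on the score) is out of scope.
* **Annotation uses the prior-aware term.** The $\arg\max$ includes the
  prior part, not just $P_m$; this is the form consistent with the
  maximised objective, and it is what makes an informative prior able to
  pull annotations onto the evidenced positions.

A useful consequence: a *uniform* prior adds the same constant to every
candidate position of a sequence, so the annotated starts are unchanged
and scores transform affinely,
$\mathrm{BIS}_{\mathrm{unif}}(m) = \lambda\,\mathrm{BIS}_{\mathrm{free}}(m) + c$
with $c$ motif-independent. Ordering among motifs — hence the entire greedy
trajectory and the reported motif — is invariant. The test suite asserts
this mechanically; it is also why a ChIP-seq coverage prior on short
(±100 bp) peak fragments adds little: its information largely duplicates
the over-representation already in the score.

## Search

**Seeding.** A depth-first extension over `A,C,G,T` enumerates width-$k$
words whose *support* (number of sequences with a window within Hamming
distance $e$) meets a quorum. A prefix is pruned when its prefix-distance
support falls below the quorum — an admissible relaxation of the full-word
distance, so no qualifying word is missed; supports of the survivors are
exact. Survivors are ranked by a binomial z-score of support against an
i.i.d. uniform-base null (windows treated as independent; exact for
single-window sequences, an approximation otherwise — it only orders
seeds). If fewer than `z_min` words survive, the quorum relaxes by
$\lceil 0.05N \rceil$ until enough do (floor 1); the list truncates at
`z_max`. Seeds are plain DNA words; degeneracy enters only during
refinement. A seeds file can bypass enumeration, so any external consensus
finder can supply starting points.

**Greedy refinement.** Starting from each of the top `z` seeds, positions
are visited cyclically; at each position all 15 IUPAC symbols are tried in
the fixed canonical order `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N` (the order is a
determinism choice — nothing in the procedure prescribes one), and a
substitution is accepted only when it *strictly* increases the score, the
inner loop then continuing against the improved motif. The search stops
after $k$ consecutive positions without an accepted move, which certifies
the output locally optimal under single-position substitutions. Termination
is guaranteed: the score strictly increases along accepted moves and the
motif space is finite, so no motif repeats. The best refined motif wins
(first found on ties, against a running best initialised with an
empty-motif sentinel of score $-\infty$ that is never user-visible).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | motif width (bp); PSPs are usually computed for 8-mers |
| `lambda` | 0.5 with priors, 1 without | weight of sequence vs prior information; without priors it plays no role |
| `weights` | uniform $1/\ell$ | convex prior weights (raw weights are normalised) |
| `delta` | 0.1 | off-consensus PSSM mass; keeps every log finite (0 = exact-match semantics) |
| `e` | 2 | Hamming radius for seed occurrences — the classic $(8,2)$ planted-motif regime |
| `quorum` | $\lceil 0.8N \rceil$ | sequences that must contain a seed occurrence |
| `z` / `z_min` / `z_max` | 10 / 10 / 50 | seeds refined / enumeration bounds |
| `max_degenerate` | unlimited (2 in the ChIP-seq preset) | cap on degenerate positions; large ChIP-seq sets otherwise drift to highly degenerate consensi |
| `prob_floor` | 1e-10 | floor for PSP entries so $\log S_p$ stays finite |

The uniform defaults for `lambda` and the `weights` follow the principle
that absent knowledge about prior quality the constants should be uniform;
both are tunable when some prior source is known to be more reliable.

## Priors

PSP files are FASTA-like: a `#k=8` width declaration, then per sequence a
`>` header and exactly $n_i - k + 1$ probabilities in 0-based start order.
Row lengths, ids and the declared width are validated against the sequence
set, so a file built for another width or sequence-set fails loudly.
Entries are floored at `prob_floor` but rows are *not* renormalised after
flooring — the files' semantics are preserved with minimal perturbation.

The ChIP-seq binding-peak prior sets row mass proportional to a Student-t
density with 3 degrees of freedom of the distance between a window's
*centre* ($j + \lfloor k/2 \rfloor$; centred distance is symmetric for even
and odd $k$, and peak evidence concerns where the motif sits, not where its
first base falls) and the peak summit, discretised into 25 bp steps: all
windows in a step share the t density at the step's midpoint distance, and
the row is normalised. Whether the original construction measured distance
from the window start or centre is not documented; centre was chosen and
is flagged here.

## The synthetic generator and what it does (not) show

`synth_spec()` defaults encode the study conditions the package is
calibrated against: $N = 200$ sequences of $n = 500$ bp (the yeast
ChIP-chip scale), one planted occurrence per sequence of a width-8
consensus (`TGACTCAT`, a bZIP-family site) carrying exactly 2 random
substitutions, uniform background, and priors that put a fraction
`prior_concentration` (default 0.5) of each row's mass on the planted
start, optionally jittered (`prior_noise_sd`, bp). Recovery is scored by
the scaled Euclidean PSSM distance — per-column distance between the
probability vectors, averaged and divided by $\sqrt{2}$ so identical
matrices score 0 and disjoint point-mass matrices 1, sliding the shorter
matrix over the longer for unequal widths — against the unsmoothed planted
consensus PSSM, with success threshold 0.25. The exact distance used by the
published yeast benchmark is defined in material not available here; this
scaling is the package's own documented choice, as is the threshold
(configurable).

The generator emulates signal strength, positional priors of controllable
informativeness, and masked-base handling. It does **not** emulate the
correlated structure of real priors (conservation tracks, energy profiles,
nucleosome maps), compositional bias beyond a global GC knob, multiple or
zero occurrences per sequence, or motif width mismatch between truth and
search. Passing recovery benchmarks therefore demonstrates that the
machinery finds planted signal under the stated noise — not performance on
any particular biological dataset.

Two behaviours of the benchmark are worth understanding rather than
designing away. First, without an anchoring prior the refinement drifts
into degenerate symbols at this scale: a 500 bp background sequence
typically contains windows within Hamming distance 2 of any 8-mer, so
widening a symbol's base set re-annotates sequences onto background
near-matches and raises the score. The reported motif is then the planted
consensus with several positions degenerated — informative at a glance but
past the 0.25 distance threshold. This is inherent to the
no-background-model objective (it is why the ChIP-seq preset caps
degeneracy at 2), and it is precisely what an informative prior prevents:
pinned annotations cannot migrate to background windows. Second, a
point-mass prior is informative only in proportion to the fraction of rows
whose peak is *exactly* right — a peak even a few bp off names a window
that does not contain the motif, and how far off barely matters. The
benchmark's "informative-but-noisy" arms therefore jitter the peak with a
1 bp standard deviation, leaving roughly 40% of rows exactly anchored;
that places single-noisy-prior recovery mid-range, so the benefit of
combining two independently erring priors (each wrong peak carries only
half the convex weight, and the sequence term wins the annotation contest
more often) is visible rather than saturated or vacuous.

Benchmark problem sizes used by the packaged checks: recovery runs use the
full $200 \times 500$ bp defaults with 20 replicates per arm; the
score/annotation/greedy property checks use thousands of miniature fuzzed
instances ($N \le 5$, $n_i \le 30$, $k \le 4$) where exhaustive oracles
(full window scans, all $4^k$ words, all $15k$ substitutions) are
affordable.

## Numerical choices

* **Smoothing.** The exact IUPAC-to-PSSM translation rule of the original
  formulation is not publicly documented; the $(1-\delta)/|set|$,
  $\delta/(4-|set|)$ rule with $\delta = 0.1$ is this package's choice. It
  avoids $-\infty$ scores when a motif lacks an exact-compatible occurrence
  in some sequence; $\delta = 0$ is supported and gives exact-match
  semantics (with $-\infty$ handled throughout).
* **Tie-breaks.** Annotation ties resolve to the smallest start, then the
  forward strand; seed ranking ties resolve by support, then
  lexicographically; the first-found refined motif wins score ties. All
  output is deterministic given inputs and configuration.
* **Strict-improvement margin.** Greedy acceptance requires an improvement
  of at least $10^{-9} + 10^{-12}|\mathrm{BIS}|$. Scores that are exact
  ties in real arithmetic (symmetric IUPAC columns produce many, and a
  uniform prior rescales the whole objective affinely) would otherwise be
  accepted or rejected on last-ulp rounding noise, breaking determinism
  and the uniform-prior invariance. Genuine improvements are orders of
  magnitude larger. Window scores accumulate in extended precision so
  equal-word windows tie exactly.
* **Masked bases.** Any window overlapping `N` is excluded from
  annotation and seeding (repeat-masked input is the norm for ChIP-seq
  fragments); a sequence with no admissible window is a named error.
* **Strands.** Forward-only by default; with `both_strands` each window is
  scored in both orientations (prior value at the forward start) and the
  better one annotated, ties to `+`.

## Limitations

* One motif of one fixed width per run; no ZOOPS/quorum variant (left as
  future work in the underlying method), no multi-motif output.
* The seed-ranking null ignores window overlap and background composition;
  it is a ranking device, not a calibrated p-value.
* Priors are consumed, never produced: translating the combined score back
  into a single PSP for EM/Gibbs tools is an open problem.
* The greedy search certifies only single-substitution local optimality;
  quality hinges on the enumerator's seeds, as intended by the
  seed-then-refine design.
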