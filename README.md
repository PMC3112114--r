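# priormotif

Combinatorial discovery of transcription-factor binding-site motifs guided
by position-specific priors.

Motif finders that rely on sequence over-representation alone face the
"futility theorem": most predicted binding sites have no function in vivo.
Probabilistic finders (MEME's EM, PRIORITY-style Gibbs samplers) mitigate
this with *position-specific priors* (PSPs) — per-sequence, per-position
probabilities that a motif starts there, derived from orthologous
conservation, DNA duplex stability, nucleosome occupancy, or ChIP-seq
coverage. `priormotif` brings that prior information to the combinatorial
setting, for anyone analysing ChIP-chip / ChIP-seq sequence-sets who wants
a fast, deterministic, consensus-based finder that can consume — and
combine — any number of PSPs.

## Method

An exhaustive extension-based enumerator proposes over-represented width-k
DNA words (occurrences counted within a Hamming distance *e*, subject to a
quorum, ranked by a binomial over-representation z-score). The top *z*
seeds are then greedily refined over the 15-letter IUPAC alphabet — one
position substituted at a time, cyclically, accepting only strict
improvements, stopping after *k* consecutive unimprovable positions — to
maximise the **Balanced Information Score**

    BIS(m, f, S) = Σᵢ maxⱼ [ λ·log P_m(fᵢ[j..j+k−1]) + (1−λ)·Σₚ αₚ·log Sₚ[i,j] ]

where `P_m` is the probability of a window under the 4×k PSSM induced from
the IUPAC motif `m`, `Sₚ[i,j]` are the `ℓ` priors (merged by convex weights
`αₚ`), and `λ ∈ (0,1]` balances over-representation against prior
information. The score is the negated joint self-information of observing
the motif and the priors at the annotated positions: always ≤ 0, equal to
0 exactly for an unsmoothed motif occurring with probability 1 everywhere.
There are no latent variables and no background model. The refined motif
with the highest score is reported, with per-sequence annotations.

Also included: PSP file I/O and validation, a ChIP-seq peak-summit prior
builder (discretised t₃ step function, 25 bp steps), a planted-motif
synthetic-data generator with priors of controllable informativeness, a
recovery-benchmark harness, broom-style `tidy()`/`glance()` and ggplot2
`autoplot()` methods, and a command-line front end
(`inst/cli/priormotif`).

## Worked example

Generate a synthetic ChIP-chip-like dataset — 50 sequences of 200 bp, each
carrying the consensus `TGACTCAT` with 2 substitutions, plus a PSP putting
half of each row's mass on the planted start — and run discovery:

```r
library(priormotif)

d <- synth_dataset(synth_spec(N = 50, n = 200, mutations = 2, seed = 42))
fit <- discover_motif(d$seqs, priors = d$priors)
fit
#> Motif discovery fit
#>   motif: TGACTCAT  (0 degenerate position(s))
#>   balanced information score: -202.4015
#>   sequences: 50, k = 8, lambda = 0.5, priors = 1
#>   seeds refined: 10
```

The reported IUPAC motif is the planted consensus. The score, −202.4, is
the summed per-sequence balanced self-information at the annotated
positions (closer to 0 = the motif and the priors are less "surprised" by
the annotated sites). `tidy()` gives one row per sequence:

```r
head(tidy(fit), 4)
#>   id    start strand word     contribution
#> 1 seq_1    60 +      TTACTCAA        -4.06
#> 2 seq_2   122 +      TGATCCAT        -4.06
#> 3 seq_3     9 +      TGCCTCAG        -4.06
#> 4 seq_4    81 +      TGATTCCT        -4.06
```

Each `start` is the 0-based annotated position (here, every one the
planted start); `word` is the matched window — the planted occurrence with
its 2 mutations. The seed table shows the enumerator at work: the true
consensus is found in all 50 sequences (support 50, z = 6.3) and ranks
first; all top seeds refine to the same motif:

```r
head(fit$seeds, 3)
#>   word     support significance refined  refined_bis
#> 1 TGACTCAT      50         6.29 TGACTCAT       -202.
#> 2 TTGCTCAT      44         4.58 TGACTCAT       -202.
#> 3 CTCATCCA      43         4.29 TGACTCAT       -202.

pssm_distance(iupac_to_pssm(fit$motif, 0.1), d$consensus_pssm)
#> [1] 0.08164966
```

The scaled Euclidean PSSM distance to the planted truth (0 = identical,
1 = maximally distinct) is 0.082 — well under the 0.25 success threshold
used by the recovery benchmark; the residual reflects only the smoothing
mass δ = 0.1. See the vignette
(`vignettes/balanced-information-motif-discovery.Rmd`) for the model,
parameter meanings, and design choices.

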