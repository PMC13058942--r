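---
title: "Bootstrap phylogenetic footprinting with motifboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap phylogenetic footprinting with motifboot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifboot)
```

## The problem and the method

Transcription factor binding sites (TFBSs) in bacterial promoters evolve
more slowly than the non-functional sequence around them. Phylogenetic
footprinting exploits this: given the promoter of a target gene and the
promoters of its orthologs in related species, de novo motif discovery on
the set highlights unusually conserved segments as TFBS candidates. Two
practical observations shape the design implemented here. First, very close
relatives are uninformative (too few background mutations) and very distant
ones are unalignable, so promoters are pre-selected by evolutionary
distance. Second, a single discovery run is unstable — its outcome depends
on exactly which orthologs were selected — so the selection step is run many
times and the results are aggregated statistically.

`motifboot` implements this bootstrap scheme end to end:

1. **Distances.** Pairwise evolutionary distances between all promoters,
   either patristic distances on a user-supplied guide tree (preferred) or,
   as a fallback, Jukes–Cantor-corrected mismatch fractions
   $d = -\tfrac34 \ln(1 - \tfrac43 p)$ from pairwise global alignments with
   fixed scores (match $+1$, mismatch $-1$, gap $-2$). When both a tree and
   sequences are available the tree wins.
2. **Stratification.** Orthologs are binned by distance to the target into
   three subgroups: $[0.05, 0.31)$, $[0.31, 0.55)$, $[0.55, 0.73]$.
   The bounds are half-open (closed at the far top) to resolve the
   overlapping endpoints deterministically; promoters below 0.05 or above
   0.73 are excluded and reported.
3. **Subset plan.** With subgroup sizes $(s_1, s_2, s_3)$ and quota
   $(3, 3, 6)$, the maximum number of complete subsets is
   $M = \min_k \lfloor s_k / q_k \rfloor$ and $N = rM$ subsets of 12
   promoters (plus the appended target) are drawn, $r = 2$ by default.
   Sampling proceeds in $r$ epochs; within an epoch each subgroup is
   shuffled and consumed without replacement, so a promoter appears at most
   once per epoch and promoters recur across epochs — this realizes
   "bootstrap with replacement" while guaranteeing maximal (but not
   exhaustive) use of the pool deterministically rather than in
   expectation. A diversity rule skips candidates closer than
   `min_intra_distance` (default 0.02, configurable; no published value
   exists) to any current member, retrying up to a budget and then waiving
   with a warning so the quota is never silently violated.
4. **Discovery.** Each subset is searched by pluggable finders sharing one
   contract; two built-ins ship. A one-occurrence-per-sequence Gibbs site
   sampler (pseudocount 0.5, both strands, best-information-content
   configuration over restarts) and a word-enumeration finder (all W-mers
   on both strands, support = sequences with an occurrence within a Hamming
   tolerance, ranked by support, then occurrences, then lexicographic
   order). Widths $W \in \{8, 10, 12, 14, 16\}$ are scanned per finder.
   Per width, finder results are combined by voting: instances overlapping
   on the same promoter and strand by at least half the shorter width form
   site clusters, clusters are linked into motif-level components through
   their source motifs, and components supported by at least `quorum`
   (default 2, auto-lowered to 1 for a single finder) distinct finders are
   rebuilt into merged motifs. A purely site-level grouping was rejected:
   it would confine each merged motif to a single promoter, and the
   downstream footprinting filter (which demands simultaneous detection on
   the target and on many orthologs) could then never fire.
5. **Aggregation.** A run's motif is projected onto the target only when it
   has a target instance *and* instances on at least `min_ortholog_support`
   (default 6, half the subset) distinct orthologs. Each run then votes 0/1
   per target position, so the histogram reads as "fraction of runs
   supporting a motif here" — per-instance counting would inflate
   wide-motif regions. Peaks are maximal runs of positions with support
   $\ge \lceil 0.25\,N \rceil$, merged across gaps $< 5$ bp, discarded
   below 6 bp width, numbered left to right.
6. **Comparison.** Discovered motifs are matched against a known-TFBS
   database (MEME minimal format) Tomtom-style: column similarity is the
   Pearson correlation of the two probability 4-vectors, an alignment score
   is the mean column similarity over an ungapped overlap of at least 5
   columns, all offsets and both orientations are scanned, and the p-value
   is empirical — the fraction of $K = 1000$ column-shuffled versions of
   the database motif whose best alignment scores at least as well, with a
   $+1/(K+1)$ correction. $E = p \times$ database size. Per peak and TF,
   one E-value per run (the best) enters the statistics: median, quartiles,
   fraction below $\alpha = 0.05$, and the top-candidate frequency — the
   fraction of runs in which that TF had the smallest E-value for the peak.
7. **Consolidation.** For each peak, the conserved segments of every
   promoter in which a similar motif was ever detected are stacked at peak
   width, re-anchored through the motif's target instance,
   reverse-complemented when detected on the opposite strand, N-padded (and
   flagged) at promoter edges, and rescored against the database as a
   single PWM. A presence map records, per taxon, whether a peak-aligned
   motif was ever detected there, distinguishing "absent" from "never
   sampled".

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `stratification_config()` bounds | 0.05 / 0.31 / 0.55 / 0.73 | distance bins (substitutions/site) |
| `sampler_config(quota)` | 3,3,6 | per-bin draw per subset |
| `sampler_config(rounds)` | 2 | epochs $r$; $N = rM$ |
| `sampler_config(min_intra_distance)` | 0.02 | within-subset diversity floor |
| `finder_config(restarts, max_iters, patience)` | 5 / 500 / 50 | Gibbs effort |
| `finder_config(pseudocount)` | 0.5 | PWM regularization |
| `finder_config(max_mismatch)` | 1 | word-finder Hamming tolerance |
| `pipeline_config(widths)` | 8,10,12,14,16 | scanned motif widths |
| `pipeline_config(quorum, overlap_frac)` | 2 / 0.5 | voting rule |
| `pipeline_config(min_ortholog_support)` | 6 | footprinting filter |
| `pipeline_config(min_support_frac, min_peak_width, merge_gap)` | 0.25 / 6 / 5 | peak calling |
| `pipeline_config(min_overlap, n_shuffle, alpha)` | 5 / 1000 / 0.05 | comparison |

Every stage is seeded: the master seed drives the sampler, run $r$ of
discovery uses `seed + r` (so adding runs never reshuffles earlier ones),
and the comparison null draws come after the discovery seeds. Identical
seed and inputs give byte-identical TSV/BED artifacts.

## The synthetic-data generator

`simulate_tree()` + `evolve_promoters()` provide ground-truthed inputs.
A pure-birth topology is generated for the orthologs, and branch lengths
are then rewritten so that target-to-leaf distances are drawn per
stratification bin in a 1:1:2 round-robin (mirroring the 3:3:6 quota): a
global rescaling of a random ultrametric tree cannot guarantee that every
bin is populated, while this construction can, and a collapsed depth range
degrades gracefully to star-like equal distances. The root promoter draws
background positions i.i.d. and implant positions column-wise from the
implant PWM; along each branch of length $d$ a background site substitutes
with the Jukes–Cantor probability $p(d) = \tfrac34(1 - e^{-4d/3})$ and a
motif site with $p(c\,d)$, conservation $c = 0.1$ by default, so motif
divergence grows with distance exactly as footprinting assumes.

Default study conditions, chosen once: 30 taxa, 250 bp promoters, uniform
background, one implant of width 10 at position 100 with column dominance
0.91 (information content $\approx$ 14 bits), depth range 0.05–0.73.
Because the root implant is *sampled* from the PWM, a noticeable fraction
of simulations implant a word 2–3 substitutions away from the PWM
consensus; discovered motifs then model the realized word, and database
discrimination for those replicates is genuinely harder. This is a feature
of the generative model, not noise to be removed.

What the generator does **not** emulate: indels (the projection logic
assumes positionally stable promoters), rearrangements, GC-content
heterogeneity, site turnover, and operon-structure artifacts of real
promoter extraction. Passing tests therefore demonstrate correctness of
the machinery and sensible behavior under the stated evolutionary model —
not performance on real genomic promoter sets.

## Numerical choices and degenerate inputs

* N bases are allowed on input, never contribute to motif counts, and
  score as background (log-odds 0) in all likelihood ratios; uniform
  (N-padded) PWM columns have zero variance, and their Pearson correlation
  with any column is defined as 0.
* Empirical p-values live on a $1/(K+1)$ grid, so exact ties between
  database motifs are common; the per-run top candidate breaks E-value
  ties by the alignment score. With $K = 1000$ and a 20-motif database the
  smallest attainable E-value is $\approx 0.02$.
* The word finder refuses $W > 12$ (enumeration guard); the voting stage
  simply skips it at larger widths.
* Interval conventions are 0-based half-open everywhere, including
  BedGraph; stratification bins are half-open with a closed far top.
* Degenerate cases are contracts, not accidents: an empty subgroup makes
  $M = 0$ and errors with guidance; an unsatisfiable diversity rule waives
  with a warning; a peak with no matched runs yields an $n = 0$ statistics
  row; a motif database is validated before discovery starts.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at the default study conditions
(30 taxa, 250 bp, $N = 4$ runs per replicate) over 20 seeded replicates
for end-to-end recovery and database discrimination, 20 seeded replicates
of the Gibbs finder at 12 sequences, 200 trials for null calibration with
$K = 500$ shuffles, and exhaustive grids up to size 20 for the subset-count
oracle. These sizes are the package's declared desk-scale reference
conditions for its own correctness claims.

## Known limitations

* OOPS only: the Gibbs finder assumes exactly one site per sequence;
  sequences lacking the motif dilute the PWM rather than being dropped.
* No indel handling anywhere downstream of the (optional) pairwise
  alignment used for distances.
* The empirical comparison null shuffles whole columns; it preserves
  column sharpness but not inter-column dependence, and two sharp motifs
  over similar alphabets can produce heavy null tails.
* Peak calling is thresholding with merge/width rules — no smoothing and
  no FDR model over peak heights; the support threshold is a declared
  engineering choice.
* The E-value headline numbers of real-genome analyses depend on curated
  databases and genome-scale ortholog sets; nothing at desk scale speaks
  to them.
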