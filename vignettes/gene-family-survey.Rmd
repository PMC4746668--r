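---
title: "Methods: a closed-loop gene-family survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop gene-family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famsurvey implements the classic survey workflow used to characterize a
plant transcription-factor family — the running example is the 36-member
TCP family of the diploid cotton *Gossypium arboreum* — as a set of
tested, reusable components: domain-based identification, curation,
phylogeny, duplication dating, gene structure and motif analysis, and
qPCR expression profiling. Because the underlying genome assembly is not
redistributable at desk scale, every input is emulated by a seeded
synthetic-data generator that records its ground truth, so each stage is
verified in a closed loop. This vignette documents the models, the
parameters that matter, and the design decisions taken where the
workflow's conventions are genuinely open.

## Domain identification

Family membership is decided by scoring each protein against a profile
hidden Markov model of the family domain (for TCPs, a 59-residue
basic-helix-loop-helix block). The model is the standard plan7 core —
match, insert and delete states with per-node emission and transition
probabilities — scored in "uni-local" mode: an alignment may enter and
leave the match chain at any node at no cost, and flanking residues are
scored against the background, which is the appropriate topology for
finding one domain anywhere in a protein. `viterbi_score()` returns the
best single alignment (with envelope coordinates and state path);
`forward_score()` sums over all alignments in log space and is the score
used for significance, mirroring total-sequence scoring in mainstream
homology search. Both kernels are exact dynamic programs (verified in
the test suite against brute-force path enumeration on small models),
implemented in C++ for throughput. Ambiguity codes (`X`, `N`) emit at
background frequency, i.e. contribute zero log-odds.

P-values come from an explicit null calibration
(`calibrate_profile()`): i.i.d. sequences of the null composition are
simulated at a ladder of lengths (60, 120, 250, 500 by default; 1000
sequences per length), and a Gumbel distribution is fitted to each
length's forward scores by censored maximum likelihood on the upper 10%
tail — the bulk of the null is deliberately ignored because P-values of
interest live in the tail, whose log-survival is close to exponential.
Location and scale are interpolated linearly in log length at scan time.
The null composition defaults to the profile background, but when the
scanned set's composition differs (as with composition-matched shuffled
decoys) the observed proteome composition, `proteome_background()`,
is the appropriate null and is what the bundled analysis uses. The
membership cutoff is a per-target P-value of 0.0011, the value used in
the published survey protocol; `scan_proteome()` is monotone in this
threshold.

Hits are optionally confirmed with a PROSITE-style pattern
(`match_prosite()`), whose grammar (`[..]` sets, `{..}` exclusions, `x`
wildcards, `(n)`/`(n,m)` repeats, `<`/`>` anchors) is translated to a
POSIX regular expression; matches are the leftmost non-overlapping ones,
1-based inclusive.

## Curation and protein statistics

Surveys over-collect: splice isoforms and truncated re-predictions of
the same locus appear as separate records. `remove_redundant()` links
two sequences when their global-alignment identity is at least 0.95
*and* the aligned region covers at least 90% of the longer sequence;
single-linkage clusters are then represented by their longest member
(ties broken by id). The coverage condition is what keeps a genuine
fragment (e.g. an exact N-terminal half) from erasing its full-length
source, while still merging near-full-length near-copies; both
thresholds are exposed. The operation is idempotent.

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da); the isoelectric point is found by bisection of the
Henderson–Hasselbalch net charge over the termini and D, E, C, Y, H, K,
R with EMBOSS-style pKa values. Different tools ship slightly different
pKa sets, so third-party pI tables are reproduced only approximately by
design; the constants used are documented in the source.

## Alignment and phylogeny

Pairwise alignment is affine-gap Gotoh (BLOSUM62, gap open 10, extend
0.5; a gap of length k costs open + (k−1)·extend) with a deterministic
traceback (match > delete > insert). The multiple aligner is standard
progressive alignment: 3-mer guide distances, a neighbor-joining guide
tree (midpoint-rooted), and profile–profile merges in post-order, with
column scores averaged over residue pairs. These are the conventional
protein defaults; the original survey's aligner ran "default
parameters" that are not otherwise reproducible. The degapping identity
(every aligned row returns its input exactly) is enforced by
construction and tested.

Distances support `p` (mismatch proportion), `poisson` (−ln(1−p)) and
`jtt`: the maximum-likelihood distance under the Jones–Taylor–Thornton
replacement model, maximized by bounded scalar search on t ∈ [1e−6, 10].
The JTT exchangeabilities and frequencies are taken at run time from
phangorn's model data and eigendecomposed once; the independent
cross-check against `phangorn::dist.ml` agrees to ~1e−4. Gap handling is
pairwise deletion by default (columns gapped or ambiguous in a pair are
dropped for that pair), with complete deletion available. A pair with no
valid columns — or a Poisson p ≥ 1 — is reported as `NA` and flagged
`saturated`, never as a silent NaN.

`neighbor_joining()` is the Saitou–Nei agglomeration with the lowest
index pair breaking Q ties, and negative branch lengths clamped to zero
with the deficit moved to the sister edge so path lengths are preserved.
On additive matrices NJ is exact; the acceptance suite verifies exact
recovery (topology and lengths, 1e−9) on 100 random trees. Bootstrap
support resamples columns with replacement; each internal bipartition's
support is the fraction of replicate trees containing it (counted with
`ape::prop.clades`). Column resampling depends only on the seed and the
column count, so supports are invariant under taxon reordering. The
bundled analysis uses 100 replicates at desk scale; the published
protocol's 1000 is a parameter.

## Duplication detection and dating

Paralog pairs are declared by the 70/70 rule: the aligned region must
cover more than 70% of the longer sequence and the similarity over
aligned columns must exceed 70%. "Similarity" is not defined in survey
protocols; here it is the fraction of aligned residue pairs that are
identical or BLOSUM62-positive, the standard meaning of protein
similarity, and the inequalities are strict ("over 70%"). Pairs sharing
a gene are all retained. Tandem duplication is likewise never formally
defined in surveys; the package's explicit rule is: same chromosome and
(separation ≤ 100 kb or ≤ 5 intervening genes), both configurable —
everything else is segmental.

Ka/Ks uses the classic Nei–Gojobori (1986) counting method on a codon
alignment obtained by back-translating the aligned protein pair
(`codon_align()`; protein gaps become `---`, and the CDS must translate
exactly, trailing stop excluded). Site potentials count the fraction of
each position's three changes that are synonymous, with stop-creating
changes counted as nonsynonymous so that S + N = 3 per codon exactly;
pathway counts average over all minimal mutational orderings with equal
weights, discarding orderings that pass through a stop (if every
ordering is blocked, all are counted — a documented, vanishingly rare
fallback). Both proportions receive the Jukes–Cantor correction
−(3/4)·ln(1−(4/3)p); p ≥ 3/4 is flagged saturated. All 61×61 codon-pair
counts are precomputed and verified exhaustively against a brute-force
pathway oracle in the tests.

Dates follow the molecular clock T = Ks/(2λ) with λ = 1.5×10⁻⁸
synonymous substitutions per site per year (the standard cotton rate),
reported in Mya. Ks above 2.0 is flagged as saturated but still dated,
since published tables retain such pairs. Feeding the published 15-pair
Ks table through `date_duplication()` reproduces every printed date to
five decimals and the 11.28–36.51 Mya range with mean 19.7 Mya.

## Gene structure and motifs

`gene_structure()` reports exon/intron architecture in gene-local
5'→3' coordinates (minus-strand models are flipped); introns are derived
as inter-exon gaps and exons plus introns tile the gene span exactly.
Gene models are stored in genomic ascending coordinates exactly as GFF3
does, so orientation is applied only at reporting time — this avoids
double-flipping bugs.

Motif discovery is ZOOPS (zero-or-one occurrence per sequence)
expectation–maximization over ungapped position weight matrices: the
E-step computes per-window occupancy responsibilities against a
0th-order background estimated from the input, and the M-step
re-estimates the PWM with a 0.01 pseudocount per cell and the site prior
γ. The monitored objective is the log posterior (data likelihood plus
the Dirichlet term corresponding to the pseudocount), which EM theory
guarantees non-decreasing — the suite asserts this at every iteration.
Each motif is fitted from several subsequence-derived starts across a
width grid within the 6–250 bound; the best width is chosen by a
BIC-style penalized log-likelihood ratio (19 free parameters per
column). Before the next motif is sought, found sites are
probabilistically erased MEME-style (positional weights scaled by
1 − responsibility), which bounds overlap between successive motifs.
`motif_occurrences()` then scans any sequence set by log-odds with
greedy non-overlapping selection. Runs are byte-deterministic given the
seed. A motif whose consensus collapses to a single letter is flagged
low-complexity.

## Expression

`relative_expression()` implements 2^−ΔCt: technical replicates are
averaged on the Ct scale within each biological replicate, ΔCt is taken
against the reference gene (a SAD1 analogue) in the same
condition × biological replicate block, and the per-block values 2^−ΔCt
are summarized across biological replicates by mean and standard
deviation on the linear scale — standard qPCR practice, documented here
because survey papers typically only cite it. The construction makes the
values invariant to any per-block Ct shift and exactly two-fold per
cycle; a ΔΔCt mode against a calibrator condition is available. A
missing reference measurement is a named error; a gene absent from a
condition is `NA`, never zero. `classify_profiles()` applies transparent
rules on the canonical seven conditions (leaf, sepal, fiber at −2, 0, 2,
5, 10 days post anthesis): fiber-enriched at ≥ 2-fold over the
vegetative mean, split into initiation (−2..2 DPA) versus elongation
(5..10 DPA) by which window holds the maximum; non-enriched genes are
ubiquitous below a 0.35 coefficient of variation, otherwise
leaf/sepal-preferential.

## The synthetic substrate

`make_family()` builds the survey's input universe at the published
study's scale: 36 true genes of 300 residues carrying a sampled domain
(width 59) at a fixed position — 15 paralog pairs evolved from common
ancestors by substituting exactly 10% of non-domain positions per
lineage, plus six singletons — 22 redundant entries (slight truncations
of ≤ 4% of the length with ≤ 1% substitutions), and 500
composition-matched shuffled decoys. These rates place pair similarity
(~0.84) and cross-pair similarity (~0.45) on opposite sides of the 70%
criterion, and redundancy identity (~0.99) above the 0.95 curation
cutoff, with wide margins rather than tuned edges. `evolve_pair()`
mutates a CDS pair to a target synonymous divergence with dN/dS = ω by
drawing Poisson event counts per lineage and applying uniformly chosen
single-nucleotide changes of the required class (stops never created);
realized event counts are recorded so estimator tests compare against
the realization, removing simulation variance from the comparison.
`make_genome_gff()` lays genes out on 13 chromosomes (pair members on
different chromosomes in the default layout, making the all-segmental
outcome checkable); `plant_motifs()` writes PWM-sampled sites into
sequences; `simulate_ct()` produces Ct = base − log2(truth) + noise with
the reference at the base cycle, so the noiseless table is inverted
exactly by `relative_expression()`. Every generator is deterministic
given its seed.

What the generator does *not* emulate: real intergenic sequence,
transposable elements, splice-isoform structure beyond truncation,
codon-usage bias, primer efficiency ≠ 2, and alignment-degrading indel
regimes. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not performance on a real
genome; on real data the scan threshold, curation thresholds and the
70/70 rule interact with annotation quality in ways no fixture can
capture.

## Problem sizes and numerical choices

The bundled analyses run at the study's scale (558-sequence proteome,
36-gene family, 15 pairs, 3×3 replicated Ct tables) with bootstrap and
simulation counts chosen for desk-scale runs: 100 bootstrap replicates,
1000 null sequences per calibration length, 20–50 replicates per Ks
recovery target, 100 NJ recovery instances. Convergence controls: EM
tolerance 1e−6 on the objective (max 500 iterations), pI bisection to
|charge| < 1e−4, JTT optimization tolerance 1e−8. Ties are broken
deterministically everywhere (alignment traceback order, NJ lowest index
pair, cluster representatives by length then id), so every pipeline
output is a pure function of inputs, configuration and seed; the
pipeline test asserts byte-identical reruns.

## Known limitations

Viterbi envelopes report the single best alignment only — multi-domain
proteins are scored by their best domain. Gumbel tail calibration is
approximate for very short targets (shorter than the profile). The
progressive aligner has no iterative refinement, so deep or indel-rich
families will show the usual progressive-alignment artifacts. The
Nei–Gojobori estimator is counting-based: no transition/transversion
weighting and no codon-frequency correction, which biases Ks slightly
for strongly biased mutation processes (the simulator's uniform process
satisfies its assumptions). Duplication-mode classification knows
nothing of synteny; the whole-genome-duplication attribution a survey
narrative makes from date concordance is supported by
`duplication_report()` but not automated.
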