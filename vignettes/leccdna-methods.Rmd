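---
title: "Identifying long extrachromosomal circular DNA from sequence-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying long extrachromosomal circular DNA from sequence-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leccdna)
```

## The problem

Long extrachromosomal circular DNA (leccDNA) molecules are nuclear circles of
thousands of nucleotides, by-products of DNA repair and replication that are
implicated in genomic instability, gene amplification and oncogenesis.
Distinguishing leccDNA from other genomic sequence by computation requires
(i) turning variable-length DNA into fixed-length numeric vectors without
destroying the discriminative signal, and (ii) a classifier that can exploit
that signal. `leccdna` implements the full predictive pipeline: benchmark-style
dataset construction, thirteen sequence encoders with early fusion,
subsequence 2-mer density analysis, and an encoder x classifier evaluation
grid under 5-fold cross-validation and independent-test protocols.

## Where the signal lives: 2-mer density regions

leccDNA-like class differences are compositional, not motif-like: certain
dinucleotides (2-mers) are over- or under-represented, and the imbalance
concentrates in the *initial* region of the sequences. The intrinsic analysis
proceeds in four steps: segment each sequence into consecutive subsequences
(default segment length `S = 500` nt, 10 segments), count the 16 overlapping
2-mers per segment, normalize each class's counts by its number of sequences,
and subtract the two class profiles. The cells of the resulting difference
matrix with the largest magnitude mark the information-rich region.

Two numerical choices matter here. Sequences that do not reach a segment
contribute zero counts there rather than being dropped, so the per-sequence
normalizer `n` is constant across segments and columns stay comparable.
Counts are normalized only by sequence count, not by segment length; the last
segment a sequence reaches is usually partial, and dividing by a shrinking
length would inflate its noise.

This localization justifies the fixed-length rule used before encoding:
`fix_length()` keeps the 5' prefix when a sequence exceeds the length
threshold (default 1000 nt) and appends the pad character `'P'` otherwise.
Pad positions are real characters in the sequence but are invisible to every
count-based encoder: any k-mer or gapped pair touching `'P'` (or the
ambiguity code `'N'`) is excluded from both numerator and denominator, so a
padded sequence encodes identically to its unpadded original. Positional
encoders emit all-zero blocks at such positions.

## The encoders

All thirteen encoders order words lexicographically over A < C < G < T and
return named numeric vectors; `fuse()` concatenates any subset, prefixing
feature names with the encoder id (early fusion).

* **NAC / DNC / TNC** — normalized overlapping k-mer frequencies, k = 1, 2, 3.
* **ENAC** — per-window nucleotide counts for a window of `W = 5` slid one
  position at a time.
* **binary / NCP / EIIP / ANF** — per-position blocks: one-hot (4); the
  chemical-property triplet ring/functional-group/hydrogen with
  A = (1,1,1), C = (0,1,0), G = (1,0,0), T = (0,0,1) (3); the electron-ion
  interaction potential constant A 0.1260, C 0.1340, G 0.0806, T 0.1335 (1);
  and the NCP triplet plus the accumulated density of the position's
  nucleotide up to that position (4).
* **CKSNAP** — for every gap g in 0..G (default `G = 5`, 96 features), the 16
  frequencies of nucleotide pairs at positions (i, i + g + 1), each gap block
  normalized by its number of valid pairs.
* **PseEIIP** — for each of the 64 trinucleotides, the sum of its three EIIP
  constants times its normalized overlapping frequency.
* **PseDNC / PseKNC / SCPseDNC** — k-tuple frequencies augmented with global
  sequence-order correlation factors computed from six dinucleotide
  physicochemical step properties (twist, tilt, roll, shift, slide, rise),
  standardized to zero mean and unit variance per property across the 16
  dinucleotides. The lag-j factor is the average over positions of the
  squared property difference between dimers j steps apart, averaged over
  properties (PseDNC/PseKNC) or kept per property (SCPseDNC, 6 factors per
  lag). The whole vector is normalized by `1 + w * sum(theta)` so it sums
  to 1. Defaults `lambda = 2`, `w = 0.1`, `k = 3` follow the encoders'
  original publications; they are surfaced as parameters because different
  corpora reward different amounts of sequence-order information.

Two open choices were resolved as follows. The correlation function is the
squared difference of standardized property values — the form published with
the original pseudo-composition encoders — and the series-correlation variant
keeps that form per property, which also gives it the natural degenerate
behavior (all factors zero for a homopolymer). ENAC emits raw window counts
rather than frequencies; windows have fixed width, so the two differ by a
constant factor only.

The shipped property table (`inst/extdata/dinucleotide_properties_synthetic.tsv`)
is a synthetic representative table: values lie in the crystallographic
literature ranges and respect complementary-step symmetry, but are not a
transcription of any single published source. Because every property is
standardized before use and all package results are internally consistent
with the same fixture, substituting a laboratory table (via the `path`
argument of `dinucleotide_properties()`) changes feature values but not any
structural property the package tests.

## Dataset construction

Negatives are made from positives by a dinucleotide-preserving shuffle
(Altschul–Erickson): the sequence is an Eulerian walk on its nucleotide
transition multigraph, so sampling a random last-edge arborescence toward the
terminal residue and randomly ordering the remaining out-edges yields a
uniform-ish random sequence with *exactly* the same multiset of overlapping
dinucleotides — same length, same mononucleotide counts, same first and last
residue. Classifier signal against such negatives can therefore only come
from higher-order arrangement, never from raw composition. The per-sequence
shuffle seed is derived from the master seed and the sequence id, so negative
sets are reproducible and independent of processing order.

Redundancy filtering approximates similarity-based clustering: sequences are
visited longest-first (id as tie-break) and join an existing cluster when the
shared distinct-5-mer containment fraction with its representative exceeds
the threshold (default 0.6); representatives survive. This is a deliberate
in-package approximation of CD-HIT — exact CD-HIT output can be imported from
a `.clstr` file instead, and no test depends on the external binary.
Train/test splits are stratified per class (default 20% held out), drawn
after ordering by id so membership is seed-stable.

The pipeline shuffles negatives before splitting; the order is recorded in
the dataset's provenance attribute.

## Classifiers and evaluation

Eleven classifier specifications are exposed behind one surface
(`classifier_spec()`, `train_and_predict()`): logistic regression, k-nearest
neighbours (k = 5), an unpruned gini decision tree, Gaussian naive Bayes,
bagging (10 bootstrapped trees), random forest (100 trees, sqrt-features),
AdaBoost (50 depth-1 stumps, learning rate 1), gradient boosting (100 trees,
learning rate 0.1, depth 3), LDA, an RBF-SVM (C = 1, gamma by the scale
heuristic `1 / (p * var)`), and extremely randomized trees (100 trees).
Features are z-score standardized on training statistics by default — the
RBF-SVM and KNN are scale-sensitive — with constant columns dropped;
`standardize = FALSE` reproduces raw-feature behavior. The logistic
regression is a plain maximum-likelihood fit; the weak ridge penalty of the
reference parameterization (l2, C = 1) is numerically negligible at these
feature counts.

Metrics follow the standard confusion-count definitions: ACC, SN, SP,
FPR = 1 − SP, F1, and MCC = (T⁺T⁻ − F⁺F⁻)/Z with
Z = √((T⁺+F⁻)(T⁺+F⁺)(T⁻+F⁺)(T⁻+F⁻)); a zero denominator reports MCC = 0 with
an explicit degenerate flag. AUC-ROC is computed by trapezoidal integration
over grouped score thresholds including the infinite endpoints, which equals
the Mann–Whitney U statistic over positive–negative pairs with ties counted
one half (a property the tests verify against a brute-force pair count).

Cross-validation is stratified with folds drawn after ordering samples by id
(bit-reproducible under a seed); each training fold fits its own
standardizer. `enumerate_ensembles()` crosses all unordered encoder pairs
with all classifiers — 13 encoders and 11 classifiers give the 858-cell
grid. `rank_scores()` summarizes a results grid by taking, per
(encoder, classifier, dataset), the maximum ACC over sequence lengths,
ranking encoders within each (classifier, dataset) group with ties sharing
the mean rank, and averaging ranks across datasets; this is one consistent
reading of a rank-score summary and is labelled as such in reports.

## The synthetic generator: what it emulates and what it does not

`synthetic_spec()` defines the study conditions used throughout the tests:
200 sequences per class, lengths uniform over 600–3000 nt, an informative
500-nt prefix, enriched dimers {TT, TA, GG}, effect size `delta = 0.8`, and
shuffle-mode negatives. Positives draw their prefix from a first-order
Markov chain — from residue x, with probability `delta` the successor is
uniform over the enriched continuations of x, otherwise uniform over
A, C, G, T — and the remainder i.i.d. uniform. The signal is planted as
transition bias rather than motif insertion because the class difference
being modelled is a dimer-density difference, not a motif. At `delta = 0`
the classes are exchangeable by construction.

These sizes keep the full end-to-end check (encode 400 sequences at 1000 nt,
5-fold CV with the RBF-SVM) at a few seconds while giving the classifier a
clear target: accuracy near 0.5 at `delta = 0` and above 0.9 at
`delta = 0.8`. What passing these tests shows is that the pipeline recovers
a planted prefix-localized compositional signal; it does *not* show that
real leccDNA corpora carry such a signal at such strength, that genome-scale
base composition, repeats, or assembly artifacts are handled, or how the
predictor performs across species. Those questions need the real benchmark
corpora.

## Degenerate inputs and tie-breaks

Empty FASTA files and headerless records raise format errors naming the
line; empty intervals (`end <= start`) are rejected; encoders refuse
sequences with no valid word (e.g. all-N). Ranking of density-difference
cells breaks ties by dimer then segment index; redundancy clustering breaks
length ties by id; all random choices flow from one master seed through
named sub-streams (`substream_seed()`), so every artifact is reproducible
from its provenance echo.

## Worked run

```{r example, eval = FALSE}
ds <- generate_dataset(synthetic_spec(delta = 0.8, seed = 7))
X <- encode_matrix(fix_length_seqs(ds, 1000), c("cksnap", "pseeiip"))
cv <- cross_validate(X, ds$label, classifier_spec("SVM"), k = 5, seed = 7)
round(unlist(cv$mean), 3)
#>    ACC     SN     SP    FPR     F1    MCC AUCROC
#>  0.980  0.975  0.985  0.015  0.980  0.960  0.999
```

## Known limitations

* The redundancy filter is an approximation; for publication-grade dataset
  construction import CD-HIT clusters.
* Strand is assumed '+' on coordinate extraction (no reverse complementing),
  and coordinates are 0-based half-open (BED dialect) with an opt-in
  conversion for 1-based inclusive tables.
* PseKNC's tuple size is exposed but the correlation factors remain
  dinucleotide-based, as in the original formulation.
* AdaBoost and bagging are compact in-package implementations over `rpart`
  trees; they follow the reference parameterizations but are not drop-in
  re-implementations of any particular library.
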