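# leccdna

Identification of long extrachromosomal circular DNA (leccDNA) from
sequence-derived features.

leccDNA molecules are nuclear DNA circles of thousands of nucleotides,
by-products of DNA repair and replication that contribute to genomic
instability, gene amplification and oncogenesis. Their wet-lab detection is
slow and requires prior knowledge, so a sequence-based predictor is useful
for triage. This package implements a complete predictive pipeline for
binary leccDNA vs non-leccDNA classification, aimed at computational
biologists building or benchmarking such predictors.

## What it does

* **Sequence I/O** — FASTA read/write (pad character `P` supported),
  coordinate-based extraction from a genome assembly (0-based half-open,
  with 1-based conversion on read), and fixed-length preprocessing that
  keeps the 5' prefix and pads with `P`.
* **Thirteen encoders** — NAC/DNC/TNC, ENAC, binary, NCP, EIIP, ANF,
  CKSNAP, PseEIIP, PseDNC, PseKNC, SCPseDNC — plus early fusion by
  concatenation. The flagship representation fuses CKSNAP (gap-based pair
  frequencies, one 16-block per gap g = 0..5)

  ```
  CKSNAP_g = ( N_AA/N_total, N_AC/N_total, ..., N_TT/N_total )_16
  ```

  with PseEIIP (per trinucleotide t, the summed electron-ion interaction
  potentials of its nucleotides times its normalized frequency)

  ```
  V_t = (EIIP_t1 + EIIP_t2 + EIIP_t3) * f_t ,  t in {AAA..TTT}_64
  ```

  giving a 96 + 64 = 160-dimensional fused vector per sequence.
* **Dataset construction** — redundancy filtering (greedy shared-5-mer
  clustering, or CD-HIT `.clstr` import), dinucleotide-preserving shuffled
  negatives (Altschul–Erickson Euler-path construction, exact dimer-multiset
  preservation), balanced stratified train/test splits.
* **Region analysis** — per-segment 2-mer density profiles per class and
  their difference, localizing the information-rich initial region that
  justifies prefix truncation.
* **Evaluation** — eleven classifiers (LR, KNN, DT, NB, Bagging, RF,
  AdaBoost, GB, LDA, RBF-SVM, ExtraTrees) behind one interface, stratified
  5-fold cross-validation and independent-test protocols, ACC/SN/SP/FPR/F1/
  MCC/AUC-ROC, 78 x 11 encoder-pair ensemble enumeration and rank-score
  summaries.
* **Synthetic data** — a generator that plants a prefix-localized dimer
  bias of tunable effect size, so the whole pipeline is testable without
  any external data.

## Worked example

```r
library(leccdna)

# 1. synthesize a labeled corpus: 200 leccDNA-like positives with a dimer
#    bias in the first 500 nt + 200 dinucleotide-shuffled negatives
ds <- generate_dataset(synthetic_spec(delta = 0.8, seed = 7))
table(ds$label)
#>   0   1
#> 200 200

# 2. where is the signal? 2-mer density difference by 500-nt segment
dd <- density_difference(
  dimer_density_profile(ds[ds$label == 1, ], S = 500, num_segments = 6),
  dimer_density_profile(ds[ds$label == 0, ], S = 500, num_segments = 6))
head(top_discriminative_dimers(dd, 3))
#>   dimer segment difference
#> 1    GG       1     118.78
#> 2    GG       2     -59.20
#> 3    GG       3     -30.73

# 3. fixed-length prefixes, fused CKSNAP + PseEIIP features, SVM, 5-fold CV
X <- encode_matrix(fix_length_seqs(ds, 1000), c("cksnap", "pseeiip"))
dim(X)
#> [1] 400 160
cv <- cross_validate(X, ds$label, classifier_spec("SVM"), k = 5, seed = 7)
round(unlist(cv$mean), 3)
#>    ACC     SN     SP    FPR     F1    MCC AUCROC
#>  0.980  0.975  0.985  0.015  0.980  0.960  0.999
```

The top-ranked difference cell sits in segment 1 — the planted 500-nt
informative prefix — with the compensating depletion spread over the later
segments of the shuffled negatives. The fused 160-dimensional representation
with the RBF-SVM recovers the planted class signal almost perfectly, while
the same pipeline at `delta = 0` stays at chance.

A command-line wrapper for the same workflow ships in
`inst/scripts/leccdna` (commands `synth`, `build-dataset`, `encode`,
`region-scan`, `train`, `evaluate`, `grid`), driven by flat `key=value`
configs with CLI overrides.

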