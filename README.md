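# cppforge

Desk-scale generation and mechanistic prioritization of candidate
cell-penetrating peptides (CPPs).

CPPs are short peptides (TAT, `GRKKRRQRRR`, is the classic one) that cross
cell membranes without a receptor and can carry cargo into cells. Modern
generative models propose CPP-like sequences by the million; the
bottleneck is choosing the handful worth synthesizing. `cppforge`
implements a pipeline that ranks generated candidates *mechanistically*:
each candidate is pulled through a membrane model by a harmonic spring at
constant velocity in `n` replicas, the replica maximum steering forces
`f_1..f_n` (an inverse permeability proxy — lower means easier crossing)
are summarized by **sample variance penalization**

```
score = m + λ √(v / n),     λ = 2.5
```

with `m` the replica mean and `v` the unbiased sample variance, and
candidates are ranked ascending. The penalty term demotes peptides whose
replicas disagree, so consistent crossers win.

The package provides:

* **seqio** — validated peptide sequences, FASTA I/O, residue-class
  annotation (hydrophobic {A,V,L,I,M,F,W}, positive {R,K,H}, negative
  {D,E}), charged-position labels, composition-preserving shuffles.
* **genmodel** — a stacked-GRU sequence generator trained on penetrating
  peptides only (random-prefix elongation to length 20), a GRU
  max-pooling permeability predictor with per-position partial scores,
  alignment-identity redundancy removal (cutoff 0.35), top-k selection
  and a rule-based synthesizability filter. The networks are hand-written
  in base R and gradient-checked in the tests.
* **surrogate_smd** — a seeded one-dimensional steered-Langevin simulator
  of membrane crossing (double-well-plus-barrier potential, spring
  constant 1000, velocity 1 nm/ns, 50 ns cap, 5 replicas) plus
  readers/writers for two-column steering-force traces (GROMACS `pullf`
  xvg dialect), so real SMD output can be ranked identically.
* **scoring** — maximum steering force extraction, the mechanistic score,
  ranking and one-decimal force tables.
* **nullmodel** — shuffled-sequence null ensembles, high/low force-group
  splits (strict > 720 / < 680 thresholds), hand-written affine-gap
  Needleman–Wunsch (validated against exhaustive enumeration), BLOSUM62
  center-star multiple alignment, consensus/occupancy/quality profiles,
  motif extraction and charged-position comparison.
* **pipeline** — the end-to-end seeded run (`run_pipeline()`), synthetic
  training fixtures emulating cationic/amphipathic composition biases,
  artifact persistence and a JSON manifest; plus a thin `cppforge` CLI
  (`inst/exec/cppforge`).

## Worked example

Annotate the reference peptide Pep-MD and rank the bundled ten-peptide
table of replica force statistics:

```r
library(cppforge)

classify_residues(pep_md())
#> Pep-MD (20 aa): 7 hydrophobic, 5 positive, 1 negative, 7 other
charged_positions(pep_md())$label
#> "R2" "H5" "R7" "K11" "D17" "K19"

rank_peptides(score_force_stats(reference_force_table()))[1:3, ]
#> peptides ranked by mechanistic score (lower = better):
#>  Rank              Peptide  Mean Standard deviation Mechanistic score
#>     1 YRGWHCRGITKNGIIFDIKW 621.3                6.0             628.0
#>     2 DIGWDTEHPPKTCQIICSVI 648.6               26.5             678.2
#>     3 KIGHQKIIGETQKRCFFQWV 639.1               36.7             680.1
```

Rank 1 is Pep-MD: the lowest mean force (621.3) *and* the smallest
replica scatter (6.0) give the best (lowest) score, 628.0 = 621.3 +
2.5·6.0/√5. Pull Pep-MD through the surrogate membrane yourself:

```r
pot <- sequence_to_potential(pep_md())
rep5 <- steered_replicas(pot, smd_protocol(seed = 7), "Pep-MD")
round(rep5$max_forces, 1)
#> 619.0 592.5 615.6 604.8 627.2
mechanistic_score_from_replicas(rep5)
#> mechanistic score Pep-MD: m = 611.8, sd = 13.5, n = 5 -> 626.9
```

A full desk run — synthetic fixtures, generator + predictor training,
50 candidates, likelihood selection, synthesizability filter, 5 pulling
replicas each, ranking, and a 20-shuffle null analysis of the top
candidate — is one call:

```r
run <- run_pipeline(run_config(master_seed = 1, out_dir = "run1"))
run$ranking          # Table-style ranking, ascending score
run$null             # force groups, low-group alignment, motifs
```

Reruns with the same master seed reproduce byte-identical score tables.
The methods vignette (`vignettes/cppforge-methods.Rmd`) documents the
model, the residue conventions, the surrogate's potential and its
sequence mapping, and what the synthetic fixtures do and do not emulate.

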