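---
title: "Generating and mechanistically prioritizing cell-penetrating peptides"
author: "cppforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and mechanistically prioritizing cell-penetrating peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppforge)
```

## The problem

Cell-penetrating peptides (CPPs) are short sequences — TAT (`GRKKRRQRRR`)
is the classic example — that cross cell membranes without a receptor and
can ferry cargo into cells. Deep generative models can propose CPP-like
sequences by the million, but a bench scientist can synthesize and test
only a handful, and a likelihood score from the generator's own
discriminator says nothing about *how* a peptide crosses a bilayer.
`cppforge` implements a desk-scale version of a two-stage strategy:

1. **Generate and screen statistically.** A recurrent (GRU) language model
   trained on known penetrating peptides proposes fixed-length candidates;
   a second recurrent network scores each candidate's likelihood of being
   cell-penetrating; the top scorers that also pass a synthesizability
   rule are kept.
2. **Prioritize mechanistically.** Each surviving candidate is pulled
   through a membrane model by a harmonic spring moving at constant
   velocity, in several replicas. The replica maximum steering forces are
   condensed into a *mechanistic score* by sample variance penalization —
   low mean force *and* low replica scatter are rewarded — and candidates
   are ranked ascending.

A shuffled-sequence null analysis then asks whether the *positions* of
residues (not just the composition) matter for the ranking of a chosen
peptide, and extracts consensus motifs from the shuffles that cross
easily.

The one deliberate substitution is the pulling engine: all-atom steered
molecular dynamics is replaced by a one-dimensional steered-Langevin
surrogate so that every stage runs in seconds on a laptop, is seeded and
exactly reproducible, and is testable against analytic results. The
scoring and null machinery accept steering-force traces from real MD
engines (two-column `pullf` xvg files), so genuine SMD output can be
ranked identically.

## The mechanistic score

For a peptide with replica maximum steering forces \(f_1, \dots, f_n\)
(kJ mol\(^{-1}\) nm\(^{-1}\)), let \(m\) be their mean and \(v\) the
unbiased sample variance. The mechanistic score is

\[ s = m + \lambda \sqrt{v / n}, \qquad \lambda = 2.5 . \]

Lower is better: the maximum steering force is an inverse permeability
proxy, and the \(\lambda\sqrt{v/n}\) term penalizes candidates whose
replicas disagree — a peptide whose pulling behaviour depends on its
(uncertain) initial structure is demoted even if its mean force is low.
\(\lambda\) trades mean against consistency; 2.5 follows the sample
variance penalization literature and is configurable everywhere. With the
\(n-1\) variance denominator the score computed from raw replica forces
agrees exactly with the score computed from a reported mean/SD pair.
Reported tables round to one decimal, half away from zero.

```{r}
rank_peptides(score_force_stats(reference_force_table()))
```

The bundled `reference_force_table()` is a fixed ten-peptide input of
reference replica means and SDs used by the test-suite to pin down the
arithmetic: seven of its rows reproduce the printed score exactly at one
decimal; the other three were evidently computed from unrounded inputs and
recompute to within ±0.1 from the rounded printed values.

## Residue conventions

The annotation module fixes hydrophobic = {A, V, L, I, M, F, W}, positive
= {R, K, H}, negative = {D, E}, positions 1-based. Reference residue
counts for the reference peptide Pep-MD (`YRGWHCRGITKNGIIFDIKW`: seven
hydrophobic, five positive, one negative, charges at R2, H5, R7, K11,
D17, K19) are only consistent with this choice: including C, G or Y among
the hydrophobics would give eight or more, and excluding histidine from
the positives would give four. No single "standard" hydrophobicity scale
exists, so the convention is documented here rather than assumed.

## The sequence models

No deep-learning framework is required: both networks are small GRUs
written in plain matrix algebra, with backpropagation through time
verified against finite differences in the test suite.

* **Generator** — two stacked GRU layers (default 64 hidden units at full
  scale, 16–32 in tests), trained as a next-residue language model on the
  positive class only, with begin/end tokens, full-batch Adam and early
  stopping on a plateaued loss; the returned model carries the weights of
  the best epoch. Sampling starts from a random prefix (length uniform on
  1..20, residues uniform) and elongates autoregressively to exactly the
  target length; the end token is masked during elongation. Sampling is
  multinomial at temperature 1 by default; greedy decoding is a flag.
* **Predictor** — a single GRU computes a hidden vector at every
  position; a one-layer dense readout turns each into a per-position
  partial score; the scores are max-pooled over positions and squashed by
  a logistic into \([0,1]\). The squashing is architectural (applied after
  pooling), so the likelihood is normalized for any input and the argmax
  position is unchanged by it. The per-position readout is linear with a
  bias and no extra activation before pooling — the simplest member of
  the family consistent with the max-pooling design. Each sequence is
  scored on its own positions only, so batch composition and padding
  cannot change a score.

Training-set redundancy is removed by greedy first-representative
clustering at pairwise global-alignment identity ≥ 0.35 (identical
positions / alignment length, BLOSUM62 affine alignments via Biostrings).
Redundancy-removal procedures in curated peptide collections are rarely stated exactly;
greedy first-seen clustering is the simplest order-stable choice and is
what `deduplicate_training()` implements.

The synthesizability filter is a documented rule-based stand-in scoring
0–5 (penalties for hydrophobic runs ≥ 5, multiple cysteines, length over
30); commercial synthesizability services are not reimplemented, and any
scorer function can be plugged in. The selection threshold defaults to 3.

## The steered-Langevin surrogate

A single coordinate \(z\) (nm) — the peptide's position along the
membrane normal — obeys overdamped Langevin dynamics under three forces:
the membrane potential \(-U'(z)\), thermal noise, and a harmonic spring
\(k\,(z_d(t) - z)\) whose other end is a dummy particle moving at constant
velocity, \(z_d(t) = z_0 + vt\). Euler–Maruyama integration with
\(\Delta t\) = 0.01 ns; the step must satisfy the enforced stability bound
\(\Delta t \le \gamma / (k + \max|U''|)\). Protocol defaults follow the
reference pulling setup: \(k = 1000\) (stored numerically; the printed
unit kJ mol\(^{-1}\) nm\(^{-1}\) is dimensionally a force and is read as
kJ mol\(^{-1}\) nm\(^{-2}\)), \(v = 1\) nm ns\(^{-1}\), a 50 ns cap, five
replicas per peptide. A run ends when the particle passes the membrane
exit by 0.5 nm or at the cap.

The membrane is a smooth double-well-plus-barrier profile: attractive
Gaussian headgroup wells at the entry (1 nm) and exit (5 nm) planes and a
broad Gaussian core barrier between them (width 1.6 nm, about the
half-width of a bilayer's hydrophobic core). The friction default
\(\gamma = 100\) kJ mol\(^{-1}\) nm\(^{-2}\) ns corresponds to a
centre-of-mass diffusivity \(D = k_BT/\gamma \approx 0.025\) nm² ns\(^{-1}\)
at 300 K, a typical membrane-associated peptide mobility. Two analytic
anchors are tested: on a flat landscape the steady-state mean spring force
is \(\gamma v\), and the mean maximum force is non-decreasing in barrier
height (paired seeds).

Replica maxima are read from the trace after a 1 ns centred running mean
(configurable, off by default in `max_steering_force()` itself): the
spring force carries thermal jitter of scale \(\sqrt{k_B T\, k} \approx
50\) kJ mol\(^{-1}\) nm\(^{-1}\), and the smoothing suppresses that
jitter while preserving the barrier-scale force peak, which lasts several
nanoseconds. Per-replica seeds are derived from (master seed, peptide id,
replica index), so any replica can be regenerated in isolation.

### From sequence to potential

The map from a sequence to its barrier is deliberately transparent — an
affine function of three interpretable features:

\[ B = B_0 - c_h \cdot \text{hyd} + c_q \cdot |q|/L + c_d \cdot d, \]

with hyd the hydrophobic fraction (hydrophobic residues partition into
the core, lowering the barrier), \(|q|/L\) the absolute net charge per
residue (buried charge pays a desolvation penalty), and \(d\) the
**charged-position dispersion**: the resultant length of the charged
positions on an ideal helical wheel (100°/residue) plus the normalized
deviation of the sorted charged positions from even spacing. \(d\) is
small when charges are spread evenly along the chain and around the
helix — the arrangement that lets charged side chains hand off from the
entry-leaflet headgroups to the exit-leaflet headgroups during crossing —
and is the only term that distinguishes composition-preserving shuffles
of one sequence. Headgroup wells deepen mildly with charged fraction.
Defaults (\(B_0 = 1230\), \(c_h = 600\), \(c_q = 400\), \(c_d = 700\)
kJ mol\(^{-1}\), floor 50) were chosen so that the simulated maximum
steering forces of 20-mers span the reference 600–850 kJ mol\(^{-1}\)
nm\(^{-1}\) range, with the reference peptide near 620 and typical
shuffles straddling the 680/720 low/high group thresholds. A sequence
with no classifiable features (e.g. polyglycine) maps to the bare
intercept, and setting \(c_d = 0\) makes the mapping position-insensitive
(all shuffles then share one potential).

The dispersion feature was designed by enumeration before any simulation
was run: across all \(\binom{20}{6}\) possible charge placements on a
20-mer with six charges, the reference peptide's arrangement
(2, 5, 7, 11, 17, 19) ranks in the best 0.2%. That is what makes the
package's end-to-end null property — the reference peptide's mechanistic
score falls below the minimum of its shuffle ensemble — achievable by a
position-generic statistic rather than by anything tuned to one sequence.

## The shuffled-sequence null analysis

`run_null_analysis()` draws composition-preserving permutations
(Fisher–Yates, per-shuffle seeds recorded in the ids), pulls each through
the surrogate with the full replica protocol, and splits the shuffles by
mean maximum force with strict thresholds: high > 720, low < 680,
boundary values intermediate. The low-force group is aligned by
center-star progressive alignment (the center maximizes summed pairwise
Needleman–Wunsch scores; merging follows "once a gap, always a gap"),
BLOSUM62 with affine gaps, open −10 / extend −1, under the convention
that a gap of length \(L\) costs open + (L−1)·extend. The traceback is
deterministic (substitution preferred over deletion over insertion on
ties), and the aligner is validated against exhaustive enumeration of all
global alignments on small alphabets.

Per-column profile statistics: **consensus** is the modal non-gap residue
(alphabetical on ties) with its fraction of rows; **occupancy** is the
non-gap fraction; **quality** is the mean pairwise BLOSUM62 score of the
column's residues, scaled to \([0,1]\) between the matrix minimum and the
largest self-score among residues present — so any perfectly conserved
column scores 1 regardless of residue (columns with fewer than two
residues score 1 vacuously). Motifs are maximal runs of columns passing
both consensus and occupancy thresholds; one interior sub-threshold
column may be bridged and is rendered `-`, permitting patterns like
`WII-G`. Finally the reference peptide's charged positions are compared
against charged consensus columns within a ±1-column window.

An alternative largest-gap splitter (maximum adjacent difference in the
sorted forces) is easy to apply by hand to `forces` when the fixed
thresholds sit awkwardly for a particular ensemble; the fixed 680/720
defaults are kept because they are the documented convention.

## Synthetic fixtures: what they emulate, and what they don't

`make_fixtures()` draws positive peptides with elevated R/K rates
(default 0.4 per position vs 0.05 in negatives) and hydrophobic residues
placed preferentially on one face of an ideal helix, emulating the
cationic and amphipathic composition biases of curated CPP collections;
negatives are near-uniform. Lengths are uniform on 8–30 (under the
52-residue training cap); the planted signal is compositional by
construction, so a position-free composition rule — and therefore the
predictor — can separate the classes (held-out accuracy > 0.8 at desk
scale), while equalizing the class parameters removes the signal and
drops accuracy to chance. Real training corpora differ in ways the
fixtures do not model: phylogenetic redundancy, length–class
correlations, shared motifs between classes, and annotation noise.
Passing tests on fixtures therefore demonstrate that the machinery
learns a planted signal reproducibly — not that the models reach any
particular accuracy on real CPP data.

## Problem sizes and numerical choices

Desk-scale defaults keep every stage interactive: 200+200 training
fixtures, hidden size 32, epoch caps of 80–200 with early stopping
(patience 25, minimum improvement 1e-4), 50 candidates of length 20,
5 pulling replicas, 20-shuffle null ensembles. The reference scale
(16,648 positives, 256 hidden units, 10⁷ candidates, 100,000 epochs,
100 shuffles) is reachable through the same configuration objects.
Other numerical choices: Glorot-uniform initialization; Adam with
lr 0.01–0.02; categorical cross-entropy masked beyond sequence ends;
ties in `select_top()` broken lexicographically by sequence then id;
ranking ties broken by lower mean then id; all stage seeds derived
deterministically from a master seed plus the stage name, so reruns are
byte-identical and stages can be reproduced in isolation.

## Known limitations

* The surrogate is one-dimensional: it has no conformational change, no
  membrane deformation, no secondary-structure dependence — mechanisms
  that matter in all-atom simulations. It preserves the *interfaces* and
  the qualitative orderings (hydrophobicity, barrier height, charge
  placement), not atomistic realism.
* The sequence-to-potential map is affine in three features; real
  permeability depends on many more (amphipathic moment of hydrophobics,
  proline kinks, aromatic anchoring).
* The predictor's likelihood is calibrated only by the logistic squash;
  it is a ranking score, not a probability.
* Structure prediction of candidates (the source of replica-to-replica
  variability in real pipelines) is out of scope; here replicas differ
  only by thermal noise.
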