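---
title: "Strand-resolved 5mC/5hmC estimation from hairpin BS/oxBS amplicons"
author: "hairpinox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved 5mC/5hmC estimation from hairpin BS/oxBS amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinox)
```

## The measurement problem

Bisulfite chemistry reads one DNA strand at a time, so ordinary bisulfite
sequencing cannot say whether a CpG dyad is methylated on both strands or
on only one. Hairpin bisulfite sequencing closes that gap: a synthetic
hairpin linker is ligated onto a restriction cut so that the Watson and
Crick strands of each fragment stay covalently joined through conversion
and PCR, and a single amplicon read reports both cytosines of every CpG
dyad. Splitting the ligation into a standard bisulfite (BS) aliquot and an
oxidative bisulfite (oxBS) aliquot then separates 5-methylcytosine from
5-hydroxymethylcytosine: under BS both 5mC and 5hmC resist conversion and
read as C, while the oxBS pre-oxidation sends 5hmC through 5fC to T, so
only 5mC reads as C.

The linker itself carries three kinds of bookkeeping: a degenerate loop
(`D` = A/T/G) acting as a unique molecular identifier (UMI) of the original
ligation event, an unmodified cytosine measuring the intended C→T
conversion rate, and one 5mC and one 5hmC base measuring the unwanted
(false) conversion of each modification. Because neither chemistry is
perfect — C conversion is ≈ 99.5% rather than 100%, 5mC falsely converts
at ≈ 6–11%, and oxBS converts 5hmC at only ≈ 92% — these control rates are
not a formality: they are the error model for everything downstream.

## From reads to dyad classes

`build_reference()` assembles a composite reference, `top + linker +
reverse(bottom)`, in the orientation the molecule is actually sequenced.
All public coordinates are 0-based offsets into this composite; dyads are
indexed by the top-strand C offset. Alignment (`align_sample()`) is
bisulfite-aware and deliberately asymmetric: a read T opposite a reference
C is a legitimate conversion and scores as a match, while a read C
opposite a reference T is a mismatch — conversion is one-directional.
Degenerate `D` slots score neutrally against A/T/G. Mates are aligned
ends-free and merged in reference space by quality-weighted consensus;
disagreement at equal quality yields N, which downstream becomes an
"unknown" call rather than a guess.

Sequence identity is the fraction of matching merged columns, counting
insertions and deletions as mismatches and excluding soft-clipped ends.
Reads are filtered at identity ≥ 0.9 for single-copy amplicons and ≥ 0.8
for repetitive elements; the linker conversion-rate analysis relaxes the
filter to ≥ 0.6 because the UMI loop can never match a single reference.
The exact identity formula of earlier interactive tools is unpublished,
so the definition above is this package's own; the thresholds are the
field's standard values.

`refold_sample()` restores the double-strand information: for each dyad
the top and bottom calls combine into one of five classes — `both`,
`hemi_top`, `hemi_bottom`, `unmod`, or `unknown` if either member is not
analysable. `dedup_umis()` collapses PCR clones sharing a UMI by per-dyad
majority vote (ties → `unknown`); per-dyad voting was chosen over
whole-pattern voting because sequencing failures hit positions, not whole
molecules. UMI collisions between genuinely distinct molecules are
accepted rather than salted away: amplicons are fixed-locus, so there is
no fragment-endpoint information to add. The default simulated UMI length
of 12 (3^12 ≈ 5.3 × 10^5 sequences) keeps the pairwise collision
probability negligible at the depths used here.

Pattern maps (`write_pattern_map()`) use the conventional colouring: red =
modified on both strands, dark green = plus strand only, light green =
lower strand only, blue = unmodified, white = not analysable; the leading
column shows each molecule's mean modification level. Non-CpG methylation
is reported as a per-molecule rate but never enters dyad classes.

## The dyad model

The estimation core is a hidden Markov model over the nine dyad states
\((s_\text{top}, s_\text{bottom}) \in \{u, m, h\}^2\) (u = unmodified C,
m = 5mC, h = 5hmC), observed through two treatment-specific emission
channels. One cell division applies, in order:

1. **replication** — one strand is retained uniformly at random and
   paired with a naked all-u daughter strand;
2. **maintenance** — the new-strand position opposite a 5mC template
   becomes 5mC with probability \(\mu\);
3. **de novo methylation** — every strand still unmodified becomes 5mC
   with probability \(\delta\), independently per strand;
4. **hydroxylation** — every 5mC strand becomes 5hmC with probability
   \(\eta\).

The composition is a 9 × 9 row-stochastic matrix (`division_matrix()`).
Three modelling commitments deserve emphasis. The event order matters and
is fixed as above: maintenance acts before de novo, so \(\mu\) captures
the hemimethylated-substrate preference of Dnmt1 while \(\delta\) captures
Dnmt3a/b-type activity; a "total methylation activity on hemimethylated
dyads" summary is reported as \(\mu + (1-\mu)\delta\). Maintenance
recognises only 5mC templates — a hemi-hydroxylated dyad receives no
maintenance boost, consistent with Dnmt1's reduced affinity for 5hmC.
And h is terminal: 5fC/5caC read as T under both chemistries and are
observationally indistinguishable from u, so further oxidation is out of
scope; \(\eta\) is therefore "hydroxylation that stays visible as 5hmC".

Each sequenced molecule samples one cell from the population marginal, so
an observed dyad is a draw from the propagated distribution pushed through
the emission matrix of its treatment. Per strand, the probability of
reading T is the measured conversion rate of the strand's true state
(`p_T_C`, `p_T_5mC`, `p_T_5hmC`, per treatment); strands convert
independently, giving a 9 × 4 emission matrix over the read classes CC,
CT, TC, TT. Emission parameters come from the linker controls
(`linker_control_rates()`, `derive_emission_parameters()`) and are plugged
in as known constants, not co-estimated — they are directly measured per
sample, and letting them float would absorb genuine biology into the
error model. Per-amplicon rates are used when each control has ≥ 200
observations (the default minimum), otherwise rates are pooled across
amplicons.

`log_likelihood()` links the BS and oxBS channels through the shared
hidden chain: the initial distribution is propagated along the division
schedule, and at every observation time the two treatments' read-class
counts are scored as independent multinomials. The default schedule maps
the demethylating mouse ESC time course (serum/LIF day 0, then 2i at days
1, 3, 6) onto 0, 2, 6, 12 cumulative divisions, i.e. a 12 h cycle; the
cycle length is a configuration choice, not an estimate.

### Fitting

`fit_dyad_model()` maximises the joint likelihood over the efficiencies
and the 8-parameter initial distribution. The search space is made
unconstrained by a logit transform of each efficiency and a softmax of
the initial distribution; optimisation is BFGS with relative tolerance
1e-8 and seeded multi-start (default 20 starts). Two starts are guided:
a moment start that maps the day-0 BS class frequencies onto u/m states,
and a 5hmC-aware start that allocates per-strand h mass from the BS
minus oxBS read-C difference — without it, runs with small true \(\eta\)
occasionally settle on a boundary local optimum with \(\eta = 0\).
Efficiencies may be piecewise-constant per inter-observation interval
(the default) or shared across intervals; estimates within 1e-3 of 0 or 1
are flagged as boundary-pinned rather than hidden, because near-zero
de novo or hydroxylation activity is a real and reportable outcome.
Optional parametric bootstrap (refits warm-started from the MLE) gives
percentile intervals.

`hydroxylation_summary()` reports the 5hmC pairing classes — h opposite
unmodified C (uh + hu), h opposite 5mC (mh + hm), and symmetric hh — plus
strand totals; `naive_5hmC()` implements the baseline subtraction
estimator (BS level − oxBS level, overall and per class).

### Why the naive estimator is biased, and the demo that shows it

Ignoring conversion errors, BS − oxBS would equal the 5hmC level. With
the measured rates it does not: a 5hmC strand survives oxBS conversion
with probability ≈ 0.08 and falsely converts under BS with probability
≈ 0.07, so the subtraction recovers only ≈ 84% of the true 5hmC (about
−0.16·h, minus a small 5mC-rate asymmetry term). The model, which carries
the measured rates in its emission matrices, is consistent. The packaged
bias demonstration therefore runs at 20,000 molecules per treatment per
time point — deep enough that this structural bias dominates sampling
noise — and compares each estimator's mean absolute error of the total
5hmC trajectory against the simulation truth over 20 seeded replicates.
At typical amplicon depths the bias is the same order as per-time
sampling noise (both ≈ 0.005 at 5% 5hmC), which is exactly why the
model-based estimate, not a deeper sequencing run, is the practical fix.

## The simulator

`simulate_dataset()` generates the full experiment: dyad populations
drawn i.i.d. from the propagated chain, conversion chemistry applied per
strand with the configured emission parameters (linker controls
included), UMIs drawn uniformly over A/T/G, geometric PCR duplication
(rate r gives 1/(1−r) expected copies sharing one UMI and one converted
sequence), optional uniform post-conversion sequencing error, and paired
FASTQ with the ground-truth state table alongside. Defaults are frozen
to the study conditions the package models: a highly methylated starting
population (55% mm, 20% uu, 16% hemimethylated, ~5% of strands carrying
5hmC), efficiencies (μ, δ, η) = (0.8, 0.1, 0.05) per division, the Afp
amplicon's published conversion rates, 5000 molecules per time point per
treatment, and the d0/d1/d3/d6 schedule.

What the generator emulates: the dyad state process, both conversion
chemistries with realistic error rates, UMI-sharing PCR clones, and
read-pair structure over a composite reference. What it does not: indels,
position- or quality-dependent error profiles, chimeras, incomplete
digestion, strand-biased PCR, or correlated dyads along a molecule
(per-dyad independence is the default; a common-state mode exists for
pattern-map realism). Passing round-trip tests on simulated data
therefore validates the algorithmic chain — alignment, refolding,
deduplication, QC, estimation — not robustness to every artefact of real
libraries.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-coverage controls yield
`NA` rates with a warning (downstream requires a configured default),
dyads with no analysable molecule are flagged, empty pattern sets refuse
to render, a single observation time fits the initial distribution only
and refuses interval efficiencies, and negative naive 5hmC estimates are
reported with a warning, never silently clipped. Likelihood evaluation
returns −Inf (not an error) when a zero-probability class has a nonzero
count. Consensus ties — in mate overlap and in UMI groups — always
resolve to the non-committal value (N / unknown).

The validation suite runs at deliberately chosen sizes: exhaustive
enumeration oracles for the division and emission matrices (all 9 states,
up to 3 divisions, agreement to 1e-12); conversion-rate recovery at
n = 5000–10,000 simulated linker reads; parameter recovery at 5000
molecules × 4 time points × 20 replicates (median absolute error ≤ 0.05
for each efficiency); FASTQ round-trips at 120 molecules per treatment;
and the bias demo at 20,000 molecules as motivated above. These sizes
make the full suite complete in minutes on one core while keeping every
statistical check comfortably powered.

## Known limitations

* The hidden-state alphabet stops at 5hmC; experiments with appreciable
  5fC/5caC need an extended chemistry (and linker controls) this package
  does not model.
* Efficiencies are per-division constants within an interval; replication-
  independent demethylation or continuously varying enzyme activity is
  not represented.
* The default fit aggregates counts over an amplicon's dyads (per-CpG
  fitting is available but needs correspondingly more depth per CpG).
* UMI deduplication keys on the UMI alone; at extreme depths or very
  short UMIs, collisions deflate molecule counts.
* The aligner is an amplicon aligner: semi-global against one composite
  reference, no genome-wide mapping, no indel realignment.
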