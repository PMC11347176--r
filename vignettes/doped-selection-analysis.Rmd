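---
title: "Methods: doped-pool selection analysis and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doped-pool selection analysis and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dzkit)
```

dzkit implements the computational side of characterizing a deoxyribozyme
discovered by reselection from a doped library: simulating the library and
the selection, processing sequencing reads, reading conservation and
covariation out of the selected pool, testing a secondary-structure model,
and summarizing activity assays. This vignette records the models, the
parameters that matter, and the design decisions taken where the published
workflow leaves them open.

## The doping model

A doped library is synthesized from a reference sequence of length $L$ so
that each position independently carries a non-reference base with
probability $d$ (the doping rate), the alternative drawn from a
distribution over the three non-reference bases. `doping_model()` defaults
to $d = 0.21$ and a uniform alternative distribution ($1/3$ each): 21% per
position is the standard doping used for reselection libraries of this
kind, and the synthesis mixture is rarely reported, so uniformity is the
neutral choice; both are plain arguments. The doping model does double
duty: it generates synthetic pools (`sample_pool()`) and it is the null
hypothesis for every statistic that asks "could this happen in the
starting library?" — the covariation scan and the exact stem-pairing null.

On a 50,000-molecule pool the per-position non-reference frequency
recovers $d$ to within Monte-Carlo error (`estimate_doping_rate()`); this
is both a generator sanity check and the calibration of the estimator the
profile module applies to real tables.

## Selection as Bernoulli survival

`run_selection()` models one round as: every molecule survives
independently with probability equal to its activity; survivors are
resampled multinomially back to the pool size (unbiased, error-free
amplification); a fixed number of sequencing reads is drawn per round.
The experimental stringency knobs (incubation time, substrate
concentration) are deliberately absorbed into the activity scale of the
fitness model — the goal is to reproduce enrichment dynamics, not reaction
chemistry. Amplification carries no polymerase error model: at $d = 0.21$
the synthesis doping dominates all other sources of variation by orders of
magnitude.

The fitness model (`fitness_model()`) is the generative inverse of the
comparative analysis: a variant is fully active when it (i) stays within a
mismatch tolerance of the reference over a set of core positions and
(ii) can form at least a minimum number of pairs in each required stem;
otherwise it retains a small background activity (default 0.01, so that a
molecule's survival odds change by 100-fold, strong but not absorbing). A
graded variant (activity proportional to the fraction of satisfied
constraints) is available for power studies. The packaged
`apollon_fitness()` requires the conserved core at positions 1–8 and
34–64 (tolerance 3) plus most of Stem 1 (≥3 of 4) and Stem 3 (≥7 of 8) —
the constraint structure the selected-pool analyses then rediscover.

Desk scale: real selections start from $\sim 10^{14}$ molecules;
simulations here use pools of $10^4$–$10^5$ and sequencing depths of
$10^3$–$10^4$ reads per round. Quantities that depend on absolute
complexity (e.g. the number of distinct surviving lineages) are therefore
scaled down, and tests compare against expectations computed at the
simulated scale, never at the experimental one.

## Read processing

The `seqio` functions reimplement, at desk scale, the standard amplicon
chain: strict 4-line FASTQ parsing (errors name the offending line),
orientation unifying and primer clipping in one pass (`clip_and_orient()`,
Hamming matching only, default `max_mismatch = 2`), overlap merging
(`merge_pairs()`, longest qualifying overlap, higher Phred call wins
disagreements), and length filtering plus unique counting
(`filter_and_count()`). Two choices deserve note:

* **Substitution-only matching.** Doped synthesis produces
  substitution-only variants, so indel-containing reads are artefacts;
  they are removed by the length filter rather than aligned, which keeps
  1-based position indices meaningful across every downstream analysis.
* **Modal-length rule.** After filtering, only the modal surviving length
  is kept (ties resolve to the shorter length), because profiles,
  covariation and stem statistics all require one uniform length.

No quality trimming is applied (not part of the published chain), and
Phred+33 is assumed throughout.

## Conservation and the core

`build_profile()` tallies per-position base counts, read-weighted by
default — after selection, abundance carries the activity signal — with a
unique-sequence weighting offered because published logos rarely state
which was used. Information content is $IC = 2 - H$ bits with $H$ the
Shannon entropy of the four-base frequencies, no small-sample correction.
Note the useful landmark that an unselected column doped at 21% has
$IC \approx 0.93$ bits, while strongly conserved columns approach 2; the
default core threshold of 1.0 bit sits between them. (The packaged
recovery test uses 1.2 bits: with a few hundred effective founder
lineages, drift at unselected positions can graze 1.0.) Consensus ties
resolve deterministically in A<C<G<T order and are flagged.

## Covariation and mutant cycles

The pair statistic is mutual information of the joint base distribution,
with two companions that make "covaries like a base pair" explicit: the
pairing-consistency fraction (among reads deviating from the reference at
*both* positions, the weighted fraction whose bases are complementary —
compensatory pairs score 1) and a Monte-Carlo null. The null draws
`n_null` unselected pools of matched read count from the doping model and
reports the fraction with MI at least the observed value; this is exactly
the "random subsets of the starting library" argument in distributional
form. Benjamini–Hochberg q-values are reported across the
$L(L-1)/2$ pairs. Null pools are capped at 5,000 reads, which bounds scan
cost at full length ($L = 85$, 100 nulls, ~25 s on one CPU) without
visibly changing the null.

Two properties are worth keeping in mind when interpreting scans. First,
conservation suppresses covariation: a stem whose positions are nearly
invariant cannot covary, which is why stem support in real datasets comes
from mutant cycles and spectroscopy instead. The planted-pair recovery
tests therefore use a stem-only fitness, where all planted pairs rank
above every non-paired position pair. Second, selection plus round
bottlenecks generate genuine (lineage) correlations between unpaired
positions; the doping null calibrates against the starting library, not
against drift, so q-values from deeply bottlenecked pools should be read
comparatively, not literally.

Mutant cycles use the interaction ratio
$R = (A_{12} A_{wt})/(A_1 A_2)$, with rescue declared at $R \ge 5$ and an
independence band of $[1/2, 2]$ (the published rule "aggravating when
$R < 1$" collides with "independent when $R \approx 1$"; the band
resolves the boundary symmetrically). Triple cycles use the
inclusion-exclusion analogue over the $2^3$ cube. Zero activities are
floored at $10^{-3} A_{wt}$ (flagged) so ratios stay defined.

## Structure bookkeeping

A `structure_model()` is a list of typed position pairs (canonical or
G–T/T–G wobble) grouped into named stems. The pairing potential of a
variant is the number of stem pairs whose bases are complementary; G–T
counts by default because the published model itself contains four such
pairs. Under the doping model the per-pair complementarity probability is
computed by exact enumeration of the 16 dinucleotide outcomes, and the
number of formable pairs is exactly Poisson-binomial (sequential
convolution), giving closed-form tails for "how unlikely is this much
pairing by chance". For an 8-pair stem at $d = 0.21$ the per-pair
probabilities are ≈0.70 (canonical reference pairs) and ≈0.75 (wobble
reference pairs), and $P(k \ge 7) \approx 0.31$ — so a *single* random
variant passes easily, and the evidential weight comes from *all* abundant
variants passing jointly (probability $\mathrm{tail}^m$ for $m$
independent variants, an identity the tests verify by simulation).

Imino-proton expectations follow the tautomer rule: one signal per
canonical pair, two per wobble. The packaged model (12 canonical + 4
wobble) therefore predicts 20 signals, and 16 after `delete_stem()`
removes the four canonical Stem 2 pairs. These counts depend only on the
printed pair composition, not on coordinates. The packaged coordinates
and the 85-nt reference are a synthetic reconstruction — built so every
stem is fully formable on its own reference — and are labelled as such;
any analysis of the real isolate must supply its own structure table.

## Kinetics and assay statistics

`fit_mm()` fits $V_0 = V_{max}[S]/(K_m + [S])$ by Levenberg–Marquardt
least squares with parameters on the log scale (positivity without
constraints), then derives $k_{cat} = V_{max}/[E]$,
$k_{cat}/K_m$, and $k_{obs}(S) = k_{cat}S/(K_m+S)$. The log-scale choice
is not cosmetic: in the non-saturating regime ($K_m$ far above the tested
range) $V_{max}$ and $K_m$ are nearly collinear and the standard `nls`
wrapper aborts on a noticeable fraction of replicates, while raw LM on
log-parameters converges and reports honest (possibly `NA`) standard
errors from the Jacobian. Fits flag `non_saturating` when the fitted
$K_m$ exceeds the largest tested $[S]$ — in that regime only the
efficiency ratio is well identified, which is why the replicate studies
report $k_{cat}/K_m$ and $k_{obs}$ rather than $V_{max}$ or $K_m$
separately. Starting values are $V_{max,0} = \max V_0$,
$K_{m,0} = \mathrm{median}[S]$ (Hill: $n_0 = 1.5$); convergence tolerance
$10^{-14}$ on the relative criteria.

The packaged kinetic presets put the optimized variant at
$k_{cat}/K_m = 200\ \mathrm{M^{-1}min^{-1}}$ and the parent isolate
10-fold lower, at $[E] = 1\ \mu M$ with $K_m = 50$ mM — far above the
1.5 mM maximum tested substrate concentration, consistent with the
observed failure to saturate. With these values
$k_{obs}(1.5\ \mathrm{mM}) \approx 0.29\ \mathrm{min^{-1}}$; note that an
efficiency of exactly 200 and a $k_{obs}$ of exactly 0.3 cannot hold
simultaneously at any finite $K_m$, so the preset matches the efficiency
exactly and the rate to within 3%. Synthetic datasets use 8
concentrations log-spaced over 1 µM–1.5 mM with 5% relative Gaussian
noise (rates truncated at zero), and replicate studies use 50 seeded
replicates with medians reported.

The Hill equation is the three-parameter form with the bottom fixed at
zero, $y = \mathrm{top}\cdot x^n/(k_{1/2}^n + x^n)$; cooperative metal
dependence appears as $n > 1$. Signal-to-noise and fold-activation both
subtract the buffer blank from numerator and denominator before taking
the ratio (and are therefore invariant to adding a constant to all three
absorbances); turnover counts are the ratio of the background-subtracted
bimolecular signal to the single-turnover unimolecular control; the
detection limit is the smallest tested concentration whose mean signal
exceeds blank $+ 3\sigma_{blank}$ — a statistical rule chosen here
because published limits are typically stated without one. Beer–Lambert
conversion takes the molar absorptivity as an argument; no value is
hard-coded.

## What the synthetic data do and do not show

The generator reproduces: the doping statistics of the starting library,
selection-driven enrichment of constraint-satisfying variants (including
the sigmoidal survival trace across rounds), compensatory covariation at
planted stems, conservation at planted cores, and construct-length
bookkeeping (85-nt insert + 20-nt primer site = 105 nt; +20-nt ligated
tag = 125 nt). It does not model: reaction chemistry or incubation-time
stringency (absorbed into activity levels), polymerase or sequencing
error, ligation/gel-recovery yields, thermodynamic folding, or
experimental pool complexity. Consequently, passing tests demonstrate
that the analysis code measures what it claims on data with known ground
truth — they do not re-derive wet-lab quantities such as melting-point
shifts, NMR spectra, or absolute signal-to-noise, which are not
recomputable from sequence data.

## Problem sizes

The packaged tests and the acceptance script run, on one CPU, with:
50,000-molecule pools for doping-rate recovery; 20,000–30,000-molecule
pools, 3 rounds, 5,000–20,000 reads per round for selection analyses;
100-null covariation scans (40 seeded scans of an 8-nt instance for the
calibration check); 20,000-draw Monte-Carlo checks of the exact
Poisson-binomial; and 50–200 seeded kinetic replicates. These sizes were
chosen so every statistical comparison has comfortable Monte-Carlo margin
at desk scale.
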