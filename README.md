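# dzkit

Analysis toolkit for doped-pool *in vitro* selection experiments on
catalytic DNA, built around the characterization workflow of the
self-phosphorylating, colorimetric deoxyribozyme Apollon: a 85-nt doped
library (21% per-position mutagenesis of a parent isolate) is carried
through selection rounds, the surviving pool is read out by
high-throughput sequencing, and the sequence data are mined for
conservation, covariation and secondary structure, while activity assays
are summarized with enzyme-kinetic and signal statistics.

The package is tidyverse-native: user-facing functions take data frames
and return tibbles, so stages chain with the pipe; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` views.

## What it computes

* **Read processing** (`read_fastq()`, `clip_and_orient()`,
  `merge_pairs()`, `filter_and_count()`): a native desk-scale version of
  the amplicon pipeline — orientation unifying, Hamming primer clipping,
  overlap merging, length filtering, unique-sequence counting.
* **Doped-pool simulation** (`doping_model()`, `sample_pool()`,
  `run_selection()`): each position of the reference mutates independently
  with probability *d* (default 0.21); selection is Bernoulli survival
  with probability equal to a variant's activity under a
  conservation/stem-based `fitness_model()`, with unbiased multinomial
  amplification between rounds.
* **Conservation profiles** (`build_profile()`, `information_content()`,
  `consensus_and_core()`, `estimate_doping_rate()`): per-position base
  counts, logo-style information content `IC = 2 − H` (bits), core calling
  by IC threshold, and doping-rate recovery.
* **Covariation** (`covariation_scan()`, `mutual_information()`,
  `pairing_consistency()`, `mutant_cycle()`): mutual information of
  position pairs against a Monte-Carlo null of unselected doped pools,
  the fraction of double-deviant reads that remain complementary, and
  double/triple mutant-cycle interaction ratios
  `R = (A_m12·A_wt)/(A_m1·A_m2)`.
* **Structure bookkeeping** (`structure_model()`, `formable_pairs()`,
  `stem_statistic()`, `null_pairing_distribution()`,
  `expected_imino_signals()`): stems as typed base pairs (Watson–Crick or
  G–T wobble), pairing potential of variants, an exact Poisson-binomial
  null for the number of formable pairs under the doping model, and
  expected imino-proton signal counts (1 per canonical pair, 2 per
  wobble).
* **Kinetics and assays** (`fit_mm()`, `fit_hill()`, `signal_to_noise()`,
  `turnovers()`, `detection_limit()`): Michaelis–Menten
  `V0 = Vmax[S]/(Km+[S])` with `kcat = Vmax/[E]` and
  `kobs(S) = kcat·S/(Km+S)`, Hill cooperativity
  `y = top·x^n/(k½^n + x^n)`, background-subtracted signal ratios,
  turnover counting and blank+3·SD detection limits.

The packaged 85-nt reference and stem coordinates
(`apollon_reference()`, `apollon_structure()`) are a synthetic
reconstruction that satisfies the published pair composition (three
stems; 12 canonical + 4 G–T/T–G pairs); the true isolate sequence is not
bundled.

## Worked example

```r
library(dzkit)

ref   <- apollon_reference()
model <- doping_model(ref, rate = 0.21)

# an unselected doped pool recovers its own synthesis rate
pool <- sample_pool(model, 50000, seed = 1)
estimate_doping_rate(build_profile(pool), ref)
#>   estimate       se n_positions
#> 1    0.210 0.000168          85

# three simulated reselection rounds enrich structure-forming variants
sel <- run_selection(model, apollon_fitness(), apollon_structure(),
                     pool_size = 20000, rounds = 3,
                     reads_per_round = 20000, seed = 11)
sel$summary
#>   round survival unique_sequences total_reads
#> 1     1   0.0248              495       20000
#> 2     2   0.606               342       20000
#> 3     3   0.993               298       20000

# every abundant survivor can still form >= 7 of the 8 Stem 3 pairs,
# although a random doped variant does so with probability only ~0.31
stem_statistic(sel$tables[[3]], apollon_structure(), "Stem3",
               read_floor = 40)$min_k
#> 7
nd <- null_pairing_distribution(model, apollon_structure(), "Stem3")
nd$distribution$tail[nd$distribution$k == 7]
#> 0.306

# kinetic fit of a noisy synthetic dataset (1 uM enzyme, 1 uM - 1.5 mM pNPP)
d <- simulate_kinetics(apollon_kinetic_preset("apollon2"),
                       c(1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 1.5e-3),
                       noise_sd_frac = 0.05, seed = 42)
fit <- fit_mm(d)
glance(fit)$efficiency      # kcat/Km, M^-1 min^-1
#> 226.9
kobs_at(fit, 1.5e-3)        # min^-1
#> 0.293
```

The survival trace mirrors the sigmoidal enrichment of a reselection
(activity detectable after round 1, near-complete survival by round 3).
The non-saturating fit leaves `Vmax` and `Km` individually poorly
determined (the fit flags `non_saturating`), but their ratio — the
catalytic efficiency — and the derived `kobs` are stable.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/dzkit.R` (stages `simulate-pool`, `select`,
`process-reads`, `profile`, `covary`, `stems`, `fit-kinetics`,
`assay-stats`, driven by YAML configs; see `?run_stage`).

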