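---
title: "Calling translational shifts from polysome-profiling microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling translational shifts from polysome-profiling microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyshift)
library(dplyr)
library(tidyr)
```

## The experimental design this package models

Polysome profiling separates a cell's mRNA by how many ribosomes it
carries: a sucrose gradient is fractionated into a non-polysomal pool (NP:
free RNPs, 40S/60S subunits and 80S monosomes) and a polysomal pool (P:
transcripts loaded with two or more ribosomes). A transcript whose
initiation is impaired slides out of P and accumulates in NP without any
change in its total abundance (T); a transcript recruited more avidly does
the opposite. Comparing a mutant line of the cap-binding initiation factor
eIF(iso)4E against wild type, each RNA pool is hybridized on a two-color
microarray (mutant in channel 1, wild type in channel 2), and genes are
sorted into:

* **Group I** — translationally inhibited: down in P *and concomitantly* up
  in NP, unchanged in T;
* **Group II** — translationally enhanced: up in P and down in NP,
  unchanged in T;
* transcriptionally changed (|z| in T beyond a cutoff), which overrides a
  concomitant call;
* unchanged otherwise.

The package implements that analysis chain end to end — spot tables to
M/A values, intensity-dependent z-scores, the concomitant-shift classifier,
qRT-PCR quantitation, UTR feature scans and a microarray-vs-qPCR
concordance report — plus a synthetic-data generator that plants known
Group I/II genes so the whole pipeline can be validated in a closed loop.

## Preprocessing: spot intensities to normalized log-ratios

Per spot, each channel's background is subtracted locally
(`subtract_background()`). Spots where a channel goes non-positive are
flagged and *excluded*, not clamped to a floor: a fabricated small
intensity would fabricate a large ratio. The intensity filter
(`intensity_filter()`) drops a spot only when **both** channels fall below
the threshold (default: twice the median background), because a spot that
is dim in one channel only may be a genuine strong ratio. Log-ratios
`M = log2(I_mut / I_wt)` and mean intensities `A = (log2 I_mut + log2
I_wt) / 2` are computed per spot and duplicate spots are averaged on the
M/A scale, after the log transform, since the ratio is the modeled
quantity (`compute_ma()`).

Dye incorporation bias depends on intensity, so `lowess_normalize()`
subtracts a robust locally weighted regression of M on A (`stats::lowess`,
span 0.4, 3 robustness iterations — a common two-color default; the span is
a parameter). Nothing else is done to the data: no print-tip stratification
and no variance stabilization, which keeps the chain minimal and auditable.

## The intensity-dependent sliding-window z-score

Ratio variance on a two-color array shrinks with intensity, so a global
z-score over-calls dim spots and under-calls bright ones. Instead each
gene's normalized M is standardized against its intensity neighbourhood:
genes are ordered by A, and for each gene the mean and sample standard
deviation of M are taken over a window of `window_size` genes (default 50)
of nearest A-rank, the focal gene included:

$$z_i = \frac{M_i - \mathrm{mean}(M_\mathrm{window})}{\mathrm{sd}(M_\mathrm{window})}.$$

Design choices worth knowing:

* **Window in rank space, not A-width.** A fixed point count behaves
  robustly where intensities are sparse; 50 points estimate an SD with
  about 10% relative error, a reasonable floor for a 1.5-SD decision rule.
* **Edges.** Windows are centered in the interior and slid inward at the
  edges so every gene is judged against a full-size window; there is no
  wraparound or reflection, and edge genes are flagged `edge_window`. With
  `window_size = n` the score reduces exactly to the global
  standardization, a useful degenerate case for testing.
* **Sample (n−1) SD**, appropriate for small windows.
* **Ties in A** are broken by gene id, so output is reproducible to the
  byte.
* **Degenerate windows.** A window whose SD is zero — or within floating
  point of zero relative to the table's M scale (`sd <= 1e-10 * max(1,
  max|M|)`) — yields `z = 0` and a `degenerate_window` flag. The relative
  guard matters on noise-free synthetic data, where smoothing residuals of
  order 1e-15 would otherwise be amplified into arbitrarily large scores.

Replicates are combined by averaging z per gene and fraction
(`combine_replicates()`); sign-discordant replicates are flagged
`discordant` but still averaged, and genes seen in a single replicate are
flagged rather than dropped. The classification (`classify_shifts()`) uses
inclusive cutoffs at |z| = 1.5 for the NP/P shift — chosen so that a
published table row with z = 1.58 or 1.6 is a member — and a configurable
total-RNA exclusion at |z| > 2.0, the transcriptome cutoff. A missing total
z (gene not detected on the total array) cannot exclude a gene. When both
the concomitant rule and the total rule fire, the gene is
`indeterminate` with both reasons recorded rather than silently assigned.

```{r}
classify_shifts(tibble::tibble(gene_id = "PHO1",
                               z_NP = 1.58, z_P = -2.3, z_T = 0.59))
```

## Validation against the packaged qPCR comparison table

`load_table1_fixture()` ships a 23-gene table of combined microarray
z-scores (T, NP, P) alongside eIF4A-normalized qRT-PCR signed fold changes
measured on an independent biological sample, with each row's printed
outcome (`Decrease`, `Increase`, or `l.c.` for lack of correspondence).
The concordance rule (`concordance()`) is sign agreement in the **P
fraction only**. That rule is an inference, not a published formula: rows
with discordant NP but concordant P are printed as validated, while all
three `l.c.` rows disagree in P — P-sign agreement is the only simple rule
consistent with every printed label, and the package test suite enforces
exactly that (20 of 23 validated, 87% confidence, the three failures being
the `l.c.` rows).

```{r}
confidence_level(load_table1_fixture())[c("n_validated", "n_total",
                                          "confidence_percent")]
```

## qRT-PCR quantitation

Three standard quantities, implemented exactly:

* `relative_expression()` — the efficiency-corrected ratio
  $R = E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}$ with
  $\Delta Ct = Ct_{control} - Ct_{sample}$ and efficiencies in (1, 2].
  With both efficiencies 2 this is algebraically $2^{-\Delta\Delta Ct}$.
* `quantity_2_delta_ct()` — $2^{-\Delta Ct}$ relative concentrations.
* `fraction_distribution()` — a gene's percentage distribution across
  gradient fractions (NP / M / LP / HP in the fine scheme), taking the sum
  over all assayed fractions as that gene's total: $q_f = E^{-Ct_f}$,
  replicates averaged on the linear quantity scale (percentages are
  linear-scale statistics), then $100\,q_f / \sum q$. An unaffected
  control transcript (e.g. eIF4A) can divide each fraction's quantity
  before the percentage step to correct per-fraction recovery; both
  normalized and raw modes are available because published per-fraction
  profiles do not always state which was used.

Signed fold changes follow the reporting convention `r >= 1 -> +r`,
`r < 1 -> -1/r`. Unmeasured primer efficiencies default to 2.0 and flag
the profile `default_efficiency`.

## UTR features

5'UTR length and structure bias cap-complex selectivity, so the classifier
output feeds a feature scan over UTR sequences (`annotate_utrs()`):
length classes (>= 100 nt, inclusive), upstream AUGs, upstream ORFs (an
in-frame stop wholly inside the UTR, at least one internal codon by
default), folding stability, and motif hits. Coordinates are 1-based
inclusive in all outputs; U and T are interchangeable on input and
sequences are reported as RNA.

The built-in folding engine (`fold_mfe()`) minimizes a deliberately simple
energy over all nested structures by dynamic programming: GC −3, AU −2,
GU −1 kcal/mol per pair, +4 per hairpin loop, minimum loop 3, no stacking
or multiloop terms. It is a thresholding surrogate, not a thermodynamic
predictor: its energies are not on the scale of nearest-neighbour programs
(mfold/RNAfold), so the −20 kcal/mol stability threshold is meaningful
only per engine, and the engine name is stamped into every output row. A
user-supplied function can replace it where a real folding program is
available. Two properties anchor the implementation: exhaustive
enumeration over all nested structures reproduces the DP exactly for short
sequences, and reverse complementation preserves the minimum energy on
alphabets without wobble-capable bases (GU maps to the unpairable AC under
reverse complement, so the symmetry genuinely holds only there — e.g. pure
GC or pure AU content).

The default motif registry matches the CPE consensus `UUUUUAU` literally
in 3'UTRs and flags "IRES-like" 5' segments as any window of >= 25 nt with
>= 80% pyrimidine content. Both are documented stand-ins — the descriptor
languages of UTRScan/RegRNA are not reproduced — and both are fully
overridable. `summarize_utr_table()` assembles group-level percentage
tables with a seeded random-accession baseline (default 80 accessions,
length and stability columns only).

The full-length filter (`filter_full_length()`) can either keep or drop
the accessions on a reference list; curated ORF lists are used both ways
in practice, so the mode is explicit and `keep_listed` (retain verified
full-length entries) is the default.

## The synthetic-data generator

Every stage is tested against planted truth, so the generator is
first-class code, not a fixture. Its defaults are the package's statement
of a realistic desk-scale experiment:

* 1000 genes, 2 biological replicates, fractions NP/P/T;
* per-gene abundance $2^{N(10, 1.5^2)}$ against an additive background of
  50 fluorescence units — about 99% of spots clear the default intensity
  filter, the detection regime of a typical two-color experiment;
* independent lognormal channel noise, SD 0.25 in log2 units (arrays of
  this vintage rarely did better; the value is ours, the source experiment
  published no noise figure);
* a linear intensity-dependent dye bias `0.5 + 0.1 * A` added to the
  mutant channel, the minimal trend Lowess must remove;
* planted universe of 50 Group I and 30 Group II genes with a 1.5 log2
  shift applied with opposite signs to NP and P (transcriptional classes
  can be planted explicitly and move every pool including total);
* one fixed channel orientation (mutant = channel 1); no dye swaps, no
  print-tip structure, no image-level simulation.

Ct tables are generated as `Ct = intercept − log_E(abundance) + noise`
from per-fraction abundances consistent with the planted classes, and UTR
sets plant feature cassettes (uAUG, a minimal AUG-AAA-UAA uORF, a 10-bp GC
stem hairpin folding to −26 kcal/mol under the built-in model) into an A/G
background that can form no base pair, start or stop codon — so a feature
is present exactly where it was planted, and scanner output can be
compared to truth without tolerance.

What passing these closed-loop tests shows — and does not show: the
pipeline recovers exactly the signal structure it models (symmetric
shifts, lognormal noise, smooth dye bias, additive background). Real
arrays add spatial artifacts, saturation, probe cross-hybridization and
non-lognormal tails that the generator deliberately omits; performance
numbers from the synthetic runs are statements about the method's
correctness and its behaviour under the stated noise model, not about any
particular wet-lab dataset.

## Performance under the reference conditions

Under the generator defaults (1000 genes, 2 replicates, effect 1.5 log2,
noise 0.25, cutoffs 1.5/2.0, window 50), recovery of the planted
Group I/II genes averages ~0.94 sensitivity with zero false discoveries
across seeds; the test suite requires sensitivity >= 0.90 and
false-discovery proportion <= 0.10 over five seeds. With noise switched
off the full chain recovers every planted class exactly. The Lowess
property (per-A-decile mean residual below 0.05) is measured on a
10,000-gene array, sized so that decile sampling noise
(~0.25·√2/√1000 ≈ 0.011 per decile) sits well below the bound being
tested.

Problem sizes throughout the suite (up to 10,000 genes, window oracles at
n ≤ 200, folding oracles at length ≤ 12, 100-sequence UTR pools) were
chosen as the smallest at which each property is measured with adequate
precision.

## A complete run

`run_pipeline()` executes the configured stages in order and writes every
intermediate table (TSV with a version + config-hash header), the
serialized configuration, a log, and a machine-readable `summary.json`
into a run directory; identical configurations reproduce identical
summaries.

```{r, eval = FALSE}
cfg <- run_config(out_dir = "polyshift_run", seed = 1)
summary <- run_pipeline(cfg)
summary$stages$classify$call_counts
```

## Known limitations

* The built-in folding model ranks stability; it does not predict real
  free energies. Use the pluggable engine for thermodynamic work.
* The IRES-like and CPE descriptors are consensus stand-ins.
* The concordance rule is reverse-engineered from a printed table; it is
  enforced by tests against that table but has no published derivation.
* The classifier's total-RNA exclusion threshold (default 2.0) is
  configurable because the boundary between "unchanged at steady state"
  and the transcriptome cutoff is not uniquely determined; results at
  |z_T| between 1.5 and 2 depend on this choice.
* GEO series imports are out of scope; the package consumes spot-level
  TSVs and FASTA files.
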