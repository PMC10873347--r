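---
title: "Models and methods behind the cofilin N-terminal screen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cofilin N-terminal screen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofilinscreen)
```

## The experiment being modeled

Cofilin-1 severs and depolymerizes actin filaments; its short disordered
N-terminus (residues 2–5, Ala-Ser-Gly-Val in humans) both mediates actin
binding and carries the Ser3 phosphosite through which LIM kinase (LIMK)
inactivates it. The screen expresses a combinatorial library of N-terminal
variants — positions 2, 4 and 5 randomized over all twenty amino acids,
position 3 restricted to Ser or Thr, 20³ × 2 = 16,000 sequences — in yeast
whose endogenous cofilin is repressed, so growth depends on the variant's
ability to sever actin. Growth in glucose keeps LIMK off; switching to
galactose induces it, so variants that remain good LIMK substrates are
phosphorylated, inactivated and outcompeted.

The pipeline covers the computational arc of that experiment: amplicon
reads → variant counts → log2 enrichment scores → kinase-sensitivity
quadrants → positional statistics (heat maps, probability logos,
covariation) — plus the curve fitting used for the accompanying
biochemistry (actin-binding K~0.5~, LIMK Michaelis–Menten kinetics).

## The competitive-growth model

Selection is modeled as deterministic exponential competition in continuous
"pooled doublings". After `d` doublings a variant with relative growth rate
`w` (doublings per wild-type doubling) changes abundance as

$$ f_v(d) \propto f_v(0)\, 2^{\,w_v d}, $$

renormalized so frequencies sum to 1. Each growth–dilution cycle (OD 0.1 →
1–2, then dilution back) contributes `doublings_per_cycle = 3.5` pooled
doublings; three cycles span the screen's ~10 doublings. Sampling
timepoints are the shared start (T0) and the end of each cycle (T1–T3) in
each sugar. Dilutions are deterministic by default; an optional binomial
bottleneck (`bottleneck_size`) adds drift for robustness studies — the
experimental description gives OD windows, not bottleneck stochasticity, so
it is off by default.

Kinase induction is not instantaneous: depletion of phosphorylatable
variants lags induction by one to two doublings. The simulator encodes this
as `induction_lag_cycles = 1`: the galactose arm grows with glucose fitness
through its first cycle and with `w_gal` thereafter. This is also why the
kinase contrasts compare T1 to T3 rather than T0 to T3.

Sequencing is a multinomial draw per sample at `depth` reads (default 10⁶,
about 60× per variant), matching how finite-depth counting perturbs
low-frequency variants. Read emission writes one amplicon per counted
molecule — 5′ anchor, 12-nt variable region, 3′ anchor — with uniform
per-base substitution errors only; indels are not modeled because they
break exact anchor framing on a 12-nt core and would simply inflate the
rejection classes. One fixed codon per residue is used at positions 2/4/5
(trimer-codon compositions of synthesized pools are rarely disclosed; the
table is documented in
`DEFAULT_CODON_TABLE`), and position 3 uses strictly ACC (Thr) / AGC (Ser),
the mixture actually synthesized.

## The empirical fitness preset

`build_fitness_map("empirical", seed)` is the generator's ground truth and
defines the study conditions for all recovery tests. It encodes the
screen's qualitative findings as main effects: position 5 requires
aliphatic/β-branched residues (base `w_glu` 1.0, partially tolerated
aromatics/small residues 0.55, charged/others 0.15); charged residues or
proline at position 4 multiply fitness by 0.3; position 2 is nearly
indiscriminate (±0.03); the Gly4–Val5 pair carries a +0.10 synergy
mirroring the observed covariation of that pair. A per-variant Gaussian
jitter (sd 0.08 doublings/doubling) makes fitness values distinct — the
scale matches the several-log2-unit spread of scores among functional
variants in real screens; much smaller jitter would make neighboring ranks
physically indistinguishable at any sequencing depth. Phosphoregulation is
binary: Ser3 variants without a bulky position-4 residue (Leu/Phe/Trp) have
`w_gal = 0.1 w_glu`; Thr3 variants and shielded Ser3 variants keep
`w_gal = w_glu`.

What the generator does *not* emulate: PCR amplification bias, plasmid
copy-number variation, graded (non-binary) phosphorylation kinetics in
vivo, position-3-specific growth effects, and higher-order epistasis beyond
the single built-in pair. Passing recovery tests therefore demonstrates
that the scoring and classification machinery inverts the generative model
faithfully at realistic depth and replication — not that every feature of
real screen data is captured.

## Scoring

Relative representation is a variant's reads over the sample's valid
on-design reads; rejected reads (anchor/frame/codon failures, off-design
position-3 codons) are excluded from the denominator since representation
is defined over library members. A pseudocount (default 0.5 per variant per
sample) keeps log-ratios finite; the right zero-count policy depends on
unknowable details of a given screen, and 0.5 gives minimal shrinkage
while avoiding dropouts. With `pseudocount = 0`, affected scores are flagged `NA` and
excluded from ranking.

Contrasts follow the screen's design: the *function* score is glucose
T0 → T2 (~6–7 doublings, beyond which changes flatten); the two *kinase*
axes are T1 → T3 in glucose and galactose. Scores are means of per-replicate
log2 ratios (an average of log fold changes, not the log of averaged
ratios); ranking is descending on the mean with lexicographic tie-breaks so
repeated runs are bit-identical; the enriched set uses strict `> 0`.

Quadrant classification gates "functional" on the glucose T1→T3 axis (the
axis the scatter plots use) with the T0→T2 enrichment flag reported
alongside, and calls a functional variant *sensitive* only on strict
galactose depletion — a tie at exactly 0 is resistant. The margin
parameter (default 0) allows a dead zone about the origin for noise-robust
calling.

## Positional statistics

Heat maps average the mean log2 fold change over the 800 sequences
(positions 2/4/5) or 8000 (position 3) carrying each residue; "fold change"
summaries are computed on the log2 scale throughout, consistent with the
box-plot axes and the per-variant tables (a linear-fold option would be a
trivial transform but is not exposed). Box statistics report the
10th/25th/50th/75th/90th percentiles with linear interpolation between
order statistics (`quantile` type 7); the convention only marginally
affects whiskers.

Probability logos use exact binomial tails, never a normal approximation:
for residue count `k` among `n` foreground sequences against background
probability `p` (exact design composition: 1/20 at positions 2/4/5, 1/2 at
position 3), the letter height is `−log10 P(X ≥ k)` when over-represented
and `−(−log10 P(X ≤ k))` when under-represented. Tail probabilities are
floored at the smallest positive double so heights stay finite. The
significance threshold is `−log10(α/m)`; the Bonferroni divisor defaults to
the 62 tested cells (20 + 2 + 20 + 20) — probability-logo tools differ in
their per-dataset conventions, so `bonferroni_m` is exposed for
sensitivity checks. An observed-T0 background can be supplied in place of
the design composition.

Covariation asks whether a residue pair occurs in a selected set more often
than its positional marginals predict: expected `N p_i(a) p_j(b)` with
marginals from the selected set itself (testing linkage *within* the set;
full-library marginals can be supplied by passing a different selected
set), exact two-sided binomial p-values, and Bonferroni correction over all
tested cells across the requested position pairs. Estimating marginals from
the same set makes the test mildly conservative, which the null-calibration
test (independently drawn sets, family-wise false-positive rate ≤ α)
confirms. "Most enriched" sets are taken by mean-score rank.

## Biochemical fits

*Binding.* The "model-independent sigmoidal dose-response" is the
four-parameter variable-slope logistic with K~0.5~ read directly as the
midpoint and the Hill slope a free nuisance parameter; plateaus are fit per
curve (sharing across variants is not assumed). Fitting uses
Levenberg–Marquardt on the residual function directly, with starting values
from the dose-extreme signals and the interpolated half-max crossing. K~0.5~
confidence intervals come from a seeded case-resampling bootstrap
(default 1000 resamples; percentile interval), a distribution-free default
that makes no assumption about the error model. Simulated curves place a two-fold dilution series across
K~0.5~ × 2^±4 plus a zero-dose point, in triplicate, with 5% multiplicative
noise, and a default true slope of 2 (cooperative filament binding).

*Kinetics.* Per-substrate rates are ordinary least squares through the
origin over the 5/10-min points (the whole time course), then
`v = V_max S/(K_M + S)` is fit with 1/rate² weights — radiolabel
quantification errors are multiplicative, so proportional-error weighting
keeps low-substrate rates informative and makes the reported standard
errors consistent with the noise; `kcat = V_max/[E]`. The simulator
enforces initial-rate validity (product ≤ 10% of substrate) and refuses
specifications that violate it. Standard-curve calibration is a
least-squares line through the origin over the 2.5/5/10 nCi standards.

## Problem sizes and numerical choices

Recovery tests run the full 16,000-variant pool, 3 replicates, at depth
10⁶ reads/sample (the screen's scale is easily simulated exactly);
FASTQ round-trip checks use a few thousand reads, which already exercise
every code path. Interval-calibration checks use 100 seeded noisy curves
per preset with 400 bootstrap resamples each — coverage estimates change
negligibly beyond that. Covariation null calibration uses 200 independent
sets of 400 sequences. Degenerate inputs (empty foregrounds, all-zero
samples, flat curves, fewer than five doses, both gel bands zero) are
errors, not silent results; read-level rejections are data, tallied in QC,
and never errors.

## Known limitations

The generator's binary phospho-sensitivity and class-structured fitness
make quadrant recovery cleaner than real data, where effects are graded.
Enrichment scores are relative: a variant is "enriched" only against the
population mean growth, so the enriched-set size depends on the fitness
distribution, not only on which variants function. Scores from
two-timepoint ratios ignore intermediate timepoints by design (no
regression-based fitness estimation, no variance shrinkage across
variants). The covariation test is pairwise only; three-way epistasis is
out of scope.
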