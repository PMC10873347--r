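# cofilinscreen

Analysis pipeline for a dual-functionality deep mutational scan of the
cofilin-1 N-terminus. The screen expresses all 16,000 variants of residues
2–5 (positions 2/4/5 over the twenty amino acids, position 3 Ser or Thr) in
yeast that depend on the variant for actin severing, with or without
induction of LIM kinase (LIMK), which phosphorylates Ser3 and inactivates
cofilin. This package implements the full computational path for such a
screen, and the curve inference for the accompanying biochemistry, for
anyone analyzing pooled competitive-growth selections of short sequence
libraries:

- **Synthetic screen generator** — ground-truth fitness landscapes over the
  16,000-variant design space, deterministic serial-dilution exponential
  competition (`f_v ∝ f_v(0)·2^(w_v·d)`, renormalized; 3.5 doublings/cycle,
  3 cycles), multinomial sequencing at finite depth, amplicon FASTQ
  emission with substitution errors, and noisy binding/kinetics curves —
  so every downstream stage is testable against known truth.
- **Variant counting** — anchor-delimited extraction of the 12-nt variable
  region, standard-genetic-code decoding (position-3 codons restricted to
  the ACC/AGC design), and QC that partitions every read.
- **Enrichment scoring** — relative representation with pseudocounts,
  per-replicate log2 fold changes for the function contrast (glucose
  T0→T2) and kinase contrasts (T1→T3 in glucose/galactose), replicate
  means, deterministic ranks, and the strictly-positive enriched set.
- **Quadrant classification** — functional variants strictly depleted
  under LIMK induction are *sensitive*; the rest *resistant*; summaries
  stratified e.g. by the Ser/Thr phosphoacceptor.
- **Sequence statistics** — residue-position heat maps (800/8000 sequences
  per cell), box statistics, exact-binomial probability logos with a
  Bonferroni threshold (`height = ±(−log10 binomial tail)`), and pairwise
  residue covariation against positional independence.
- **Biochemical fits** — four-parameter sigmoidal dose-response for actin
  binding (K_0.5 as the midpoint, bootstrap CIs), radiolabel standard-curve
  calibration, Michaelis–Menten kinase kinetics (kcat, KM with SEs),
  WT-normalized rates, and Phos-tag phospho-fractions.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on a
simulated screen and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_screen.R
Rscript analysis/03_score_enrichment.R
Rscript analysis/04_classify_quadrants.R
```

which prints, for the default seeds:

```
ASGV (WT-like, Ser3): w_glu 1.11, w_gal 0.11
ATGV (Thr3):          w_glu 1.16, w_gal 1.16
ASGV galactose T1 -> T3 frequency: 2.33e-04 -> 7.33e-06 (depleted)
ATGV galactose T1 -> T3 frequency: 2.67e-04 -> 1.36e-03 (persists)

variants enriched (mean function log2FC > 0): 3101 of 16000
Spearman(true w_glu, mean function score): 0.958
ASGV: mean function log2FC +2.74, rank 385

fraction of functional variants sensitive to the kinase: 0.41
  Ser3: 0.80   Thr3: 0.000
ASGV -> functional_sensitive
ATGV -> functional_resistant
ASLV -> functional_resistant
```

The wild-type-like Ser3 sequence thrives without the kinase but is
depleted once LIMK is induced, while its Thr3 counterpart (not a LIMK
substrate) and the bulky-position-4 Ser3 variant (functionally shielded)
persist — and the scoring recovers the generating fitness landscape
(Spearman 0.96). Stage 5 adds logos and covariation (the Gly4–Val5 pair is
over-represented among top sequences, log2(obs/exp) ≈ +1.1); stage 6 fits
the biochemistry, e.g.:

```
WT binding: K0.5 0.62 uM [0.58, 0.67] (true 0.61), h 2.07
WT kinetics: kcat 0.193 +/- 0.008 1/s, KM 8.7 +/- 0.5 uM
G4F kinetics: kcat 0.530 +/- 0.023 1/s, KM 11.6 +/- 0.7 uM
```

In R, the core loop is:

```r
library(cofilinscreen)
fitness <- build_fitness_map("empirical", seed = 1)
sim     <- simulate_screen(fitness, screen_design(depth = 1e6), seed = 101)
records <- score_screen(sim$counts, pseudocount = 0.5)
calls   <- classify_quadrants(records)
logo    <- binomial_logo(select_enriched(records))
```

See `vignettes/screen-methods.Rmd` for the models, parameter choices and
limitations.

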