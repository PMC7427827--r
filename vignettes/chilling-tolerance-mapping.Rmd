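---
title: "Mapping seedling chilling tolerance: traits, mixed models and candidate genes"
author: "coldqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping seedling chilling tolerance: traits, mixed models and candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldqtl)
```

## The problem

Asian rice (*Oryza sativa*) is unusually sensitive to chilling: temperatures
around 10 °C damage young seedlings that other cereals shrug off. The two
subspecies differ sharply — *JAPONICA* accessions, selected in temperate
climates, tolerate chilling far better than tropical *INDICA* accessions —
so a diversity panel spanning both is a natural mapping population for the
genetics of chilling tolerance.

`coldqtl` implements the full analysis chain for such a panel:

1. **Trait statistics.** Percent electrolyte leakage
   (`%EL = 100 · initial / total` conductivity, a membrane-damage proxy;
   low = tolerant) and percent low-temperature seedling survivability
   (`%LTSS = 100 · alive / initial`), measured at five chilling temperatures
   (4, 8, 10, 12, 16 °C) in up to three replicate boxes of up to eight
   seedlings, replicate values averaged per accession.
2. **LT50.** The median lethal temperature per accession, from a binomial
   GLM (logit link) of pooled alive/dead counts on temperature:
   `LT50 = −β₀/β₁`.
3. **Association.** An EMMAX-style single-marker mixed-model scan with an
   identity-by-state (IBS) kinship random effect, after the allele filters
   MAF > 10%, MAC > 1, missing < 30%.
4. **QTL.** Intervals with ≥ 3 significant SNPs (−log10 p > 4) within 1 Mb,
   merged across the 11 mapping traits (EL and LTSS at five temperatures
   each, plus LT50) into unique and multi-trait QTL.
5. **Candidates.** Genes in QTL, purged of transposable elements, filtered
   for significant SNPs in the gene body and for major alleles that are both
   frequent (at least the Tolerant-cluster fraction, 205/354 ≈ 58%) and
   tolerance-increasing.

Because the per-accession measurements of the original panel are not
publicly deposited, every stage is exercised against a synthetic generator
that emulates the panel's structure; the package also ships the curated
40-row multi-trait QTL table (`load_table1()`) as the machine-checkable
slice of the published results.

## The synthetic panel

`simulate_genotypes()` draws a Balding–Nichols panel: each SNP has an
ancestral frequency `p ~ U(0.05, 0.95)` and each cluster draws its own
frequency from a Beta distribution with mean `p` and variance
`F·p(1−p)`. The default `fst = 0.3` produces subspecies-level divergence —
deliberately strong, so that population structure is confounded with the
phenotype and the kinship correction has real work to do. Accessions are
fully inbred (genotypes 0 or 2), in three clusters of 205 (Tolerant), 20
(Intermediate) and 129 (Sensitive) accessions. A single RNG stream keyed by
`seed` fixes the draw order (documented in the source) so fixtures are
bit-reproducible; phenotype draws use `seed + 1` so they never alias
genotype draws.

`simulate_phenotypes()` gives accession *i* a true median lethal
temperature

    LT50_i = baseline(cluster) + Σ_causal (allele count × effect/2) + N(0, 0.5),

and at treatment temperature *T* the survival probability
`p = plogis(slope · (T − LT50_i))` with `slope = 0.8 /°C`. Alive counts per
replicate box are binomial; EL is a noisy monotone transform of mortality,
`clamp(8 + 30 · (1 − p) + N(0, 5), 0, 100)`.

Calibration choices, made once from the published summary statistics and
then frozen:

* cluster baselines 8.5 / 10 / 11.8 °C, which with slope 0.8 reproduce the
  panel's printed survival extremes (Sensitive ≈ 0.3% alive at 4 °C and
  ≈ 95% at 16 °C; Tolerant ≈ 98% at 16 °C). The saturation at the extreme
  temperatures is what decouples EL from LTSS there, reproducing the
  observed pattern that the EL–LTSS linear R² peaks at intermediate
  temperatures and collapses at 16 °C;
* the planted causal allele *lowers* LT50 by 2 °C (a tolerance allele),
  matching the direction convention of the candidate filter; causal SNPs
  are drawn among SNPs with overall MAF ≥ 0.2 so they are detectable after
  the study's own allele filters;
* an EL baseline of 8% reflects that unstressed tissue still leaks a little;
  the published cluster-mean EL range (≈ 9–35%) has a nonzero floor.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
exchangeable given cluster frequencies, so simulated QTL contain no LD
blocks), epistasis, genotype-by-environment interaction beyond the logistic
temperature response, and measurement idiosyncrasies such as box-position
effects. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not performance on real panels with LD —
in particular, power estimates here are per-SNP and do not translate into
tag-SNP power.

## LT50 estimation

Counts are pooled across replicate boxes into binomial totals per
(accession, temperature) before fitting — fitting pooled counts is exactly
the binomial likelihood of the replicated design when boxes are
exchangeable. IRLS runs to a deviance tolerance of 1e-8 with at most 100
iterations; non-convergence is flagged, never silently reported.

Degenerate patterns get deterministic, documented treatment: all-alive and
all-dead accessions have no crossing and are flagged; a clean 0/1 step in
the alive fractions is complete separation, for which the reported LT50 is
the midpoint of the two bracketing temperatures; fits with β₁ ≤ 0
(survival *decreasing* with temperature) are flagged and excluded. An LT50
outside the tested range extended by one full span on each side is reported
but flagged `out_of_range`. Only `ok` accessions enter the LT50 mapping
phenotype (`lt50_table()`); the exclusions travel in an attribute so a run
can always account for every accession. The 120-seedling design (24 × 5
temperatures) estimates LT50 with a sampling SD of ≈ 0.35 °C and
negligible bias (the median estimate over 500 simulated designs sits within
0.01 °C of the truth); per-accession LT50 is accordingly the noisiest of
the eleven mapping phenotypes.

## Kinship and the mixed model

IBS kinship is `K[i,j] = mean(1 − |g_i − g_j|/2)` over loci non-missing in
both accessions. It is computed on the post-filter SNP set (the order is
unstated in the source protocol; filtered SNPs avoid rare-allele noise).
With complete data K is numerically PSD; with pairwise-complete missing
data small negative eigenvalues can appear, and the spectrum is clamped at
1e-10 (tolerated up to 10% of the leading eigenvalue, a hard error beyond).

The null model `y = μ + u + e`, `Var(u) = σ²_g K`, `Var(e) = σ²_e I` is
fitted by REML on the eigenbasis of the intercept-projected kinship,
maximizing the profile likelihood in the single ratio
`δ = σ²_e/σ²_g` (121-point grid on `log10 δ ∈ [−6, 6]`, refined by
golden-section search — the profile is smooth and this is robust to the
flat-likelihood case `K = I`, which is flagged unidentifiable). Variance
components are then held fixed for every SNP (the EMMAX approximation),
making each test a weighted least-squares fit in the rotated basis: O(n)
per SNP after one rotation. P-values use the t distribution with n − 2
degrees of freedom (equivalent to the 1-df F test). With `K = NULL` the
scan *is* ordinary least squares, which the tests exploit as an exact
oracle (`K = I` must reproduce OLS to machine precision).

Missing genotypes drop accessions for that SNP only; the GLS system is then
solved exactly on the kinship submatrix. Zero-variance SNPs are skipped and
logged. Effect direction is re-expressed for the **major** allele (the
candidate filter is stated in those terms); at an exact 0.5 frequency no
major allele exists and the direction is reported for the non-reference
allele by convention.

Calibration, verified in the acceptance suite at full scale (354
accessions, 10,000 SNPs, 100 null traits): on polygenic null traits
`y = u + e`, `u ~ N(0, K)` — the canonical structured-null construction,
with heritability 0.5 — the empirical type-I error at α = 0.01 is within
three binomial SEs of 0.01 and the genomic inflation factor λ stays at
≈ 1.00, while the uncorrected OLS scan on the same traits inflates to
λ ≈ 2.5–2.9. Treating cluster means as *fixed* effects instead produces a
mild anti-conservative excess (type-I ≈ 0.011), the known limit of the
one-random-effect correction; users mapping phenotypes with large fixed
subpopulation shifts should interpret borderline hits accordingly.

## QTL calling

The calling rule — at least `min_snps = 3` significant SNPs
(−log10 p strictly > 4) within a `window = 1 Mb` region — does not by
itself pin down cluster boundaries. The package freezes the
maximal-window-union semantics: every maximal run of significant SNPs
whose span fits in the window and that contains ≥ 3 SNPs is found, and
runs sharing a SNP are unioned. This is deterministic, independent of
input order, and provably identical to brute-force enumeration of maximal
qualifying SNP subsets (the test suite checks 1,000 random configurations
against an independently coded enumerator). A greedy left-anchored scan
was rejected because it drops SNPs that belong to a qualifying window
anchored further right.

The QTL interval is the member-SNP span, not the span padded by the
window: the published interval widths are irregular spans, inconsistent
with fixed padding. Unique QTL merge on ≥ 1 bp overlap, transitively
(touching intervals stay apart); multi-trait QTL are merged regions with
≥ 2 distinct trait-temperature sources, named `qMT<chr>-<k>` by position
(bare `qMT<chr>` for a lone region, mirroring the published naming).
Genome coverage is union length over summed chromosome lengths.
Coordinates are 1-based inclusive internally; BED I/O converts to 0-based
half-open exactly (round-trip tested on fuzzed intervals).

## Candidate filtering

The cascade is monotone — each stage subsets the previous one — and its
stage counts are always reported: genes overlapping a QTL by ≥ 1 bp; minus
transposable elements (description keywords "transposon",
"retrotransposon", "transposable", case-insensitive, configurable); genes
with a SNP of p < 1e-4 strictly, inside the gene body only (no promoter
window — the source protocol says "within their genomic regions"); and
finally genes with at least one supporting SNP whose major-allele
frequency is ≥ the Tolerant-cluster fraction **and** whose major allele
moves the trait toward tolerance (decreasing EL, increasing LTSS,
decreasing LT50 — the LT50 direction is an interpretive choice: a lower
lethal temperature means a hardier seedling). Both conditions must hold on
the *same* SNP. The frequency threshold uses the unrounded fraction
(205/354 ≈ 0.5791); 58% is display rounding. The expression-data filter
mentioned in the source protocol has no stated criterion and is omitted.

## Numerical and interface notes

* Welch's ANOVA (via `oneway.test`) with Games–Howell post hoc
  comparisons handles the strongly unequal cluster sizes (205/20/129) and
  variances; Games–Howell refers `q = t·√2` to the studentized range with
  Welch–Satterthwaite degrees of freedom. Games–Howell is a parametric
  procedure; it is implemented as such. Simulation tests confirm its size
  at α = 0.05 under unequal variances and sample sizes.
* The two initial conductivity readings of an EL assay are averaged before
  the %EL formula (the combination rule is unstated in the source
  protocol; averaging is standard practice).
* `trait_correlation()` reports R² as undefined (NA, flagged), never 0,
  when the predictor is degenerate.
* Problem sizes in the test suite are the package's own choices: full-scale
  panels (354 × 10,000 SNPs, 100 null traits; 50 power replicates at 354 ×
  3,000) in the acceptance suite, reduced panels (60–180 accessions,
  150–2,000 SNPs) in the unit suite where only correctness, not power, is
  at stake.
* `run_pipeline()` chains every stage on a synthetic scenario and writes
  stage artifacts plus a JSON run manifest recording seed, thresholds and
  stage counts — no timestamps, so identical seeds give byte-identical
  manifests. The R functions are the interface; there is no separate shell
  tool.

## A worked example

```{r example, eval = FALSE}
library(coldqtl)

sim <- sim_config(n_per_cluster = c(tolerant = 58, intermediate = 6,
                                    sensitive = 36),
                  n_snps = 2000, seed = 42)
res <- run_pipeline(sim = sim, config = run_config(seed = 42),
                    out_dir = "coldqtl_demo")

res$manifest$counts
res$qmt[, c("qtl", "chrom", "start", "end", "traits", "peak_lod")]
```

## Known limitations

* No LD simulation means synthetic QTL are driven by single causal SNPs;
  interval widths and member counts on real panels, where LD creates
  clusters of associated SNPs, will look different.
* The EMMAX approximation holds variance components fixed across SNPs; for
  SNPs of very large effect an exact per-SNP REML would give slightly
  different p-values.
* LT50 for accessions outside the tested temperature range (fully dead or
  alive everywhere) is not estimable and those accessions are excluded
  from the LT50 phenotype; panels with many such accessions will map LT50
  with reduced power.
* The candidate filter's direction convention for LT50-supporting SNPs is
  inferred from the trait's meaning, not stated in the source protocol.
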