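---
title: "Pooling case-control SNP association studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling case-control SNP association studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A case-control association study of a biallelic SNP yields two genotype
count triples — common homozygotes, heterozygotes, variant homozygotes in
cases and in controls. Any single study is noisy and prone to genotyping
artefacts; a meta-analysis pools many of them. This vignette documents the
statistical pipeline the package implements, the choices that were genuinely
open, and what the bundled tests do and do not establish.

## Pipeline and model

**1. Hardy-Weinberg screening.** Control arms should follow HWE proportions
$(\hat p^2, 2\hat p\hat q, \hat q^2)$ computed from the observed allele
frequencies; departure usually signals genotyping error or a non-random
sample rather than biology. `hwe_test()` uses the uncorrected Pearson
chi-square on 1 df — not the exact test and not Yates-corrected, because
the bundled reference tables were produced with the plain chi-square and the
package reproduces all 126 of their printed 3-decimal p-values to within
0.001 under this choice. Studies with control-arm $P < \alpha$
(default $\alpha = 0.05$) are excluded. Case arms are tested and reported
but do not drive exclusion: a true association legitimately distorts
case-arm genotype frequencies. A monomorphic arm (one allele absent) has
no testable departure and maps to the degenerate result $\chi^2 = 0, p = 1$,
so it never triggers exclusion by itself.

**2. Genetic-model contrasts.** Each study is collapsed into a 2×2 table
under five contrasts: allele ($b$ vs $a$, individuals contributing two
alleles each), homozygote ($bb$ vs $aa$), heterozygote ($ab$ vs $aa$),
dominant ($ab{+}bb$ vs $aa$) and recessive ($bb$ vs $aa{+}ab$). A table
whose exposure or reference class is empty in *both* arms carries no
information about the odds ratio and is dropped from that contrast (with
the study listed in the fit's `dropped` field). This is why the bundled
codon-25 corpus pools 19 studies under the allele model but only 14 under
the homozygote and recessive models. The alternative policy — dropping any
study with a single zero cell — would discard information the continuity
correction can retain, and does not reproduce the reference study counts.

**3. Per-study effects.** Woolf log odds ratios,
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$, log-normal confidence
intervals. If any cell is zero, 0.5 is added to all four cells of that study
only (flagged `corrected`). The treatment of alleles as independent
observations in the allele contrast is the field's convention and exactly
matches the bundled reference rows.

**4. Heterogeneity.** Cochran $Q = \sum w_i (y_i - \bar y_w)^2$ with
fixed-effect inverse-variance weights $w_i = 1/\mathrm{SE}_i^2$ about the
inverse-variance mean; $P_{het}$ from $\chi^2_{k-1}$;
$I^2 = \max(0, (Q - df)/Q) \cdot 100$; DerSimonian-Laird
$\tau^2 = \max(0, (Q - df)/C)$ with $C = \sum w - \sum w^2/\sum w$. With a
single study, $Q = 0$, $I^2 = 0$, $\tau^2 = 0$ and $P_{het} = 1$ by
convention.

**5. Model selection and pooling.** Fixed effects iff $P_{het} > 0.1$ and
$I^2 < 50\%$, random effects otherwise; boundary values go to random
effects (the rule is stated with strict inequalities). The fixed-effects
estimator is Mantel-Haenszel,
$\widehat{OR} = \sum_i (a_i d_i/n_i) \big/ \sum_i (b_i c_i/n_i)$, with the
Robins-Breslow-Greenland variance; the random-effects estimator is
DerSimonian-Laird with weights $1/(\mathrm{SE}_i^2 + \tau^2)$, which reduces
to inverse-variance fixed effects exactly when $\tau^2 = 0$
(`pool_fixed_iv()` is exported for cross-checks). Zero-cell studies enter
the MH estimator with the same all-four-cells 0.5 correction as the Woolf
effects: on corpora containing zero-cell studies this is the convention
that reproduces the reference results (the widely used Cochrane software
behaves the same way), and on zero-free tables it changes nothing.
Significance is the two-sided normal Z test on the pooled log OR; text
output floors p-values at "<0.00001" and prints $I^2$ as an integer
percentage while full precision is kept in the objects.

**6. Publication-bias diagnostics.** `egger_test()` offers two
formulations. The classic form regresses the standardized effect
$y_i/\mathrm{SE}_i$ on precision $1/\mathrm{SE}_i$ by OLS and t-tests the
intercept on $k-2$ df. The weighted form regresses $y_i$ on
$\mathrm{SE}_i$ with meta-analytic weights $1/(\mathrm{SE}_i^2+\tau^2)$
($\tau^2$ re-estimated by DL within the regression for the random-effects
variant, zero for the fixed variant) and z-tests the coefficient on
$\mathrm{SE}_i$. The two agree on direction but can differ noticeably in p
when heterogeneity is high; the weighted random-effects form is what
reproduces the reference Egger column, so `run_pipeline()` uses the
weighted form tied to the selected pooling model, while the classic form
remains the default of the standalone function. `begg_test()` computes the
Kendall rank correlation between standardized deviates
$(y_i - \bar y_{FE})/\sqrt{v_i - \bar v}$ and the variances, using the
tau-b tie correction and the continuity-corrected normal approximation
(rounded effects tie; the untied statistic is the special case). Both
tests require $k \ge 3$; their p-values on few studies are indicative, not
calibrated.

**7. Subgroups and sensitivity.** `subgroup_analysis()` partitions the
HWE-retained corpus by disease etiology and pools each partition
independently — its own $Q$, its own $\tau^2$, its own FE/RE choice —
because sharing $\tau^2$ across subgroups would couple estimates the
reference analysis treats as independent. Single-study subgroups report the
study's own Woolf estimate with heterogeneity columns suppressed in text
output. `leave_one_out()` re-pools $k$ times omitting one study at a time,
under random effects regardless of the selection rule (the conventional
sensitivity procedure; `model = "auto"` re-selects per omission), and
reports whether every omission keeps the CI excluding 1 on the same side as
the full fit.

## The synthetic-data generator

`simulate_corpus()` draws study corpora with known truth. Controls follow
the inbreeding-parameterized genotype distribution
$P(aa) = (1-q)^2 + fq(1-q)$, $P(ab) = 2q(1-q)(1-f)$,
$P(bb) = q^2 + fq(1-q)$, so $f = 0$ is exact HWE and $f > 0$ depletes
heterozygotes (the HWE-filter power checks use $f = 0.5$). Cases reweight
the control distribution by genotype-level odds ratios
$(1,\; or_{het} e^{s},\; or_{hom} e^{s})$, where the study shift
$s \sim N(0, \tau^2)$ is shared by both variant genotypes. The generative
scale is genotype-level so every contrast has a computable expected value
(`expected_contrast_log_or()`); a multiplicative pair
($or_{hom} = or_{het}^2$) makes the allele-model odds ratio exactly
$or_{het}$. Two scale facts matter when interpreting recovery tests: the
shift passes through the homozygote contrast one-to-one, so $\tau^2$ is
recovered on that scale, while the allele-scale between-study variance is
attenuated by the squared derivative of the allele log OR in the shift
(about $0.61^2$ at $q = 0.3$, $or_{het} = 1.5$); recovery tests compare
against the implied truth, not the raw generator parameter. Arm sizes are
uniform over configurable ranges; the random stream is split into per-study
sub-seeds drawn up front, so a given seed always yields the same corpus and
appending studies never perturbs earlier ones.

What the generator does *not* emulate: linkage disequilibrium, covariate
confounding, genotyping error beyond HWE departure, and
publication-bias-generating selection. Passing calibration tests therefore
show the estimators are correct under the random-effects model's own
assumptions, not that real corpora satisfy those assumptions.

## Test problem sizes and numerical conventions

The simulation-based checks in the test suite use: type-I error and CI
coverage of the pooled Z test at $k = 15$, $n = 300$/arm over 1,000
replicates plus a large-corpus coverage check at $k = 200$, $n = 1000$/arm
over 500 replicates; parameter recovery at $k = 50$, $n = 500$/arm over 200
replicates; Egger type-I error at $k = 15$ over 1,000 replicates. These
sizes give Monte-Carlo standard errors small enough for the nominal bands
(e.g. ±0.014 on a 0.05 rejection rate at 1,000 replicates) while keeping
the default suite fast.

Numerical conventions: confidence intervals use `qnorm(0.975)` rather than
the rounded 1.96; $I^2$ is computed as 0 when $Q = 0$; filtering at
$\alpha = 1$ removes every testable study (every non-degenerate $p < 1$);
reported arm sizes that disagree with genotype sums produce a warning and
the genotype sums win, since the counts feed every downstream statistic.
Serialization (`write_results()`) fixes column and key order and renders
floats at 6 significant digits so repeated runs are byte-identical.

## Bundled data

The three packaged corpora transcribe the published genotype tables of
TGF-β1 -509C/T (25 study arms), codon 10 (18) and codon 25 (20) in chronic
liver disease, including the published per-arm HWE p-values as reference
metadata ("/" marks a monomorphic arm). Two idiosyncrasies are preserved
as printed: the codon-25 Falleti 2008 row sums to 187 cases while the
characteristics table reports 188 (the genotype table wins), and the
Sánchez-Parada 2013 / Maria 2013 codon-25 rows carry identical arm sizes —
both are retained as separate studies, exactly as pooled in the reference
analysis. Studies contributing several disease arms against a shared
control series (e.g. Qi 2009 CHB and HCC) are likewise kept as separate
records; no unit-of-analysis correction is attempted.

## Known limitations

Only biallelic loci and odds ratios; no exact HWE test; no REML or
Paule-Mandel $\tau^2$, Hartung-Knapp adjustment, Peto pooling,
meta-regression, or trim-and-fill; subgrouping only by the disease label;
plotting is limited to a base-graphics forest method plus plot-ready data
tables. These are deliberate scope boundaries, not oversights.
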