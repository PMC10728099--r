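---
title: "Methods: LINE-1 amplicon methylation quantification and cohort evaluation"
author: "amplibeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LINE-1 amplicon methylation quantification and cohort evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplibeta)
```

# Scope and model

`amplibeta` turns targeted bisulfite amplicon reads over a 10-probe LINE-1
panel into per-probe methylation beta values, and evaluates genomic
hypomethylation as a predictor of immune-checkpoint-blockade (ICB)
response: probe weighting, mean-split survival stratification with a
signed log-rank P bootstrap, GLM/ROC-AUC response classification, and
paired longitudinal monitoring. A synthetic-data module generates both
reads with known truth and whole cohorts under an explicit generative
model, so every stage is testable at desk scale without patient data.

## The measurement model and the beta formula

Bisulfite treatment converts unmethylated cytosine to uracil (read as T);
methylated cytosine is protected. After conversion the two strands are no
longer complementary, so each probe has two alignment templates: the
Watson reference with all C→T, and the Crick strand which, expressed in
Watson coordinates, is the reference with all G→A. Methylation evidence
is a retained C (Watson) or retained G (Crick) at a target site.

Strand geometry matters for where evidence sits. At a CpG with cytosine
offset $i$, the Crick-strand cytosine pairs with the Watson guanine at
$i+1$, so Watson reads are scored at $i$ (C = methylated, T = converted)
and Crick reads at $i+1$ (G = methylated, A = converted). CpA methylation
(present on the non-CpG probes P8–P10) is strand-asymmetric — the Crick
dinucleotide opposite a CpA is TpG, with no cytosine — so CpA targets are
scored on Watson reads only. For the same reason, conversion-rate
estimation uses Watson-strand observations of the annotated naïve
cytosines.

Counts are pooled over all target sites and both strands of a probe into
$(M, U)$, which weights sites by their read depth. With sample conversion
rate $c$,

$$\beta = \frac{M}{U + M} \times c, \qquad \beta \in [0, 1].$$

The correction multiplies rather than subtracts: a completely unmethylated
site with conversion failure probability $1-c$ reads as methylated at rate
$1-c$, so the raw fraction for true methylation $m$ is
$m + (1-m)(1-c)$, and the corrected beta converges to
$(m + (1-m)(1-c)) \cdot c$. This closed form is the oracle used throughout
the tests: the pipeline run on simulated reads must land within binomial
sampling error of it.

The conversion rate is the *unweighted mean* of per-position conversion
fractions over the panel's 92 annotated naïve cytosines (positions with at
least one observation). Averaging per position rather than pooling counts
keeps deeply covered probes from dominating the estimate; at typical
depths the difference is far below the assay's resolution.

## Read assignment and filtering

Amplicons are short and enumerated, so assignment is alignment against the
20 known templates (10 probes × 2 strands), in both read orientations.
Reads whose length matches the template are scored by direct per-position
comparison; only the remainder (indel-bearing reads, typically a few
percent) fall back to global gapped alignment. Bisulfite-consistent
differences — C where the Watson template has T, G where the Crick
template has A — are never counted as mismatches; everything else is, and
reads above a 10% mismatch fraction stay unassigned. Reads shorter than
30 nt are dropped (the adapter-trimming length floor collapses to this at
amplicon scale).

Reads with an insertion or deletion intersecting the probe's target region
extended by ±30 nt (half-open interval arithmetic, 0-based coordinates
throughout) are removed before counting. Indels that survive filtering are
harmless to counting: deleted positions carry a `-` and contribute no
calls. A SAM/BAM ingestion path (`assigned_from_bam()`) accepts reads
pre-aligned to references named `<probe>_watson` / `<probe>_crick` and
reconstructs template-coordinate bases from CIGAR strings.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `window` | 30 nt | indel exclusion flank around the target region |
| `min_depth` | 100 reads/probe | below this, beta is reported missing |
| `max_mismatch_frac` | 0.10 | assignment rejection threshold |
| `min_read_length` | 30 nt | post-trimming length floor |
| `context_mode` | `auto` | score all annotated targets; `cpg_only` restricts P8–P10 to CpG sites (for array comparability) |

`min_depth = 100` is a deliberate floor: the assay's intent is ~0.5%
resolution, which single-digit depths cannot support; the value is
configurable and missing betas are recoverable by imputation.

## The bundled panel

The bundled panel is *synthetic*: 10 LINE-1-like amplicons (110–132 nt,
AT-rich base composition, realistic CpG/CpA density), with P1–P7 carrying
CpG targets only and P8–P10 carrying CpG plus CpA targets, and exactly 92
annotated naïve cytosines panel-wide. Real deployments load their own
FASTA + sites table (`load_panel()`); the sites table makes the CpG/CpA
enumeration per amplicon explicit, since that choice is a property of the
deployed panel, not of the method. The panel abstracts each probe as one
consensus amplicon: the pipeline's arithmetic is per probe, and modelling
the ~2000 genomic LINE-1 copies individually would add nothing testable at
desk scale.

## Imputation of the non-CpG probes

Samples missing P8–P10 are imputed by per-probe ordinary least squares on
P1–P7 with intercept, trained on samples with complete 10-probe vectors
(at least 9 required; rank-deficient designs are rejected naming the
collinear probes). Predictions are clipped to $[0,1]$ and flagged; whether
to clip is not dictated by the method definition, but beta values outside
the unit interval are not interpretable, so clipping with a flag is the
conservative choice. No regularization and no uncertainty propagation —
this is a deterministic fill-in, not multiple imputation, and imputed
entries are marked as such.

## Probe weighting

Candidate weight vectors are generated by drawing probes uniformly *with
replacement*: set sizes 10, 15, 20, 30, 50, 75, 100, 150, 200, 300, and
5000 draws per size, giving 50,000 candidates; a probe's weight is its
count divided by the set size (a probe drawn 6 times in a set of 30 weighs
0.2). Sampling with replacement is forced by the arithmetic — counts above
1 per probe are impossible otherwise. Weights are exact rationals
(count/size), so each candidate sums to exactly 1; the integer counts are
retained in the object so the unit-sum property can be checked exactly.

Each candidate stratifies the training cohort at the mean of its weighted
scores and is scored by the log-rank test. Selection minimizes the
*directional* (one-sided) P value for the hypothesized direction
(methylation-high group survives longer), $(1 - s(1-p))/2$ where $s$ is
the sign defined below. The raw signed value $s \cdot p$ is kept for
reporting but is not a monotone performance scale — ordering by it would
place any wrong-direction split below every confirming one — so it is not
used for ranking. On a direction-consistent cohort the two orderings
coincide. Ties go to the earliest candidate, and the single seeded
generator plus recorded seed make candidate lists byte-reproducible.

Weights trained on one cohort are applied *unchanged* to another (cross-
cancer, cross-specimen): `select_best_weights()` never refits on the
application side, and the training evaluation endpoint (overall vs
progression-free survival) is whatever the supplied clinical table
declares — metadata, not hard-coding.

## Survival evaluation and the signed-P convention

Stratification is at the cohort mean: `high` strictly above, ties to
`low` (a documented, tested convention; the method definition is silent on
ties). Kaplan–Meier estimation and the two-group log-rank chi-square are
delegated to the `survival` package; the tests additionally verify the
chi-square against the textbook O−E−V formula and an exact permutation
oracle on small fixtures.

The signed P value attaches direction: $+p$ when the methylation-high
group shows better survival, $-p$ otherwise. Direction is read from the
high group's observed-minus-expected event count in the log-rank table
(O−E < 0 means fewer events than expected, i.e. better survival); O−E = 0
takes the positive sign. O−E is internal to the statistic and tie-free,
unlike comparisons of median survival or curve ordering.

The bootstrap resamples *patients* with replacement, keeping each
patient's score–time–event triple intact, re-splits each resample at its
own mean, and records the signed P. Degenerate resamples (constant scores
or zero events) are redrawn, not dropped, so a run always yields exactly
the requested number of values and distributions remain pairable. When
several predictors are evaluated, each replicate reuses the same resampled
patients for all of them — this shared-resample pairing is what justifies
the paired Wilcoxon signed-rank comparison (`compare_predictors()`), which
operates on the signed values, two-sided, with the conventional
significance bands (\*\*\*\* < 1e-4, \*\*\* < 1e-3, \*\* < 1e-2,
\* < 0.05).

One property of this machinery deserves emphasis: the bootstrap
distribution of a *single* cohort is centred on that cohort's realized
association, including the chance association a null cohort carries (its
realized log-rank z-score is a N(0,1) draw). Null *calibration* — the
statement that signs are balanced when methylation and survival are
unrelated — is therefore a property marginal over cohorts, and the test
suite assesses it by pooling bootstrap draws across hundreds of
independent null cohorts rather than resampling one cohort harder.

## Response prediction

Probe selection drops the probe with the smallest across-sample SD *and*
every probe with SD < 0.015; the conjunction means the smallest-SD probe
is dropped even when it clears the threshold, with first-index
tie-breaking. The classifier is a binomial (logit) GLM of DCB/NDB on the
kept probes — the standard reading of a "general linear model" for a
binary outcome; perfect separation is flagged but the monotone fitted
scores remain usable for ranking. Accuracy is in-sample ROC-AUC computed
as the Mann–Whitney rank statistic with 0.5 credit for ties; the tests
pin it to exhaustive pair counting and to `pROC` as an independent
reference.

## The synthetic cohort generator

The generator encodes the study's structural assumptions explicitly:

- **True tumor methylation.** Per patient, a global methylation factor
  $z_i \sim N(0, 0.4)$ on the logit scale shifts all probes together
  (genome-wide loss is a global phenomenon); probe-level means (0.45–0.70,
  non-CpG probes lowest) plus probe noise (sd 0.15, logit scale) complete
  $m_{ij}$.
- **Specimens as mixtures.** Tissue: $p \cdot m + (1-p) \cdot 0.85$ with
  purity $p \sim U(0.1, 0.9)$. cfDNA: $f \cdot m + (1-f) \cdot 0.85$ with
  ctDNA fraction $f \sim U(0.15, 0.25)$ drawn independently of $p$. PBMC:
  the 0.85 normal level with 0.01 jitter. Non-malignant DNA is nearly
  fully methylated, which is exactly why low purity inflates tissue betas.
- **Measurement noise.** Binomial at 5000 reads/probe, reusing the
  read-level sampling model rather than an ad hoc Gaussian.
- **Survival.** Exponential with hazard
  $h_0 e^{-\gamma(\bar m_i - \overline{\bar m})}$, $h_0 = 0.08$/month,
  $\gamma = 6$ by default ($\gamma = 0$ is the null), censored by the
  earlier of a 36-month horizon and a uniform dropout time.
- **Response.** DCB when the methylation-linked latent score exceeds the
  cohort quantile implied by a 35% responder rate, with latent noise
  sd 0.05 — mirroring durable-benefit labelling as a
  survival-correlated but noisy binary.

The wide purity range against the narrow ctDNA-fraction range is the
deliberate asymmetry: biopsy cellular composition varies enormously from
specimen to specimen, while the generator idealizes plasma tumor fraction
as varying modestly around 20%. Under the mixture algebra this yields an
average-beta-to-true-methylation correlation of about 0.9 for cfDNA
versus about 0.6 for tissue, so cfDNA-based stratification stochastically
dominates tissue-based in the paired bootstrap — the generative analogue
of the purity-confounding argument. This is also the generator's main
idealization: real plasma tumor fractions vary over orders of magnitude
and can be near zero in low-burden disease, where the liquid readout
degrades in ways these simulations do not exhibit. Passing tests
demonstrate internal consistency of the pipeline under the stated model,
not clinical performance.

The read simulator draws strand uniformly per read, methylates each target
cytosine independently with probability $m$, converts unmethylated and
naïve cytosines with probability $c$, emits Crick reads as reverse
complements (as sequenced), and can inject 1-nt indels at a configured
per-read rate. Truth tables (read origin, strand, indel status; patient
purity, fraction, $m$) accompany all outputs.

## Numerical conventions and degenerate inputs

- Coordinates 0-based, intervals half-open, declared once and used
  everywhere (panel offsets, indel windows, regions).
- Betas are clipped to $[0,1]$; conversion rates outside $[0,1]$ are
  rejected rather than clipped (a rate above 1 indicates a broken
  estimate, not a correctable one).
- $M + U = 0$ or depth below `min_depth` gives a *missing* beta, never 0.
- Constant scores cannot be mean-split: an error, which the bootstrap
  layer converts into a counted redraw.
- Zero-variance paired deltas take the degenerate t-test limit (P of 0,
  1, or 0.5 by the sign of the common value).
- All stochastic components take explicit integer seeds and restore the
  caller's RNG state on exit.

## Problem sizes used in the checks

The acceptance-style checks run at: read-level recovery at depth $10^4$
(tolerance 3 binomial SDs); candidate generation at the full 50,000;
purity confounding at n = 200; bootstrap dominance at n = 150 patients ×
1000 shared resamples; null calibration pooled over 500 null cohorts × 2
resamples; oracle equivalence on fixtures up to n = 100 (AUC) and n = 6
(exact log-rank permutation). These sizes make every distributional claim
testable in seconds to a couple of minutes on one CPU while keeping
binomial/bootstrap noise well inside the asserted tolerances.

## Known limitations

- One consensus amplicon per probe; no per-genomic-copy resolution, no
  genome-scale alignment, no PCR-duplicate handling.
- Substitution sequencing errors are not simulated (only indels);
  the assigner tolerates them but recovery bounds are derived without
  them.
- In-sample AUC matches the evaluated procedure but overstates
  out-of-sample accuracy; a CV switch exists and defaults off.
- The cohort generator's independence of $f$ from $p$, and its modest
  $f$ variation, are assumptions — see above.
- Endpoint choice (overall vs progression-free survival) is metadata
  supplied per cohort; nothing validates that the supplied endpoint
  matches the clinical source.
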