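---
title: "Translating composite expression-signature scores from FF to FFPE: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating composite expression-signature scores from FF to FFPE: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene-expression signatures that summarize pathway activation — such as
the 18-gene RAS/MEK/ERK panel whose per-sample mean is the "RAS score" —
are typically developed on fresh-frozen (FF) tumour material profiled on
microarrays. Clinical material is overwhelmingly formalin-fixed
paraffin-embedded (FFPE), where cross-linking and storage degrade RNA;
a signature is only clinically useful if its score survives the journey
from FF microarray data to FFPE measurements on whatever platform a lab
runs (counting assays such as NanoString, targeted or whole-transcriptome
RNA-seq, or FFPE microarrays).

`ffpesig` implements that translation workflow end to end:
platform-appropriate normalization, probe filtration and probe-to-gene
collapse, composite scoring, PCA-based detection of degraded samples,
cross-platform rank concordance, and a nearest-shrunken-centroids (PAM)
classifier of mutation status built on the signature genes. Because no
matched FF/FFPE cohort at this design scale is publicly deposited, the
package ships a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, so every stage can be
exercised and validated on data with known ground truth.

# The synthetic cohort

`generate_cohort()` draws a latent gene-by-sample log2 matrix

$$x_{gs} = \mu_g + a_s + \beta\,[g \in \text{signature}]\,[\text{label}_s = \text{MUT}] + \varepsilon_{gs},
\qquad \varepsilon_{gs} \sim N(0, \sigma_b^2),$$

and derives five platform datasets from it: FF and FFPE microarrays at
probe level (1–4 probes per gene, each with a fixed affinity offset),
NanoString-like and targeted count panels (signature + housekeeping
genes; counts are size-factor-scaled, exponentiated and rounded to
non-negative integers), and a whole-transcriptome FPKM matrix.

**Degradation model.** Each sample carries an RNA-quality factor
$q_s \in (0, 1]$. FFPE measurements report

$$\text{floor} + q_s\,(x - \text{floor}) + N\!\big(0,\ \sigma_t^2 (2 - q_s)\big)$$

on the platform's scale; FF is measured at $q = 1$. The model is
deliberately minimal — a multiplicative collapse toward a log2
background floor plus heteroscedastic noise — because it reproduces with
two parameters the two empirical signatures of degraded FFPE samples
this workflow exploits: depressed per-sample mean signal and reduced
signal-to-noise. A planted subset (default 15 of 54) draws $q_s$ from a
low interval, giving ground truth for the QC stage. No attempt is made
to simulate fixation chemistry, probe-level CEL intensities or
sequencing reads.

**Default parameters and why.** The defaults are the study conditions
the rest of the package is validated under, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 54 | matched-pair cohort size of the design being emulated |
| `n_bad_samples` | 15 | planted degraded fraction matching that design |
| `class_fraction_mut` | 0.5 | balanced MUT/WT (27/27) two-class structure |
| `signature_effect` | 1.0 log2 | a clearly detectable but not trivial pathway shift (2-fold) |
| `quality_good` / `quality_bad` | [0.85, 1] / [0.2, 0.5] | well-separated quality strata: degraded samples lose 50–80% of dynamic range |
| `noise_sd_biological` | 0.7 log2 | typical per-gene biological spread in bulk tumour expression |
| `noise_sd_technical` | 0.25 log2 | platform replicate noise well below biological spread |
| baseline means | $N(7, 1.5^2)$ log2; housekeeping $N(9.5, 0.3^2)$ | mid-dynamic-range genes; a high, stable reference panel whose counts stay bounded away from zero |
| degradation floor | 1.0 log2 | near-background signal level |
| probe offsets | $N(0, 0.5^2)$ | probe-to-probe affinity differences shared by the FF and FFPE arrays |
| size factors | $2^{N(0, 0.2^2)}$ | modest per-sample depth/loading variation for count and FPKM platforms |

Housekeeping genes receive no class effect but are *not* exempt from
degradation or size-factor variation: they must be usable references,
not perfect ones.

What passing tests on this cohort do **not** show: robustness to
gene-specific degradation rates (ours is uniform given $q_s$), to
batch structure, to unbalanced or drifting class composition, or to
cross-hybridization artifacts. Results on real FFPE material will be
worse than on the emulation in proportion to how much those effects
matter.

# Normalization

Three normalizations are implemented exactly as defined for their
platforms:

* **Housekeeping geometric mean** (`housekeeping_normalize()`, for
  NanoString-style counts): per-sample factor
  $f_s = \overline{g}/g_s$ where $g_s$ is the sample's housekeeping
  geometric mean and $\overline{g}$ the across-sample average of those
  means; all counts in sample $s$ are multiplied by $f_s$. The
  housekeeping geometric mean is afterwards equal across samples —
  the method's defining fixed point, asserted in the tests at 1e-9
  relative tolerance. Factors are returned for audit. Normalized
  counts are *not* re-rounded: downstream statistics are means and
  ranks, which gain nothing from re-quantization. A zero or negative
  housekeeping count is an error naming the sample and gene; guessing
  an imputation here would silently change every factor.
* **Per-sample median centering** (`median_normalize()`, for targeted
  counts): subtract each sample's median; idempotent; missing values
  are excluded from the median and propagated.
* **log2 + z-score** (`log2_zscore_normalize()`, for FPKM):
  $y = \log_2(x + 1)$ (pseudocount configurable; the source
  material does not fix one), then each feature row is standardized
  across samples. Standardization is per *feature*, not per sample:
  downstream the workflow averages gene values within a sample, which
  is only meaningful if genes are on a common across-sample scale.
  Zero-variance features cannot be standardized and are excluded with
  a warning that lists them. Re-applying the function to its own
  output skips the log step (the scale metadata says the values are
  already z-scores), making the operation idempotent. Standard
  deviations use the $n-1$ denominator throughout the package.

# Probe filtration and collapse

`filter_probes()` retains a probe iff (a) at least 20% of its
non-missing samples deviate from the probe median by at least
$\log_2 1.5 \approx 0.585$ (in either direction), and (b) at most 50%
of its values are missing. The fraction denominator is the non-missing
count, so a mostly-missing probe cannot pass on a handful of
observations; the comparisons are `>=`/`<=` exactly as "at least"/"at
most" dictate. A linear-scale ratio mode is available behind
`values_are_log2 = FALSE`. The report is exhaustive — every probe is
either retained or dropped with a reason — so reductions of the
60,000-to-24,000-probe kind are auditable.

Two collapse rules produce gene-level matrices:
`collapse_by_mean()` (average all probes of a gene; used for the
full-signature scores) and `select_max_mean_probe()` (keep the single
retained probe with the highest across-sample mean; used after
filtration). Max-mean ties are broken toward the lexicographically
smallest probe id — the choice is arbitrary but must be deterministic.
`restrict_signature()` intersects the panel with the surviving genes,
preserving panel order and logging drops; the result is the "reduced"
signature (16 genes in the emulated design when two genes lose all
probes).

# Scoring and concordance

`signature_score()` is the unweighted arithmetic mean of the signature
genes' values per sample, applied identically on every platform scale.
No per-gene standardization or direction weighting is applied before
averaging: cross-platform comparisons downstream are rank-based, so
monotone scale differences between platforms are tolerated, and the
plain mean keeps the score interpretable on each platform's own scale.

`spearman_cor()` ranks with average ties and takes the Pearson
correlation of ranks; the two-sided p-value uses
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ df, the standard
large-sample approximation at this workflow's $n \approx 39$–$54$
(at $|\rho| = 1$ the p-value is reported as 0).
`pairwise_concordance()` builds the full table over all unordered
pairs of score sets (6 datasets give 15 pairs), pairing samples by id
and optionally excluding flagged outliers; pairs with fewer than 3
shared samples are reported `NA` rather than fabricated.
`fisher_exact_2x2()` enumerates the hypergeometric distribution over
all tables with the observed margins and sums the probabilities not
exceeding the observed table's (with 1e-7 relative slack against
floating-point ties) — the sum-of-small-probabilities two-sided
convention.

# Sample QC by PCA

`pca_sample_scores()` centers each feature across samples, forms the
sample-by-sample covariance matrix over features
($n_{\text{features}} - 1$ divisor), and takes its top two unit
eigenvectors as the per-sample PC1/PC2 scores. The input is the *full*
feature matrix of the FFPE microarray, not the signature subset: the
degradation fingerprint is genome-wide, and 18 genes would be far too
few to resolve it.

Eigenvector signs are arbitrary, so each component is oriented to
correlate non-negatively with per-sample mean expression (tie-break:
non-negative entry sum); degraded, signal-attenuated samples then land
at *low* PC1 deterministically, and the orientation applied is recorded
in the result. The flagging threshold (default $-0.10$) applies to the
unit-norm eigenvector entries — the scale on which $-0.10$ is a
meaningful cut for a ~54-sample cohort, where a perfectly uniform
loading would be $1/\sqrt{54} \approx 0.136$. Flagging is strictly
`pc1 < threshold`. Automatic threshold selection and RNA-integrity
metrics (RIN/DV200) are out of scope.

# The shrunken-centroids classifier

`nsc_train()` implements nearest shrunken centroids from its defining
formulas. With class centroids $\bar{x}_{kj}$, overall centroid
$\bar{x}_j$, pooled within-class standard deviation $s_j$ (pooled over
classes, $n - K$ denominator), fudge constant $s_0 = \text{median}_j(s_j)$
and $m_k = \sqrt{1/n_k - 1/n}$:

$$d_{kj} = \frac{\bar{x}_{kj} - \bar{x}_j}{m_k\,(s_j + s_0)}, \qquad
d'_{kj} = \text{sign}(d_{kj})\,\big(|d_{kj}| - \Delta\big)_+, \qquad
\bar{x}'_{kj} = \bar{x}_j + m_k\,(s_j + s_0)\,d'_{kj}.$$

$m_k = \sqrt{1/n_k - 1/n}$ is the standardization that makes $d_{kj}$
a t-like statistic, since
$\mathrm{Var}(\bar{x}_k - \bar{x}) = \sigma^2(1/n_k - 1/n)$; the
$\sqrt{1/n_k + 1/n}$ variant seen in parts of the literature is
available behind `offset_variant = "plus"` and covered by the same
test oracle. Prediction minimizes
$\delta_k(x) = \sum_j (x_j - \bar{x}'_{kj})^2/(s_j+s_0)^2 - 2\log\pi_k$;
exact ties go to the first declared class. Priors default to observed
class proportions. Genes with all $d'_{kj} = 0$ drop out of the
discriminant entirely — shrinkage is the gene selector.

`nsc_loocv()` evaluates a threshold grid — default 30 evenly spaced
values from 0 to $\max|d_{kj}|$ on the full data, a span that by
construction runs from no selection to total shrinkage — with the
*entire* fitting recomputed for each held-out sample ($s_j$, $s_0$,
centroids, gene selection), so gene selection is nested inside every
fold and the error estimate is honest. The chosen $\Delta$ minimizes
the LOOCV error; ties break toward the largest $\Delta$ (the most
parsimonious surviving model). Sensitivity and specificity come from
the chosen-$\Delta$ LOOCV predictions with MUT as the positive class,
and are reported as explicit quotients (e.g. `0.926 = 25/27`). Note a
known LOOCV artifact worth expecting in output: at total shrinkage with
balanced classes, every held-out sample is predicted as the *other*
class's majority, so the error at the top of the grid approaches 100%,
not 50%.

Correctness is established against an independently coded naive-loop
oracle (25 random instances; $d$, $d'$, surviving sets and predictions
at every grid point), with genes whose $|d_{kj}|$ sits within 1e-9 of
$\Delta$ excluded from the survival comparison — their fate is decided
by last-bit rounding and two correct implementations may legitimately
disagree there.

# Pipeline and reproducibility

`run_pipeline()` chains the stages — simulate/load, normalize, score
(full signature), QC, filter (on QC-passed FFPE microarray samples,
mirroring the design where probe selection happens on the cleaned
data), reduce, score (reduced), the four concordance tables
({all, QC-passed} × {full, reduced}) and per-dataset LOOCV
classification — with stage-level logging of sample/probe counts and a
manifest recording seed and parameters. All randomness derives from
the cohort seed; the generator saves and restores the caller's RNG
state, and every downstream stage is deterministic, so a rerun with the
same config is byte-identical. Matrix TSVs are written with 17
significant digits so doubles round-trip exactly through text.

Problem sizes used in the shipped validation: the full study design
(54 samples, ~1,030 genes, ~2,600 probes) for the end-to-end
properties, 20 replicate cohorts for the QC-recovery and
concordance-improvement checks, 25 random instances for the classifier
oracle, and reduced cohorts (12–20 samples) for structural unit tests.

# Known limitations

* The degradation model is a stylized two-parameter stand-in; its
  parameters are design knobs, not estimates from FFPE data.
* The PC1 threshold is taken at face value on unit-norm entries; no
  automatic threshold selection is provided, and the cut's
  meaningfulness degrades for cohort sizes far from ~50.
* Spearman p-values use the t approximation; for $n < 10$ an exact
  permutation approach would be preferable (the tests use enumerated
  micro-oracles at such sizes).
* The classifier is the plain two-class algorithm; no adaptive or
  heterogeneity-weighted variants, and no probabilistic posteriors.
* The signature panel ships with the published token `SLCO4A`, which
  is almost certainly the HGNC symbol `SLCO4A1`; the token is kept
  verbatim so panel files match the published list, and the reader of
  real data should map symbols accordingly.
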