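---
title: "Methods: mutation-methylation co-detection for brainstem glioma liquid biopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-methylation co-detection for brainstem glioma liquid biopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsgdiag)
```

## The problem

Brainstem gliomas (BSG) split into three molecular subtypes with sharply
different prognoses: H3K27M-mutant tumors (K27M substitution in H3F3A or
HIST1H3B/C; median survival under a year), IDH1/2-mutant tumors (markedly
better outcomes), and double-wildtype (DW) tumors carrying neither driver.
Because brainstem surgery and biopsy are high-risk, cerebrospinal fluid (CSF)
ctDNA is the natural liquid-biopsy medium — but CSF yields little DNA, driver
mutations drop out at low tumor fraction, and genome-wide methylation arrays
need far more input than CSF provides. This package implements the full
analysis chain for a targeted co-detection design: a small CpG panel whose
methylation pattern identifies the subtype, combined with gene-level mutation
calls, so that each modality covers the other's failure mode.

## The statistics at the core

**Methylation Signature Score (MSS).** For a panel of $n_{H3}$ H3-specific
and $n_{IDH}$ IDH-specific CpG sites ($N = n_{H3} + n_{IDH}$ probes), a
sample with beta values $\beta_j \in [0,1]$ scores

$$\mathrm{MSS} \;=\; \frac{\sum_{j \in H3} \beta_j \;+\; \bigl(1 - \sum_{j \in IDH} \beta_j\bigr)}{N}.$$

The formula is read literally: sums of beta values, a single $+1$, divided by
the total probe number. Its exact range is
$[(1 - n_{IDH})/N,\; (n_{H3}+1)/N] \subseteq [-1, 1]$. H3K27M tumors
(hypermethylated at H3 sites, hypomethylated at IDH sites) score high; IDH
tumors (hypermethylated everywhere, and most strongly at IDH sites) score
negative; DW tumors sit near zero. With missing probes, each class sum is
rescaled to its full class size ($\Sigma_{obs} \cdot n_c / n_{obs,c}$), which
is unbiased under missing-completely-at-random dropout; a coverage fraction
below `min_coverage` (default 0.5) flags the score as failing QC without
suppressing it.

**Methylation Risk Score (MRS).** The predicted probability of the H3K27M
class from the random-forest methylation classifier. Unlike the MSS, which is
close to linear in the CSF tumor fraction, the forest's vote fraction
saturates once the subtype pattern is recognizable, which is why the MRS is
the more stable statistic in tumor-poor (BLOD) samples.

**BSGdiag fusion.** Mutation evidence is deterministic: a K27M call in
H3F3A/HIST1H3B/C sets the mutation-predicted H3K27M probability to 1, an
IDH1/2 call sets the IDH probability to 1, and the DW probability is always 0
(absence of a driver is never positive evidence). Fusion takes the per-class
maximum of the mutation triple and the methylation triple; the diagnosis is
the argmax, ties broken H3K27M > IDH > DW — the clinically conservative
order, since missing an H3K27M tumor is the costliest error. The combined
triple is deliberately not renormalized: renormalization cannot change the
argmax but would dilute a driver's certainty. When both mutually exclusive
drivers appear, the call is H3K27M with a `conflict_flag`, never a silent
drop. Samples below the 5 ng DNA-mass limit (BLOD) get no mutation testing
and are diagnosed from methylation alone.

```{r fusion-example}
# a mutation-negative CSF sample with high methylation risk
fuse_bsgdiag(c(H3K27M = 0, IDH = 0, DW = 0),
             c(H3K27M = 0.778, IDH = 0.111, DW = 0.111))
```

## Marker discovery

Discovery runs on tissue beta matrices with a stratified 70/30 split.
Per-site screening uses the Wilcoxon rank-sum test with
Benjamini–Hochberg adjustment across sites and a stringent effect-size
cutoff of $|\Delta\beta| \ge 0.3$ (difference of available-case group
means). Surviving candidates are ranked by three algorithms — random-forest
impurity importance, linear-SVM weight magnitude, and entry order along an
L1-regularized multinomial path — and a site is selected when it reaches the
top-$k$ of at least two of the three ("2-of-3" majority; the literature on
this assay names the three algorithms but not the combination rule, so the
majority vote is this package's documented choice). Marker classes then
follow the mean-methylation pattern with a margin of 0.2 on mean beta
(chosen to be stringent and consistent with the 0.3 screening delta):
H3-specific sites are at least the margin above both other groups in H3K27M
samples; IDH-specific sites are high in IDH samples while H3K27M samples
stay within the margin of the reference group. The wet-lab reduction of a
discovered set to assayable primers is outside a desk-scale package and is
modeled as a seeded random subset preserving both classes.

## The classifier

A random forest (500 trees) on panel-restricted betas, with stratified
ten-fold cross-validation over a deliberately small grid (`mtry` at
$\sqrt{p}$ and $p/3$), scored by pooled micro-AUC, then refit on all
training data. Missing probes are imputed with class-agnostic training
medians stored on the model, so no label information leaks at predict time.
Probabilities are the forest's vote fractions; no further calibration is
applied.

## Evaluation statistics

Sensitivity and specificity are true-positive and true-negative rates with
Agresti–Coull 95% intervals (adjusted counts $\tilde n = n + z^2$,
$\tilde p = (x + z^2/2)/\tilde n$, truncated to $[0,1]$). AUC is the
Mann–Whitney probability with ties credited one half, which is also the
test oracle (pairwise enumeration). Multiclass performance uses one-vs-rest
AUCs, their unweighted mean (macro-AUC), and the AUC of the pooled
(sample $\times$ class) binary expansion (micro-AUC — the standard reading;
the source protocol does not define it). Bootstrap intervals are equi-tailed
percentile intervals over $R = 100$ resamples, stratified within each truth
class so that small negative classes never vanish from a resample.
Percentile intervals at $R = 100$ are known to run slightly below nominal
coverage; the package keeps the protocol's $R$ rather than silently
increasing it.

## Survival and monitoring

Risk stratification dichotomizes the CSF MRS at the fixed operating point
0.44 (strictly-greater is high risk); how that constant was originally
derived is not documented, so the package also ships a maximally-selected
log-rank grid search whose optimum statistic is labelled exploratory —
selection inflates it and it must not be read as a test. Kaplan–Meier
medians use the product-limit curve with the earliest-time-at-or-below-0.5
convention and a Not-Reached sentinel; Cox models use Efron tie handling
and report Wald intervals plus Harrell's concordance, with monotone
likelihood detected and flagged.

Monitoring tracks MSS and driver VAF over timepoints A–D (pre-op, intra-op,
post-op, follow-up). "Undetectable" VAF is an explicit sentinel (`NA`),
never a measured zero. A point is MRD-positive when the VAF is undetectable
while the MSS stays above a detection floor; the floor is not a published
constant, so it is calibrated as the 95th percentile of MSS in
background-like (DW) CSF samples and is configurable. Direction calls in
MSS dynamics use a stability band of $|\Delta| < 0.005$.

## The synthetic cohort generator

Every analysis is exercised on synthetic cohorts whose structure mirrors the
assay's assumptions:

* **Tissue betas**: beta distributions parameterized by a
  (subtype $\times$ site-class) mean and a concentration of 20 — bounded
  support matches methylation ratios. Default means (H3K27M: 0.80 at H3
  sites / 0.15 at IDH sites; IDH: 0.50 / 0.90; DW: 0.12 / 0.15; noise sites
  0.30 everywhere) encode the published hyper/hypo pattern and give tissue
  MSS medians ordered H3K27M > DW > IDH with the IDH group negative.
* **CSF dilution**: $\beta_{CSF} = f\,\beta_{tumor} + (1-f)\,\beta_{bg}$
  with tumor fraction $f \sim \mathrm{Beta}(2,4)$ and a low-methylation
  background (mean 0.10, matching control profiles). No CSF tumor-fraction
  distribution is published for this disease; the Beta(2,4) default is a
  documented placeholder, not a cohort estimate.
* **DNA mass and detection limits**: mass is lognormal with
  $\mathrm{meanlog} = \log 2.5 + 2.5 f$, coupling recoverable DNA to tumor
  content so that BLOD ($< 5$ ng) samples are genuinely tumor-poor — the
  property that makes the BLOD/ALOD MSS contrast meaningful. BLOD samples
  carry no mutation calls.
* **Mutations**: every H3K27M tumor carries an H3F3A or HIST1H3B K27M call
  (9:1 isoform split), every IDH tumor an IDH1 call; concurrent TP53/ATRX
  calls appear at their reported subtype frequencies. CSF calls are detected
  with probability 0.95 (configurable) and VAF $= f/2$ times lognormal
  noise — a heterozygous driver, monotone in tumor content.
* **Survival**: Weibull proportional hazards (shape 1.2) whose scale
  shrinks with a latent risk and with H3K27M status, with administrative
  censoring.
* **Trajectories**: per-phase multipliers on a baseline tumor fraction,
  with distinct detection floors for mutation VAF and methylation signal
  (the methylation floor lower), so the minimal-residual-disease window —
  methylation persisting after the VAF disappears — exists by construction.

**What the generator does not emulate**, and hence what passing tests do not
show about real data: fragment-level biology (fragmentomics, digestion
chemistry, bisulfite conversion error), probe-specific noise and batch
effects, dependence between neighboring CpGs, non-linear relationships
between ctDNA content and methylation recovery, and cohort-realistic class
imbalance. Two consequences are worth stating plainly. First, the linear
dilution toward a 0.10 background shifts the absolute scale of CSF betas, so
a forest trained on undiluted tissue does not transfer its split thresholds
to synthetic CSF; the CSF analyses therefore train on CSF-type samples from
an independently seeded cohort. In the real assay, CSF methylation ratios
retain tissue-like scale and tissue-trained models transfer. Second, the MRS
saturates for clearly H3K27M synthetic samples, making the high-risk group
nearly collinear with H3 status; the multivariate independence of the risk
group is demonstrated on cohorts where the risk is generated independently
of subtype, not on the default cohort.

## Numerical and design choices

* Problem sizes in the test suite are chosen for a single-CPU desk run:
  cohorts of 45–200 samples per arm, panels of ~76–116 sites, 500 bootstrap
  coverage replicates, 500-patient survival checks.
* Degenerate inputs error loudly and early: empty classes, all-missing
  probes, out-of-range betas (reported by sample and CpG), non-monotone
  timestamps, unnormalized probability triples.
* Seeds are explicit everywhere randomness exists; fixed seeds give
  byte-identical cohorts, CV reports, forests, and bootstrap intervals.
  CSF derivation seeds a stream per timepoint from the cohort seed.
* Consensus selection canonicalizes candidate order before fitting, so the
  selected set is invariant to the order candidates are supplied.
* The exact published MSS values are not reproducible by construction — the
  probe identities of the real panel are not published — so all cohort-level
  claims are qualitative pattern checks (orderings, monotonicity,
  dominance), while formula-level behavior is checked exactly against
  independent oracles.

## Known limitations

The mutation rule is gene-level and ignores VAF magnitude; the classifier's
probabilities are uncalibrated vote fractions; the bootstrap resamples
samples, not patients, so repeated CSFs from one patient would be treated as
independent; and the DW subtype has no positive marker of its own — it is
recognized by the absence of both patterns, which is exactly why its
misclassification risk rises at low ctDNA content.
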