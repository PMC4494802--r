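---
title: "Methods: single-patient RNA-seq profiling against a frozen reference"
author: "nof1seq"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: single-patient RNA-seq profiling against a frozen reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The n-of-1 problem

Clinical transcriptomics asks a question cohort statistics were not built
for: given *one* tumor sample from *one* patient, which genes, pathways
and drug targets are altered? There is no contemporaneous cohort to
normalize against, and the answer must be reproducible months later when
the next patient arrives. `nof1seq` addresses this with a
*documentation-by-value* strategy: every quantitative parameter a new
sample's analysis needs is computed once from a reference cohort of
breast tumor and normal-tissue RNA-seq profiles and frozen into a single
versioned artifact (`FrozenReference`). A new patient sample is then
processed "add-on": it is scaled, filtered, tested and classified against
the frozen values without ever touching the cohort data again.

# Add-on normalization

The cohort is reduced to per-gene geometric means of raw counts,
$g_j = (\prod_s c_{js})^{1/S}$, with $g_j = 0$ whenever any cohort sample
has a zero count for gene $j$ (the median-of-ratios convention). A
sample's size factor is the median of $c_j / g_j$ over genes with
$g_j > 0$ and $c_j > 0$; requiring a positive count in the sample keeps
shallowly sequenced samples from having their medians dragged toward
zero. Because the add-on computation is identical to the cohort
computation, any sample that was part of the cohort recovers its cohort
size factor exactly — the property the package's consistency tests assert
to 1e-12. Normalized counts are reported on the $\log_2(x + 1)$ scale.

# Reliability filtering

Genes with zero raw counts in *every* cohort sample ("background genes")
estimate the noise floor of the platform. The patient's expression cutoff
is a quantile (default 0.95, linear interpolation) of the patient's own
log-expression over those background genes, and a gene is *reliably
expressed* only if its log-expression lies strictly above the cutoff.
Strict inequality guarantees that at quantile 1.0 the background genes
themselves never pass. Which side computes the cutoff — the patient's
values or the cohort's — was genuinely open; the patient side is used
because the cutoff should track the noise level of the sample actually
being reported, and the choice is a single exposed parameter
(`bgQuantile`).

# Single-sample differential expression

Classical cohort DE engines need replicates on both sides. The n-of-1
contrast instead tests each reliably expressed gene's observed count
against a negative-binomial null with mean
$\mu_j \cdot s_\text{patient}$ (frozen normal-tissue mean scaled by the
patient's size factor) and frozen per-gene dispersion $\alpha_j$
(variance $\mu + \alpha\mu^2$). Dispersions are method-of-moments
estimates $\max((v_j - \mu_j)/\mu_j^2,\ 10^{-8})$ over the normal
samples; the floor keeps the NB well-defined and approaches the Poisson
limit for underdispersed genes. No cross-gene shrinkage is applied —
moment estimates are transparent and directly testable; shrinkage is a
possible extension. The two-sided p-value is the doubled smaller tail,
$p = \min(1,\ 2\min(P[X \le x],\ P[X \ge x]))$, which is simple,
conservative, and exactly checkable against a mass-summation oracle.
Benjamini–Hochberg adjustment runs over the tested genes; a gene is
called at `adj_p < 0.05` and $|\text{log}_2\text{FC}| \ge 1$ by default
(both surfaced in configuration and report provenance; the thresholds are
conventional, not prescribed). Fold changes use a pseudocount of 1 on
both sides. Genes whose frozen normal mean is zero cannot be tested and
are flagged `degenerate` with $p = 1$ rather than dropped silently.

Because counts are discrete, the doubled-tail p-value is conservative by
construction: its null distribution exceeds uniform by roughly the
expected point mass at the observed count (~0.02–0.04 at the count
magnitudes of reliably expressed genes). The package's calibration tests
reflect this: the fraction of null raw p-values below 0.05 is asserted in
[0.03, 0.07] on a full-size simulation (~5,700 tested genes), while the
Kolmogorov–Smirnov uniformity check runs on 500 null genes, where the
test retains power against genuine errors (a mis-parameterized or
one-sided implementation fails it grossly) without triggering on
discreteness alone.

# Receptor status and molecular subtype

Binary receptor calls (ER/PR/HER2-style) and the 4-class intrinsic
subtype are nearest-shrunken-centroid classifiers on log-expression.
Standardized class-centroid differences
$d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))$ with
$m_k = \sqrt{1/n_k + 1/n}$, $s_0 = \text{median}_j(s_j)$, are
soft-thresholded at $\Delta$; genes with any surviving difference are the
model's signature. Prediction minimizes the prior-penalized standardized
distance $\delta_k(x) = \sum_j (x_j - \bar x'_{kj})^2/(s_j+s_0)^2 -
2\ln\pi_k$ and reports posterior-style probabilities
$\propto e^{-\delta_k/2}$; at $\Delta = 0$ this is exactly a
diagonal-covariance Gaussian classifier, which an independent oracle
verifies in the tests. $\Delta$ is selected by 10-fold stratified
cross-validation over a 30-point grid from 0 to $\max|d_{kj}|$, ties
resolved toward the largest $\Delta$ (fewest genes); the grid and fold
protocol are this package's choices since only error rates, not the
selection protocol, are conventionally reported. The argmax class is
always reported with its probability — no probability threshold is
applied. No pre-trained signatures are shipped — rebuilding a large
public tumor cohort is out of scope — so models are trained on the
user's (or synthetic) labeled cohort and serialize inside the frozen
reference.

# Topological pathway impact

Pathways are signed directed graphs (activation $+1$, inhibition $-1$;
other edge types configurable, weight 0 by default). With
$B_{ij} = \beta_{ij}/n_{ds}(j)$ (downstream counts floored at 1 so leaf
genes do not divide by zero), the net perturbation solves
$PF = \Delta E + B\,PF$, i.e. $PF = (I - B)^{-1}\Delta E$, where
$\Delta E$ carries the log2 fold changes of significant genes and 0
elsewhere. The per-gene accumulation is $Acc = PF - \Delta E$ and the
pathway statistic is $t_A = \sum Acc$. Its significance (`pPERT`) comes
from a bootstrap null that places the observed nonzero fold changes on
uniformly random pathway positions (2,000 draws by default, two-sided
around the null median, floored at 1/n_boot, seed recorded in
provenance). Over-representation (`pNDE`) is the hypergeometric upper
tail with the reliably expressed genes as the universe — the natural
universe since only tested genes could have been called. The two
components combine as $p_G = c - c\ln c$, $c = p_{NDE}\,p_{PERT}$, and
are BH-adjusted across pathways. A numerically singular $I - B$
(reciprocal condition number below 1e-10, e.g. a feedback loop of gain 1)
excludes the pathway with an explicit "unsolvable" warning rather than a
silently damped result — explicit failure is safer in a clinical report.

# Variant and fusion evidence

Variant calling and effect annotation happen upstream; this package
applies the filtering and joining rules. A variant is removed iff it is
flagged common/no-known-medical-impact or its population minor allele
frequency is present and strictly above 0.1; a missing MAF retains the
variant, since absent population data must not suppress a potentially
actionable call. Clinical evidence (COSMIC-like, ClinVar-like, CADD-like,
variant–drug rules) attaches only on an exact (chrom, pos, ref, alt) key
match — never position alone. Multi-allelic records are split per
alternate allele before filtering because the rules are per-allele;
indels are processed by the same exact key and flagged, as the stated
rule concerns single-nucleotide variants. Fusion candidate tables are
ingested and stably sorted by ascending oncogenic-potential p-value with
absent values last.

# Drug matching

Approved compounds match on three evidence types: expression (inhibitor,
antagonist and antibody actions pair with up-regulated targets, agonists
with down-regulated targets, "other" with either direction), variants
(exact-key rules), and significantly dysregulated pathways. The
action/direction rule table is this package's explicit definition —
whether the original workflow required direction concordance is unknown,
so `requireConcordance` is configurable and the applied rule is printed
in the report. Candidates consolidate to one row per drug ranked by
(distinct evidence types desc, evidence count desc, name asc) — a
deterministic total order.

# The synthetic cohort

The fixture generator emulates the statistical structure each stage
consumes, at desk scale, with one master seed determining everything:

* gene abundances lognormal (median 100 counts, sdlog 1) — typical of
  reliably expressed genes in bulk RNA-seq; dispersions gamma with mean
  0.05, the magnitude seen in homogeneous tissue cohorts;
* per-sample depth multipliers lognormal (sdlog 0.25) — the true size
  factors, returned as ground truth;
* 5% of genes forced to zero everywhere (background), matching the role,
  not the count, of the never-expressed gene set in a real cohort;
* a patient drawn from the normal model with 50 genes spiked at
  |log2 FC| = 3 (60% up), restricted to genes with normal mean ≥ 50,
  reflecting that recurrently dysregulated cancer genes are expressed
  genes; a handful are renamed to real drug-target symbols so the
  matching demo is meaningful;
* a 4-class subtype structure (30 marker genes shifted 2 pooled SDs,
  40 samples/class in classifier tests) and 20 random signed pathway
  topologies plus one planted pathway whose upstream hub activates
  up-spiked members;
* a hand-enumerable clinical fixture: 6 SNVs of which exactly 3 survive
  filtering, exactly 3 clinical annotations attach, and a 6-drug table
  with a fully enumerated match set (all synthetic).

What the generator deliberately does not emulate: gene–gene correlation,
batch effects, GC/length bias, isoform structure, or realistic breast
cancer expression covariance. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under their stated model,
not clinical performance on real tumors — the latter depends on a real
reference cohort and validated classifiers.

Classifier held-out evaluation reuses the training cohort's baseline
gene means and redraws only the noise, so held-out samples come from the
same population; redrawing the baseline would measure covariate shift,
not classifier error.

# Problem sizes and numerics

Simulation-based checks run at: 6,000 genes × 60 cohort samples for DE
calibration (~5,700 tested genes), 50 samples for add-on consistency,
500 genes × 160 samples for classifier training with 100 held-out
samples, 50 pathways × 2,000-gene universe for the pathway null, and
2,000 bootstrap draws for pPERT. These sizes make every distributional
band stable at its asserted tolerance while keeping a full run in tens of
seconds. Key numeric conventions: quantiles are type-7 (linear
interpolation); the dispersion floor is 1e-8; singularity is declared at
reciprocal condition number 1e-10; frozen references serialize doubles at
17 significant digits so thaw(freeze(x)) is bit-exact; BH ties and rank
handling follow `p.adjust`; classifier tie-breaks go to the largest
shrinkage (fewest genes), and prediction ties to the first class in
label order.

# Known limitations

* The single-sample NB test treats frozen normal parameters as known;
  uncertainty in the frozen means/dispersions is not propagated, so
  p-values are approximate for small normal cohorts.
* Discrete counts make the doubled-tail p conservative (see above).
* No cross-gene dispersion shrinkage; genes with extreme moment
  estimates get extreme dispersions.
* Pathway topologies must be supplied as edge lists; native Biocarta/
  KEGG/NCI/Reactome formats are not parsed here.
* Drug matching is evidence linking, not recommendation: dosing,
  interactions and trials are out of scope, and the printed rule table
  is the entire semantics.
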