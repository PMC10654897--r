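---
title: "Multivariate GWAS of cranial vault shape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate GWAS of cranial vault shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`vaultgwas` implements a joint multi-ancestry, global-to-local genome-wide
association pipeline for 3D cranial vault shape, together with simulators
that generate admixed genotype cohorts, local-ancestry tracts, vault-like
mesh cohorts with planted effects, and case-parent trios. The real cohorts
this class of study uses are access-restricted, so every stage here is
exercised end to end on synthetic data with known ground truth.

The pipeline, in order:

1. **Phenotyping.** Registered vertex configurations are symmetrized
   (averaged with their relabeled mirror image), aligned by generalized
   Procrustes analysis (GPA), quality-controlled by a Mahalanobis rule,
   and adjusted for covariates by partial least squares regression (PLSR).
2. **Segmentation.** A vertex similarity matrix blends the correlation of
   per-vertex distance-to-centroid profiles (weight 0.6) with spatial
   proximity on the mean shape (weight 0.4); hierarchical spectral
   clustering splits the vertex set 2-ways recursively into 1, 2, 4, and 8
   segments at levels 1-4, i.e. 15 segments in total.
3. **Per-segment shape spaces.** Each segment is independently aligned by
   GPA and decomposed by PCA; the retained dimension K comes from Horn's
   parallel analysis.
4. **Association.** Per SNP and segment, PC scores are residualized on the
   local ancestry of the SNP's 0.2 cM window (EUR and AFR diploid dosages,
   AMR as reference), and tested by canonical correlation analysis (CCA):
   with a single SNP the canonical correlation is the multiple correlation
   of regressing dosage on the K scores. Significance uses Bartlett's
   chi-squared, `-(n - 1 - (K + 2)/2) * log(1 - r^2)` on K df.
5. **Multiplicity and inflation.** The effective number of independent
   tests M_eff is estimated by genotype permutation (per probe SNP: 10,000
   permutations, minimum p across segments, `0.05 / 5th percentile`); the
   study-wide threshold is `5e-8 / M_eff`. Genomic inflation compares
   median normalized statistics `nu = chi2 / (D (1 + chi2 / N))` between
   the observed scan and an empirical permutation null.
6. **Loci.** Three-step clumping (250 kb; 1 Mb with r² > 0.01; merge leads
   within 10 Mb with r² > 0.01; drop singletons that miss the study-wide
   threshold), frontal/parietal labeling under the most-significant-hit and
   most-specific-hit schemes, and deformation hotspot maps.
7. **Population-genetic context.** Weir-Cockerham F_ST, genomic PCs with
   iterative LD pruning, covariate-adjusted LD scores, F_ST enrichment
   against MAF/LD-matched nulls, ancestry-partitioned dosages, and
   heterogeneity-of-effect likelihood-ratio tests.
8. **Replication and sharing.** Latent-trait projection with an F test and
   BH control, the transmission disequilibrium test for trios, and
   block-averaged Spearman statistics for cross-GWAS genetic sharing.

# The association model

For segment scores $Y \in \mathbb{R}^{n \times K}$ (covariate-adjusted,
then residualized on local ancestry at the SNP's window) and dosage
$g \in \{0,1,2\}^n$, the CCA with a univariate right-hand side reduces to
the OLS regression of $g$ on $Y$: $r^2 = R^2$, the loading is the
coefficient direction normalized to unit length in PC space, and

$$\chi^2 = -(n - 1 - (K+2)/2)\,\log(1 - r^2), \qquad p = P(\chi^2_K > \chi^2).$$

The rationale for this choice: the method is specified as a right-tailed
chi-squared with df equal to the number of phenotypic PCs; Bartlett's
correction is the standard CCA asymptotic, and its calibration (rather
than numerical identity with any particular implementation) is the
contract — the test suite verifies uniform null p-values, a genomic
inflation factor within [0.95, 1.05] against a permutation null, and
agreement of $r$ with an independent `stats::cancor` oracle on 200 fuzzed
instances.

Local-ancestry adjustment residualizes each score column on
$[1, a_{EUR}, a_{AFR}]$. Adjusting the phenotype on ancestry means the
scan has, by construction, no power against the ancestry-collinear part of
a SNP's dosage; a fully differentiated marker driving an ancestry mean
shift in shape is significant before adjustment and null after it (this is
asserted in the acceptance suite). Note the adjustment is not guaranteed
to *reduce* every association — residualized score space is not nested in
the raw one — but it removes ancestry-driven signal, which is its purpose.

The heterogeneity model partitions dosage by ancestry of the carrying
haplotype ($x_{EUR} + x_{AFR} + x_{AMR} = g$) and compares, by Gaussian
likelihood ratio, a full model with ancestry-specific slopes against the
constrained equal-slope model:
$\bar y = \beta_0 + \beta_1 a_{EUR} + \beta_2 a_{AFR} + \beta_3 x_{EUR} +
\beta_4 x_{AFR} + \beta_5 x_{AMR}$, with $\beta_2 = \beta_5 = 0$ in the
2-way (EUR vs AFR) scenario; the statistic is
$n \sum_j \log(RSS_{0j}/RSS_{1j})$ over phenotype dimensions with
$(k_{\text{groups}}-1)\,m$ df. Ancestries without allele copies are
dropped with the df reduced; fewer than two testable groups yields an
explicit "untestable" result.

# What the simulators emulate

**Genotypes.** Ancestral frequencies are uniform on (0.05, 0.95); each of
EUR/AFR/AMR drifts from them under the Balding-Nichols model
`Beta(p(1-F)/F, (1-p)(1-F)/F)`. The default drift F = 0.1 per population
plants differentiation that the Weir-Cockerham estimator recovers: the
ratio-of-sums ("weighted") multi-locus estimate centers on 0.10 at 5,000
SNPs and 200 diploids per population (the per-SNP ratio average centers
slightly lower, near 0.08, by Jensen-type bias; `fst_summary()` reports
both). Admixed haplotypes follow a Markov chain along the cM map: switch
events are Poisson with rate `generations_g` per Morgan (default 8) and
each switch re-draws the ancestry from the global proportions — a
stationary, deliberately simple tract model. Alleles are Bernoulli with
the local ancestral population's frequency, i.e. Hardy-Weinberg within
local ancestry and **no background LD beyond that induced by ancestry
tracts**; this suffices to exercise clumping and LD scores but does not
reproduce human haplotype structure (a documented limitation). Admixture
proportions default to 0.6/0.3/0.1 (EUR/AFR/AMR) in tests — the emulated
cohort's composition is not published, so proportions are a free
parameter.

**Shapes.** The template is a triangulated ellipsoidal dome (lateral
semi-axis 70 mm, longer front-to-back, mirror-symmetric about x = 0) at a
configurable vertex count — the real template has 11,410 vertices; tests
use 36-256. A subject's shape is the template plus background variation on
a latent orthonormal basis, plus `beta * dosage * direction` per causal
SNP, an optional per-ancestry mean shift scaled by window ancestry dosage,
covariate terms, and isotropic vertex noise (default SD 0.5 mm).

Three generator choices matter and were fixed once, from first
principles:

* *Causal directions are shape, not size.* Each causal direction is a
  regional normal-displacement bump projected orthogonal to the template's
  seven similarity modes (translations, infinitesimal rotations, uniform
  scaling) — GPA removes exactly those modes, so only their complement can
  carry signal through alignment. The default bump width is 0.3 of the
  mesh diameter: a regional deformation, matching the regional-to-global
  effects real loci show, and robust to where segmentation boundaries
  fall.
* *Causal directions segregate in the population.* Each causal direction
  is included among the background modes with SD 0.55 mm (`sd_causal`).
  An eigenvalue-based retention rule can only retain directions whose
  population variance stands above the noise bulk (the spiked-covariance
  detection threshold); a trait direction with no standing variation would
  be invisible to PCA regardless of the planted genetic effect. 0.55 mm
  sits above that threshold at the simulated mesh sizes while leaving the
  dose effect (beta = 0.4 mm per allele at MAF 0.5, vertex noise 0.5 mm,
  n = 600) detectable at 5e-8 with high power.
* *Power-study SNPs are not ancestry proxies.* `pick_causal_snp()` targets
  MAF 0.5 and requires local-ancestry R² < 0.1, because the adjusted test
  deliberately has no power against ancestry-collinear dosage variance —
  that property is tested separately.

**Trios.** Parents are drawn in Hardy-Weinberg equilibrium; heterozygous
parents transmit the target allele with probability `tau` (0.5 under the
null). The TDT statistic `(b - c)^2 / (b + c)` is tallied from genotypes.

# Numerical and procedural choices

* **GPA** iterates translation/unit-centroid-size scaling/rotation to a
  mean-shape tolerance of 1e-10 (max 100 iterations); rotations are proper
  (det +1). Scaling is on: shape, not form, is analyzed, with cranial size
  handled as a covariate.
* **Order of operations.** Symmetrized shapes are used only to build the
  similarity matrix and the segmentation; the shape spaces tested for
  association use the unsymmetrized adjusted shapes. Symmetrization makes
  mirrored-vertex noise perfectly correlated (rank-deficient), which
  breaks the column-permutation reference of parallel analysis.
* **Parallel analysis** compares observed eigenvalues with a percentile of
  eigenvalues from column-permuted data (1000 permutations by default; the
  function's conventional default percentile is 95). The *pipeline*
  default for segment spaces is the 99th percentile: Procrustes-aligned
  spectra have a noise bulk running a few percent above the permutation
  reference over many ranks, and the leading-run rule at the 95th
  percentile then returns unstable, inflated K; the stricter reference
  stabilizes K without affecting clearly separated modes.
* **Spectral bisection** uses the symmetric normalized Laplacian's Fiedler
  vector followed by seeded 1-D 2-means with 10 restarts; 2-vertex
  segments split trivially; a constant Fiedler vector (perfectly uniform
  similarity) falls back to an index split. Child segments are ordered by
  their smallest vertex index, so ids are deterministic.
* **Clumping** iterates the lead-merging step to a fixpoint, with ties in
  p broken by ascending (chrom, bp), making the locus set independent of
  processing order; the exhaustive-rule oracle in the test suite confirms
  identity on random instances.
* **Percentiles** (M_eff, F_ST enrichment, hotspots) use type-7 linear
  interpolation.
* **PLSR** is a SIMPLS-style deflation written in-package (each
  component's weights are the dominant singular direction of the deflated
  cross-covariance); with components equal to the covariate rank it
  removes the full linear effect. `mixOmics::pls` serves as an independent
  oracle in the tests.
* **Degenerate inputs.** Monomorphic SNPs are kept by the simulator and
  filtered (MAF >= 0.01) before association; constant genotypes and failed
  window lookups are skipped with recorded reasons; constant ancestry or
  covariate columns are dropped; negative F_ST estimates are clamped to 0
  for enrichment with the raw value retained; p-values are floored at the
  smallest positive double before -log10.

# Problem sizes used in the checks

The packaged checks run at desk scale, chosen to leave clear statistical
margins: null calibration uses 2,000 SNPs x 15 segments at n = 500;
effective-test bounds use 10,000 permutations; F_ST recovery uses 5,000
SNPs and 200 diploids per population; heterogeneity calibration uses 500
replicates at n = 2,000; detection/localization uses 50 replicates at
n = 600 on a 36-vertex vault; genetic sharing uses 50 replicate pairs of
600-SNP scans over 120 blocks. Meshes are far smaller than the 11,410
vertices of a real template — the algorithms are dimension-agnostic, but
passing tests demonstrate correctness and calibration of the machinery,
not field performance on imaging data.

# Known limitations

* No background LD, phasing error, or imputation uncertainty in the
  simulator; clumping and LD-score behavior on real haplotype structure is
  untested here.
* The tract model is a homogeneous Poisson process with re-draws from
  global proportions; real admixture tract-length distributions and
  assortative structure are richer.
* Eigenvalue-based M_eff estimators, mixed-model relatedness correction,
  X-chromosome models, and annotation/colocalization are out of scope.
* The one-tailed sharing p-value uses a normal approximation on the
  bootstrap SE; a percentile-bootstrap alternative would differ in small
  samples.
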