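---
title: "Stratification-aware association testing in half-sib dairy populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratification-aware association testing in half-sib dairy populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairygwas)
```

## The problem

Contemporary dairy cattle populations are shaped by artificial
insemination and decades of directional selection. A genotyped sample of
cows therefore contains large paternal half-sib families — all daughters
of one heavily used sire — and, frequently, an *elite* subgroup: one very
large family of high-merit cows that is genetically and phenotypically
distinct from the rest. Genome, pedigree and phenotype stratification
then overlap, and a naive per-SNP least-squares test confounds two
things: true allelic effects, and the mean difference between the elite
subgroup and everyone else. Alleles that are rare in the population but
common in the elite family (every daughter inherits half her alleles
from the shared sire) produce strong association signals whose
interpretation is ambiguous.

`dairygwas` implements the three standard corrections side by side, at
desk scale, together with the diagnostics that make the confounding
visible:

* a **GLS** test under half-sib intraclass correlation with a
  closed-form O(n) whitening factor,
* an **EMMAX-style mixed model** with IBS, Balding–Nichols or
  family-incidence kinship,
* **PCA-corrected least squares** (top principal components as
  covariates),
* IBS distance + classical MDS stratification maps, elite-cluster
  assignment, and elite-vs-average **allele-frequency-difference (AFD)**
  scoring,
* a forward **simulator** of half-sib populations that reproduces the
  confounding mechanism so every claim above is testable without any
  external data.

## Models

### Half-sib GLS

Phenotypes follow `y = X g + Z f + e` with family effects
`f ~ N(0, I sigma_f2)` and residuals `e ~ N(0, I sigma_e2)`. Within a
family of size `n_i` the covariance is compound-symmetric:
`V_i = sigma_e2 I + sigma_f2 J`. Writing `sigma2 = sigma_f2 + sigma_e2`
and the intraclass correlation `rho = sigma_f2 / sigma2`, each block has
the closed-form inverse `(1/sigma_e2)(I - r_i J)` with
`r_i = rho / (1 + (n_i - 1) rho)`. The package never forms `V` or its
inverse: `build_whitener()` constructs an upper-triangular factor `L`
with `L'L = V^{-1}` whose rows hold one diagonal value and one constant
off-diagonal value, derived by an O(n_i) recurrence per family
(matching the entries of `L'L` row by row), and `whiten()` applies it
with running suffix sums in O(n_i) per column. Storage is O(n), never
O(n^2); `whitener_dense()` materializes `L` only for verification.

Variance components are estimated once per trait under the null model
by profiling the Gaussian likelihood over `rho` on a grid over
[0, 0.999] (boundary admissible) with closed-form `sigma2(rho)`,
followed by Brent refinement; ML is the default, matching the original
estimation choice for this model, with REML available. The fitted
covariance is then held fixed for every SNP — the same once-per-trait
approximation the mixed model uses, appropriate when scanning tens of
thousands of markers.

Each SNP is tested with a 3-genotype-class design (one indicator per
observed class, ordered by decreasing allele-1 dosage). Contrasts are
the equal-weight orthogonal pair: additive `(1, 0, -1)` and dominance
`(-1, 2, -1)/2`, with the two-class difference contrast when only two
classes are observed; the provider is pluggable (`default_contrasts`) so
frequency-weighted contrasts can be substituted. The statistic
`T = s'g / sqrt(s2 * s'(X'V^{-1}X)^{-1}s)` is referred to Student-t with
`n - k` degrees of freedom, two-sided. The per-SNP summary p-value is
`min(p_additive, p_dominance)` — a *ranking* device, retained alongside
both constituent p-values; calibration statements in this vignette and
in the tests always use a single contrast. `coding = "additive"`
switches to a 0/1/2 dosage regression, which is what makes the GLS and
mixed-model scans directly comparable.

### EMMAX-style mixed model

`y = X b + u + e` with `var(u) = K sigma_a2`. K is eigendecomposed once
(`estimate_vc_emma`), the likelihood (REML by default — the mixed-model
software convention; ML for cross-method comparisons) is profiled over
`delta = sigma_e2/sigma_a2` on a log grid spanning 1e-5…1e5 with Brent
refinement, and the scan reuses the rotation: after one O(n^2 m)
rotation of the dosage matrix, each SNP costs O(n) (Frisch–Waugh
projection under the fixed weights). With `K = kinship_family()` — the
0/1 family-incidence Gram matrix — the mixed model's covariance
`sigma_a2 ZZ' + sigma_e2 I` is *exactly* the GLS covariance, which gives
the package its strongest internal consistency check: both scans must
agree per SNP to optimizer precision (observed ~1e-8 in p) when both
use ML.

Kinship flavors: `kinship_ibs` (mean shared-allele proportion, pairwise
complete over called genotypes), `kinship_bn` (Gram matrix of dosages
centered by `2p` and scaled by `sqrt(2p(1-p))`, monomorphic SNPs
dropped, missing entries mean-imputed on the standardized scale), and
`kinship_family`. The IBS matrix doubles as the MDS distance input
(`distance = 1 - IBS`).

### PCA correction and the elite-exclusion rerun

`compute_pcs` takes the same standardized dosage matrix and returns
orthonormal individual-space components from the eigendecomposition of
`ZZ'`; `ls_scan(..., n_pcs = 20)` uses them as covariates (20 is the
study convention; the count is a free parameter and results can depend
on it). PCs are computed once on the full marker set including each
tested SNP — a single basis, not leave-one-chromosome-out.
`ls_scan(..., exclude = )` re-runs the uncorrected analysis without a
set of individuals (the elite family), recomputing allele frequencies
and PCs on the retained sample.

### Stratification maps and AFD

`classical_mds` is Torgerson MDS via `stats::cmdscale` on `1 - IBS`;
axis signs are fixed (elite mean positive on C1) for reproducible
plots, and non-positive eigenvalue dimensions are dropped.
`assign_clusters` either labels a known family or runs 2-means on
(C1, C2) with a deterministic initialization (the two individuals
furthest apart on C1), labelling the smaller cluster elite.
`afd_table` reports, per SNP, the favorable-allele frequency in each
cluster and `AFD = |p_elite - p_average|`; AFD is invariant to which
allele is designated, so threshold counts (e.g. AFD >= 0.3, 0.4) are
trait-free, while the reported allele is oriented by the trait's
direction of favorability (low PTA favorable for somatic cell score,
calving ease and stillbirth traits; high for the rest — see
`default_trait_catalog()`).

## The simulator

`simulate_population(sim_config())` generates the study conditions:
1,654 cows from 355 sires with family sizes 1–160, the largest family
(160 daughters) being the elite one. Sires are two haplotypes drawn
from a base allele-frequency distribution (uniform on 0.05–0.95,
mimicking array-ascertained common variants); each daughter receives
one paternal haplotype recombined with a Poisson crossover count
(mean 1 per chromosome per meiosis) at uniform breakpoints, plus one
maternal haplotype drawn site-wise from the base frequencies — dams are
unrelated, which is exactly the half-sib intraclass model downstream.
On the X chromosome the sire transmits a single haplotype without
recombination outside the pseudo-autosomal interval
(`par_boundary_bp`, default 0: no pseudo-autosomal sites, since no
boundary is claimed), so all daughters of a sire share it identically —
the mechanism behind the X chromosome's uniquely clean stratification
pattern.

At *planted* loci the elite sire's haplotypes are overridden to carry
the designated allele and elite daughters' maternal draws are adjusted
so the realized elite frequency matches its target while the rest of
the population sits at the average-cluster frequency. Phenotypes per
trait are `mu + sum(dosage x effect x dir) + f + e` with Gaussian
family effects (variance `sigma_f2`), residuals (`sigma_e2`), and
`dir = -1` for low-favorable traits. `elite_mean_shift` adds a
family-level shift in each trait's favorable direction, representing
elite polygenic merit not attributable to the typed loci. Identical
configurations are bit-identical (`seed`).

What the generator does **not** emulate: linkage disequilibrium between
markers, dam-side pedigree, multi-generation selection dynamics, and
genotyping error. Passing tests therefore demonstrate the estimators'
behavior under the assumed covariance structure and a clean version of
the elite-confounding mechanism — not robustness to LD, call-rate
artifacts or mis-specified pedigrees.

### Scenario presets and problem sizes

The package fixes four scenarios (`?scenarios`) used by its tests and
by `scripts/acceptance.R`:

* `sim_null_config` — balanced intraclass null, 100 (or 500) families
  of 10, `sigma_f2 = 1`, `sigma_e2 = 3` (`rho = 0.25`), 2,000 markers:
  type-I calibration and variance-component recovery.
* `sim_cluster_confounded_config` — 1,654 cows, `sigma_f2 = 0`,
  elite shift 2 SD, 2,000 markers. Setting the family variance to zero
  isolates the elite-cluster axis as the *only* confounder; that is the
  case PCA correction is designed for (20 components cannot span 354
  additional small-family effects, which would be a different — and for
  PCA, unfavorable — question).
* `sim_elite_confounded_config` — the full mechanism: family variance
  plus elite shift plus 20 planted loci (elite 0.9 vs average 0.1,
  additive effect 0.25). Here the correlation-based methods absorb the
  elite family through the family/kinship term.
* `sim_mds_config` — 5 autosomes + X at 80 markers each. Simulated
  markers carry no LD, so each is fully informative; 80 per chromosome
  corresponds to the LD-limited effective marker count of a real array
  chromosome. Above that the elite family separates at purity 1.0 on
  *every* chromosome and the X-versus-autosome contrast — double IBS
  signal on X because daughters share the whole paternal X rather than
  a recombined half — has no room to appear.

Marker counts per scenario (2,000 for calibration, 500 for the
20-replicate mechanism runs, 80/chromosome for MDS) are the package's
scaled-down study sizes; the generator's population shape (1,654 / 355
/ 160) is kept throughout.

## Numerical choices

* `rho` is searched on [0, 0.999]; boundary estimates are reported, not
  errors; `sigma_e2` under 1e-12 aborts whitener construction with the
  offending value.
* Whitening orientation: the factor satisfies `L'L = V^{-1}` and the
  whitened normal equations reproduce `X'V^{-1}X` exactly (verified
  against dense solves to ~1e-15); the notational question of whether
  the "prime" sits on the factor or its application is resolved by that
  contract.
* Rank-deficient per-SNP designs (a class indicator collinear with
  covariates) mark the SNP untestable rather than aborting the scan;
  monomorphic SNPs are untestable with `p = NA`.
* Ties in p-value ranking break by (chromosome, position) ascending,
  X after the autosomes; AFD ranking ties likewise. Significance
  flagging is inclusive (`p <= threshold`).
* Missing calls: excluded from a SNP's test (GLS/LS rebuild the
  whitener for the reduced family sizes, reusing the null variance
  components) and from frequency counts; mean-imputed only in the
  mixed-model scan's dosage (to keep the cached rotation aligned) and
  in the standardized matrix behind kinship/PCA. No imputation of
  output genotypes.
* `estimate_vc_ml` is ML by default, `estimate_vc_emma` REML by
  default — deliberately asymmetric, matching each method's native
  convention; both are switchable and the equivalence checks pin both
  to ML.

## Design decisions taken where the design was open

* The per-SNP summary `min(p_add, p_dom)` is an assumption about how
  two contrasts combine into one ranking; both p-values are always
  exported so any other combination can be applied downstream.
* The 3-class coding is used for the PCA-corrected scan (comparability
  with GLS); the mixed-model scan uses additive dosage (its tool
  convention). `coding = "additive"` aligns them when needed.
* The Balding–Nichols kinship is implemented as the
  frequency-standardized Gram matrix — the de-facto construction in
  mixed-model association software; no bit-equivalence with any
  specific external implementation is claimed. Note a single
  all-homozygote SNP at `p = 0.5` yields standardized values
  `+-sqrt(2)` (diagonal 2), a direct consequence of the
  Hardy–Weinberg scaling.
* Daughter stillbirth (DSB) is treated as low-favorable by analogy
  with the explicitly low-favorable calving traits; the flag is
  overridable in `default_trait_catalog()`.
* The elite cluster defaults to the MDS/2-means assignment; a family-id
  override reproduces the known-family usage.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_elite_confounded_config(seed = 3)
pop <- simulate_population(cfg)
thr <- significance_threshold(0.05, n_snps(pop$genotypes))

ls   <- ls_scan(pop$genotypes, pop$phenotypes, "MY")
gls  <- gls_scan(pop$genotypes, pop$phenotypes, "MY", pop$families)
emx  <- emmax_scan(pop$genotypes, pop$phenotypes, "MY",
                   K = kinship_ibs(pop$genotypes))
lsx  <- ls_scan(pop$genotypes, pop$phenotypes, "MY",
                exclude = pop$elite_ids)

planted <- pop$truth$snp_id
hits <- function(r) sum(r$p[match(planted, r$snp_id)] <= thr, na.rm = TRUE)
c(LS = hits(ls), GLS = hits(gls), EMMAX = hits(emx), LS_no_elite = hits(lsx))
```

On this seed the planted loci yield 20 significant effects under
uncorrected LS, 1 under GLS, 15 under EMMAX-IBS, and 0 once the elite
family is removed from LS — the confounding mechanism in miniature:
correction and elite removal take away largely the same signals, so a
correction can discard effects that are real but carried by the elite
subgroup.

## Limitations

* No LD, so marker counts are effective-marker counts; absolute
  significance levels on simulated data do not transfer to real arrays.
* The GLS family term covers sire families only; other shared
  environments (herds, years) would need their own grouping.
* No dominance variance component, multi-trait models, or exact per-SNP
  variance re-estimation (full mixed-model scan).
* The 2-means elite assignment assumes exactly one elite cluster;
  populations with several distinct subgroups need the family-id
  override.
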