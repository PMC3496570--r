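Package: dairygwas
Title: Stratification-Aware GWAS for Half-Sib Dairy Cattle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association testing for dairy cattle populations with strong
    half-sib family structure. Implements a generalized least squares (GLS)
    test under compound-symmetry (intraclass) covariance with a closed-form
    O(n) whitening factor, an EMMAX-style mixed-model test with identity-by-
    state (IBS), Balding-Nichols or family-incidence kinship, principal-
    component-corrected and uncorrected least squares scans, IBS/classical-
    MDS genome stratification analysis with elite-cluster assignment, and
    elite-versus-average allele-frequency-difference (AFD) scoring. Includes
    a forward simulator of half-sib populations with an elite family,
    planted divergent loci, X-chromosome sire-haplotype sharing, and
    PLINK-style text genotype input/output, so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
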