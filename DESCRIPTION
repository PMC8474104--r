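Package: delcall
Title: Indirect Genotyping of a Recurrent Alpha-Globin Deletion from SNP-Array Data
Version: 0.1.0
Authors@R:
    person("delcall", "maintainers", email = "delcall@example.org", role = c("aut", "cre"))
Description: Tools for evaluating indirect genotyping of the common 3.7 kb
    alpha-thalassaemia deletion from genome-wide SNP-array data. Provides a
    seedable synthetic cohort generator emulating a recurrent deletion on
    multiple haplotype backgrounds with dosage-dependent probe intensities;
    haplotype and linkage-disequilibrium statistics (r, r-squared, D-prime,
    extended haplotype homozygosity, haplotype diversity, Tajima's D);
    intensity-based genotype callers (density cut-offs, hierarchical
    clustering, multinomial softmax regression, classification trees);
    Li-Stephens haplotype-copying imputation with cross-validation and
    no-call thresholds; covariate-adjusted case-control association testing
    under additive, genotypic, dominant, recessive and heterozygous models;
    and unified performance reporting comparing inferred against directly
    typed genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
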