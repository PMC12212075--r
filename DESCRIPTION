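Package: aneudose
Title: Sex-Chromosome Aneuploidy Dosage Analysis for RNA-seq and RRBS
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Territory-aware analysis of sex-chromosome dosage effects in
    47,XYY and 47,XXY karyotypes from bulk RNA-seq counts, allele-specific
    SNP read counts and RRBS CpG methylation tables. Implements
    pseudoautosomal (PAR1/PAR2) and NPX/NPY territory classification,
    negative-binomial Wald differential expression with median-of-ratios and
    TMM normalization, allelic-fraction classification of mono- and
    biallelic SNP expression, Pearson Y-dosage sensitivity screening,
    clone-resampling bootstrap assessment of DEG stability, male-median
    LOESS expression profiles along a chromosome, cross-syndrome DEG
    concordance, and beta-binomial differentially methylated region calling.
    Ships a synthetic-data generator that emulates aneuploid karyotypes with
    a patient-clone hierarchy for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
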