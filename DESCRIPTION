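Package: tgdrive
Title: Trans-Complementing and Full CRISPR Homing Gene-Drive Genetics and
    Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetics and population-dynamics machinery for CRISPR homing
    gene drives, with an emphasis on split ("trans-complementing") drives in
    which the Cas9 and guide-RNA cassettes occupy separate loci and home only
    when combined in one individual.  Provides exact inheritance cubes
    (offspring genotype distributions per parental pair) for autosomal and
    X-linked, linked and unlinked architectures; a fly cross simulator with
    zygotic maternal-deposition cleavage, clonal germline-precursor structure
    and categorical resistant-allele (indel) spectra; maximum-likelihood
    estimation of conversion efficiency from vial scoring tables;
    randomization tests for differences in means and proportions; and a
    single-patch, daily-time-step, genotype-resolved stochastic mosquito
    life-history model with release schedules and replacement/suppression
    experiment drivers and summary metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
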