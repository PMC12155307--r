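Package: burdenscan
Title: Deleterious Mutation Burden Screening in Crop Breeding Gene Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens deleterious variants in genotyped crop cohorts by
    combining SIFT functional-effect scores with GERP++ rejected-substitution
    conservation scores, estimates per-cultivar homozygous, heterozygous and
    total mutation burdens per deleterious locus, and tests burden trends over
    cultivar registration years and yields. Includes per-site nucleotide
    diversity by breeding period, genotype principal component analysis,
    yield harmonization across report sources, and a synthetic-cohort
    generator with known ground truth that emulates a century-scale
    selfing-crop breeding pool for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
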