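Package: autozyg
Title: Runs of Homozygosity, Genomic Inbreeding Coefficients and ROH Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) in diploid SNP genotype
    panels under outcome-based criteria (minimum length, heterozygote and
    missing-call allowances, a false-positive-rate derived minimum SNP count,
    marker density and inter-marker gap bounds), estimation of four genomic
    inbreeding coefficients (F_ROH, F_GRM, F_HOM, F_UNI) and their
    correlations, genome scans for ROH islands with adjacent-SNP linkage
    disequilibrium ratios, identity-by-state distance matrices with principal
    component cluster checks, PLINK PED/MAP and BED/BIM/FAM input/output with
    quality-control filtration, and a genotype-panel simulator that plants
    autozygous identity-by-descent tracts and shared homozygous haplotype
    islands with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
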