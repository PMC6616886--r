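Package: hcr
Title: Homologous Coverage Ratio for Genome-to-Genome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the homologous coverage ratio (HCR), an overall
    genome relatedness index for microbial taxonomy built from
    whole-genome comparison.  A fast k-mer cross-containment
    approximation screens large genome collections for suspect
    taxon pairs; a precise alignment-coverage ratio, computed from
    E-value-filtered local alignments projected onto both genomes,
    refines the candidates.  Includes taxonomy-aware ambiguity
    screening of genus and phylum boundaries, classical
    multidimensional scaling of HCR distances for ordination plots,
    a deterministic synthetic genome-pair generator with planted
    homologous fractions, and a command-line interface for the
    two-stage screen/refine workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
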