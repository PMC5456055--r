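Package: plastomeCompare
Title: Comparative Analysis of Annotated Chloroplast Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of closely related chloroplast
    genomes (plastomes): detection of the inverted repeat and quadripartite
    partitioning (LSC/IRb/SSC/IRa) with junction profiling and gene census;
    extraction of homologous coding and noncoding (spacer/intron) regions
    with one inverted-repeat copy removed; per-region divergence statistics
    (variable positions, substitutions, indel events, percent variability)
    and mutational-hotspot screening; perfect chloroplast microsatellite
    (cpSSR) detection and classification; and whole-plastome concatenation
    statistics with a Jukes-Cantor neighbor-joining tree and bootstrap
    support. Includes a simulator of annotated quadripartite plastomes
    evolved along a known tree, so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    BiocGenerics,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'align.R'
    'divergence.R'
    'sequence-utils.R'
    'quadripartite.R'
    'regions.R'
    'simulate.R'
    'evolve.R'
    'genbank-io.R'
    'phylo.R'
    'utils.R'
    'tables.R'
    'ssr.R'
    'pipeline.R'
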