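Package: litmesh
Title: Literature-Based MeSH Annotation of Transcriptome BLAST Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based functional annotation for de novo assembled
    transcriptomes of non-model organisms, aimed at teleost fish. Instead of
    transferring pre-defined ontology tags from a best homolog, litmesh takes
    deep BLAST hit lists (up to 500 protein hits per query contig), resolves
    each protein accession to its linked PubMed articles, and scores the MeSH
    headings of those articles with a per-query normalized correlation score
    (term count divided by the query's article count). Term scores are summed
    over queries, ranked, and optionally restricted to the immune-system
    branches of the MeSH tree (A15, G12). Includes parsers for BLAST tabular
    output, MEDLINE XML, MeSH tree maps and NCBI taxonomy dumps, a taxon
    subtree extractor for building taxon-restricted BLAST databases, a
    hit-depth sensitivity scan, report writers, and a seeded synthetic corpus
    generator with planted term enrichment for end-to-end offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
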