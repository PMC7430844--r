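Package: metaprof
Title: Abundance Profiles, Subsets and Queries for Assembled Metagenome
    Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parses tab-separated project tables from assembly-based
    metagenomic pipelines (ORFs, contigs, bins, sample metadata) into a
    single project object, and recomputes all aggregate profiles from the
    ORF level: read and base counts, TPM (length- and depth-normalised
    abundances), per-genome function copy numbers anchored on the
    RecA/RadA universal single-copy gene (COG0468) or on the median of a
    configurable set of universal single-copy genes, and taxonomic
    percentages over total sequenced reads.  Provides taxonomy, bin and
    function subsetting with explicit rescaling semantics, a boolean
    query language over contig taxonomy, function content and per-sample
    abundance for prefiltering large assemblies, a synthetic-project
    generator with known ground truth, and exporters for Krona text,
    spreadsheet tables and plot-ready summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
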