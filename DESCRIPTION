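Package: cubkit
Title: Codon Usage Bias Analysis for Viral Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias in coding sequences, built
    around the indices used to study host adaptation of RNA viruses of the
    honeybee: nucleotide and positional base composition, relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC) with its
    GC3s-conditional null curve, dinucleotide odds ratios, codon adaptation
    index (CAI), relative codon deoptimization index (RCDI), PR2 bias and
    neutrality regressions, correspondence analysis of RSCU profiles, protein
    hydropathy (GRAVY) and aromaticity, and index correlation matrices. A
    seeded synthetic coding-sequence generator with controllable GC3s, host
    mimicry and CpG depletion makes every stage testable without downloads,
    and a pipeline function reproduces the full multi-virus analysis surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
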