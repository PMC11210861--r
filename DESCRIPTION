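Package: knotlink
Title: Cystine-Knot Ligand Dimerization Analysis and Survival-Based
    Genetic Interaction Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether TGF-beta family ligands can form
    homo- and heterodimers, built around the Caenorhabditis elegans
    ligands TIG-2 and TIG-3. Annotates ligand precursors by scanning for
    proprotein-convertase cleavage sites with the (R/K)-Xn-(R/K) motif
    rule and splitting chains into signal, prodomain and mature domains;
    assigns cystine-knot intrachain disulfide connectivity and detects
    the presence or substitution of the interchain dimerization cysteine
    by pairwise alignment; parses predicted dimer structures (PDB/mmCIF)
    and predicted-aligned-error (PAE) matrices to extract
    confidence-filtered interchain contacts and region-pair interface
    summaries; turns multimer confidence metrics (pLDDT, pTM, ipTM) into
    dimer-support verdicts benchmarked against a panel of known dimers;
    and classifies genetic interactions between ligand pairs from
    right-censored survival cohorts using Kaplan-Meier estimation and
    the log-rank (Mantel-Cox) test. A synthetic-data generator produces
    every input the pipeline consumes with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
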