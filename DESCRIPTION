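Package: nitroguild
Title: Nitrogen-Cycle Functional Guilds and Co-Occurrence Networks from
    Amplicon Community Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links amplicon-derived soil community composition to
    nitrogen-cycle function. Provides qPCR-based scaling of relative OTU
    abundances to absolute SSU gene copy numbers, genus-level annotation
    and quantification of nitrogen-cycle functional guilds
    (denitrification, DNRA, nitrate reduction, nitrogen fixation,
    ammonia oxidation), ensemble co-occurrence network inference with
    five association measures, permutation nulls, bootstrap edge
    stability, Brown's dependent p-value merging and Benjamini-Hochberg
    correction, keystone-OTU identification by node centrality,
    fumigation-extraction microbial biomass and soil stoichiometry
    calculators, and a synthetic community generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    vegan,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
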