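Package: tallysearch
Title: Closed Database Search of DDA Tandem Mass Spectra with Satellite-Ion Intensity Tally
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-search kernel for data-dependent acquisition (DDA)
    proteomics. Compiles a user's fixed and variable modifications into a
    minimal set of compatible combinations, digests protein databases in
    silico, matches MS/MS spectra in two stages (primary b/y ions, then
    satellite neutral-loss and doubly charged ions whose intensities are
    tallied onto the primaries), scores peptide-spectrum matches by
    progressive hypergeometric enrichment, controls FDR by target-decoy
    competition with subclass transfer, localizes modification sites by a
    counting statistic, and groups proteins by incidence clustering with
    greedy set cover. Ships a seeded synthetic-spectrum generator so the
    whole engine is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    Matrix,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
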