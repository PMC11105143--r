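Package: icd11impact
Title: Assessing the Impact of the ICD-11 Transition on Comorbidity Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how transitioning administrative diagnosis
    coding to ICD-11 for Mortality and Morbidity Statistics (ICD-11-MMS)
    affects the Charlson and Elixhauser comorbidity indices. Builds directed
    crosswalks between ICD-9-CM, ICD-10-CM and ICD-11-MMS from general
    equivalence mapping (GEM) files, WHO ICD-10-to-ICD-11 map tables,
    ICD-10-CM-to-ICD-11 map tables with postcoordinated expressions, and
    UMLS concept-equivalence (MRCONSO) extracts, completing coverage by
    hierarchy-based reverse engineering. Assigns comorbidity categories to
    coded hospital stays in any of the three versions, derives ICD-11
    category tables by mapping inheritance, scores the indices under
    configurable weight schemes with severity hierarchies, and compares
    score distributions across codings (paired t tests, Pearson correlation
    with Fisher intervals, backward stepwise logistic reweighting with
    integer weight derivation, Spearman comparison of weight vectors). A
    ground-truthed synthetic data generator emulates MIMIC-style diagnosis
    tables and mapping sources so the whole pipeline is testable without
    access to credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
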