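Package: ehrformer
Title: Transformer Representation Learning for Coded Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional self-attention sequence modelling for longitudinal
    coded electronic health records. Patient histories are tokenized as
    CLS/SEP-delimited visit sequences with a four-channel embedding (diagnosis
    code, age, alternating visit segment, sinusoidal visit position), pretrained
    with a masked-language-model objective over diagnosis codes, and fine-tuned
    for multi-label prediction of diseases in the next visit or a 6/12-month
    horizon. Includes a seeded synthetic trajectory generator with planted
    disease-group and attribute structure, per-patient average-precision and
    AUROC evaluation (disease-wise, first-incidence, embedding-channel
    ablation, attribute-consistency audit), attention-map extraction and
    cosine nearest-neighbour exploration of learned disease embeddings, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
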