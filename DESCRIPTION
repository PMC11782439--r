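Package: cvdfewshot
Title: Few-Shot Adaptation of Vision-Language Image Classifiers to Color
    Vision Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how few-shot (in-context) vision-language
    classification of dermoscopic images behaves under simulated color
    vision deficiency (CVD). Provides dichromat simulation (protanopia,
    deuteranopia, tritanopia) by projection in LMS cone space, applied
    identically to query and reference images; a leave-one-out few-shot
    classification protocol with a pluggable backend contract and a
    deterministic nearest-reference mock backend; a repeat-and-consensus
    evaluation harness with confusion counts and a matched-versus-
    non-simulated reference ablation; mining of prediction explanations
    into RED/PINK color-mention groups with per-replicate melanoma-rate
    comparison; and a synthetic two-class lesion image generator so the
    whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
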