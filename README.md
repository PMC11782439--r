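# cvdfewshot

Few-shot adaptation of vision-language image classifiers to color vision
deficiency (CVD), with an offline, fully reproducible evaluation harness.

## The problem

Color vision deficiency affects roughly 8% of the population, and
dermoscopy is one of the most color-dependent diagnostic skills: the
difference between a melanoma and a benign nevus often rides on red,
pink, brown and blue-gray cues. A vision-language classifier that reasons
about an image in *normal* color terms is of limited help to a dichromat
user — its explanations reference colors the user does not perceive.

The idea implemented here is **matched-condition adaptation**: simulate the
*same* dichromacy (protanopia, deuteranopia or tritanopia) on both the query
image and the few-shot reference images placed in the prompt, so the
classifier's color reasoning is aligned with the user's percept. The package
provides everything needed to study this protocol without any proprietary
model or clinical data:

* **Dichromat simulation** by projection in LMS cone space. For a linear-RGB
  pixel `c`, the simulated pixel is
  `c' = M⁻¹ · P · M · c`, where `M` is the RGB→LMS matrix and `P` is a rank-2
  idempotent projection onto the dichromat's residual color plane. Protanopia
  and deuteranopia use a single plane through the display-white axis
  (Viénot-style reduction); tritanopia uses the two-half-plane Brettel
  construction with spectral anchors at 485 nm and 660 nm. The Machado
  severity-1.0 matrices are available as an alternative family.
* **A few-shot protocol**: leave-one-out reference sampling (k per class),
  versioned prompt composition, a pluggable backend contract, and a
  deterministic mock backend that literally implements the
  "pick the most similar reference" rule via mean-color distance.
* **A repeat-and-consensus harness**: n repeats with per-repeat accuracy
  (mean ± sd), majority-vote consensus (melanoma iff ≥ 5 of 10 votes by
  default), confusion counts, and a matched-vs-non-simulated reference
  ablation with shared sampling seeds.
* **Explanation mining**: partition prediction explanations into RED
  (mentions red, regardless of pink) and PINK (pink without red) groups and
  compare per-replicate melanoma-prediction percentages with a two-tailed
  Welch t-test.
* **A synthetic fixture generator** producing balanced two-class
  lesion-on-skin image sets whose class-conditional color distributions
  differ (multi-hued, red-heavy, irregular melanomas vs uniform light-brown
  or pink nevi), so every downstream stage has real signal to work with.

## Worked example

```r
library(cvdfewshot)

man <- generate_fixtures(
  fixture_spec(n_per_class = 10, image_size = c(64, 64), seed = 20240427),
  file.path(tempdir(), "readme"))
class_counts(man)
#> melanoma    nevus
#>       10       10

ab <- run_ablation(man, "tritanopia", backend_mock(),
                   config = experiment_config(n_repeats = 10, base_seed = 1))
ab
#> <cvd_ablation> tritanopia | matched 0.800 vs non-simulated 0.735 (diff +0.065)

consensus(ab$matched)
#> <cvd_consensus> threshold >= 5 votes | accuracy 0.950 over 20 images

mine_explanations(ab$matched)$comparison
#> <cvd_group_comparison> RED (62.2%, n=10) vs PINK (34.5%, n=10)
#>   welch t = 7.187, df = 13.77, p = 5.112e-06
```

Reading the numbers: with tritanopia simulated on the queries, the mock
classifier scores a mean per-repeat accuracy of 80.0% when the references
are simulated to match, versus 73.5% when they are left in original color —
the matched-condition advantage the framework exists to measure. Vote
consensus over the ten repeats lifts accuracy to 95% on this small set.
Explanations mentioning red predict melanoma far more often (62.2% of
replicate-level predictions) than explanations mentioning pink without red
(34.5%), and the Welch test puts that difference at p < 0.001.

Every result type has `tidy()`, `glance()` and `autoplot()` methods, so runs
drop straight into dplyr/ggplot2 workflows. A command-line front end with
`simulate`, `generate-fixtures`, `run`, `consensus`, `ablate`, `mine` and
`demo` subcommands is installed under `inst/cli/`, and
`run_demo(out_dir, seed)` executes the whole pipeline end to end with no
network.

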