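---
title: "Methods: dichromat simulation and the matched-condition few-shot protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dichromat simulation and the matched-condition few-shot protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures behind `cvdfewshot`: how
dichromacy is simulated, how the few-shot classification protocol and its
evaluation harness are defined, what the synthetic fixtures do and do not
emulate, and the numerical and design choices a user should know about.

## Dichromat simulation

### The projection model

A dichromat lacks one of the three cone classes, so the set of colors they
can distinguish forms a two-dimensional subspace of cone-excitation (LMS)
space. Simulation therefore has a natural linear-algebraic form: map a pixel
from sRGB to linear light (IEC 61966-2-1 piecewise transfer function:
linear segment below 0.04045 on decoding, exponent 2.4 above), then to LMS,
project onto the dichromat's residual plane, and map back:

    c' = clip( M⁻¹ · P · M · decode(c) )

with `M` the linear-RGB→LMS matrix (the unnormalised D65
Hunt–Pointer–Estevez scaling) and `P` a projection. The projection form is
what makes the module testable: `P` is rank 2 and idempotent, so simulating
twice equals simulating once (up to clipping), every simulated pixel cloud
is planar, and the achromatic axis is a fixed line of the map.

For protanopia and deuteranopia the package uses the single-plane reduction:
one plane containing the display-white axis, in the direction fixed by the
published coefficients (2.02344 for the missing-L reconstruction, 0.494207
for missing-M). One numerical refinement is applied: the published S-axis
coefficients place the display white on the plane only to about one part in
10⁴, which would leave visible (if tiny) residues on gray ramps. The package
keeps the published leading coefficient and re-solves the S coefficient so
the plane contains the white axis *exactly*; grays are then preserved to
machine precision, and the coefficient shift is in the fifth decimal.

Tritanopia keeps the original two-half-plane construction: the residual
surface is a pair of half-planes hinged on the white axis, one through a
660 nm spectral anchor (used for yellowish pixels) and one through a 485 nm
anchor (bluish pixels). The anchors are carried into the same LMS space via
the CIE 1931 2° color-matching values, so the whole construction is
self-consistent and both half-plane projections preserve the white axis and
their own anchor exactly. Membership is decided by the sign of the dot
product with the separating-plane normal `(M_w, −L_w, 0)` — the plane
spanned by the white axis and the S-cone axis. Because that normal has no S
component and the tritan projections modify only S, a pixel can never
change sides under simulation, which is what makes tritan simulation
exactly idempotent. Ties (dot product zero, a measure-zero set) go to the
first (660 nm) half-plane.

Note a geometric consequence: a tritanopia-simulated image's pixel cloud is
planar *per half-plane*, not globally — the union of two planes through a
common line is not a plane. The package's planarity checks are therefore
stated per half-plane for tritanopia and globally for the single-plane
conditions.

The Machado et al. (2009) severity-1.0 matrices are available as an
alternative family (`model = "machado"`), since many public implementations
use them. Their rows are renormalised to sum to exactly 1 (the published
values do so only to ~1e-6) so gray preservation is exact in this family
too. These matrices are not projections, so the idempotence and planarity
guarantees apply only to the default family. Severity is fixed at complete
dichromacy in both families; anomalous trichromacy is out of scope.

### Gamut and quantisation policy

Projected colors can leave the RGB gamut; the package hard-clips in linear
RGB. This is the simplest deterministic policy, and the invariant tests
exclude clipped pixels where exactness is claimed. On disk, 8-bit files
decode as `value / 255` and re-encode as `round(value × 255)`; outputs are
written as PNG so repeated runs are byte-stable (JPEG is accepted on input
only). In memory, double precision is kept throughout: idempotence holds to
1e-6 in memory, while a file round trip may move a channel by one 8-bit
quantum (1/255) when requantisation flips a rounding decision.

## The few-shot protocol

Each classification task presents a backend with an instruction text, `k`
labeled reference images per class (melanoma examples first, then nevus,
each in sampled order), and the unlabeled query last. References are drawn
uniformly without replacement from the remaining images (leave-one-out),
determined completely by the manifest order, the query id, `k` and the
seed; repeat `r` of an experiment uses seed `base_seed + r`, so the ten
repeats differ in sampling yet reproduce exactly. The instruction asks for
one class word followed by an explanation of the color features used —
mirroring a "find the most similar reference and use its label" protocol —
and answers are parsed case-insensitively on token boundaries
(melanoma/malignant vs nevus/naevus/benign). A reply whose first token is
the class word parses as `clean`; a keyword found later is `recovered`; no
keyword, or keywords from both classes, is `failed`. Failed parses are
excluded from accuracy denominators and vote counts but always counted and
reported — silently imputing them would bias accuracy.

Backends are plain functions from a composed message to a response, so a
proprietary vision-language endpoint and the offline mock are
interchangeable; transport errors are retried with exponential backoff and
are distinguishable from parse failures. The bundled mock backend
implements the most-similar-reference rule literally: Euclidean distance
between mean linear-RGB colors (or, optionally, 8-bin-per-channel histogram
intersection), ties resolved to the earliest reference in presentation
order (hence melanoma). Its explanation names the dominant hue word of the
query's lesion region — background estimated from a 2-pixel border frame,
lesion as pixels more than 0.12 (Euclidean sRGB) from that background, hue
word by fixed HSV bands (low saturation → gray; red sector split into light
desaturated pink vs red; warm hues → brown; cyan–blue → blue; magenta →
pink). This gives the mining module realistic red/pink/brown vocabulary
that genuinely tracks the simulation.

Two scoring backends bound the harness: an oracle that reads the true label
(accuracy must be exactly 1) and an adversary that inverts it (accuracy 0,
confusion counts exactly mirrored). They validate the harness, not any
model.

## Evaluation harness

An experiment runs every image as a query across `n_repeats` repeats
(default 10) with `k_per_class` references (default 2). Reported are
per-repeat accuracies with their mean and *population* standard deviation
(ddof 0; a single repeat has sd 0 by convention — the estimator is stated
because error bars are not comparable otherwise), and a consensus label per
image: melanoma iff at least `consensus_threshold` melanoma votes (default
`ceiling(n_repeats / 2)`, i.e. 5 of 10) among scoreable replicates.
Confusion counts use melanoma as the positive class. Prediction records
stream to a JSONL log as they complete; records carry no timestamps, so
identical configurations reproduce logs byte for byte, and completed
(query, replicate) pairs found under the same configuration digest are
reused on rerun (interrupted runs resume).

The ablation fixes the query condition and toggles only the references:
`matched` simulates them under the query's condition, `non_simulated`
leaves them in original color. Both arms share `base_seed`, so reference
*identities* per (query, replicate) coincide and only their coloring
differs; the harness asserts this from the logs. Whether a study's repeats
should share draws *across* conditions is a separate question; this package
shares seeds within an ablation pair only, where the comparison demands it.

## Explanation mining

Explanations partition into RED (any red-stemmed token, regardless of
pink), PINK (pink without red) and NEITHER. Matching is exact on lowercased
tokens split at non-letters — "red-brown" contributes both halves, while
"infrared" or "reduced" can never hit — and the keyword lists are arguments,
so the rule is configurable. Negated mentions ("no red areas") still count:
the grouping is about the color being *mentioned*, a documented
simplification. Grouping is per (image, replicate) prediction rather than
per unique image: repeats may legitimately produce different explanations
for the same image, and the per-replicate percentages are what the group
comparison consumes. Rates are `100 × melanoma predictions / group size`
per replicate; replicates where a group is empty are missing, not zero.

Group comparison is a two-sample two-tailed t-test on per-replicate rates,
unequal-variance (Welch) by default since nothing guarantees equal spread
between groups; the pooled variant is a flag. Degenerate inputs are
explicit: fewer than two rates in either group is an error (the test is
undefined); two zero-variance groups report t = 0, p = 1 when means agree
and p = 0 with an infinite statistic otherwise, flagged as zero-variance in
both cases.

## Synthetic fixtures: what they emulate, and what they do not

The generator emulates the *color structure* of a balanced dermoscopic
two-class set at desk scale — by default 50 images per class at 128 × 128
pixels, seed 20240427. Each image is a skin-tone background (mean sRGB
(0.894, 0.741, 0.666), per-image jitter sd 0.02) with an elliptical lesion:
melanomas draw a mixture of dark-brown, black, red and blue-gray components
laid out in angular sectors (the red component's weight is drawn from
0.35–0.60, which is what keeps the classes color-separable) with an
irregular, radially perturbed outline; nevi are a uniform blend of
light-brown and pink with a smooth outline. Additive Gaussian noise
(sd 0.02 per channel) is clipped to gamut. Generation is a pure function of
(spec, seed): identical inputs give byte-identical PNG sets.

Class separation is stated as a *red-dominance* margin: the mean of
`R − (G + B)/2` over lesion pixels must differ between classes by at least
0.08. Red dominance rather than the raw red channel is the right quantity
here: a pale pink nevus has a *high* red channel without being red, and the
tritanopia story — red lesions drifting toward pink under simulation — is a
story about red dominance, not red brightness.

What the fixtures deliberately do not emulate: dermoscopic texture
(networks, globules, streaks), hair and rulers, varied illumination,
histopathology ground-truth noise, or any non-color diagnostic feature.
Consequently, passing tests show that the *protocol machinery* behaves as
specified on color-separable inputs — they say nothing about diagnostic
accuracy on clinical images, which requires real data and a real backend
behind the same contract.

## Problem sizes and runtime choices

The unit tests run on 6-image-per-class, 32 × 32 fixture sets; the
end-to-end property suite uses the full default spec (50 per class,
128 × 128, 10 repeats, k = 2), which is also what `scripts/acceptance.R`
runs: a baseline plus three ablation pairs — seven experiment runs of 1000
predictions each — completing in a couple of minutes on one CPU. Per-image
features and simulations are cached within a run by content digest, so cost
scales with unique images, not with tasks.

## Known limitations

* Complete dichromacy only; no severity interpolation, no daltonization
  (recoloring to compensate), no ICC management beyond sRGB.
* The mock backend is a color-statistic nearest-neighbor; it validates the
  harness and produces realistic explanation text, but its accuracies are
  properties of the synthetic fixtures, not of any vision-language model.
* The explanation grammar of real models is richer than token matching;
  the keyword rule is a deliberate, configurable simplification.
* No real-API adapter is bundled; the backend contract (message →
  `raw_text` + `backend_id`, transport errors as a distinct condition
  class, caching keyed by `request_digest`) is the integration point.
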