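---
title: "Classifying bacterial transcription terminators from sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial transcription terminators from sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseterm)
```

## The problem

Rho-independent (intrinsic) transcription terminators are short DNA elements
— a GC-rich inverted repeat that folds into an RNA hairpin, followed by a
poly-U (poly-T on the DNA template) tract — that stop bacterial RNA
polymerase without accessory factors. `pseterm` treats terminator
recognition as binary sequence classification: encode each sequence as a
numeric feature vector, select the informative features, and train a
supervised classifier. Everything downstream of the raw sequence is ordinary
tabular machine learning, which is why every user-facing function takes and
returns a data frame.

## Feature encoders

Five families, combinable via `extract_group()`:

**PWM log-odds (`kpwm(k)`).** A position weight model over k-tuples is
trained on the positive class: at each start site $i$,
$p_{xi} = (n_{xi} + c)/(N_i + 4^k c)$ with pseudocount $c$ (default 0.25 per
k-tuple per site, additive smoothing), and $W_{xi} = \ln(p_{xi}/p_0)$
against the uniform background $p_0 = 4^{-k}$. A sequence scores the *mean*
weight over the sites it has, not the sum, so sequences of different length
are comparable — important here because positives are ~50 bp and negatives
80+ bp. Sequences longer than the model are scored on the model's sites;
shorter ones on their own. We train the model on positives only and rebuild
it inside every cross-validation fold: nothing in the literature of this
encoder pins down the training population, and positives-only, fold-internal
is the only choice that is both a class profile and leakage-free. With
$c = 0$, empty cells would be $-\infty$; they are floored at
$\ln(10^{-3}/p_0)$ and the model flagged.

**Base content (`basecontent`).** AT/GC content, AT:GC ratio, GC skew
$(G-C)/(G+C)$, AT skew $(A-T)/(A+T)$. Compositionally degenerate input
(e.g. GC skew of `TTTT`) yields 0 with a `degenerate` flag rather than an
error, so batch encoding never aborts on an odd sequence.

**Per-position nucleotide properties (`nucleotidepro`).** Each position is
described by 47 values: 3 binary chemical dichotomies (ring structure,
hydrogen-bond strength, functional group) and 32 dinucleotide plus 12
trinucleotide physicochemical properties, each k-mer property standardized
to mean 0, sd 1 across its k-mers and placed at the k-mer's start position.
Sequences are right-padded with zeros to a fixed width `l_max` (default 82,
the longest benchmark-style sequence), giving `47 * l_max` features named
`<property>_p<position>`. Padding, rather than truncation or scaling, keeps
positional identity; the resulting length signature (zero tail) is real
information in a dataset whose classes differ in length, and users whose
classes share a length are unaffected. The packaged dinucleotide and
trinucleotide tables are *synthetic standardized stand-ins* (marked in their
filenames): they have the exact shape, naming and standardization of
published property compilations so the machinery is fully exercised, but for
biological conclusions you should load a measured property table through
`load_property_table()`. The 3 chemical properties are exact.

**Pseudo K-tuple composition (`pseknc1(k)`, `pseknc2(k)`).** Normalized
k-tuple frequencies $f_u$ extended with $\lambda$ "pseudo" tiers measuring
physicochemical correlation between dinucleotides $j$ positions apart, using
$\Lambda = 6$ helical parameters (rise, slide, shift, twist, roll, tilt).
Parallel mode (type I) averages the squared property differences into one
tier per distance ($4^k + \lambda$ features); series mode (type II) keeps one
tier per distance and property ($4^k + 6\lambda$). All components share one
normalizer, so each vector is a probability distribution — asserted by the
tests for all modes. For the series tiers we use per-property squared
differences by default (`series_correlation = "sqdiff"`): it preserves the
invariant that every correlation tier vanishes on a homopolymer, which the
product convention breaks; the product form is available by switch.
$\lambda = 5$ and $w = 0.1$ are conventional defaults for ~50 bp sequences
(they are not dictated by any dataset; both are recorded in the fitted
pipeline), and $k \in \{4,5,6\}$ keeps the k-mer table denser than the
sample count.

## Two-step feature selection

Step one ranks features: **F-score** (between-class mean separation over
summed unbiased within-class variances; the default) or **binomial
confidence** for count-valued features (how surprising a feature's
concentration in one class is under the class-prior binomial; computed via
the stable survival function, and refused for non-count features instead of
silently binarizing). Ties are broken by original column index, so rankings
are reproducible. Ranking happens on unscaled features: min-max scaling
changes per-class variance ratios and hence could reorder, and the ranking
should describe the data, not the scaler.

Step two, **incremental feature selection (IFS)**, traces cross-validated
accuracy over growing prefixes of the ranking and keeps the best prefix
(smallest on ties). Two cost controls matter for multi-thousand-column
groups: `stride` (evaluate every s-th prefix; `"auto"` picks ~20) and a
prefix cap `ifs_max_features` (pipeline default 1024 — on every dataset we
have examined the optimum sits far below it, and the curve can be traced to
full width by setting it `NULL`). The IFS evaluator is a deliberately light
gradient-boosted tree CV (default 5-fold, 5 repeats; 3-fold, 1 repeat inside
pipeline CV).

`pearson_matrix()` provides the redundancy diagnostic that motivates
selection, and `kmer_class_preference()` the per-class k-mer enrichment
summary (presence-based by default — the share of sequences containing the
k-mer — with an occurrence-share mode, since either convention is defensible).

## Models, normalization, evaluation

`model_spec()` declares one of ten algorithms: SVC, naive Bayes, logistic
regression, decision tree, MLP, KNN, bagging and AdaBoost over four base
learners, classic gradient boosting, and extreme gradient boosting (the
default — it is consistently the strongest here). Min-max normalization to
[0, 1] (or [−1, 1]) is fitted on training rows only and applied exactly to
the margin/distance learners; tree and probability models are
scale-invariant and skip it. AdaBoost uses weighted-bootstrap resampling so
bases without case-weight support can serve; both boosting wrappers and
bagging are implemented in-package. Grid search (`grid_search()`) is
exhaustive over the declared grid with ties resolved toward smaller
ensembles and learning rates.

Evaluation uses sensitivity, specificity, accuracy and MCC in their
"one-minus-error-rate" forms — algebraically identical to the TP/TN/FP/FN
definitions, which the tests assert exhaustively over all small confusion
tables — plus rank-based AUC (equal to the Mann–Whitney statistic, ties
averaged). `repeated_cv()` runs stratified 5-fold CV with configurable
repeats; per repeat, out-of-fold predictions are pooled into one confusion
matrix, and the report gives means ± standard errors over repeats. Every
fold refits everything that learns — scaler, ranking, IFS, and per-fold PWM
features when the group includes `kpwm` — so test folds never touch any
fitted parameter; the default of 5 repeats keeps routine runs fast and can
be raised to 100 for publication-grade standard errors.

## The synthetic benchmark

`simulate_terminator_data()` generates positives of 50 bp containing, at a
random offset, a 9 bp stem with 90% GC bias, a 5 bp loop, the reverse
complement of the stem and a 7 bp poly-T tail, with i.i.d. flanks; negatives
are 80 bp of i.i.d. uniform bases. This reproduces the two signals real
benchmarks carry — the hairpin/poly-T cassette and the class length
asymmetry — and the default sizes (400 + 400) give stable CV estimates in
about two minutes of single-core compute. What it does *not* emulate:
genomic base composition, the correlation structure of promoter-proximal
background, rho-dependent terminators, or partially degenerate hairpins. A
pipeline that excels here has demonstrated signal recovery and
leakage-freedom, not field performance; on this separable task the default
pipeline reaches CV accuracy ≥ 0.99 (the acceptance script recomputes this
end to end).

## Numerical and degenerate-input choices

Zero denominators in base content → 0 plus flag; zero PWM cells under zero
pseudocount → floored log-odds; constant features → correlation 0 (flagged)
and min-max midpoint; features constant within both classes → F-score 0 on
equal means, large sentinel (ranked first) on distinct means; MCC → 0
whenever a factor under its root vanishes; CV folds missing a class (only
possible unstratified) → warned and skipped, counted in the report. All
randomness flows through explicit integer seeds; identical seeds give
bitwise-identical splits, simulations, CV reports and fitted pipelines, and
serialized pipelines (`save_pipeline()`/`load_pipeline()`) reload to
identical predictions.

## Limitations

The packaged physicochemical tables are synthetic stand-ins; the classifier
is binary and offers no genome scanning (you supply candidate windows);
`l_max` bounds prediction-time sequence length by design; and IFS explores
ranking prefixes only — interactions between low-ranked features are
invisible to it, as in any filter-then-wrap selection scheme.
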