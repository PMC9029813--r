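---
title: "Autoencoder descriptor reduction for similarity-based virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder descriptor reduction for similarity-based virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`aescreen` implements a descriptor-reduction approach to ligand-based
virtual screening: a tied-weight sigmoid autoencoder compresses
1024-feature extended-connectivity count fingerprints (ECFC-style)
into a low-dimensional code, and similarity searching runs over the
codes with the continuous Tanimoto coefficient. Around that core sit
the standard evaluation instruments of the field — recall at top-1%
and top-5% cutoffs averaged over random references, per-class recall
tables with best-method counts, and Kendall's coefficient of
concordance over method rankings — plus a seeded generator of
synthetic fingerprint datasets emulating MDDR-style activity-class
benchmarks.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic data model, and the numerical and design
choices a user should know about.

## The autoencoder

### Model and objective

The encoder applies `h = σ(Wx + b)` layer by layer down to the code
layer; the decoder mirrors the chain back up to the input width. The
training objective is the mean squared reconstruction error
`ℒ = mean((x − ẑ)²)`, minimized by minibatch gradient descent with
backpropagation. With tied weights, decoder layer `j` always reads the
transpose of encoder weight `N − j + 1`; its gradient therefore
accumulates contributions from both uses of the matrix. The tie is
structural — decoder weights are computed as transposed views at every
use — so it cannot drift during training, and the test suite asserts
it after every epoch anyway.

Decoder biases are free parameters. A literal transposed-bias tie is
dimensionally impossible when consecutive layers have different
widths, so they are initialized to zero (under the default scheme) and
learned.

### Stopping rule and the "learning rate"

Training stops when the epoch-mean reconstruction error drops below
the tolerance `α` (default 0.01) or after `max_epochs` (default 100).
The descriptions this design descends from conflate the words
"learning rate" and "error rate" for `α`; here `α` is strictly the
stopping tolerance, and the gradient step size is an independent
parameter (`step_size`, default 0.05). A literal weight update of the
form "add the scalar loss to the weight matrix" is not a usable
learning rule, so standard gradient descent on `ℒ` is used while the
control flow (train until `ℒ < α`, cap at 100 epochs) is preserved.

### Input scaling

Sigmoid output layers can only reconstruct values in (0, 1), but raw
ECFC features are unbounded counts. `minmax_scale()` therefore maps
each feature to [0, 1] via `(x − min)/(max − min)` before training;
the per-feature minima and maxima are stored on the dataset and
`inverse_scale()` recovers the counts exactly. Constant features map
to 0 (avoiding a 0/0 with no information loss, since the inverse
restores them from the recorded minimum). Binarizing instead of
scaling (`binarize()`) is supported for presence/absence experiments.

### Architectures

Three presets target 1024-feature input: encoder widths
1024-900-700-500 (`AE1-DR`, code 500), 1024-800-600-400-300 (`AE2-DR`,
code 300) and 1024-900-800-600-400 (`AE3-DR`, code 400). All are tied,
so decoder widths mirror the encoder. (One published description of
the first network lists an asymmetric decoder width of 800 where the
tied transpose forces 900; the tied mirror is the default here, and an
untied `ae_architecture()` can realize any explicit decoder chain.)

### Initialization

Default `glorot`: weights uniform on ±sqrt(6/(fan_in + fan_out)),
biases zero — the standard choice for sigmoid stacks. The alternative
`uniform01` mode draws every weight and bias uniformly on (0, 1);
it is retained for fidelity experiments but saturates wide sigmoid
layers (every pre-activation is a sum of hundreds of positive terms)
and is not recommended for real training.

### Training mode

Dataset-level epochs with shuffled minibatches (default size 32) and a
stop on the epoch-mean loss. A per-molecule mode
(`train_config(per_molecule = TRUE)`) that drives each molecule to
tolerance in sequence exists for fidelity experiments; it is
degenerate as a learning procedure (later molecules overwrite earlier
ones) and is not used by the pipeline.

## Similarity coefficients

For non-negative vectors the canonical continuous Tanimoto is

    S(a, b) = Σab / (Σa² + Σb² − Σab),

with `S(a, a) = 1`. A variant with `+Σab` in the denominator
(`"as_printed"`) is also implemented: some descriptions of the measure
print it that way, but it is not the continuous Tanimoto — its
self-similarity is 1/3 — and it is dominated by the standard form
everywhere. Because the two variants can rank databases differently,
every screening result records which variant produced it; the default
is `"standard"`. The binary coefficient `c/(a + b − c)` on binarized
fingerprints is the TAN baseline.

Similarity of two all-zero vectors is undefined and raises an error;
the synthetic generator therefore guarantees at least one on-feature
per molecule, and an all-zero *database* row scores 0 against a
nonzero query.

## The screening protocol

For each activity class, `n_references` molecules (default 10) are
sampled without replacement, seeded; classes smaller than the request
contribute all members with a warning. Each reference ranks the whole
database by similarity in decreasing order; ties are broken by
molecule id ascending so runs are bit-reproducible. Recall at cutoff
`p`% counts the class's actives in the top `k = round(p·N/100)`
(minimum 1) of the ranked list — `round` matches the convention that
the top 1% of a 102,516-molecule database is ~1025 molecules.

By default the reference is excluded from both the ranked database and
the active count (`exclude_reference = TRUE`), the common benchmark
protocol that avoids a guaranteed self-hit; the alternative is a flag
because published protocols do not always state the choice.
Background molecules (label `"__bg__"`) are never actives and never
references, but always rank as decoys.

`run_benchmark()` shares one reference draw across all methods, so
every column of a recall table answers the same queries. Summary rows
(per-method mean over classes; count of classes where the method
attains the row maximum, ties crediting all) are always recomputed
from the cells, never trusted from input files.

## Kendall concordance

Activity classes act as judges ranking the methods by recall; higher
recall gets a higher rank and ties get average ranks. With rank totals
`R_i`, `S = Σ(R_i − R̄)²` and `W = 12S / (m²(n³ − n))`; the
significance is the Friedman chi-square `m(n − 1)W` on `n − 1` degrees
of freedom. Ranks start at 0 by default — published mean ranks in this
literature sum to `n(n−1)/2`, which is only consistent with 0-based
ranks — and the offset is configurable because `W` is translation
invariant. No tie-correction term is applied by default (the formula
above has none); a tie-corrected denominator is available via
`tie_correction = TRUE`.

## The synthetic data model

The generator emulates the *structure* of MDDR-style benchmarks: a
handful of activity classes of stated sizes whose mean intra-class
pairwise Tanimoto similarity is controllable (homogeneous benchmarks
sit around 0.23–0.36, heterogeneous around 0.10–0.13), plus a pool of
background decoys.

Each class draws a prototype feature support (each of the F features
on with probability `density`, default 0.05). A member keeps each
prototype feature with retention probability `θ` and gains each
non-prototype feature at a compensating background rate
`p(1−θ)/(F−p)`, so its expected number of on-features equals the
prototype's. On-features carry counts `1 + Poisson(λ − 1)` (default
`λ = 3`), making binarization well defined — a substructure that
occurs has count at least 1. Background molecules draw independent
supports at the prototype density. Everything is driven by named
substreams of one seed, so datasets are bit-reproducible.

Under this model the expected pairwise binary similarity is
approximately `θ²/(2 − θ²)`, but count noise and finite supports shift
it, so `calibrate_homogeneity()` finds `θ` for a target similarity by
bisection against simulated 500-member pilot classes (tolerance 0.02).
All pilots share one fixed internal seed: coupling them to the same
uniform draws makes the achieved similarity monotone in `θ`, which
bisection requires, and keeps calibration independent of the caller's
RNG state. At small feature dimensions the model has an attainable
floor — with F = 64 and density 0.05 a class cannot be made less
similar than ≈0.13, because ~3-feature supports plus the guaranteed
on-feature concentrate similarity — so heterogeneous targets near 0.1
need the full 1024-feature dimension (where tests run the
homogeneity-contrast experiments; reduced 64-feature data are used
where a deliberately small autoencoder is the object under study).

What the generator does **not** emulate: chemical scaffold topology,
correlated feature co-occurrence, class-size imbalance of real
benchmarks, and inter-class similarity structure. Passing tests on
synthetic data therefore demonstrate the correctness and the
qualitative behavior of the machinery (homogeneous classes screen
better than heterogeneous ones, seeded reproducibility, calibration),
not the absolute recall levels of any licensed benchmark.

## Bundled benchmark tables

Published per-class recall tables for the MDDR DS1/DS2/DS3 benchmarks
(six methods at 1% and 5% cutoffs; DS3 lacks the ASMTP column) ship as
CSV under `inst/extdata/` and load with `benchmark_recall_table()`.
They are evaluation *inputs*: the package recomputes their column
means, best-method counts and Kendall analysis — reproducing the
published summary statistics — but regenerating the cells themselves
would require the licensed MDDR dataset and the proprietary ECFC_4
implementation, which is out of scope. One published summary row (the
DS1 top-5% best-method counts) and one concordance value (DS2 top-5%)
are internally inconsistent with their own printed cells; the
recomputed values are treated as ground truth.

## Numerical choices

* All arithmetic in 64-bit doubles; the sigmoid uses the two-branch
  stable form, so codes are always strictly inside (0, 1).
* Gradient correctness is verified against central finite differences
  (step 1e-4, relative error below 1e-5) for tied and untied models,
  including 1/32-width versions of all three presets.
* `k = round(p·N/100)` uses R's `round`; the minimum of 1 guards
  degenerate tiny databases.
* Similarity ties in rankings break by id ascending; rank ties in the
  concordance analysis take average ranks.
* Scaled CSV round-trips print 17 significant digits and reproduce
  doubles to < 1e-12; integer datasets round-trip bit-exactly.

## Problem sizes

The test suite and examples run deliberately small configurations —
tens to a few thousand synthetic molecules, 16–256 features,
autoencoders up to a few hundred units, 10⁴-replicate Monte-Carlo and
property sweeps — sizes chosen so the full suite completes in a couple
of minutes on a laptop while still exercising every code path at
non-trivial scale. The end-to-end pipeline test uses 10 classes × 100
molecules + 1000 decoys, the scale at which screening statistics
(recall at 1% of a ~2000-molecule database) stop being granular.

## Known limitations

* Training is plain gradient descent; no momentum, adaptive steps or
  GPU support. The preset 1024-wide architectures train slowly on
  large corpora.
* No variational, denoising or sparse autoencoder variants.
* The package does not compute ECFC_4 fingerprints from structures;
  inputs are count matrices.
* Comparison methods from the literature (ASMTP, SQB, Bayesian
  inference networks) are consumed as printed recall columns only,
  never reimplemented.
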