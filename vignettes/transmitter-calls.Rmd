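---
title: "From synapse predictions to hemilineage transmitter calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From synapse predictions to hemilineage transmitter calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcall)
```

## The problem

Modern EM connectomes attach a neurotransmitter prediction to every
automatically detected presynapse: a classifier looks at the local
ultrastructure and outputs one of six classes (GABA, acetylcholine,
glutamate, serotonin, octopamine, dopamine). Those per-synapse predictions
are noisy, and detection itself is imperfect — a substantial share of
"presynapses" are not synapses at all. Biology supplies strong structure to
aggregate against: under Dale's law a neuron releases one small-molecule
transmitter at all of its presynapses, and developmentally related neurons
of a hemilineage typically share a single fast-acting transmitter. `ntcall`
implements the statistical layer between raw per-synapse classifier output
and biologically interpretable annotations: filtered neuron-level calls
with calibrated confidence, entropy diagnostics of within-hemilineage
multimodality, Bayes-factor inference on how many transmitters a
hemilineage truly expresses, and consistency checks between matched
homologous neurons.

## The error model

Everything downstream leans on a 6x6 row-stochastic confusion matrix `C`
estimated on a labeled test set: `C[y, yhat]` is the probability that a
unit with true transmitter `y` is predicted as `yhat`. Two levels are used:
a synapse-level matrix for confidence scoring and a neuron-level matrix
(majority-vote error rates) for hemilineage inference.

Because the test set is finite, observed zero error rates are artifacts.
`estimate_confusion()` supports additive smoothing on the counts
(pseudo-count `beta`), equivalent on the normalized matrix to
`smooth_confusion()`'s

$$\tilde C_{y\hat y} = \frac{C_{y\hat y} + \alpha}{1 + 6\alpha},$$

which preserves row sums exactly, recovers `C` at `alpha = 0`, and tends to
uniform 1/6 as `alpha` grows. Rather than fixing one `alpha`,
`expected_confusion()` marginalizes it under a shifted exponential prior
`p(alpha) = lambda * exp(-lambda (alpha - epsilon))` on `[epsilon, Inf)`:
most mass sits just above the observed matrix and decays with heavier
smoothing; `alpha < epsilon` is excluded so no misclassification ever has
probability exactly zero. The expectation is applied entrywise to the
smoothed matrix. Because smoothing is an affine shrink toward uniform,

$$\tilde C(\alpha) = \tfrac16 + \bigl(C - \tfrac16\bigr)\frac{1}{1+6\alpha},$$

the entrywise expectation reduces exactly to one scalar integral
`E[1/(1+6 alpha)]`, which we evaluate by adaptive quadrature after the
substitution `u = exp(-lambda (alpha - epsilon))`; the substitution maps the
infinite integration range to `(0, 1]` and absorbs the exponential tail
exactly, leaving a smooth bounded integrand. The tests cross-check the
quadrature against a 10^6-draw Monte-Carlo average of directly smoothed
matrices.

Two defaults matter here. `epsilon = 1e-3`: the offset only needs to be
small and positive; 1e-3 keeps the epsilon-smoothed matrix within a few
tenths of a percent of the observed one while bounding every entry away
from zero. `lambda = 16`: the rate used for the reference hemilineage
analyses; `expected_accuracy()` and `solve_lambda_for_accuracy()` expose
the interpretable side of this dial — the prior-expected mean diagonal —
so a user can pick `lambda` by choosing how much residual accuracy they are
willing to assume (accuracy runs from chance 1/6 at `lambda -> 0` up to the
epsilon-smoothed test-set accuracy as `lambda -> Inf`, monotonically).

## Filtering and neuron-level calls

`filter_policy()` encodes the presynapse quality rules with their exact
boundary semantics: detection score strictly above the threshold (50 for
the FAFB cleft-score dialect, 0.5 for the HemiBrain confidence dialect);
compartment in {axon, dendrite}; distance from the soma at least 15 um and
from the primary dendrite at least 0.1 um (inclusive); and at least 100
surviving presynapses per neuron for a call (30 in test-set-style voting).
Rows lacking an optional column pass that specific check, so minimal tables
degrade gracefully; `strict = TRUE` inverts that. `filter_synapses()`
reports a per-rule removal ledger, attributing each removed row to the
first rule it violates.

`call_neurons()` then takes, per neuron, the majority vote of surviving
per-synapse predictions. A call is `"uncertain"` when the top two vote
fractions are within 0.10 of each other — we read the "<10%" margin rule as
ten percentage points of presynapse share, applied to the same synapse set
used for the vote — when too few presynapses survive, or on an exact tie.
Both the threshold-only vote (`top_nt`) and the fully filtered vote
(`conf_nt`) are reported, since filtering occasionally flips the call. The
confidence score of a call is the mean confusion-matrix entry in the
winning transmitter's row over the neuron's synapse predictions
(`neuron_confidence()`): unanimous support by a reliably classified
transmitter gives values near the diagonal entry; dissenting synapses pull
the score down through the corresponding misclassification probabilities.
Algebraically the score equals the vote-fraction-weighted row average, an
identity the tests assert.

## Entropy diagnostics

For a hemilineage `h`, `neuron_level_entropy()` computes the base-6 Shannon
entropy of the distribution of member neurons' winning transmitters, and
`neuron_synapse_entropy()` / `hemilineage_synapse_entropy()` the mean
base-6 entropy of per-synapse label frequencies within each neuron. Base 6
normalizes both to [0, 1]: 0 means perfect homogeneity, 1 means all six
classes equally common. Comparing the two separates genuinely split
hemilineages (high neuron-level, low synapse-level entropy: neurons are
individually confident but disagree) from noisy prediction substrates
(high synapse-level entropy: individual neurons are already multimodal).
`"uncertain"` calls are excluded from the neuron-level distribution — they
are a report of abstention, not a seventh transmitter — and the exclusion
count is carried along.

`entropy_quadrants()` cuts the population at the empirical 25th/75th
percentiles of each entropy (linear interpolation between order statistics,
`stats::quantile()` type 7, so boundaries are reproducible) and labels each
hemilineage `neuron_segregated`, `synapse_multimodal`, `homogeneous` or
`intermediate`, matching first in that order. Eligibility is strict: more
than 10 member neurons, each counted neuron with more than 30 presynapses.

## How many transmitters does a hemilineage express?

Under the i.i.d. error model, the probability of observing neuron-level
winners $\hat y_1,\dots,\hat y_n$ if the hemilineage truly expresses a set
$S$ of transmitters, with flat priors over the $\binom{6}{m}$ size-$m$ sets
and over members within a set, is

$$p(\hat y \mid m) = \binom{6}{m}^{-1} \sum_{S \in P_m(Y)} \prod_j
  \frac{1}{m} \sum_{y \in S} C_{y \hat y_j}.$$

`log_marginal_likelihood()` computes this entirely in log space (per-subset
log terms combined by log-sum-exp) so studies with hundreds of neurons do
not underflow; `-Inf` is a legitimate value meaning the data are impossible
under the hypothesis. Hypotheses are compared by the pairwise Bayes factor
`K[m1, m2]` and summarized by the one-versus-rest factor
`K[m, not m] = p(yhat|m) / sum_{n != m} p(yhat|n)` with the five
alternatives summed unweighted. Evidence classes follow Jeffreys-style
inclusive thresholds: substantial at `10^{1/2}`, good at `10`, strong at
`10^{3/2}`, decisive at `10^2`. `m` ranges over 1..6 even though biological
interest concentrates on 1-3, because the one-versus-rest denominator needs
all alternatives. `"uncertain"` neurons are dropped before inference, with
the count logged — the observation model is defined over the six labels
only. The unit of observation is the neuron-level winner scored against the
neuron-level confusion matrix; a synapse-level variant is available simply
by passing per-synapse labels and a synapse-level matrix.

Degenerate cases have exact closed forms the test suite pins down: a single
observation under an identity matrix yields `p = 1/6` for every `m` (one
observation cannot distinguish transmitter counts); a uniform matrix makes
every pairwise factor 1 and every one-versus-rest factor 1/5; two identical
winners under identity give `K[1,2] = 2`, two different winners give
`K[2,1] = Inf`. For `n <= 3` the marginals provably sum to 1 over all
`6^n` winner configurations, which the tests verify by exhaustive
enumeration against tolerance 1e-10.

## Homolog consistency

Matched homologous neurons (left/right within a brain, or the same cell
across datasets) should receive the same call. `pair_agreement_matrix()`
tabulates paired calls on a 7x7 grid (six classes plus uncertain) with a
row-normalized view; `pair_consistency()` adds per-pair KL divergences
between the neurons' synapse-level prediction distributions — the mean
per-synapse score vectors when scores are present, otherwise label
histograms with a pseudo-count of 1 per class — and `mismatch_summary()`
contrasts confidence between matching and conflicting pairs. KL is
computed in nats; since homolog pairs have no privileged direction, the
symmetrized divergence is the default report and the directed variant is
kept alongside. When the target distribution lacks support where the
source has mass, both are mixed with a small uniform pseudo-mass and the
value is flagged as smoothed rather than returned infinite.

## The synthetic study generator

`simulate_study()` generates classifier output with exactly the structure
the analysis assumes, so every stage is testable end to end without any
connectome download: hemilineages composed of 1-3 true transmitters
(optionally with a deviant "first-born" neuron), neurons obeying Dale's
law, per-synapse predictions drawn i.i.d. from the confusion-matrix row of
the neuron's true transmitter, and a configurable share of false
detections carrying contamination labels.

Defaults emulate the published scale of the real data and are fixed study
conditions, not tuning dials:

* synapse counts per neuron: lognormal parameterized by median (202, the
  FAFB filtered median; 386 fits the HemiBrain dialect) and log-SD 0.8,
  giving the heavy right tail typical of output neurons;
* false-detection rate 0.32 of all detected rows, matching the audited
  share of erroneous auto-detections;
* detection scores: two truncated normals per dialect whose means were
  solved once from the truncated-normal CDF so the standard threshold
  removes 13% of valid and 60% of false detections — the published
  calibration anchors. The parameters sit in the config
  (`detection_mixture()`) so the calibration is transparent;
* compartment shares axon 0.76 / dendrite 0.19 / soma 0.02 /
  primary-dendrite 0.02 / cell-body-fiber 0.01 (axonic majority as
  observed in real split neurons), and Gamma-distributed distance fields
  whose small sub-threshold tails exercise every filter rule;
* contamination labels uniform over the six classes by default, with an
  octopamine-skewed preset reflecting the tendency of false detections to
  be read as octopamine.

What the generator deliberately does not model: spatial synapse positions,
morphology, co-transmission, transmitters outside the six-class space, and
correlated (non-i.i.d.) prediction errors within a neuron. Passing tests on
synthetic studies therefore validate the statistical machinery under the
stated error model, not the classifier itself, and real-data deviations
from i.i.d. errors (e.g. neuropil-correlated confounds) will make real
Bayes factors overconfident relative to the simulation.

## Reference problem sizes and numerical choices

The packaged checks run at deliberately modest scale: parameter-recovery
experiments use 100 hemilineages per condition with 30 neurons and 200
synapses per neuron under a diagonal-0.9 confusion matrix and the
`lambda = 16`, `epsilon = 1e-3` prior, recovering the true transmitter
count in >=90% of single-transmitter and >=80% of balanced two-transmitter
hemilineages; mixture calibration is checked at n = 10^5 draws within two
percentage points; Monte-Carlo validation of the quadrature uses 10^6
draws. Exact ties in votes and modes resolve to `"uncertain"`; ranking
ties break by canonical label order and are flagged. All probability
accumulation is in natural-log space; quadrature targets absolute error
below 1e-8.

## A worked example

```{r example, eval = FALSE}
st <- simulate_study(sim_config(seed = 1, n_hemilineages = 4,
                                m_true = c(1, 1, 2, 1), n_neurons = 25,
                                homolog_pairs = TRUE))
cfg <- run_config(policy = filter_policy(min_presynapses = 30),
                  confusion_synapse = st$config$C_syn,
                  confusion_neuron = confusion_matrix(unclass(st$config$C_syn),
                                                      level = "neuron"),
                  min_neurons = 10, seed = 1)
rep <- run_pipeline(st$synapses, st$neurons, cfg)
rep$bayes[, c("hemilineage", "n_neurons", "best_m", "evidence")]
```

The README shows this run's printed output; the Bayes table recovers each
hemilineage's simulated transmitter count with decisive evidence at these
sizes.

## Limitations

Confidence scores inherit every bias of the test-set confusion matrix;
classes that are rare in the test set have noisy rows and hence noisy
confidences. The Bayes factors assume exchangeable neurons within a
hemilineage and known (marginalized) error rates; they quantify evidence
about transmitter counts under that model, not about co-transmission or
neuropeptides, which are outside the six-class space entirely.
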