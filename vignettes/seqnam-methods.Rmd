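---
title: "Methods: additive convolutional models of regulatory sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive convolutional models of regulatory sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

seqnam fits sequence-to-activity models in the neural additive family: the
prediction for a one-hot encoded DNA sequence is a *linear* combination of
the scalar outputs of U independent units,

$$ \hat{y}_t(x) \;=\; b_t + \sum_{u=1}^{U} w_{ut}\, f_u(x), $$

where each unit $f_u$ is a small convolutional network with a **single**
filter: a valid (un-padded) convolution of width W (default 19 bp), batch
normalization, an exponential activation, max pooling (kernel 7, stride 7),
a fully connected layer with 100 nodes (batch norm, ReLU, 30% dropout), and
a second fully connected layer with 1 node (batch norm, ReLU). The
exponential activation, rather than ReLU, sharpens the motif representation
learned by the filter. Because the final layer is linear and the units
share no parameters, the model is its own explanation: the weights
$w_{ut}$ play the role of regression coefficients, the per-sequence
products $f_u(x)\,w_{ut}$ are exact additive contributions, and removing a
unit changes the prediction by exactly $-f_u(x)\,w_{ut}$.

An ablated head (`unit_head = "global_max_pool"`) replaces everything after
the activation with a global max over positions, so a unit degenerates to
the best match of its filter anywhere on the sequence -- an independent
motif scan. Comparing the two heads isolates what the fully connected
layers contribute, which turns out to be positional information (see
*Distance dependence* below).

Assumptions worth stating: the receptive field of any single unit is one
filter width, so the model cannot represent features requiring wider
context except through the per-unit fully connected layers acting on the
pooled activation profile; and the additive combination rules out learned
interactions *between* units by construction.

## Training

Mini-batch Adam (learning rate 0.003, batch 100), with binary cross-entropy
(binary tasks; the sigmoid lives in the loss so the model output stays
linear), softmax cross-entropy (multiclass, e.g. enrichment cycles as
classes), or mean squared error (regression). Training and validation sets
are augmented with the reverse complement of every sequence under the same
label. Sequences containing N are discarded, never imputed. Early stopping
monitors the validation loss with patience 10 (configurable) up to 100
epochs, and the parameters of the best validation epoch are returned. We
early-stop on loss rather than a task metric so that the same rule applies
across task types.

Random splits are 80/10/10 by default, optionally stratified to preserve a
binary class ratio; a chromosome-held-out mode assigns records to splits by
their `chrom` field. Probe-intensity labels can be quantile-normalized with
`quantile_normalize()`, which maps values to uniform quantiles
`(rank - 0.5) / n` with average ranks for ties.

Numerical conventions: batch-norm uses eps `1e-5` and momentum 0.1, biased
variance for normalization and unbiased variance for the running update;
evaluation mode is deterministic (running statistics, no dropout).
Pre-activation values are clipped at 20 before exponentiation as an
overflow guard; after batch normalization this never binds in practice.
Convolution and linear layers carry no additive bias -- each is followed
immediately by a batch norm whose shift parameter subsumes it, so the
function class is unchanged. Max-pool and argmax ties resolve to the lowest
position. Parameter initialization is uniform in
$\pm 1/\sqrt{\text{fan-in}}$ and fully determined by the seed.

The per-batch forward/backward pass exists twice: a pure-R reference
implementation and a compiled (RcppArmadillo) fast path used for training
and prediction. They share layouts, batch-norm conventions, and even the
dropout RNG draw order, and the test suite holds them equal to machine
precision across multiple optimization steps; the gradient itself is
checked against central finite differences. Models with plugged-in
function submodels run on the reference path.

## Interpretation

*Filter visualization.* For each unit we record, per sequence, the maximum
of the post-activation convolution signal and its position (evaluation
mode). A position frequency matrix is built from the filter-width windows
at the argmax of every sequence that (a) is correctly predicted and (b)
activates the unit at >= 50% of its dataset-wide maximum activation.
Reverse-complement copies, when part of the interpretation set, count as
their own sequences. The PFM becomes a PWM by adding a total pseudocount of
1 (0.25 per base) and taking log2 odds against the uniform 0.25 background;
a uniform column therefore has zero log-odds. Units with no qualifying
sequences are flagged non-interpretable rather than silently zeroed.

*Correctness predicate.* Binary tasks: post-sigmoid prediction at 0.5
against the label, per task (a sequence can qualify for one task and not
another); PFM construction uses "correct on at least one task" by default.
Multiclass: argmax class. Regression with several outputs: per-sequence
Pearson correlation >= 0.75; with a single output, the better half of
sequences by absolute error. All of these are conventions -- the cutoffs
are exposed as arguments.

*Unit importance.* For unit u and task t, the median over qualifying
sequences of $f_u(x) w_{ut}$. Because of additivity this equals the median
of the (negated) nullification deltas over the same sequences, and the
importance ranking agrees closely with the mean nullification impact over
a held-out set. An empty qualifying set yields an undefined (NA) median,
flagged rather than reported as 0.

*Annotation.* Unit PWMs are matched to a motif database either with the
external `tomtom` comparator (q-value <= 0.05) or with the built-in
similarity: the maximum Pearson correlation of aligned probability columns
over all ungapped offsets (minimum overlap 5 columns) and both strands,
keeping matches >= 0.8. The internal backend is symmetric under reverse
complement of the query.

A caveat the weight heatmap inherits from the architecture: a unit whose
output is constantly zero (a dead output ReLU) receives no gradient on its
final-layer weight, which therefore retains its random initial value and
sign. Such units always have importance exactly 0; their weights should be
read jointly with the importances, never alone.

## De novo motif discovery

`discover()` trains one many-unit model (default 100 units) on a labelled
set, extracts one PWM per unit from the validation split (with reverse
complements), ranks the PWMs by unit importance (positive class for binary
tasks, the last class for multiclass, the single output for regression),
and evaluates each PWM by its best-hit score -- the maximum over both
strands and all offsets of the summed log-odds -- via the AUPRC
(classification) or the Pearson correlation of best-hit scores with the
labels (regression) on the validation split. The best PWM is chosen by
validation performance. The AUPRC uses step-wise integration over the
unique score thresholds (no linear interpolation), which makes a constant
scorer score the prevalence; the implementation is pinned by an
exhaustive-threshold oracle in the tests.

## Motif-database initialization

Profiles are resized to the filter width: wider profiles are trimmed to
the window with the highest summed information content (ties: most
central, then leftmost; a plain central trim is available as a strategy
option), narrower ones are padded with uniform background columns, the
extra column on the right for odd parity. Probabilities minus 0.25 become
filter weights, so every filter column sums to zero. Redundancy in a
profile collection is removed by farthest point sampling on a similarity
matrix (internal similarity by default; externally computed similarities
can be imported from TSV): distance is 1 - similarity, the first pick is
the profile with the largest mean distance to all others, and each
subsequent pick maximizes the minimum distance to the selected set, with
ties broken by id order. `add_reverse_complements()` doubles a set.
Initialized filters may be frozen; freezing is implemented as gradient
nullification, so frozen filters are bit-identical after any amount of
training while the fully connected and final layers keep learning.
Initialization with profiles that include the data's true motif reaches a
given validation loss faster than training from scratch; at longer
training the two converge, so the comparison in the acceptance checks is
made at a small, equal epoch budget.

## Distance dependence (cooperativity)

`distance_dependence()` fixes motif A's consensus at the center of random
backbone sequences (i.i.d. bases at a specified GC content) and embeds
motif B at signed edge-to-edge distances d (negative = left of center).
For each backbone and distance the residual on the predictor's output
scale is the double difference

$$ r(d) = p_{AB}(d) - p_A - p_B(d) + p_{bb}, $$

which is exactly zero for any predictor additive in motif occurrences
(and for any linear functional of the one-hot matrix); the reported
residual fold change is $2^{r}$. A ratio-scale alternative
$p_{AB}\,p_{bb}/(p_A\,p_B)$ is available for strictly positive outputs.
A control k-mer (default `GGGCT`) slides in place of motif B. Profiles
aggregate the per-backbone mean, sd, and standard error at each distance
over 256 backbones by default.

*Flatness.* We summarize a profile by the contrast between the mean log2
residual at close range (|d| <= 10) and at long range (|d| > 25). A
trained nonlinear model retains small systematic distance-independent
residuals (for the global-max-pool ablation a constant negative offset is
structural: with outputs driven by a max, a second site adds almost
nothing, so two-site sequences are sub-additive at *every* distance), so
an absolute zero test at 256 backbones would reject any trained model;
the contrast isolates distance *dependence*, which is the quantity of
interest. We call a profile flat when the contrast is below 0.1 in log2
units -- less than 10% of the planted interaction bonus.

*Study conditions.* The packaged experiments train on 10,000 sequences of
100 bp whose labels are planted counts plus an interaction bonus of 1.0
for two instances within 10 bp (noise sd 0.1), using the 12-bp synthetic
motifs so that a motif pair (span >= 24 bp) never fits inside one 19-bp
filter, and embedding consensus instances: the distance analysis itself
embeds consensus strings, and training on PWM-sampled instances mixes
instance-strength variation into the count response, which shows up as a
spurious sub-additive offset at all distances.

*What we find, and a limitation of the folklore.* The two-FC-layer model
reproduces the expected pattern: strongly elevated residual fold change
inside the bonus window, none beyond, while the global-max-pool ablation
and the control k-mer are flat -- the fully connected layers, not the
filters, carry the positional information. For *heterotypic* pairs,
however, the architecture is often said to be unable to learn the
interaction because units are independent. On planted heterotypic-bonus
data this is not borne out: the model recovers a substantial fraction
(roughly a fifth to two fifths across seeds in our conditions) of the
heterotypic bonus at short range. The mechanism is visible in the trained filters: single
units learn *bispecific* (OR) filters with high similarity to both motifs,
and the unit's own fully connected head then reads the spacing of the two
activation bumps of that one filter. No cross-unit integration is needed,
so unit independence does not forbid it. The corresponding acceptance
check asserts the conventional expectation (a flat heterotypic profile)
and fails honestly; the inability reported on real enhancer data is an
empirical regime -- many competing motifs, weak effects, noisy labels --
not an architectural theorem.

## The synthetic-data generator

`generate_dataset()` draws i.i.d. backgrounds at a target GC content,
embeds non-overlapping motif instances (PWM-sampled by default, consensus
optionally; uniform positions unless fixed or centered), and derives
labels exactly from a ground-truth ledger of every planted instance:
presence/absence, weighted counts with Gaussian noise, or counts plus a
pairwise bonus when two qualifying instances fall within an edge-to-edge
distance window. GC-matched negatives are subsampled from a pool in 5
percentage-point GC bins with adjacent-bin borrowing (logged; an
exhausted pool errors with a per-bin deficit report). Dinucleotide-shuffled
negatives use the Eulerian-path shuffle, preserving the exact dinucleotide
count multiset, length, and terminal bases.

The built-in synthetic motifs place probability 0.94 on the consensus base
per column -- sharp, strong-TF-like sites chosen so that instances sampled
from a PWM are reliably detectable by that same PWM (with broader columns,
even the generative PWM cannot separate its own planted instances from
background, and planted-recovery experiments measure the generator's
ambiguity rather than the model).

What the generator does *not* emulate: genomic sequence composition
(repeats, CpG islands), peak-shape or read-level noise, label correlation
across tasks, motif grammar beyond a single pairwise bonus, and
single-cell sparsity. Passing the packaged checks therefore demonstrates
correctness of the machinery and recoverability under controlled
conditions, not performance on real epigenomic data.

## Problem sizes in the packaged checks

The test suite and `scripts/acceptance.R` use: planted-motif recovery on
5,000 x 100 bp sequences with a 10-unit model (<= 30 epochs);
cooperativity on 10,000 sequences with 16-unit models (<= 25 epochs);
weight recovery on 5,000 sequences with 20 units; initialization contrasts
on 2,000 sequences at a 4-epoch budget over 3 seeds; oracle equivalences
on 100+ random cases each. These sizes were chosen as the smallest at
which the planted effects are estimated stably.

## Known limitations

Single-filter units bound the receptive field; there are no recurrent or
attention components, and tasks needing long-range context are out of
scope. The final-layer weights of unused (dead) units are unidentified
(see above). Training determinism is guaranteed in single-threaded BLAS
mode; multi-threaded BLAS may reorder floating-point reductions.
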