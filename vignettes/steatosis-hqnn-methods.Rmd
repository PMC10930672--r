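---
title: "Hybrid quantum classification of hepatic steatosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantum classification of hepatic steatosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoq)
```

## The clinical problem

Hepatic steatosis — fat accumulating inside liver cells — is the single most
important variable for deciding whether a donor liver can be transplanted.
On hematoxylin-eosin sections the fat dissolves during processing, so
droplets appear as white, rounded gaps in pink tissue; vessels and artifacts
are also white but irregular and elongated. Pathologists stage steatosis
semi-quantitatively by the fraction of tissue area occupied by fat:

| fat area fraction | grade | suitability |
|---|---|---|
| < 5% | 0 | suitable |
| 5–33% | 1 | suitable |
| 33–66% | 2 | not suitable |
| > 66% | 3 | not suitable |

`steatoq` implements a complete desk-scale pipeline for this decision:
slide tiling, a synthetic tile generator with exact ground truth, a hybrid
quantum-classical classifier, a false-negative-penalizing loss, a federated
averaging simulation, and evaluation/sweep tooling.

Shared grade boundaries are ambiguous in the staging table ("5–33%" vs
"33–66%"). We fix a half-open convention, closed on the left of the higher
grade: `[0, 0.05) -> 0`, `[0.05, 0.33) -> 1`, `[0.33, 0.66) -> 2`,
`[0.66, 1] -> 3`. The convention is unit-tested explicitly so it stays
visible.

## The quantum depth-infused (QDI) layer

The core model component is a data re-uploading variational circuit. With
$n$ qubits and $B$ re-uploading blocks it encodes $nB$ classical features
(100 for the default $n = 5$, $B = 20$): block $b$ encodes features
$(b-1)n + 1, \dots, bn$ as Z-axis rotations, one per qubit. Each encoding
block is followed by a variational layer of trainable X-rotations
$R_X(\theta_{bq})$ plus a CNOT entangler; one extra variational layer
precedes the first block, giving $(B + 1)\,n = 105$ trainable rotation
gates. Before measurement, qubits $1..n-1$ each control a CNOT onto qubit
0, spreading the readout; the layer output is the vector of Pauli-Y
expectations $\langle Y_q \rangle \in [-1, 1]$, a classical
$n$-neuron activation.

Conventions that the numerical results depend on (all fixed and tested):

* $R_A(\phi) = \exp(-i \phi A / 2)$, little-endian qubit ordering;
* entangler: linear chain CNOT$(q, q+1)$, $q = 0..n-2$ (a ring closure is
  available via `qdi_config(entangler = "ring")`). The chain is the
  minimal standard choice for re-uploading circuits; nothing in the
  design pins down a denser topology.
* exactly one initial variational layer. This is forced by the trainable
  gate count: $(20 + 1) \times 5 = 105$.
* the initial variational layer is not decorative: Z-rotations act on
  $|0\rangle$ as pure phase, so without it the first block's features
  would be provably dead. A property test asserts exactly this.

The encoding scale is a genuinely open design point ("an angle
proportional to the value"); we squash the preceding dense layer's output
through $\pi \tanh(\cdot)$ so encoded angles live in $(-\pi, \pi)$ and
cannot alias.

### Simulation and gradients

The circuit is simulated as a dense statevector (complex vector of length
$2^n$) in C++; no shot noise or noise channels are modeled, matching the
noiseless-simulation setting of the reference architecture. Correctness is
established against an independent brute-force oracle that multiplies out
explicit $2^n \times 2^n$ gate matrices in R, to $10^{-10}$.

Every trainable gate is a single-qubit rotation, so the two-point
parameter-shift rule
$\partial f / \partial \theta = [f(\theta + \pi/2) - f(\theta - \pi/2)]/2$
is exact; `qdi_gradient()` uses it for both the trainable angles and the
encoded features, making the layer trainable end-to-end without an
autodiff framework. For batched training the same derivatives are computed
by an adjoint sweep (one forward pass, one reverse pass per sample), which
is mathematically identical and two orders of magnitude faster; the test
suite checks parameter-shift, adjoint and central finite differences
against each other.

## Hybrid and classical models

The full-scale architecture puts a pretrained 1000-feature ImageNet
backbone in front of the head. Pretrained weights cannot be fetched in an
offline build, so the default backbone here is `tiny-test-cnn`: three
valid-convolution blocks (3×3 kernels, relu, 2×2 average pooling) and a
dense projection to a 64-feature vector, randomly initialized and trained
from scratch. `backbone_spec("pretrained-resnet18")` exists for parameter
accounting and errors informatively if built.

* hybrid head: affine layers map the backbone features to 100 values
  (1000-dim backbones get 1000→512→100 with a tanh between, matching the
  two-fully-connected-layer design; the tiny backbone uses a single
  64→100 affine), then $\pi\tanh$, the QDI layer, and an affine 5→2.
* classical baseline: the same affine stack with the quantum layer
  replaced by relu + affine 100→2, so the only structural difference is
  the head.

`count_parameters()` reports exact per-component counts; for the
single-affine 1000→100 head the hybrid totals $100100 + 105 + 12 =
100217$.

## The loss: penalizing the dangerous error

The positive class is **not suitable** (grades 2–3). A *false negative* —
a diseased liver predicted suitable — is the clinically dangerous error:
transplanting a steatotic graft risks initial poor graft function. (The
literature this package follows is itself inconsistent between "false
negative" and "false positive" for that same error; we fix this one
convention everywhere, including the checkpoint sidecar.) Training uses

$$ l_\lambda = -\sum_{c=1}^{k} w_c\, y_c \log p_c, \qquad
   w_c = \begin{cases} \lambda & c = \text{not suitable} \\ 1 &
   \text{otherwise,} \end{cases} $$

with probabilities clamped at $10^{-12}$ before the logarithm (a numerical
guard, not part of the model). At $\lambda = 1$ this is exactly the plain
cross-entropy, and on the penalized class $l_\lambda = \lambda\, l_1$, so
monotonicity in $\lambda$ is exact. The reported `fn_rate` is the miss
rate, FN / (actual not-suitable); the denominator choice is ours — the
source material reports a "percentage of false negatives" without defining
one.

Optimization is minibatch Adam (lr $10^{-3}$, $\beta = (0.9, 0.999)$,
$\epsilon = 10^{-8}$, batch 32, 30 epochs by default). The original
hyperparameters were found by a search whose results were never printed;
these are standard placeholders, not reconstructions, and the test suite
uses fewer epochs at smaller scale.

## Synthetic tiles: the stated world

Real slides (jpeg2000, order $10^5$ px per side, 41 patients, 4400 graded
1024-px tiles) are available only on request, so the package generates its
own ground-truthed world:

* background: smooth pink noise field (coarse Gaussian grid, bilinearly
  upsampled, plus fine grain), values capped at 0.86 so tissue is never
  mistaken for fat;
* droplets: near-white ellipses with axis ratio ≥ 0.9 (circularity > 0.9,
  the pathologist's roundness cue), radii 2–5.5% of the tile side
  (floor 1.5 px), added one at a time until the droplet-mask pixel
  fraction reaches the target — near the target the next droplet shrinks
  toward the remaining deficit so the overshoot stays within tolerance;
* confounders: elongated, wobbled white shapes standing in for vessels
  and artifacts, drawn under the droplets and excluded from the fat
  fraction.

The recorded `fat_fraction` is the realized droplet pixel fraction, so
grade and label are exact by construction; an independent pixel-counting
oracle on the emitted image recovers it. Tiles are pure functions of their
spec (seed included), and the manifest stores the full recipe
(target fraction, confounder count, seed) so datasets regenerate
bit-identically. Balanced datasets draw targets uniformly inside each
grade's staging interval, 0.01 away from shared boundaries; grade 3 is
capped at 0.96 because droplet-union coverage approaches 1 only
asymptotically.

What a green test does **not** establish: nothing about stain variation,
nuclei, zonality, macro- vs microvesicular droplets, scanner artifacts, or
any real-data accuracy. The generator encodes exactly one separating cue
(white rounded area fraction); results on it validate the artifact's
plumbing and optimization, not clinical performance. The reference study's
97% / 95.2% accuracies live on private clinical data and are deliberately
not acceptance targets here.

## Federated simulation

`run_federated()` simulates horizontal federated learning in-process:
disjoint, class-balanced, equal-size client shards (patient-disjoint when
patient ids allow it; shards of odd size split classes 62/63-style), 15
rounds × 1 local epoch by default, vanilla FedAvg aggregation
(sample-count-weighted mean — with equal shards, the plain mean), all
clients training and evaluated every round against a centralized 8:2
held-out test split. Only weight tensors cross the client boundary. Local
Adam moments are reset each round; only weights are exchanged, which is
the vanilla algorithm. Because the centralized and federated paths share
one per-epoch seed stream, a single client with `rounds = 1,
local_epochs = E` reproduces centralized E-epoch training bit-identically —
the degenerate-equivalence test. (With `rounds = E, local_epochs = 1`
bit-identity is impossible by design, since centralized Adam keeps its
moments across epochs.)

`client_grid_experiment()` reproduces the (samples-per-client × client
count) table layout with fold means ± standard deviations; infeasible
cells are reported absent, not zero.

## Numerical choices and degenerate inputs

* statevector norm asserted to $10^{-10}$; circuit outputs bounded in
  $[-1, 1]$;
* tiling discards partial edge tiles (the grid is the reassembly
  coordinate system for the heatmap tool); images smaller than one tile
  yield an empty list plus a warning;
* `center_crop` is a true centered crop (offset $\lfloor (1024 - 258)/2
  \rfloor = 383$ for the reference sizes), never a resize;
* `epochs = 0` and `rounds = 0` return initialized models with empty
  histories; empty and single-class datasets are rejected;
* fn_rate on a test set with no positive tiles is `NA` with a warning,
  never silently 0.

## Known limitations

* No pretrained backbone offline: transfer learning — a load-bearing
  ingredient of the full-scale result — is out of reach here, so absolute
  accuracies are not comparable to the reference study's.
* The synthetic world is linearly separable in one engineered feature;
  hybrid-vs-classical comparisons on it say nothing about relative power
  on clinical data.
* jpeg2000 ingestion is unsupported in this build (no offline decoder);
  PNG is the tested image format, as intended for desk scale.
* No privacy cryptography (FHE/SMPC), no differential privacy, no client
  dropout, no unbalanced shards: the simulation mirrors the balanced
  scenario only.

## A compact end-to-end run

```{r example, eval = FALSE}
ds <- synth_dataset(n_per_grade = 125, side_px = 32, seed = 5) # 500 tiles
sp <- holdout_split(ds, ratio = 0.8, seed = 2)
fit <- train_model(sp$train, default_model_spec(sp$train),
                   train_config(epochs = 10, seed = 4))
evaluate(fit, sp$test)
```
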