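---
title: "Predicting self-interacting proteins from sequence profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting self-interacting proteins from sequence profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A self-interacting protein (SIP) binds another copy of itself
(homo-oligomerisation). SIPs coordinate gene expression and many complex
cellular functions, and curated interaction databases now hold enough of
them to train sequence-only predictors. The practical setting is harshly
imbalanced: curated gold-standard sets contain roughly one SIP per eleven
non-SIPs (1441 : 15,938 in human, 710 : 5511 in yeast), so a useful
predictor must be judged by specificity, F1, MCC and AUC rather than by
accuracy alone.

`sipgraph` implements a full sequence-based SIP prediction pipeline:

1. each protein is encoded by its PSSM (position-specific scoring
   matrix), the $N \times 20$ profile of per-position substitution
   scores produced by an iterative profile search such as PSI-BLAST;
2. variable-length profiles are summarised into fixed-length
   evolutionary composition features;
3. a graph convolutional network (GCN) whose layer propagation is
   estimated by Monte-Carlo node sampling embeds the proteins;
4. a bootstrap-aggregated random forest votes on the embeddings.

Every stage is exposed as a function, and a repeated five-fold
cross-validation harness reports the full metric suite.

## From profile to fixed-length features

PSI-BLAST emits, for a protein of $N$ residues, a matrix
$\mathrm{PM} \in \mathbb{Z}^{N \times 20}$ of log-odds scores
$\sigma_{i,j}$ describing how readily residue $i$ mutates to amino acid
$j$. The package parses the standard ASCII layout and keeps exactly the
first 20 numeric columns (the log-odds block).

Two choices here are the package's own, because the upstream literature
typically leaves them implicit:

* **Logistic normalization.** Raw log-odds are unbounded; we map each
  score through $x \mapsto 1/(1+e^{-x})$, giving bounded
  pseudo-probabilities in $(0,1)$. This reconciles the
  "mutation-probability" reading of the PSSM with its log-odds file
  content and keeps GCN inputs on a common scale.
* **Residue-grouped composition.** Proteins differ in length, but a GCN
  needs one feature vector per node. We use the $20 \times 20$
  composition matrix $C$, where $C[a, j]$ is the mean normalized score
  in profile column $j$ over all positions carrying residue $a$ (zero
  rows for absent residues), flattened row-major into 400 values with
  both axes in alphabetical amino-acid order. Composition is the
  standard fixed-length PSSM summary in sequence-based interaction
  work and preserves the per-residue-type evolutionary signal.
  Ambiguous residues (X/B/Z/U) are tolerated in sequences but
  contribute no rows, since the profile has exactly 20 columns.

The autocovariance (AC) baseline is also provided:
$\mathrm{AC}(l, j) = \frac{1}{N-l} \sum_{i=1}^{N-l}
 (S_{i,j}-\mu_j)(S_{i+l,j}-\mu_j)$
for lags $l = 1..lg$ on the normalized scores, giving $20\,lg$ values.
The default lag bound $lg = 5$ (100 features) is configurable; small
lags keep the dimension comparable with other baselines.

## The protein graph

No graph is given a priori, so one is built from the features: each
protein is connected to its $k = 10$ most cosine-similar neighbours,
edges are symmetrised by union, self-loops added, and the adjacency
normalized symmetrically,
$\hat A = D^{-1/2}(A + I)D^{-1/2}$,
whose spectrum lies in $[-1, 1]$. This is the standard construction for
GCNs over tabular features and keeps the transductive structure the
sampled estimator assumes: the graph spans all nodes, but the training
loss only ever sees training-fold labels.

## Sampled graph convolution

Layer propagation is viewed as an integral over a probability measure
$P$ on the vertex set: the pre-activation embedding of node $v$ at layer
$l+1$ is $\int \hat A(v, u)\, h^{(l)}(u)\, W^{(l)} \, dP(u)$, with
$h^{(l+1)} = \sigma(\tilde h^{(l+1)})$. The full-batch layer
$\sigma(\hat A H W)$ is its exact population form.

Drawing $t$ i.i.d. nodes $u_1..u_t$ from a sampling distribution $q$,
the package estimates the pre-activation as

$$\tilde h(v) \approx \frac{1}{t} \sum_{j=1}^{t}
  \frac{\hat A(v, u_j)\, h(u_j)\, W}{q(u_j)}.$$

The $1/q(u_j)$ importance weight makes the estimator unbiased for the
full-batch product $\hat A H W$ under *any* strictly positive $q$ — the
property the acceptance suite verifies empirically at three standard
errors — and its variance decays as $1/t$. The default $q(u) \propto
\lVert \hat A(:,u) \rVert^2$ is the variance-reducing importance choice;
a uniform measure is selectable, under which the deterministic
"exhaustive" test mode (every node enumerated once, weights $1/(nq)$)
reproduces the full-batch layer exactly. A plain unweighted average
would instead target the integral under $P$, which differs from
$\hat A H W$ by a population factor; we prefer the importance-weighted
form precisely because it makes the full-batch layer the verifiable
limit of the estimator.

### Architecture, loss and training

The network has one hidden layer: input (400) → 256 ReLU units → 2
classes, i.e. two weight matrices. Training minimises the mean
cross-entropy of the softmaxed outputs over the labelled training nodes
plus an L2 weight penalty $\lambda(\lVert W^{(0)}\rVert^2 +
\lVert W^{(1)}\rVert^2)$ with $\lambda = 5\times10^{-4}$; a pure weight
penalty has no data term and cannot train a classifier, so the
cross-entropy data term is taken as read. Both layers are propagated
through the sampled estimator with fresh draws per epoch and per layer
(sample size $t_l = \min(256, n)$), and gradients flow through the
sampled support.

Published settings are kept as defaults: learning rate $0.1$, 256
hidden units, 200 iterations. The optimiser is plain gradient descent.
We evaluated Adam at the same learning rate and found it destabilises
the hidden layer on composition-scale inputs — parameter steps of order
$0.1$ per epoch drive every ReLU unit negative within tens of epochs,
collapsing the embeddings to zero — whereas plain gradient descent at
$0.1$ converges smoothly (the training-loss trajectory is recorded on
the model and tested for a downward trend). Adam remains selectable for
smaller learning rates.

Downstream features are the post-activation hidden outputs of a
deterministic full-batch forward pass ($n \times 256$, non-negative) —
the conventional "learned representation" read-out.

Two ambiguities are resolved explicitly and flagged here: the GCN is
trained *supervised* on training-fold labels and then harvested for
embeddings (training it unsupervised is the other reading), and the
graph is transductive — test-node *features* participate in neighbour
structure while test-node *labels* are masked to `NA`, so any attempt to
train on them is a hard error. Transductive feature visibility is
leakage-adjacent and is called out wherever the harness is documented.

## Classification

The random forest follows the classical three-step ensemble strategy,
implemented in-repo: (a) bootstrap resamples of size $n$ drawn with
replacement, (b) one full-depth decision tree per resample (induction
delegated to `rpart`), (c) majority voting, with the fraction of trees
voting SIP as the score. Defaults: 100 trees, $\lceil\sqrt d\,\rceil$
features per tree. Feature subsampling is per tree rather than per
split, since `rpart` exposes no per-split hook; at these
dimensionalities the ensembles behave equivalently (an independent
forest implementation agrees with ours on separable data in the test
suite). Vote ties go to non-SIP, the majority class — deterministic and
conservative under imbalance. A bootstrap resample that happens to
contain a single class yields a constant-vote tree.

Ablation classifiers mirror the published comparisons: KNN (Euclidean,
$k = 5$, score = positive-neighbour fraction) and an extreme learning
machine (seeded random projection, sigmoid hidden layer of 256,
least-squares output weights by pseudo-inverse against $\pm 1$ targets,
ridge fallback if the hidden design degenerates). All classifier
hyperparameters are this package's defaults; none are stated upstream.

## Evaluation protocol

With SIP as the positive class,
$\mathrm{Acc} = \frac{TP+TN}{TP+TN+FP+FN}$,
$\mathrm{Spe} = \frac{TN}{TN+FP}$,
$F1 = \frac{2TP}{2TP+FP+FN}$, and
$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TN+FN)(TP+FN)(TN+FP)}}$.
Any metric with a zero denominator is defined as 0. The ROC curve is a
threshold sweep over unique scores with trapezoidal integration, so the
AUC equals the Mann–Whitney statistic
$P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$ under ties.

Cross-validation shuffles the indices into five disjoint folds whose
sizes differ by at most one — *unstratified*, matching the protocol's
plain wording; a stratified option exists but is off by default. Each
fold is the test set exactly once; the graph is rebuilt per fold, the
GCN retrained with masked test labels, and the classifier fit on
training-fold embeddings only. Fold metrics are aggregated as mean ±
sample (n−1) standard deviation, and the whole procedure can be
repeated (100 repetitions matches the full published protocol; the
default is 1). Every random draw — fold shuffles, GCN initialisation
and sampling, bootstrap resamples — derives from one master seed, so
reports reproduce bit-for-bit. A test fold containing one class gets an
undefined (NA) AUC with a warning rather than a fabricated value.

## The synthetic generator

Real gold-standard data require PSI-BLAST profiles against SwissProt
and curated database downloads, so the package ships a seeded generator
instead: random sequences over the 20 standard amino acids, lengths
uniform in a configurable range (default 50–300, inside the curated
50–5000 band), integer score matrices of rounded Gaussian noise (mean
0, sd 2), and a planted class signal — an effect size $\delta$ added to
designated profile columns (default columns 1–3) of positive-class
proteins. A column-mean shift is used rather than a sequence motif so
that the composition featurizer provably carries the signal; it is a
test scaffold, not a biological claim.

What passing tests therefore show: the estimator, harness and
classifiers recover a planted location signal and stay at chance on
exchangeable nulls. What they do not show: performance on real
evolutionary profiles, whose column correlations, homology structure
and length distribution the generator deliberately does not emulate.

The study conditions used by the acceptance checks are fixed once:
$\delta = 3$ with 200 + 200 proteins for signal recovery (accuracy
≥ 0.95), $\delta = 0$ with 500 + 500 for null calibration (AUC in
[0.45, 0.55]), and a weak-signal imbalanced condition of 60 SIPs :
660 non-SIPs ($\delta = 0.5$, the 1 : 11 curated-human ratio), which
reproduces the specificity-dominant ordering Spe > Acc > F1
characteristic of imbalanced SIP benchmarks. Estimator diagnostics run
on small fixed graphs (6 nodes for unbiasedness at 20,000 draws; 20
nodes for variance decay at $t \in \{1, 4, 16\}$, since $t$ may not
exceed the node count). These sizes keep the whole suite to a few
minutes on one core while leaving every probabilistic check
well-powered.

## Numerical and degenerate-input conventions

* Zero-denominator metrics return 0 (logged in the function docs);
  empty confusion tables are errors.
* Vote ties → class 0; KNN score ties at 0.5 → class 0.
* Weight initialisation is Glorot-uniform from the training seed;
  sampled node draws use the same stream, so a seed fixes the entire
  trajectory.
* Zero-norm feature rows make cosine similarity undefined and are
  rejected by name; sequences with no standard residues are rejected by
  the featurizer.
* PSSM rows with fewer than 20 numeric fields, missing column headers
  and empty profiles raise format errors naming the offending row.
* The curated-mode length filter (50–5000 residues) is enforced only
  when requested, since synthetic fixtures may be shorter.

## Limitations

Sequence-only: no physicochemical or structural features. The graph is
built from the same features the GCN consumes, so the embedding cannot
recover signal the composition destroys. Transductive evaluation means
deployment on disjoint new proteins (via `predict()` on a fitted
bundle, which appends new nodes to the graph) may be slightly
optimistic relative to the cross-validated numbers. PSI-BLAST itself is
out of scope: the package documents the conventional invocation
(e-value 0.001, 3 iterations, SwissProt) but never runs it.
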