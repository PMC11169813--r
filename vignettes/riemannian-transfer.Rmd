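---
title: "Riemannian transfer learning for EEG covariance matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian transfer learning for EEG covariance matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor-imagery brain-computer interfaces decode which movement a user is
imagining from multichannel EEG. A robust representation of a trial is its
spatial covariance matrix: an $n \times n$ symmetric positive definite (SPD)
matrix capturing the band power distribution over the scalp. SPD matrices do
not form a vector space; they form a curved Riemannian manifold, and
classifiers that respect that geometry (nearest Riemannian mean, prototype
methods in the tangent space) are compact, noise-robust and need little
training data.

Their weakness is *covariance shift*: between recording sessions, and even
more between subjects, the distribution of trial covariances moves --
electrodes sit slightly differently, impedances and the user's state change.
A decoder trained on one session then meets test data whose geometric mean,
dispersion and spatial mixing have all drifted. `riemalign` implements
unsupervised alignment methods that remove this drift before classification,
together with the geometry, classifiers, synthetic benchmarks and evaluation
protocols needed to study them.

## Geometry: two metrics on the SPD manifold

Everything rests on two Riemannian metrics.

Under the **log-Euclidean metric (LEM)** the matrix logarithm
$X \mapsto \log X$ (computed by symmetric eigendecomposition) is a global
isometry onto the Euclidean space of symmetric matrices:

$$\delta_{LE}(X_1, X_2) = \lVert \log X_2 - \log X_1 \rVert_F, \qquad
  \bar X = \exp\Big(\tfrac{1}{N}\sum_i \log X_i\Big).$$

The Fréchet mean is a *closed form* -- one pass over the data -- and the
distance is invariant under inversion and orthogonal congruence. Geodesics,
exponential and logarithmic maps (`lem_geodesic`, `lem_exp_map`,
`lem_log_map`) are line segments in the log-domain.

Under the **affine-invariant metric (AIRM)**,
$\delta_R^2(X_1, X_2) = \sum_k \log^2 \lambda_k$ over the eigenvalues of
$X_1^{-1} X_2$. The payoff is full congruence invariance
($\delta(AXA^\top, AYA^\top) = \delta(X,Y)$ for any invertible $A$); the
cost is that the mean has no closed form. `airm_mean` runs the
deterministic full-batch Karcher fixed point
$M \leftarrow M^{1/2}\exp\big(\overline{\log(M^{-1/2} X_i M^{-1/2})}\big)M^{1/2}$
to a gradient-norm tolerance of $10^{-8}$ (at most 100 iterations,
initialized at the LEM mean). A stochastic variant would converge to the
same point with extra variance; the deterministic iteration is reproducible
and directly testable against the first-order optimality condition.

**Numerical policy.** All matrix functions symmetrize their input as
$(X + X^\top)/2$ before decomposing, guaranteeing real spectra. Eigenvalues
below $10^{-12}\,\lambda_{\max}$ raise a singular-matrix error naming the
offending eigenvalue rather than being clipped silently -- rank-deficient
trial covariances should be visible, not papered over. An opt-in
`regularize` flag adds $\varepsilon I$ (default
$\varepsilon = 10^{-10}\,\mathrm{tr}(X)/n$) for callers who do want a ridge.

## Alignment

All three methods are unsupervised: they see the two unlabeled matrix
clouds, never the class labels, so they can run at test time on an
unlabeled incoming session.

**PA-LEM** performs classical Procrustes standardization in the log-domain.
Each domain is centred at its own log-mean and divided by the square root of
its mean squared log-deviation:

$$\log X_i \;\mapsto\; \frac{\log X_i - \overline{\log X}}{\sqrt{d'}},
  \qquad d' = \tfrac1N \sum_i \lVert \log X_i - \overline{\log X}\rVert_F^2 .$$

Dividing by $d'$ itself (a variance) would leave the two domains at
*different* residual dispersions $1/d'_S \ne 1/d'_T$; only the square root
standardizes both to exactly unit variance, which is the entire point of the
step, so that is what the package does. The output is mapped back to the
manifold with `exp` by default (so SPD-consuming classifiers work
unchanged); `log_domain = TRUE` returns the raw tangent points. Rotation is
deliberately omitted (see Limitations).

**RPA-LEM** works on the manifold itself: *re-centering* by the congruence
$X \mapsto M^{-1/2} X M^{-1/2}$ with $M$ the domain's closed-form LEM mean,
then *stretching* the target along geodesics through the identity,
$X \mapsto X^{s}$ with $s^2 = d / \tilde d$ the ratio of source to target
dispersion. Two conventions needed fixing:

* **Where dispersions are measured.** By default they are computed on the
  *re-centered* sets around the identity (`dispersion_order = "post"`).
  Under AIRM the pre- and post-recentering dispersions coincide by
  congruence invariance; under LEM they differ slightly, and only the
  post-recentering convention makes the stretch exact:
  $\sum_i \lVert s \log X^{(rct)}_i \rVert^2 = s^2 \tilde d = d$
  identically. The literal-order alternative is kept behind
  `dispersion_order = "pre"`.
* **Sum versus mean.** The stretch ratio uses summed squared distances by
  default (`normalize = "sum"`); with equally sized domains the two
  conventions give the same $s$, and both are exposed because dispersion is
  reported both ways in the field. $s$ is the positive square root.

A target whose matrices are all identical has zero dispersion and no finite
stretch; this raises a `degenerate-dispersion` error rather than producing
$s = \infty$.

**RPA-AIRM** is the same recenter + stretch scheme under AIRM (Karcher
means, AIRM dispersions). It is the accuracy reference: congruence
invariance makes its post-conditions *exact* -- the Karcher mean of each
re-centered set is the identity to solver tolerance, and refitting on its
own output returns the identity transform. For RPA-LEM the congruence
re-centering does not commute with the LEM mean, so refitting on its own
output is the identity only up to a second-order non-commutativity residual:
exactly zero on commuting (e.g. diagonal) data, and measured at about
$6\text{--}10\times10^{-3}$ (max entry of the refitted re-centering matrix
against $I$) on the package's standard synthetic fixture. The test suite
asserts the commuting case at $10^{-8}$ and the general case at a documented
loose $10^{-2}$.

Fitted transforms are plain parameter objects (`log_center`, `scale_divisor`
for PA-LEM; `recenter_matrix`, `stretch_exponent` for the RPA variants),
apply one sample at a time (`apply_to_new_sample`) with numerics identical
to the batch path -- the online use case -- and serialize to JSON with 17
significant digits, making round trips lossless.

## The PLVQ-LEML classifier

Probabilistic learning vector quantization with log-Euclidean metric
learning models the class-conditional densities with labeled prototypes
$W_j$ (stored as $\log W_j$) and a learnable metric tensor
$Q = \Omega\Omega^\top$:

$$\delta(X, W_j, Q) = \mathrm{Tr}\big[Q\,(\log X - \log W_j)^2\big], \qquad
  p(j \mid X) \propto P(j)\,e^{-\delta_j / 2\sigma^2},$$

with posteriors computed by log-sum-exp and the cost being the negative
log-likelihood $\sum_i \log\big(Z_{all}/Z_{y_i}\big)$. Training is
stochastic gradient descent in the log-domain with per-epoch seeded
shuffling. Design points:

* **Symmetrized prototype gradient.** The unconstrained gradient of
  $\delta$ involves $Q\Delta$, which is not symmetric for general $Q$; the
  prototype must remain a symmetric matrix, so the update applies
  $(Q\Delta + \Delta Q)/2$ -- precisely the restriction of the gradient to
  the symmetric subspace. Both the prototype and the $\Omega$ update are
  verified against central finite differences of the cost (relative error
  below $10^{-4}$) in the test suite; `plvq_gradients` exposes them.
* **Scale fixing.** $Q$ and $\sigma^2$ share a scale degeneracy, so
  $\Omega$ starts at the identity and $Q$ is re-normalized to
  $\mathrm{Tr}(Q) = n$ after every metric step. Priors are fixed uniform
  ($1/M$): no update rule for them is part of the model.
* **Initialization.** Prototypes start at the class-conditional LEM means,
  plus a seeded symmetric jitter of Frobenius norm $0.01$ when a class owns
  several prototypes (symmetry breaking). With all learning rates zero the
  fitted model is bit-identical to this initialization.
* **Learning-rate schedules.** $\alpha(t) = \frac{n\xi}{100}\,0.01^{t/T}$
  for prototypes and $\eta(t) = \frac{n\xi}{10000}\,0.01^{(t-t_0)/(T-t_0)}$
  for the metric, where $n$ is the matrix dimension, $\xi$ the prototypes
  per class, $T$ the epoch budget (default 100) and $t_0$ the epoch at
  which metric learning starts (default 1). $\eta$ stays roughly two orders
  of magnitude below $\alpha$, which keeps joint training stable. The
  exponent of the $\eta$ schedule is read as $(t - t_0)/(T - t_0)$.
* **$\sigma^2$ and prototype location.** With $\sigma^2$ large relative to
  the within-class squared-distance scale, neighbouring classes exert
  soft-assignment repulsion and the optimal prototypes sit *away* from the
  class means -- that is a property of the likelihood, not a bug. Prototype
  positions reproduce the class means only when $\sigma^2$ matches the
  within-class scale, which is also the regime cross-validation selects on
  separable data; the recovery test uses $\sigma^2 = 0.1$ for data whose
  within-class mean squared distance is $\approx 0.1$.

`grid_search_cv` selects prototypes-per-class and $\sigma^2$ by stratified
five-fold cross-validation on mean kappa, breaking ties toward the smaller,
simpler model. `mdrm_fit` / `mdrm_predict` provide the
minimum-distance-to-Riemannian-mean baseline under either metric; ties in
prediction always break toward the lowest class index.

## Preprocessing

`bandpass_filter` applies a 5th-order Butterworth bandpass (default
10--30 Hz, the sensorimotor mu/beta band) per channel. No DSP package ships
with the supported environment, so the design -- analog Butterworth
prototype, lowpass-to-bandpass transform, bilinear discretization with
prewarping -- is implemented in the package and pinned by a test against
reference coefficients computed independently (agreement at $10^{-12}$).
Filtering is zero-phase by default (forward-backward passes with
odd-reflection padding and steady-state initial conditions), which keeps
epochs time-aligned; the order counts per pass, and a `causal` flag gives a
single forward pass for online settings.

`extract_window` cuts the analysis window (canonically 0.5--2.5 s after the
cue: 500 samples at 250 Hz) and `trial_covariance` forms
$X_i = E_i E_i^\top/(l-1)$ *without* mean subtraction -- after a bandpass
the signals are zero-mean, and subtracting an estimated mean would spend a
degree of freedom for nothing (a `center` flag exists for unfiltered
inputs). Rank-deficient trials fail loudly with the trial index unless a
ridge is requested.

## The synthetic world

`sample_lem_gaussian` realizes the "Riemannian Gaussian" class-conditional
model in the log-Euclidean chart: $\log X = \log M + \sigma S$ with $S$
standard normal in an orthonormal basis of symmetric matrices (diagonal
units, off-diagonal units scaled by $1/\sqrt2$). In this chart the model is
exactly samplable and exactly analyzable -- the population LEM mean is $M$
and the population mean dispersion is $\sigma^2 n(n+1)/2$, which the tests
verify at Monte-Carlo rates. The alternative (the AIRM heat-kernel
density) admits no exact sampler of comparable simplicity and the methods
under study are LEM-based; the discrepancy is acknowledged and accepted.

Covariance shift is simulated by three primitive operations, composable in
the fixed order translation → dispersion scaling → congruence
(`shift_spec`): a log-domain translation $\log X \mapsto \log X + \log B$
(mean displacement), a rescaling
$\log X \mapsto \log\tilde M + c(\log X - \log\tilde M)$ around the set's
own mean (state change), and a congruence $X \mapsto A X A^\top$ (spatial
re-mixing, e.g. electrode displacement). Each is the exact inverse image of
one alignment operation, so recovery experiments have a known ground truth.

**The standard fixture** (`standard_transfer_fixture`) is the package's
reference world: $n = 8$, $C = 4$, 60 trials per class and domain,
composite shift with $\lVert \log B \rVert_F = 2$ and $c = 2$. The free
parameters were fixed once, by two considerations stated before the
acceptance experiments were run, and not revisited:

* *Class geometry*: pairwise mean separation 1.2 with within-class spread
  $\sigma = 0.33$ puts the no-shift oracle at kappa $\approx 0.9$ -- the
  performance of a high-quality motor-imagery subject, so the benchmark is
  neither saturated nor hopeless. (`make_class_means` draws candidates so
  that typical distances sit just above the requested minimum; a naive
  coordinate scale would make "separation" a $6\times$ loose bound in the
  36-dimensional symmetric space and strip it of meaning.)
* *Shift direction*: the translation $\log B$ is drawn inside the span of
  the centred class log-means. A translation in a uniformly random
  direction of the 36-dimensional log-space is almost orthogonal to the
  3-dimensional discriminant subspace and measurably barely affects a
  nearest-mean classifier (degradation $\approx 0.01$ kappa); real session
  changes, by contrast, shift power in the same sensorimotor channels that
  discriminate the classes, and displace sessions further than classes are
  separated. The in-span translation of norm 2 ($\approx 1.7\times$ the
  class separation) reproduces that regime: no-transfer kappa drops by
  $\approx 0.35$ and RPA-LEM recovers to within $\approx 0.04$ of the
  oracle.

What the generator does **not** emulate: $1/f$ spectra and band-limited
oscillatory structure, artifacts, within-session nonstationarity, heavy
tails, channel-count realism, or label noise. A green transfer-recovery
test therefore establishes that the alignment removes the modeled shift
family under LEM-Gaussian scatter -- not that it will do so on any given
recording.

## Evaluation

`kappa_score` is the balanced-class chance-corrected accuracy
$\kappa = (D - 1/C)/(1 - 1/C)$: 1 for perfect prediction, 0 at chance
$1/C$. `run_cross_session` fits alignment unsupervised, trains on the
aligned source, scores on the aligned target, and times alignment,
training and prediction separately (process CPU time, not wall clock).
`run_cross_subject` runs all directed subject pairs and reports mean (sd)
per test subject; `run_repeated` aggregates over consecutive seeds;
`timing_comparison` averages fitting CPU time over repeats -- the
closed-form LEM mean makes RPA-LEM several times cheaper than the Karcher
iteration inside RPA-AIRM (a factor enforced qualitatively, with a generous
margin, by the tests). The CLI (`riemalign_cli`) exposes `simulate`,
`align`, `train`, `evaluate` and `benchmark-timing` over YAML or JSON
configs; every run writes its resolved configuration with a content hash
next to its outputs. (YAML 1.1 note: a bare `n:` key parses as a boolean,
so the config key is `n_channels`.)

## Known limitations

* **No rotation step.** Re-centering plus stretching cannot undo an
  orthogonal re-mixing between domains: after re-centering, the two clouds
  still differ by a rotation, which only a Procrustes rotation (not
  implemented, following the finding that it does not help motor-imagery
  decoding) could remove. Congruence shifts are therefore corrected only up
  to their rotational part. Per-class means are computed into
  `DomainStatistics` for completeness but no transform consumes them.
* **RPA-LEM refit residual.** See above: second-order in the dispersion,
  zero on commuting data.
* **Sum-normalized stretch with unequal domain sizes** matches summed, not
  mean, dispersions; pass `normalize = "mean"` when $N_S \ne N_T$.
* **PLVQ training cost** is $O(T \cdot N \cdot M)$ eigendecomposition-free
  updates but one $n \times n$ eigendecomposition per sample up front; very
  large $n$ (60+) is workable but slow in pure R.
* The GDF/EDF adapters for the public competition recordings are interface
  stubs (`read_epochs` / `read_event_table` define the exchange formats);
  parsing proprietary formats is out of scope.
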