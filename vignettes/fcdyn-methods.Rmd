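---
title: "Models and methods in fcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fcdyn asks a single question of multi-session parcel time series: how much of
the variability in behavioural traits across people is carried by
*time-varying* functional connectivity (FC), over and above the *time-averaged*
FC and the anatomy? Its answer is built from four pieces: a covariance-state
hidden Markov model (HMM), Kullback–Leibler (KL) distance matrices, kernel
ridge regression (KRR) under family-respecting cross-validation, and
representation-similarity statistics. This vignette records the models, the
defaults, and the design decisions — including the ones that were genuinely
open.

## The covariance-state HMM

Each standardized session is a $T \times J$ matrix (timepoints by parcels;
every column demeaned, unit sample variance with the $T-1$ divisor). The
working model is a $K$-state HMM whose states, in the default `"fc"` variant,
are zero-mean Gaussians with full covariance:

$$ p(x_t \mid z_t = k) = \mathcal{N}(x_t \mid 0, \Sigma_k). $$

Forcing the mean to zero is the point of the model: with amplitude excluded
from the state description, a state switch *is* a change in correlation
structure, i.e. in FC. Two control variants deliberately remove that
information: `"mean"` gives each state its own mean but one covariance shared
across states (amplitude dynamics only), and `"var"` gives each state a
diagonal covariance with zero mean (variance dynamics only, blind to
cross-parcel correlation). If predictions from the `"fc"` variant beat both
controls, the predictive information is in the connectivity dynamics, not in
amplitude or variance excursions.

Inference is variational Bayes with conjugate priors:

* state precisions: Wishart, with $J + 2$ degrees of freedom and prior scale
  matched to the pooled data covariance, so the prior mean precision is the
  pooled inverse covariance. One-state fits therefore reproduce the pooled
  second-moment matrix essentially exactly;
* transition-matrix rows: Dirichlet with concentration 1 plus a
  self-transition pseudo-count boost (default `stickiness = 10`). This is the
  temporal regularizer: it penalizes spurious fast switching without fixing
  dwell times;
* initial state probabilities: flat Dirichlet.

The E-step runs a scaled forward–backward pass per session using the expected
log-parameters; the M-step applies the conjugate updates. The reported free
energy (the negative evidence lower bound: parameter KL terms minus the
forward-pass log-normalizer) is non-increasing across iterations for all three
variants — this is asserted by tests, and a violation indicates a defect, not
noise. Iteration stops when the relative free-energy change falls below
`tol = 1e-5` or at `max_iter = 500`.

Initialization clusters sliding-window covariance summaries (window means for
the `"mean"` variant) with k-means and adds seed-controlled noise; short
sessions fall back to a random Dirichlet draw. Because the optimisation is
seed-dependent, `fit_group_hmm_reps()` treats repeated fits (default five
seeds) as first-class replicate estimates: each repetition yields its own
distance matrix, predictions, and comparison rows downstream. The default
state count `K = 8` follows common practice for this model class and is not
optimised over; all desk-scale examples in the package use smaller `K`
matching their generators.

## Dual estimation and the reconstruction identity

Subject-specific models come from one re-estimation cycle against the group
model: (1) decode the subject's sessions under the group model to get state
time courses; (2) form subject state covariances as the gamma-weighted second
moments of the subject's data; (3) re-decode under those subject states to get
the subject's state time courses and transition matrix (Dirichlet prior plus
expected transition counts). States stay aligned with the group model's states
by construction, which is what makes between-subject model distances
meaningful without any matching step.

The fractional occupancies $w_k$ returned on the subject model are the time
averages of the *state-defining* gammas from step (1). With that binding, the
reconstruction identity

$$ \sum_k w_k \Sigma_k^{\mathrm{dual}} \;=\; \frac{1}{T}\sum_t x_t x_t' $$

holds to machine precision for every subject: the dual-estimated model loses
none of the time-averaged FC. (Binding $w$ to the re-decoded gammas of step
(3) would pair weights and covariances from different posteriors and break the
identity; both gamma sets are kept on the object.) Time-averaged FC divisors
are deliberately asymmetric: $T-1$ for standardization, $T$ for the
second-moment matrix, exactly so the identity's algebra closes.

States whose defining occupancy falls below 10 effective samples are retained
with a prior-dominated covariance and a warning — never pruned — so the state
space stays identical across subjects. That blending deliberately trades the
exact reconstruction identity on (vanishingly weighted) near-empty states for
positive definiteness in the downstream divergences; identity checks use
`occupancy_floor = 0`, which keeps the raw weighted moments.

`fc_temporal_variability()` summarizes the time-varying content: the
elementwise variance (population divisor) across time of the instantaneous FC
estimate $\sum_k \gamma_{tk} \Sigma_k$. On cohorts where state covariances are
drawn independently of the mixing weights, this variability map is essentially
uncorrelated with the time-averaged FC — the two summaries carry separate
information.

## Distances

Every representation is reduced to an $N \times N$ subject distance matrix:

* **avfc** — each subject's time-averaged FC matrix is read as a zero-mean
  Gaussian, and pairs are compared by symmetric KL. For standardized data this
  respects the non-Euclidean geometry of correlation matrices; the
  log-determinant terms cancel in the symmetrized sum.
* **hmm** — there is no closed-form KL between HMMs; the directed divergence
  is approximated by a stationary-weighted sum of per-state terms,
  $\mathrm{KL}(M^1\|M^2) = \sum_k \nu_k\,[\mathrm{KL}(P^1_k, P^2_k) +
  \mathrm{KL}(G^1_k, G^2_k)]$, symmetrized over both directions. Each directed
  term is weighted by *its own* first argument's stationary distribution
  $\nu$ (the natural binding in this approximation). Transition rows are
  compared as Dirichlet posteriors over pseudo-counts by default — they are
  posterior objects, and the counts carry the evidence; `dirichlet = "point"`
  switches to categorical KL on the expected rows.
* **structural** — plain Euclidean distance between per-subject component
  weight vectors, which carry no special geometry.

$\nu$ is the leading left eigenvector of the transition matrix, validated
against the power-iteration limit of $\pi P^n$; reducible or periodic chains
(where that limit depends on the start) fall back to the subject's fractional
occupancy with a warning. Matrix inversions jitter by $10^{-8}\cdot
\mathrm{mean(diag)}$ once before failing. All distance matrices are
symmetrized, zero-diagonal, and nonnegative by construction and by test.

## Prediction

`krr_predict_cv()` predicts one trait from one distance matrix with Gaussian
kernel ridge regression, $H_{ij} = e^{-(\tau\,\mathrm{Dist}_{ij})^2}$ and
$\hat y = h\,(H + \lambda I)^{-1} y$, under 10-fold cross-validation that
assigns whole families to folds (greedy size-balanced assignment), so familial
resemblance can never leak across the train/test boundary.

Open choices and their resolutions:

* **Hyperparameter selection.** $(\lambda, \tau)$ are chosen per outer fold by
  an inner cross-validation that reuses the outer partition: each remaining
  outer fold serves once as the inner validation set (nine inner splits at ten
  outer folds). This keeps families unsplit in the inner loop for free and
  adds no second fold-randomization path. $\lambda$ ranges over 10 log-spaced
  values in $[10^{-4}, 10^3]$; $\tau$ over $\{0.25, 0.5, 1, 2, 4, 8\}$ divided
  by the median training-fold distance, because KL distances carry no fixed
  units.
* **Kernels from KL distances are not guaranteed positive semi-definite.**
  The kernel is symmetrized, the minimum eigenvalue is recorded per fold, and
  the ridge term absorbs small negative spectrum; if $(H + \lambda I)$ still
  approaches singularity the penalty floor is raised with a warning.
* **Missing traits** drop their subjects listwise per trait;
  `predict_traits()` rebuilds folds on the observed subset (families still
  unsplit) unless a shared partition is supplied, as the pipeline does.
* **Motion confounds** are removed from the trait by a linear fit estimated on
  training subjects only and applied to test subjects — the same CV-safe
  residualization used for structure.
* **Accuracy** is reported as squared Pearson correlation (the field's
  convention), with the signed correlation and mean-squared error alongside,
  since $r^2$ alone hides anti-correlated or biased predictions. Significance
  is a t-test of the correlation on $n - 2$ degrees of freedom over the pooled
  cross-validated predictions, Bonferroni-corrected across traits.

Deconfounding is cross-validated: the trait is predicted from the structural
distance matrix, and the out-of-sample residuals $y - \hat y_{CV}$ become the
deconfounded trait for the functional predictions. This is gentler and less
biased than in-sample regression: it removes only what structure can actually
predict, and noise traits pass through almost unchanged.

Representation comparisons within a behavioural group use the mean per-trait
difference in $r^2$ with a sign-flip permutation null (default 10,000 flips,
add-one-smoothed two-sided p). The group-level HMM can optionally be refit
inside every outer training fold (`hmm_scope = "fold"`, the conservative
default in `run_pipeline()`): the held-out subjects then never influence the
states they are embedded with. Because the HMM is fully unsupervised, fitting
once on the whole cohort (`"cohort"`) is also defensible and much cheaper; the
fold-isolation property of the `"fold"` path is asserted by test.

## Representation similarity and reproducibility

For each behavioural group, `prediction_similarity_matrix()` correlates the
out-of-sample prediction vectors of every pair of representations across
subjects and averages over the group's traits — two representations are
similar *with respect to behaviour* when they push the same subjects up and
down, whatever their internal parameterization. Constant (degenerate)
prediction vectors are dropped pairwise.

`bootstrap_compare_similarities()` resamples subjects with replacement,
recomputing the mean similarity of two sets of representation pairs; each set
gets its own independent resamples, so the two densities are estimated
independently and identical sets give $p \approx 0.5$ rather than a
degenerate tie. The bootstrap unit is subjects because the underlying
correlations are across subjects; trait-level resampling would treat the
trait battery, not the cohort, as the random quantity. The p-value is
one-sided for an a-priori direction, add-one smoothed.

`split_half_reproducibility()` correlates the upper triangles of two distance
matrices estimated on disjoint session subsets — day 1 vs day 2, or first vs
second session of each day.

## The synthetic cohort generator

`generate_cohort()` produces data with exactly the structure the analyses
assume: $K$ group states drawn as random correlation matrices (unit
variances, so the states differ purely in correlation — visible to the `"fc"`
variant, invisible to `"var"`); subject states perturbed on the matrix-log
scale (positive definiteness is free) and renormalized to correlation
matrices; subject transition matrices drawn row-wise from a Dirichlet around a
sticky group matrix; sessions sampled by Markov switching with Gaussian
emissions; family blocks; two measures of head motion; and low-rank
FA/MD/VBM-like structural features whose shared latent is partially coupled
(default 0.4) to the leading principal components of the subjects'
time-averaged FC — structure and time-averaged FC are deliberately not
independent, mirroring what is observed empirically.

Day-level drift is an *independent per-day* perturbation of both the states
(matrix-log scale, default SD 0.12 against a subject-effect SD of 0.25) and
the transition matrix (Dirichlet concentration four times the subject-level
concentration, i.e. half the subject-effect scale). Drawing the drift per day
— rather than marking one day as "drifted" — keeps the two days statistically
exchangeable, so split-half reproducibility probes drift rather than a
variance asymmetry between days.

Traits are standardized mixtures of four standardized components with designed
variance fractions: a projection of the time-averaged FC entries
(`f_static`); a projection of transition/occupancy features residualized at
the population level against the time-averaged FC principal components
(`f_dynamic` — uncorrelated with static FC and with structure by
construction); a projection of the observed structural feature matrices
(`f_struct`, optionally restricted to one measure via `struct_source`); and
Gaussian noise. An oracle regression on the true components recovers the
designed fractions within 0.05 at $N = 1000$. Motion contamination is added
on top of the fractions and defaults to zero; set `motion_loading > 0` to
exercise confound handling.

What the generator does **not** emulate: hemodynamics and autocorrelated
scanner noise (emissions are white within state), subject-specific spatial
maps (the parcellation is implicit and common), non-Gaussian trait
distributions, and any calibrated effect size linking dynamics to real
behavioural traits — those are unknown at the source. Passing tests on these
cohorts therefore demonstrate the *machinery* (identities, leakage control,
calibration, directional contrasts), not effect sizes in real data.

## Reference problem sizes

The test suite and `scripts/acceptance.R` run fixed desk-scale conditions,
chosen so each check completes in seconds to a few minutes: reconstruction
identity on $N=50$, $J=10$, $K=3$, $T=800$; state recovery on a two-state
correlation-switching series of $T=5000$; trait-source discrimination and
deconfounding on one $N=200$, $J=10$, $K=3$ cohort with source-pure traits;
test calibration over 500 null replicates; reproducibility on three replicate
$N=50$, $T=400$ drifting cohorts.

## Known limitations

* The KL-based HMM distance is an approximation; distances built purely from
  temporal or purely from spatial model components are out of scope.
* Kernel predictions carry one coefficient per subject, not per region, so no
  anatomical interpretability map falls out of the regression.
* On synthetic cohorts the reproducibility gap between the time-averaged FC
  and the state-model distance matrices is small and seed-dependent (both
  carry strong stable subject signal); the direction is asserted on averages
  over replicate cohorts, and single draws can invert it.
* Squared-Pearson accuracy ignores prediction bias; the reported `mse` and
  signed `r` are the diagnostics for that.
* Serialization uses delimited text and JSON only (sessions, distance
  matrices, traits as CSV; manifests as JSON).
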