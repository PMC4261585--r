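---
title: "Models and methods in mkrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mkrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkrates)
```

# The model

`mkrates` estimates evolutionary rates of discrete characters — gene-family
sizes, intron presence/absence, morphological states — on a fixed phylogeny
with branch lengths. Each character site evolves as a continuous-time
Markov chain over states $0, 1, \dots, a-1$ with generator $Q$. The chain
starts at the root from a prior $\pi$ and runs independently down every
branch; the probability of the observed tip states is computed by the
Felsenstein pruning algorithm and maximized over the model parameters with
the PORT routines (`stats::nlminb`), the same optimizer family used by the
original implementations of this class of analyses.

## Rate matrices

The off-diagonal structure of $Q$ is given by a *template*: an $a \times a$
integer grid tying cells to shared relative-rate parameters (0 marks a
structural zero). Presets:

* **ER** — all transitions share one rate.
* **SYM** — $q_{ij} = q_{ji}$, one rate per unordered pair.
* **ARD** — every directed rate free (irreversible).
* **BDER / BDSYM / BDISYM / BDARD** — birth-and-death ladders with
  non-zero entries only between neighbouring copy-number states
  ($n \to n \pm 1$). BDISYM gives the $0 \leftrightarrow 1$
  (innovation/loss) pair its own rate and ties all other rungs together;
  at $a = 2$ that second class is empty, so BDISYM requires $a \ge 3$ and
  the constructor points the user to BDSYM instead.
* **CUSTOM** — any user grid; structural zeros that disconnect states from
  the root prior's support raise a warning, not an error, because such
  models can still be meaningful for conditioned data.

The entry layout of the ladder models is a package convention: published
descriptions constrain them only through prose ("all entries except
$\alpha$ are equal"), which we read with $\alpha$ as the innovation/loss
pair — the interpretation under which BDISYM is the classical
birth-death-and-innovation model.

**Calibration.** Every assembled $Q$ is rescaled so that
$-\sum_i \pi_i q_{ii} = 1$. The branch-rate parameter $\mu$ then measures
the expected number of transition events per site per unit branch length.
We calibrate with the $\pi$ *currently in force* — uniform by default, the
estimated prior when `rootprobability = TRUE` — and recalibrate at every
optimizer step, so $\mu$ keeps its event-count interpretation under the
fitted model rather than under a reference model. The alternative (always
calibrating with the uniform prior) changes only the parameterization, not
the maximized likelihood.

**Identifiability.** After calibration only ratios of relative rates
matter, so the first template parameter is pinned to 1 whenever $\mu$ is
estimated; `n_params` counts the quantities actually free.

## Reversibility and the root

`reversible = TRUE` multiplies each template entry by the destination-state
prior, $q_{ij} = s_{ij}\pi_j$, which enforces detailed balance
$\pi_i q_{ij} = \pi_j q_{ji}$ for symmetric templates — exactly the GTR
construction, and `model = "GTR"` is expanded internally to
`SYM + reversible + rootprobability`. Reversible likelihoods are invariant
to the root position (the pulley principle); the test suite checks this to
$10^{-8}$. Irreversible configurations — asymmetric templates, or an
estimated prior without forced reversibility — are root-dependent, so an
unrooted input tree (basal polytomy) is first midpoint rooted, with a
message.

Midpoint rooting places the root halfway along the longest leaf-to-leaf
path. Two deterministic choices close gaps the definition leaves open: ties
among equally long paths go to the lexicographically smallest leaf-label
pair, and a midpoint falling exactly on an internal node makes that node
the root rather than inserting a zero-length branch. All leaf-to-leaf path
lengths are preserved to $10^{-12}$.

## Rate variation and branch categories

Among-site rate variation uses the discrete-Gamma approximation: $K$
equal-probability categories (default $K = 4$) of a mean-one
Gamma$(\alpha)$ distribution, each represented by its *conditional mean*
computed in closed form. Mean-based (rather than median-based) category
rates keep the category average exactly 1, so calibration is preserved for
every $\alpha$. The site likelihood is the equal-weight mixture over
categories. $\alpha$ is estimated on the log scale within
$[10^{-3}, 10^3]$; at the upper end the mixture is numerically identical
to the homogeneous model.

Branch-specific rates come from a `$`-labelled Newick dialect: a node
label suffix `$k` assigns the branch *above* that node to rate category
$k$, and one $\mu_c$ is estimated per category. Categories are relabelled
to contiguous `1..C` preserving numeric order. The published example
labels every branch; for partially labelled trees we default unlabelled
branches to category 1 with a warning — a package choice, since the
original tool's behaviour on such input is undocumented. On binary data,
note that $\mu$ and strongly skewed priors (and $\mu$ and small $\alpha$)
are partially confounded; the per-parameter estimates then sit on a ridge
even though the maximized likelihood is well determined.

## Correction for unobservable data

Gene families lost from every sampled genome are invisible: the data
acquisition itself conditions on the pattern being observable.
`zerocorrection = TRUE` divides each site likelihood by $1 - L_-$, where
$L_-$ is the likelihood of the single all-zero pattern (every taxon in
state 0). For multistate data only the *all-absent* pattern is treated as
unobservable; patterns that merely lack high copy numbers are observable.
Under the Gamma mixture, $L_-$ is mixed across categories *before* the
division, because dividing the mixed site likelihood by the mixed $1 -
L_-$ is what defines a proper conditional distribution over observable
patterns (the per-category alternative does not sum to one; the test suite
verifies the chosen form sums to one to $10^{-9}$ by enumeration).

# Numerical choices

* **Transition kernels.** $P(\nu) = e^{Q\nu}$, $\nu$ = branch length
  $\times$ $\mu_{\text{cat}}$ $\times$ Gamma rate. Reversible generators
  use the symmetrized eigendecomposition
  $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}(\pi)$), one decomposition
  reused for all branches; general generators use `eigen()` with the
  spectrum clamped to $\le 0$ and fall back to `Matrix::expm` when the
  eigenbasis is ill-conditioned. Entries are clipped to $[0, 1]$ and rows
  renormalized — rows of a true kernel sum to exactly 1, so this only
  removes round-off (and it matters: without renormalization, clipped
  rows can sum above 1 and inflate likelihoods at extreme $\mu$).
* **Underflow.** Pruning rescales every partial-likelihood row by its
  maximum and accumulates the log factors, so site log-likelihoods stay
  finite on large trees. A genuinely impossible pattern yields `-Inf`,
  which the optimizer treats as a rejected point.
* **Optimization.** Parameters are transformed — $\log \mu$,
  $\log$ relative rates, $\log \alpha$, additive-log-ratio for $\pi$ —
  and box-bounded: $\mu \in [10^{-8}, 10^4]$, rates $\in [10^{-6},
  10^6]$, $\alpha \in [10^{-3}, 10^3]$. The default start ($\mu = 1$,
  rates 1, uniform $\pi$, $\alpha = 1$) makes fits deterministic;
  `n_restarts` adds seeded jittered starts. Convergence uses a relative
  function tolerance of $10^{-9}$. Estimates at a bound are flagged
  (`at_bound`), e.g. $\hat\mu$ at the lower bound for an all-zero matrix
  without zero-correction.
* **Site patterns.** Identical columns are collapsed with multiplicity
  weights before any likelihood work; per-site fits share one
  optimization per unique column.

# The simulator and what green tests establish

`simulate_matrix()` draws, per site, a Gamma category, a root state from
$\pi$, and then each child state from the parent's row of $P(\nu)$ —
exact for tip data, with no event-level simulation. With
`condition_on_observable = TRUE` it rejection-samples all-zero patterns,
which targets exactly the conditional distribution assumed by the
zero-correction.

The generator emulates i.i.d. sites on a known tree under the fitted model
class. It does *not* emulate model misspecification, rate autocorrelation
along the sequence, branch-length error, lineage-specific alphabets, or
gene-family ascertainment beyond the all-zero rule. A green
parameter-recovery test therefore establishes internal consistency
(simulate–estimate round trip within Monte-Carlo error at 5000 sites),
not field validity on real gene-family tables. The published numerical
estimates for the Bacillaceae B1 clade are encoded in the acceptance
tests but require the journal's supplementary inputs, which are not
redistributable with the package; those tests report the missing inputs
and the same workflows run on a clearly labelled synthetic stand-in
clade.

# Known limitations

* Missing-data codes (`?`, `-`) are rejected, not marginalized.
* No ancestral-state reconstruction, stochastic mapping, model-search
  automation, or confidence intervals.
* Per-site Gamma estimation is permitted but weakly identified from one
  column and is flagged rather than forbidden.
* The `$` dialect is read-only input by design; written trees use `$`
  suffixes only when a branch is outside category 1, so plain trees
  round-trip as plain Newick.
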