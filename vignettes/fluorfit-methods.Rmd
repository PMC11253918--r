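---
title: "Estimating fluorosequencing error rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fluorosequencing error rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorfit)
```

## The problem

Single-molecule protein fluorosequencing reads out the positions of
fluorescently labeled amino acids in surface-immobilized peptides: specific
residue types (typically lysines or azido-lysines) are dye-labeled, the
peptides are imaged by TIRF microscopy, one N-terminal residue is removed
per Edman degradation cycle, and imaging is repeated. Each molecule yields a
*read* — a time series of fluorescence intensities, one value per color
channel per imaging step. Interpreting these reads, whether to benchmark the
chemistry or to classify reads against a peptide database, requires knowing
the error rates of the process.

`fluorfit` estimates six such rates from reads of a single known labeled
peptide:

| parameter | meaning | unit |
|---|---|---|
| `edman_failure` | an Edman cycle fails to remove the N-terminal residue | per cycle |
| `dye_loss` | a fluorophore is destroyed (chemical destruction and photobleaching combined) | per fluorophore per cycle, per channel |
| `detach` | the whole peptide leaves the surface; background signal thereafter | per cycle |
| `dud` | a label is dark or absent from the start ("missing fluorophore") | per fluorophore, per channel |
| `initial_block` | the N-terminus is chemically blocked before cycle 1, stopping Edman degradation | per molecule |
| `cyclic_block` | the N-terminus becomes blocked during a cycle | per cycle |

All six are probabilities. Dud and dye-loss rates are per-channel vectors;
the package broadcasts scalars.

## The generative model and its HMM

A molecule's state is summarized by the number of successful Edman cycles,
the number of surviving fluorophores on each channel, whether the N-terminus
is blocked, and whether the peptide has detached. Because same-channel
fluorophores are exchangeable, merging all configurations with equal counts
keeps the state space small (27 states for a two-label peptide over 10
cycles). Successful-cycle counting is capped at the last labeled position:
beyond it no fluorophore remains, so appending unlabeled C-terminal residues
provably cannot change any likelihood — the notation convention of ending
peptides at the last label with `|` is exact, not an approximation.

The transition matrix is never formed. It is the product of one sparse
factor per error type — detachment, per-channel dye loss, cyclic blocking,
Edman degradation, preceded (before the first image) by the dud and
initial-block factors. Each factor is row-stochastic; the Edman factor is
the identity on blocked and detached states. Emissions are normal per
channel: a state with $k$ fluorophores emits
$\mathcal{N}(\mu_{bg} + k\mu,\; k\sigma^2 + \sigma_{bg}^2)$ under the
default linear-variance rule (independent fluorophores), with a
constant-variance alternative selectable in the channel model. Observation 0
is imaged before any chemistry, so a run of $T$ cycles has $T+1$
observations.

The within-cycle factor order (detachment, dye loss, cyclic block, Edman) is
a package constant shared verbatim by the simulator and the HMM, so
simulation and inference agree by construction; order effects are
second-order in the small per-cycle rates.

## Fitter 1: modified Baum-Welch

The classical Baum-Welch algorithm re-estimates every transition probability
independently. Here the transitions are all functions of six rates, so the
M-step instead computes a weighted maximum likelihood estimate of each rate
directly. The factored transition matrix makes this natural: running the
forward-backward recursions across every sub-step yields, for each factor
application, the posterior flow through each sub-transition. For each rate
the flows give a weighted trial count $n$ and event count $x$ (for dye loss,
fluorophores at risk and fluorophores lost; for Edman failure, informative
attempts and no-advance mass; and so on), and the update is $x/n$, clamped
to $[10^{-9}, 1-10^{-9}]$ for numerical safety. Trials whose outcome is
unobservable (Edman attempts past the last label, or on molecules with no
surviving fluorophore) contribute posterior mass equal to the prior and so
cannot move the estimator; the implementation excludes the provably
uninformative ones.

**Censoring.** A molecule whose labels are all dud never appears as a read.
Fitting only observed reads therefore biases the dud rate low. With current
dud rates $d$, a molecule is invisible with probability
$x = \prod_{\text{labels}} d_{ch}$, and the expected number of censored
molecules behind $N$ observed reads is $m = N x/(1-x)$. Each EM iteration
adds $m$ phantom all-dud molecules to the dud statistics only — censored
molecules carry no information about any cycle-level rate. This is the
standard EM treatment of truncated count data, and the monitored quantity is
accordingly the *conditional* log-likelihood
$\sum_r \log P(\text{read}_r) - N\log(1-x)$, which is non-decreasing across
iterations; the fitter treats a decrease beyond $10^{-8}|\ell|$ as an
implementation fault and stops with an error rather than silently
continuing.

**Identifiability.** With a single label, dye loss and detachment are
visually identical, the dud rate is uninformable (no all-dud molecule is
ever seen), and the last-visible-cycle distribution
$\kappa_i = (1-b)\binom{i+r-1}{i}(1-e)^r e^i (1-c)^{r+i}$ depends on $e$ and
$c$ only through $e(1-c)$ — two blocking parameterizations with matched
$\kappa_0$ are exactly indistinguishable. One-label fits therefore fix
`detach`, `dud`, and `cyclic_block` at zero. The initial block rate stays
free: it is identified (given the $e(1-c)$ convention of $c = 0$) through
the overall never-advancing fraction, and one-label experimental datasets
report it.

Defaults: every free rate starts at 0.05; convergence is declared when the
largest parameter change falls below $10^{-5}$ (parameters, not likelihood,
are the deliverable); 250 iterations cap. None of these alters the fixed
point.

## Fitter 2: dye-track RMSE with trisection search and Powell refinement

The second, deliberately different estimator reduces every read to a *dye
track* — per observation and channel, the fluorophore count whose emission
density is highest at the observed intensity (ties to the smaller count) —
and tabulates the tracks into a histogram. A candidate rate vector is scored
by simulating molecules under the generative model, tabulating their tracks,
rescaling to the observed total, and taking the root-mean-square difference
of counts over the union of track keys.

Design choices that make this objective optimizable:

* **Common random numbers.** Each simulated molecule consumes a fixed
  layout of random draws regardless of outcomes, and the whole pool is
  drawn once per fit and reused by every evaluation. The objective is then
  a deterministic, piecewise-constant function of the rates with steps at
  the resolution of single molecules — effectively smooth at the scale the
  optimizer works on. A noisy objective would break the line searches.
* **Symmetric reduction noise.** The observed histogram carries count
  misassignments from emission noise (a count-1 intensity read as 0 or 2).
  Simulated tracks are therefore passed through the same emission model and
  the same density-argmax reduction before tabulation. We measured the
  asymmetric alternative (noise-free simulated tracks) to bias the initial
  block rate by about +1 percentage point at the default conditions, an
  order of magnitude above the estimator's statistical error, so the
  symmetric channel is the default (`sim_noise = FALSE` restores the
  truth-level comparison).
* **Censoring matched.** Simulation uses a fixed number of *attempted*
  molecules and keeps the observed ones, mirroring the censoring of the
  data; rescaling to the observed total absorbs the observability rate.
* `n_sim` defaults to five times the read count, making the simulation
  contribution to the objective's sampling error subdominant to the data's.

Optimization proceeds in two stages. A coordinate trisection search walks
over the box (default $[0, 0.5]$ per rate; widen the upper bound toward 1
for intentionally blocked peptides): along one dimension at a time it
evaluates two points symmetrically about the current center, keeps the best
of the three, halves the step, and cycles, returning the best point ever
evaluated. The refinement stage then runs line minimizations
(golden-section/parabolic, box-clipped) along the coordinate directions,
adding after each cycle a *pattern move* along the cycle's net displacement.
The pattern step matters: the objective has a narrow ridge coupling the two
blocking rates and the Edman failure rate, and we measured plain coordinate
descent stalling on it nearly a percentage point away from the optimum that
the same line searches reach when the ridge direction is available. Line
search results are accepted only when they improve the objective, so the
refinement is monotone by construction; started inside a local basin it
stays there, which is why the global stage runs first. Two further
safeguards address the valley's geometry. First, the refinement runs from
up to three well-separated low-objective candidates of the global stage and
keeps the lowest final objective (a standard multi-start safeguard; on one
in roughly six simulated datasets the single best candidate alone settles a
fraction of a percentage point away from the better basin). Second, a
valley-walk polish steps each coordinate of the solution by 1% of the box,
briefly re-optimizes the remaining parameters, and keeps going while the
objective floor drops — needed because descending the *curved* valley floor
yields per-cycle gains below any practical stopping tolerance, so line
searches alone can halt partway along it. What remains after these stages
is statistical: near the optimum the floor is flat enough that datasets of
40,000 reads leave the initial block rate determined only to a few tenths
of a percentage point, an intrinsic property of the count-histogram RMSE
criterion rather than of the optimizer (verified by confirming that
refinements started at the simulation truth reach the same objective
floor).

## Preprocessing

Emission parameters are estimated independently of the rate fit and held
constant. `estimate_mu_sigma()` histograms intensities (Freedman–Diaconis
bins), takes the dominant positive mode as $\mu$ (with parabolic sub-bin
refinement) and converts the half-width at half-maximum to $\sigma$ —
mode-based rather than least-squares because real intensity distributions
deviate from normality in their tails. The background spread is the median
of per-peak local background values supplied by the upstream image
processing. Expert overrides are always possible: every parameter can be
given verbatim. Likely contaminants are removed by intensity ranges: a read
is dropped if *any* of its values falls in an excluded half-open interval
$[lo, hi)$ for its channel (per-read, not per-value, matching how
contaminant signals invalidate a whole molecule). Filtering is idempotent.

## Bootstrap

Uncertainty comes from a nonparametric bootstrap: resample the observed
reads with replacement at the original size, refit, repeat (default 100
replicates), and report percentile intervals (default level 0.9; the level
is configurable and deliberately not BCa). Only observed reads are
resampled; the censoring correction runs inside every replicate. Replicate
seeds derive from the master seed by a counter scheme, so each replicate is
individually reproducible. Replicates warm-start at the full-data estimate —
for Baum-Welch as the EM initial point, for the RMSE fitter by skipping the
global stage and refining from the point estimate with `n_sim` equal to the
read count. Warm starting does not move either estimator's fixed point; it
only avoids re-paying the cold-start cost on every resample. One subtlety
is measured and accounted for: EM contracts slowly near its optimum, so a
loose stopping tolerance leaves each replicate a few multiples of the
tolerance short of its fixed point *toward the warm start*, which visibly
deflates the bootstrap spread (about 15% on the blocking rates at a
tolerance of $10^{-4}$). The replicate tolerance default of $2\times
10^{-5}$ keeps that residual an order of magnitude below the replicate
sampling spread. Bootstrap resamples are handled as per-read multiplicities,
which is mathematically identical to materializing duplicated reads.

## What the simulator does and does not emulate

The simulator draws molecules exactly under the six-parameter model with
Gaussian emissions and censoring of all-dud molecules — the same model the
HMM assumes. Passing the suite's recovery tests therefore demonstrates
correctness of the estimators *under the model*, not robustness to what real
data adds: contaminant reads, heavy-tailed intensity distributions,
cycle-to-cycle brightness drift, and residue-specific chemistry are absent
by design (the first two are addressed by preprocessing, the others are out
of scope). Conclusions about real data always require the preprocessing
step and should be cross-checked between the two fitters, which is the
package's reason for shipping both.

## Study conditions and problem sizes

The verification suite and the acceptance script use, as their standard
conditions: the two-label single-channel peptide `NH2-G{azK}*AG{azK}*|`, 10
Edman cycles, true rates `edman_failure = 0.06`, `dye_loss = 0.05`,
`detach = 0.05`, `dud = 0.07`, `initial_block = 0.04`,
`cyclic_block = 0.02` (the magnitudes reported for the chemistry: historic
Edman failure around 6%, dye loss and detachment a few percent, dud rates
up to ~20%), and a channel model with $\mu = 6000$, $\sigma = \sigma_{bg} =
750$ arbitrary units ($\mu/\sigma = 8$, comfortably above the
well-separated threshold of 5 while still producing the occasional count
misassignment real data shows). The headline recovery check runs at 40,000
reads with 100 bootstrap replicates per fitter; unit tests use 1,000–10,000
reads, and the dispersion-scaling check compares bootstrap interquartile
ranges at 1,000 versus 10,000 reads, where the $1/\sqrt{n}$ law predicts a
$\sqrt{10}$ ratio. The scaling law is asserted on the median ratio across
the six parameters: with 40 replicates an individual parameter's IQR ratio
still carries substantial sampling noise, while the median isolates the
systematic trend.

## Numerical choices

* Forward/backward recursions renormalize at every observation and
  accumulate the scale in log space; sub-step flow posteriors are
  normalized per sub-step. Factored and dense-matrix forwards agree to
  $10^{-12}$ on small instances; forward and backward likelihoods to
  $10^{-10}$.
* Rates are stored as probabilities, not logits; fitters clamp to
  $[10^{-9}, 1-10^{-9}]$.
* Emission support is never truncated or pruned: unlikely observations keep
  their exact (tiny) densities.
* Ties in the dye-track reduction go to the smaller count; intensity-range
  filters are half-open $[lo, hi)$; intensities are compared as given.
* Batch forward-backward accumulates per-read flow contributions in a fixed
  read order (pairwise within blocks of 64), so a fit is bit-reproducible
  for a given read order, and read order itself cannot change the stats
  beyond floating-point association.

## Known limitations

* The exact sub-transition order inside the authors' own tooling is
  unpublished; ours is internally consistent between simulator and HMM but
  cannot be verified against theirs.
* Per-cycle intensity drift is not modeled; applying one intensity model
  across all cycles can bias fits on drifting data.
* The RMSE fitter's statistical efficiency for the initial block rate is
  several-fold worse than the likelihood-based fitter's — visible in its
  wider bootstrap distributions — which matches its role as an independent
  cross-check rather than the primary estimator.
* Multi-peptide mixtures and joint emission-parameter fitting are out of
  scope; the channel model is held fixed during rate fitting.

## A worked example

```{r example, eval = FALSE}
peptide <- parse_peptide("NH2-G{azK}*AG{azK}*|")
truth <- error_model(edman_failure = 0.06, dye_loss = 0.05, detach = 0.05,
                     dud = 0.07, initial_block = 0.04, cyclic_block = 0.02)
channels <- channel_model(mu = 6000, sigma = 750, bg_sigma = 750)

reads <- simulate_reads(peptide, truth, channels, n_reads = 10000,
                        n_cycles = 10, seed = 1)
fit <- fit_baum_welch(reads, peptide, channels)
fit
boot <- bootstrap_error_model(reads, peptide, channels, method = "bw",
                              n_boot = 100, seed = 2)
boot
```
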