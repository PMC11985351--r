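---
title: "Inferring ancestral population structure from a single diploid genome"
author: "ghostpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral population structure from a single diploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostpulse)
```

## The model

ghostpulse fits a *pulse model* of ancestral population structure to the
pattern of heterozygosity along one unphased diploid genome. Looking
backward in time from the present, the sampled population A is panmictic
until the admixture time $T_1$, at which a fraction $\gamma$ of lineages
instantaneously derive from a second, unsampled ("ghost") population B.
A and B remain in complete isolation until the split time $T_2$, when both
merge into the common ancestral population. The free parameters are the
piecewise-constant scaled sizes $n_A(t)$ of A (which continue above $T_2$
as the ancestral size), the constant scaled size $n_B$ of B on $[T_1,
T_2)$, the pulse fraction $\gamma \in [0, 1]$, and the per-window scaled
recombination rate $\rho$; $T_1$ and $T_2$ are fixed within a run and
searched over a grid (`grid_scan()` / `cml_select()`).

All times are measured in units of $2 N_\mathrm{ref}$ generations and sizes
relative to $N_\mathrm{ref}$, where $N_\mathrm{ref}$ is set by the scaled
mutation rate per window, $\theta = 4 N_\mathrm{ref}\, \mu\, b$ for bin
size $b$. At the human-like default ($\mu = 1.25\times 10^{-8}$ per bp per
generation, $b = 100$), $\theta = 0.08$ corresponds to $N_\mathrm{ref} =
16{,}000$ diploids; note that the conventional *per-site* scaled rate is
$\theta / b = 8\times10^{-4}$. `scaled_time_to_years()` and relatives
convert for reporting (default generation time 29 y).

### The hidden Markov model

As in the classic pairwise sequentially Markovian coalescent (SMC)
framework, the genome is cut into windows of $b$ bases, each labelled K
(contains a heterozygous site), T (homozygous) or N (missing), and the
hidden state of a window is its discretized time to most recent common
ancestor (TMRCA). Emissions are $P(K \mid t) = 1 - e^{-\theta\,
\bar t_\beta}$ with $\bar t_\beta$ the conditional mean TMRCA within
interval $\beta$ under the current model; N windows contribute no emission
factor, and contig breaks restart the chain at the marginal TMRCA
distribution (which is stationary under the transition kernel by
construction).

The scientific content of the method is in the transition kernel. Given a
recombination event on a branch of the current genealogy at position $u
\sim \mathrm{Uniform}(0, t)$, the detached lineage re-coalesces with the
surviving lineage at rate $1/n_A(s)$ while both are in A, $1/n_B$ while
both are in B, zero while they are in different demes, and $1/n_A(s)$
unconditionally beyond $T_2$; a floating lineage crossing $T_1$ backward
migrates to B with probability $\gamma$. Within each stratum of the
breakpoint position ($u < T_1$, $T_1 \le u < T_2$, $u \ge T_2$) and
conditional on the discrete migration choices, the re-coalescence rate
trajectory is piecewise constant on the grid intervals and independent of
$u$, so both the $u$-integral and the re-coalescence integral have closed
forms; the kernel is computed exactly (no quadrature), row-normalized, and
validated against an independent Monte-Carlo event simulation
(`mc_transition_oracle()`), which shares no code path with the closed
form.

Setting $\gamma = 0$ makes every quantity — profile, kernel, likelihood —
identical to the panmictic model, which is therefore exactly nested.

### Identifiability

For any structured model there is a panmictic model with an identical
pairwise coalescence-rate profile (`matched_unstructured()`: sizes set to
the inverse hazard at the interval midpoints of the target grid, evaluated
from the closed-form marginal profile rather than via an intermediate fine
grid). The two nevertheless differ in the *conditional* distribution of
neighboring TMRCAs; `xi_relative_difference()` computes the relative
difference $\xi = (Q^U - Q^S)/Q^S$ of the two conditional kernels, which
is clearly nonzero for, e.g., a constant-size pair with $\gamma = 0.3$,
grows with $\gamma$ and with $T_2 - T_1$, and does not shrink under grid
refinement. This is the information the HMM exploits.

## Fitting

`em_fit()` runs Baum–Welch: a scaled forward–backward E-step (compiled)
and a numerical M-step maximizing the expected complete-data
log-likelihood over transformed free parameters (log sizes, logit
$\gamma$, log $\rho$) with box constraints (sizes in $[10^{-3}, 10^3]$
relative, L-BFGS-B). Because transitions are nonlinear in the parameters
there is no closed-form M-step; any improvement of the Q-function
suffices (generalized EM), so the inner optimizer is capped
(`m_step_maxit`, default 20). Representative times $\bar t_\beta$ are
refreshed from the current model once per EM iteration and held fixed
during the M-step; on the rare occasion that this refresh lowers the
likelihood, the previous parameters are restored and the fit is flagged
(`$fallback`), so the recorded trajectory is non-decreasing. Convergence
is declared when the change in total log-likelihood drops below `psi_tol`
(default 1, a convenient threshold that is comparable across models; use
0.1 for stricter runs).

**Initialization matters.** The default start is flat sizes, $\gamma =
0.1$ and $\rho = \theta/4$. When $\rho$ starts far from its true value the
likelihood becomes extremely flat in $\gamma$ and EM can converge, under
the `psi_tol` rule, onto a near-panmictic ridge even when the data are
strongly structured. The protocol used throughout the package's own
studies is therefore two-stage: fit the nested unstructured model first,
warm-start $\rho$ (and optionally the sizes) from it, and run the
structured fit from a small set of $\gamma$ starting values
(`gamma_starts`), keeping the best final likelihood. This is ordinary
multi-start maximum likelihood, not a data-dependent tuning of the model.

Model choice between the structured fit and the nested panmictic fit uses
`model_compare()`: $\Delta_\mathcal{L} = \mathcal{L}_S - \mathcal{L}_U$
and AIC with $k_U = n_\mathrm{free} + 1$ and $k_S = n_\mathrm{free} + 5$
parameters (33 and 37 at the standard 32 size groups: the four extra
structured parameters are $\gamma$, $n_B$, $T_1$ and $T_2$).

## Decoding ancestry paths

`decode_paths()` augments the hidden state with the lineage-path label
$c \in \{AA, BB, AB\}$: which demes the two sampled lineages occupied
during $[T_1, T_2)$. Legality follows from the model: $c = AA$ below
$T_1$; $AA$ or $BB$ (demes must match to coalesce) in the structured
period; all three above $T_2$. Emissions depend on $t$ only.

Two constructions of the augmented transitions are provided. By default
the old window's path label does not enter the transition — the surviving
pair's demes are drawn from their posterior given the old coalescence time
— so the time-marginal of the augmented chain reproduces the time-only HMM
*exactly* (likelihood and posteriors; asserted to $10^{-6}$ in the tests)
and path information accumulates purely through persistence between
recombination events. With `condition_on_path = TRUE` the explicit label
fixes the surviving demes — the full generative conditioning, validated
against a path-labelled Monte-Carlo oracle — at the cost of exact
marginalization consistency, since the label then carries information
across recombination events. The default follows the construction in
which the path state is a read-out rather than a dynamical input; the
difference between the two is small in practice (a few log-likelihood
units per $10^5$ windows in the regimes examined here).

The migration-choice prior over paths is $(1-\gamma)^2$, $\gamma^2$,
$2\gamma(1-\gamma)$ (`path_choice_prior()`); at $\gamma = 0.2$ a
homozygous-B path has prior probability $0.04$, which is why confident BB
assignments are rare. Note that *conditioning on the coalescence time*
reweights these by survival through the structured period — the
conditional $P(c = BB \mid t \ge T_2)$ equals $\gamma^2$ only when
structured-period coalescence is negligible; the package's prior function
reports the migration-choice prior.

Downstream statistics: the cross-sample admixture density
$$H(x) = \frac{\sum_j P(c_x^j = BB,\, t_x^j > T_1 \mid X^j) +
\tfrac12 P(c_x^j = AB,\, t_x^j > T_1 \mid X^j)}
{\sum_j P(t_x^j > T_1 \mid X^j)}$$
evaluated every 1 kb by default (`h_statistic()`; the stride samples the
window containing each position, and positions where every sample is
missing are flagged uncallable); the windowed A-ancestry fraction
$\overline{P(AA) + P(AB)/2}$ (`ancestry_fraction_windows()`); and a
gene-overlap tail test (`enrichment_test()`): the top or bottom
`pct` of callable positions by $H$ (exactly `round(n * pct)` of them, ties
broken by $H$ then coordinate) are intersected with intervals in
closed-open coordinates, and significance is the two-sided exact binomial
test in the minimum-likelihood convention (`binom.test`), with the
background hit probability either estimated from all callable positions or
supplied.

## The simulator

`simulate_sequence()` draws hidden (time, path) states and K/T symbols
from the discretized path-augmented HMM itself, so parameter-recovery and
decoding tests are free of discretization mismatch by design;
`sample_coalescence_times()` draws continuous-time TMRCAs by direct event
simulation of the backward process, so discretization error is measurable
independently. What the simulator deliberately does *not* emulate:
mutation- and recombination-rate heterogeneity along the genome, linked
selection, genotyping error, and the correlation structure of real
callability masks. Passing recovery tests therefore demonstrates
correctness of the inference machinery under the model, not robustness to
those violations on real data.

`scenario_presets()` fixes the study conditions used across the package's
tests and the acceptance script, all at the human-like scale
($N_\mathrm{ref} = 16{,}000$, $\mu = 1.25\times10^{-8}$, $r = 10^{-8}$,
$b = 100$, generation time 29 y, admixture 300 ka, split 1.5 Ma):
`"gamma-recovery"` (constant sizes, $\gamma = 0.3$), `"matched-constant"`
and `"paired-panmictic"` (the structured model plus its rate-matched
panmictic twin), and `"bottleneck"` ($n_A$ reduced to $0.25$ between 40
and 300 ka — the depth of the bottleneck is the package's own choice, as
only the bottleneck's presence and interval are prescribed by the study
design).

## Numerical choices and problem sizes

* Time grid: $t_i = 0.1\,(\exp((i/n)\log(1 + 10\,t_\mathrm{max})) - 1)$,
  $i = 0..n{-}1$, final interval open-ended; `t_max` defaults to 15
  coalescent units. $T_1$ and $T_2$ snap onto (and replace) the nearest
  interior boundaries (`snap_times()`).
* Representative times: conditional mean TMRCA per interval (closed form
  from the piecewise-exponential mixture), midpoint fallback where the
  interval mass underflows; `representative = "midpoint"` is available
  throughout.
* The transition kernel is exact (closed-form $u$- and re-coalescence
  integrals, all exponentials of non-positive argument for stability);
  rows are renormalized and asserted to sum to 1 within $10^{-10}$.
* Degenerate inputs: posterior weights over path components are computed
  in log space, so survival underflow deep in the tail cannot produce
  0/0; `matched_unstructured()` truncates the grid with a warning if
  survival underflows entirely.
* Ties in `cml_select()` break toward smaller $T_2$, then larger $T_1$
  (the most conservative structured period), and are reported.
* Simulation studies in the tests and the acceptance script use 16
  atomic intervals and $10^6$ windows (100 Mb at $b = 100$) for the
  recovery and discrimination studies, $10^5$–$3\times10^5$ windows for
  decoding properties, and $10^6$ Monte-Carlo draws for oracle
  comparisons; these sizes give standard errors comfortably inside the
  asserted bounds while keeping each study to minutes on one core.

## Known limitations

* Exactly one pulse and one ghost deme; no continuous migration,
  time-varying $\gamma$, or more than two ancestral populations.
* $n_B$ is constant by default (the relaxed per-interval mode is exposed
  but known to be weakly identified against $n_A(t)$).
* SMC rather than SMC' transitions (no back-coalescence correction).
* Single unphased diploid; no site-frequency-spectrum information.
* The $\psi_\mathcal{L} < 1$ stopping rule can terminate on flat ridges;
  use the two-stage warm-start protocol above (and, for real data, a
  $(T_1, T_2)$ scan with `grid_scan()`) rather than a single cold run.
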