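# ghostpulse

Inference of deep ancestral population structure — a split-and-rejoin
"pulse" of ghost admixture — from a **single unphased diploid genome**,
using a structured-coalescent hidden Markov model.

## The problem

The pairwise coalescence rate along one diploid genome is the classic
signal for reconstructing effective population size history (the PSMC
family of methods). But that signal is fundamentally ambiguous: for any
structured history there is a panmictic history with size changes that
produces *exactly the same* coalescence rate profile, so rate-based
inference cannot tell ancient population structure from population size
change. ghostpulse exploits the information that survives this
ambiguity: the **conditional distribution of neighboring coalescence
times** — the transition matrix of the sequentially Markovian coalescent
(SMC) — differs between a structured model and its rate-matched panmictic
twin.

The model: backward in time, the sampled population A is panmictic until
an admixture time `T1`, where a fraction `gamma` of lineages derive from
an isolated ghost population B (constant size `n_B`); A and B merge into
the common ancestor at the split time `T2`. Free parameters are the
piecewise size history `n_A(t)`, `n_B`, `gamma` and the recombination
rate `rho`, fitted by Baum–Welch EM at fixed `(T1, T2)`; candidate time
pairs are scanned and combined across samples by composite maximum
likelihood. Setting `gamma = 0` recovers the panmictic model exactly, so
the two are nested and comparable by log-likelihood difference
`delta_L = L_S - L_U` and AIC.

A path-augmented HMM decodes, per window, the posterior probability that
the local ancestry path went through B (labels `AA`/`AB`/`BB`), yielding
admixture tracks, the cross-sample admixture density `H(x)`, and
gene-overlap enrichment tests of its tails.

## What is in the package

| area | functions |
|---|---|
| demography | `build_time_grid`, `snap_times`, `structured_demography`, `unstructured_demography`, `marginal_coalescence_profile`, `matched_unstructured` |
| SMC kernels | `conditional_transition_matrix`, `hmm_transition`, `xi_relative_difference`, `mc_transition_oracle` |
| inference | `emission_matrix`, `forward_backward`, `log_likelihood`, `em_fit` |
| time scans | `grid_scan`, `cml_select`, `model_compare` |
| ancestry decoding | `path_state_space`, `path_transition_emission`, `decode_paths`, `h_statistic`, `ancestry_fraction_windows`, `enrichment_test`, `binomial_enrichment` |
| simulation | `simulate_sequence`, `sample_coalescence_times`, `scenario_presets` |
| io | `read_bins`/`write_bins` (psmcfa-style), `vcf_to_bins`, `read_bed_mask`, `read_gene_intervals`, `export_results`, `write_model_json`/`read_model_json` |

A thin command-line front end (`inst/cli/ghostpulse`, subcommands
`infer`, `scan`, `decode`, `hstat`, `enrich`, `simulate`, `vcf2bins`)
wraps these functions for shell pipelines.

## Worked example

Simulate 20 Mb from a structured history (two demes of 16,000 diploids,
admixture 300 ka, split 1.5 Ma, `gamma = 0.3`, human-like mutation and
recombination rates) and re-estimate the admixture fraction with sizes
and times held at their true values:

```r
library(ghostpulse)

pre <- scenario_presets("gamma-recovery", gamma = 0.3, n_intervals = 16)
sim <- simulate_sequence(pre$model, 2e5, seed = 15)   # 2e5 windows of 100 bp
init <- pre$model
init$gamma <- 0.1                                      # start away from truth
fit <- em_fit(sim$obs, init, free = "gamma")
round(fit$model$gamma, 3)
#> [1] 0.242
fit$converged
#> [1] TRUE
```

The estimate 0.242 recovers the simulated pulse fraction 0.30 to within
the sampling noise of 20 Mb; admixture fractions are systematically
somewhat underestimated at moderate sequence lengths (at the 100 Mb scale
used by `scripts/acceptance.R`, the same protocol returns 29.4% for seed
1). Decoding the same data and averaging the admixture density:

```r
post <- decode_paths(sim$obs, pre$model)
trk  <- h_statistic(list(post), stride = 1000)
round(mean(trk$H, na.rm = TRUE), 3)
#> [1] 0.266
```

Genome-wide `H(x)` sits near `gamma`, as it should: it estimates the
expected local fraction of ancestry drawn from the ghost deme B among
lineages that coalesce before the admixture event.

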