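#' Simulate a binned observation sequence with recorded truth
#'
#' Sequentially simulates hidden states and K/T symbols from the
#' discretized HMM itself: the first state is drawn from the model's
#' marginal (time, path) prior, subsequent states from the path-augmented
#' per-window transition matrix (time-only for unstructured models), and
#' symbols from the emission model. Because the simulator and the inference
#' engine share the same discretization, parameter-recovery tests are free
#' of discretization mismatch; [sample_coalescence_times()] provides the
#' complementary continuous-time event simulation.
#'
#' @param model structured or unstructured demography.
#' @param n_windows number of windows to simulate.
#' @param seed integer RNG seed; the output is fully reproducible.
#' @param missing_prob per-window probability of masking the symbol to N
#'   (truth retained); default 0.
#' @param representative row-conditioning rule.
#' @param condition_on_path path-transition construction, see
#'   [path_transition_emission()]; the default matches the inference model
#'   exactly, so recovery tests are free of model mismatch.
#' @return list with `obs` (an [obs_sequence()]) and `truth` (class
#'   `simulation_truth`: per-window hidden interval `t_index`, `path`
#'   label, `model`, `seed`).
#' @export
simulate_sequence <- function(model, n_windows, seed = 1, missing_prob = 0,
                              representative = c("cond_mean", "midpoint"),
                              condition_on_path = FALSE) {
  stopifnot(inherits(model, "demography"), n_windows >= 1)
  representative <- match.arg(representative)
  set.seed(seed)
  if (inherits(model, "structured_demography")) {
    pte <- path_transition_emission(model, representative, condition_on_path)
    sim <- .sim_chain(pte$a, pte$emit[, "K"], pte$initial, n_windows)
    t_index <- pte$space$interval[sim$states]
    path <- pte$space$path[sim$states]
  } else {
    tb <- representative_times(model, representative)
    cond <- .cond_matrix_at(model, tb)
    ht <- .hmm_pieces(model, cond, tb)
    sim <- .sim_chain(ht$a, emission_matrix(model, tb)[, "K"], ht$initial,
                      n_windows)
    t_index <- sim$states
    path <- rep("AA", n_windows)
  }
  symbols <- sim$symbols
  if (missing_prob > 0) {
    symbols[stats::runif(n_windows) < missing_prob] <- 3L
  }
  truth <- structure(
    list(t_index = t_index, path = path, model = model, seed = seed),
    class = "simulation_truth"
  )
  list(obs = obs_sequence(symbols, bin_size = 100), truth = truth)
}

#' Continuous-time draws of pairwise coalescence times and paths
#'
#' Direct event simulation of the backward generative process (not the
#' discretized transition matrix): two lineages start in A, coalesce at rate
#' `1/n_A(s)`; uncoalesced pairs draw a lineage-path choice at `T1`
#' (AA/BB/AB with the migration prior), coalesce during the structured
#' period at the path's rate (0 for AB), and merge at `T2`. Used as the
#' independent Monte-Carlo oracle for the analytic marginal profile.
#'
#' @param model structured or unstructured demography.
#' @param n number of independent draws.
#' @param seed integer RNG seed.
#' @return data frame with columns `t` (coalescent units) and `path`
#'   (`"AA"` for coalescence before `T1` and for unstructured models).
#' @export
sample_coalescence_times <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "demography"), n >= 1)
  set.seed(seed)
  b <- model$grid$boundaries
  ni <- model$grid$n_intervals
  race <- function(start_j, cur, rates, alive_idx, res) {
    # segment-wise exponential race from boundary index start_j
    cur_j <- rep(start_j, length(alive_idx))
    alive <- rep(TRUE, length(alive_idx))
    while (any(alive)) {
      ii <- which(alive)
      lj <- rates[cur_j[ii]]
      dt <- stats::rexp(length(ii)) / lj
      hit <- (cur[ii] + dt) < b[cur_j[ii] + 1L]
      res[alive_idx[ii][hit]] <- cur[ii][hit] + dt[hit]
      alive[ii[hit]] <- FALSE
      adv <- ii[!hit]
      done <- adv[cur_j[adv] + 1L > ni]
      if (length(done)) {
        # only possible when a zero-rate tail exists; flag unresolved
        res[alive_idx[done]] <- Inf
        alive[done] <- FALSE
        adv <- setdiff(adv, done)
      }
      cur[adv] <- b[cur_j[adv] + 1L]
      cur_j[adv] <- cur_j[adv] + 1L
    }
    res
  }
  if (inherits(model, "unstructured_demography")) {
    t <- race(1L, rep(0, n), 1 / model$n, seq_len(n), numeric(n))
    return(data.frame(t = t, path = rep("AA", n)))
  }
  i1 <- model$T1_index; i2 <- model$T2_index
  T1 <- b[i1]
  t <- rep(NA_real_, n)
  path <- rep(NA_character_, n)
  # phase 1: both in A until T1
  rA <- 1 / model$n_A
  t1draw <- race(1L, rep(0, n), ifelse(seq_len(ni) >= i1, 0, rA),
                 seq_len(n), numeric(n))
  # zero rate beyond T1 in phase 1 => Inf marks survival to T1
  pre <- is.finite(t1draw)
  t[pre] <- t1draw[pre]
  path[pre] <- "AA"
  surv <- which(!pre)
  if (length(surv)) {
    pr <- path_choice_prior(model$gamma)
    cl <- names(pr)[sample.int(3L, length(surv), replace = TRUE, prob = pr)]
    path[surv] <- cl
    struct <- seq(i1, i2 - 1L)
    for (lab in c("AA", "BB", "AB")) {
      sel <- surv[cl == lab]
      if (!length(sel)) next
      rates <- rA
      rates[seq_len(i1 - 1L)] <- 0  # not reachable, defensive
      if (lab == "BB") rates[struct] <- 1 / model$n_B
      if (lab == "AB") rates[struct] <- 0
      t[sel] <- race(i1, rep(T1, length(sel)), rates, sel, t)[sel]
    }
  }
  data.frame(t = t, path = path)
}

#' Ready-made simulation scenarios
#'
#' Named presets reproducing the package's standard study conditions, all
#' on the human-like scale `N_ref = 16000` diploids: per-window
#' `theta = 0.08` (per-site `4*N*mu = 0.0008` at `mu = 1.25e-8`, `b = 100`)
#' and `rho = 0.064` (`r = 1e-8`), generation time 29 years:
#'
#' * `"matched-constant"`: constant-size structured model (`n_A = n_B = 1`,
#'   `gamma = 0.3`, admixture 300 ka, split 1.5 Ma) plus the rate-matched
#'   unstructured model on the same grid - the canonical identifiability
#'   pair whose transition matrices differ while their coalescence rate
#'   profiles agree.
#' * `"gamma-recovery"`: the same constant-size structured model with
#'   `gamma` (default 0.3) free to vary; the admixture-fraction recovery
#'   benchmark.
#' * `"bottleneck"`: as above plus a bottleneck in A (`n_A = 0.25`) between
#'   40 and 300 ka, the regime where panmictic inference reports a spurious
#'   size peak.
#' * `"paired-panmictic"`: the `"gamma-recovery"` structured model and its
#'   rate-matched panmictic twin, for likelihood-difference power studies.
#'
#' @param name preset name.
#' @param gamma admixture fraction for presets that accept one.
#' @param T1_years,T2_years admixture and split times in years.
#' @param n_intervals,t_max grid resolution.
#' @return list with the `model` (and `matched` unstructured model where
#'   applicable), plus `theta`, `rho`, `mu`, `gen_time`, `bin_size`.
#' @export
scenario_presets <- function(name = c("matched-constant", "gamma-recovery",
                                      "bottleneck", "paired-panmictic"),
                             gamma = 0.3, T1_years = 3e5, T2_years = 1.5e6,
                             n_intervals = 32, t_max = 15) {
  name <- match.arg(name)
  theta <- 0.08; rho <- 0.064; mu <- 1.25e-8; gen_time <- 29; b <- 100
  grid0 <- build_time_grid(n_intervals, t_max)
  T1 <- years_to_scaled_time(T1_years, theta, mu, b, gen_time)
  T2 <- years_to_scaled_time(T2_years, theta, mu, b, gen_time)
  sn <- snap_times(grid0, T1, T2)
  base <- function(n_A) {
    structured_demography(sn$grid, n_A = n_A, n_B = 1, gamma = gamma,
                          T1_index = sn$T1_index, T2_index = sn$T2_index,
                          theta = theta, rho = rho)
  }
  out <- list(theta = theta, rho = rho, mu = mu, gen_time = gen_time,
              bin_size = b)
  if (name == "bottleneck") {
    bd <- sn$grid$boundaries
    lo <- years_to_scaled_time(4e4, theta, mu, b, gen_time)
    mid <- interval_midpoints(sn$grid)
    n_A <- ifelse(mid >= lo & mid < T1, 0.25, 1)
    out$model <- base(n_A)
  } else {
    out$model <- base(1)
  }
  if (name %in% c("matched-constant", "paired-panmictic")) {
    out$matched <- matched_unstructured(out$model)
  }
  out
}
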