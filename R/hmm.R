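#' Binned observation sequence
#'
#' A per-window symbol sequence over the alphabet K (window contains at
#' least one heterozygous site), T (homozygous window), N (missing /
#' uncallable window), with optional contig breaks at which the HMM chain
#' restarts from its initial distribution.
#'
#' @param symbols character vector of `"K"`/`"T"`/`"N"` (or the integer
#'   codes 1/2/3).
#' @param bin_size bases per window (default 100).
#' @param seg_starts 1-based window indices at which a new contig starts;
#'   must begin with 1.
#' @param contig_names optional names, one per segment.
#' @return object of class `obs_sequence`.
#' @export
obs_sequence <- function(symbols, bin_size = 100, seg_starts = 1L,
                         contig_names = NULL) {
  if (is.character(symbols)) {
    sym <- match(symbols, c("K", "T", "N"))
    if (anyNA(sym)) {
      bad <- which(is.na(sym))[1]
      stop(sprintf("illegal symbol '%s' at window %d", symbols[bad], bad),
           call. = FALSE)
    }
  } else {
    sym <- as.integer(symbols)
    if (any(sym < 1L | sym > 3L)) stop("integer symbols must be 1 (K), 2 (T) or 3 (N)")
  }
  seg_starts <- sort(unique(as.integer(seg_starts)))
  stopifnot(length(sym) >= 1L, seg_starts[1] == 1L,
            all(seg_starts >= 1L & seg_starts <= length(sym)))
  if (!is.null(contig_names)) stopifnot(length(contig_names) == length(seg_starts))
  structure(
    list(symbols = sym, bin_size = as.integer(bin_size),
         seg_starts = seg_starts, contig_names = contig_names),
    class = "obs_sequence"
  )
}

#' @export
print.obs_sequence <- function(x, ...) {
  tab <- tabulate(x$symbols, 3L)
  cat(sprintf(
    "<obs_sequence> %d windows of %d bp (%d contigs): K=%d T=%d N=%d\n",
    length(x$symbols), x$bin_size, length(x$seg_starts),
    tab[1], tab[2], tab[3]
  ))
  invisible(x)
}

#' @export
length.obs_sequence <- function(x) length(x$symbols)

symbols_as_character <- function(obs) c("K", "T", "N")[obs$symbols]

#' Emission probabilities per coalescence-time interval
#'
#' The probability that a `b`-base window contains at least one heterozygous
#' site given its TMRCA interval: `P(K | beta) = 1 - exp(-theta * t_bar)`,
#' `P(T | beta) = exp(-theta * t_bar)` with `t_bar` the interval
#' representative time; missing windows are uninformative
#' (`P(N | beta) = 1`, handled as a skip emission).
#'
#' @param model a demography (supplies `theta` and the grid).
#' @param t_bar representative times (default: conditional mean TMRCA per
#'   interval under `model`).
#' @return n x 3 matrix with columns `K`, `T`, `N`.
#' @export
emission_matrix <- function(model, t_bar = representative_times(model)) {
  pK <- -expm1(-model$theta * t_bar)
  cbind(K = pK, T = 1 - pK, N = rep(1, length(pK)))
}

#' Scaled forward-backward algorithm
#'
#' Numerically stable (per-window scaled) forward-backward over an
#' observation sequence; contig breaks restart the chain at the initial
#' distribution; missing windows contribute no emission factor.
#'
#' @param obs an [obs_sequence()].
#' @param trans an [hmm_transition()] (or any list with `a` and `initial`).
#' @param emit emission matrix as from [emission_matrix()].
#' @param want_posterior return the per-window posterior matrix (may be
#'   large: `n_states x n_windows`).
#' @param want_counts return Baum-Welch expected transition / emission /
#'   initial-state counts.
#' @return list with `loglik`, and optionally `posterior`, `trans_counts`,
#'   `emit_counts`, `init_counts`.
#' @export
forward_backward <- function(obs, trans, emit, want_posterior = TRUE,
                             want_counts = TRUE) {
  stopifnot(inherits(obs, "obs_sequence"))
  .fb_core(obs$symbols, trans$a, emit, trans$initial, obs$seg_starts,
           want_posterior, want_counts)
}

#' Forward log-likelihood of a model
#'
#' Runs the forward algorithm only (no parameter updates); usable on
#' held-out data for train/test comparisons.
#'
#' @inheritParams forward_backward
#' @param model a structured or unstructured demography.
#' @param representative row-conditioning time rule.
#' @return the log-likelihood (an all-missing sequence gives 0).
#' @export
log_likelihood <- function(obs, model,
                           representative = c("cond_mean", "midpoint")) {
  representative <- match.arg(representative)
  stopifnot(inherits(obs, "obs_sequence"), inherits(model, "demography"))
  tb <- representative_times(model, representative)
  cond <- .cond_matrix_at(model, tb)
  ht <- .hmm_pieces(model, cond, tb)
  .forward_loglik(obs$symbols, ht$a, emission_matrix(model, tb), ht$initial,
                  obs$seg_starts)
}

# conditional kernel rows at externally supplied representative times
# (used by the M-step, which freezes t_bar while parameters move).
# Compiled hot path; .cond_matrix_at_r is the R reference (cross-checked in
# the test suite).
.cond_matrix_at <- function(model, t_bar) {
  if (inherits(model, "structured_demography")) {
    n_struct <- model$T2_index - model$T1_index
    .marginal_kernel_cpp(model$grid$boundaries, 1 / model$n_A,
                         rep(1 / model$n_B, length.out = n_struct),
                         model$gamma, model$T1_index, model$T2_index, t_bar)
  } else {
    .marginal_kernel_cpp(model$grid$boundaries, 1 / model$n, numeric(0),
                         0, 0L, 0L, t_bar)
  }
}

.cond_matrix_at_r <- function(model, t_bar) {
  n <- model$grid$n_intervals
  q <- matrix(0, n, n)
  for (beta in seq_len(n)) q[beta, ] <- .marginal_kernel_row(model, t_bar[beta])
  q / rowSums(q)
}

.hmm_pieces <- function(model, q, t_bar) {
  p_rec <- -expm1(-model$rho * t_bar)
  a <- diag(1 - p_rec) + p_rec * q
  initial <- colSums(interval_masses(model))
  list(a = a, initial = initial / sum(initial), p_rec = p_rec)
}

# ---------------------------------------------------------------------------
# Baum-Welch EM

# pack/unpack free parameters on transformed scales (log sizes, logit gamma,
# log rho) with box constraints.
.param_spec <- function(model, free, size_bounds, rho_bounds) {
  structured <- inherits(model, "structured_demography")
  par <- numeric(0); lower <- numeric(0); upper <- numeric(0); tags <- list()
  push <- function(v, lo, hi, tag) {
    v <- unname(v)
    par <<- c(par, v); lower <<- c(lower, rep(lo, length(v)))
    upper <<- c(upper, rep(hi, length(v)))
    tags[[length(tags) + 1L]] <<- list(tag = tag, idx = seq.int(
      length(par) - length(v) + 1L, length(par)))
  }
  lsz <- log(size_bounds)
  if (structured) {
    if ("n_A" %in% free) {
      grp <- model$grid$groups
      gvals <- vapply(split(model$n_A, grp), function(v) v[1], 0)
      push(log(pmin(pmax(gvals, size_bounds[1]), size_bounds[2])),
           lsz[1], lsz[2], "n_A")
    }
    if ("n_B" %in% free) {
      push(log(pmin(pmax(model$n_B, size_bounds[1]), size_bounds[2])),
           lsz[1], lsz[2], "n_B")
    }
    if ("gamma" %in% free) {
      g0 <- min(max(model$gamma, 1e-6), 1 - 1e-6)
      push(stats::qlogis(g0), stats::qlogis(1e-6), stats::qlogis(1 - 1e-6),
           "gamma")
    }
  } else {
    if ("n" %in% free || "n_A" %in% free) {
      grp <- model$grid$groups
      gvals <- vapply(split(model$n, grp), function(v) v[1], 0)
      push(log(pmin(pmax(gvals, size_bounds[1]), size_bounds[2])),
           lsz[1], lsz[2], "n")
    }
  }
  if ("rho" %in% free) {
    push(log(min(max(model$rho, rho_bounds[1]), rho_bounds[2])),
         log(rho_bounds[1]), log(rho_bounds[2]), "rho")
  }
  if (!length(par)) stop("no free parameters", call. = FALSE)
  unpack <- function(p) {
    m <- model
    for (tg in tags) {
      v <- p[tg$idx]
      switch(tg$tag,
        n_A = { m$n_A <- exp(v)[model$grid$groups] },
        n = { m$n <- exp(v)[model$grid$groups] },
        n_B = { m$n_B <- exp(v) },
        gamma = { m$gamma <- stats::plogis(v) },
        rho = { m$rho <- exp(v) }
      )
    }
    m
  }
  list(par = par, lower = lower, upper = upper, unpack = unpack)
}

# expected complete-data log-likelihood of candidate parameters given the
# E-step counts; t_bar (and hence emissions) are frozen for the M-step.
.q_function <- function(cand, t_bar, tc, ic) {
  q <- .cond_matrix_at(cand, t_bar)
  ht <- .hmm_pieces(cand, q, t_bar)
  sum(ic * log(pmax(ht$initial, 1e-300))) +
    sum(tc * log(pmax(ht$a, 1e-300)))
}

#' Fit a demography by Baum-Welch expectation-maximization
#'
#' Iterates the E-step (scaled forward-backward) and a numerical M-step
#' (box-constrained quasi-Newton over transformed free parameters:
#' log sizes, logit admixture fraction, log recombination rate) at fixed
#' split/admixture times. Stops when the change in total log-likelihood
#' between consecutive iterations drops below `psi_tol` (default 1, the
#' standard convergence rule for this model family) or at `max_iter`.
#' Interval representative times - and with them the emission matrix - are
#' recomputed from the current model at the start of each iteration and
#' frozen during the M-step; if an update ever lowers the log-likelihood the
#' previous parameters are restored and the fit is flagged.
#'
#' @param obs an [obs_sequence()].
#' @param init initial demography (structured or unstructured); split and
#'   admixture times stay fixed at their `init` values.
#' @param free character subset of `c("n_A", "n_B", "gamma", "rho")`
#'   (structured) or `c("n", "rho")` (unstructured); default all.
#' @param psi_tol convergence threshold on `|delta log-likelihood|`.
#' @param max_iter maximum EM iterations.
#' @param representative row-conditioning rule for the discretization.
#' @param size_bounds box constraints on relative sizes.
#' @param rho_bounds box constraints on the per-window scaled recombination
#'   rate.
#' @param m_step_maxit inner quasi-Newton iteration cap per M-step; any
#'   improvement of the expected complete-data log-likelihood suffices
#'   (generalized EM), so a modest cap trades per-iteration cost against
#'   iteration count without changing the fixed points.
#' @param gamma_starts optional vector of admixture-fraction starting values
#'   (structured models): one EM run per start, the best final likelihood
#'   wins, and the per-start summary is attached as `$gamma_starts`.
#'   Recommended together with warm-starting `rho` from an unstructured fit,
#'   since a poorly scaled recombination rate flattens the likelihood in
#'   `gamma`.
#' @param want_posterior also return the final per-window TMRCA posteriors.
#' @param verbose print the per-iteration log-likelihood.
#' @return object of class `fit_result`: `model`, `loglik`, `trajectory`
#'   (non-decreasing within numerical slack), `n_iterations`, `converged`,
#'   `fallback` (`TRUE` if an M-step failed to improve and was reverted),
#'   and optionally `posterior_t`.
#' @export
em_fit <- function(obs, init, free = NULL, psi_tol = 1, max_iter = 200,
                   representative = c("cond_mean", "midpoint"),
                   size_bounds = c(1e-3, 1e3), rho_bounds = c(1e-7, 1),
                   m_step_maxit = 20, gamma_starts = NULL,
                   want_posterior = FALSE, verbose = FALSE) {
  representative <- match.arg(representative)
  if (!is.null(gamma_starts) && inherits(init, "structured_demography")) {
    # multi-start over the admixture fraction: the likelihood in gamma is
    # multimodal/flat when the size profile can mimic the structure, so a
    # small set of starts with the best final likelihood is standard
    fits <- lapply(gamma_starts, function(g0) {
      ini <- init
      ini$gamma <- g0
      em_fit(obs, ini, free = free, psi_tol = psi_tol, max_iter = max_iter,
             representative = representative, size_bounds = size_bounds,
             rho_bounds = rho_bounds, m_step_maxit = m_step_maxit,
             want_posterior = want_posterior, verbose = verbose)
    })
    best <- which.max(vapply(fits, function(f) f$loglik, 0))
    out <- fits[[best]]
    out$gamma_starts <- data.frame(
      start = gamma_starts,
      loglik = vapply(fits, function(f) f$loglik, 0),
      gamma = vapply(fits, function(f) f$model$gamma, 0)
    )
    return(out)
  }
  stopifnot(inherits(obs, "obs_sequence"), inherits(init, "demography"),
            psi_tol > 0, max_iter >= 1)
  structured <- inherits(init, "structured_demography")
  if (is.null(free)) free <- if (structured) c("n_A", "n_B", "gamma", "rho")
                             else c("n", "rho")
  model <- init
  if (structured && "gamma" %in% free && model$gamma == 0) model$gamma <- 1e-6
  traj <- numeric(0)
  converged <- FALSE
  fallback <- FALSE
  prev_model <- model
  last_fb <- NULL
  for (iter in seq_len(max_iter)) {
    tb <- representative_times(model, representative)
    q <- .cond_matrix_at(model, tb)
    ht <- .hmm_pieces(model, q, tb)
    em <- emission_matrix(model, tb)
    fb <- .fb_core(obs$symbols, ht$a, em, ht$initial, obs$seg_starts,
                   FALSE, TRUE)
    ll <- fb$loglik
    if (!is.finite(ll)) {
      stop("non-finite likelihood during EM; parameters: ",
           paste(utils::capture.output(utils::str(model)), collapse = " "))
    }
    if (length(traj) && ll < traj[length(traj)] - 1e-6) {
      # accepted update lowered the likelihood (discretization refresh):
      # fall back to the previous parameters and stop
      model <- prev_model
      fallback <- TRUE
      break
    }
    traj <- c(traj, ll)
    last_fb <- fb
    if (verbose) message(sprintf("EM iter %d: loglik = %.6f", iter, ll))
    if (length(traj) >= 2L &&
        abs(traj[length(traj)] - traj[length(traj) - 1L]) < psi_tol) {
      converged <- TRUE
      break
    }
    if (iter == max_iter) break
    # M-step
    spec <- .param_spec(model, free, size_bounds, rho_bounds)
    obj <- function(p) -.q_function(spec$unpack(p), tb, fb$trans_counts,
                                    fb$init_counts)
    res <- tryCatch(
      stats::optim(spec$par, obj, method = "L-BFGS-B", lower = spec$lower,
                   upper = spec$upper,
                   control = list(maxit = m_step_maxit, factr = 1e7)),
      error = function(e) NULL
    )
    prev_model <- model
    if (!is.null(res) && is.finite(res$value) &&
        res$value <= obj(spec$par) + 1e-9) {
      model <- spec$unpack(res$par)
    } else {
      fallback <- TRUE
      break
    }
  }
  out <- list(
    model = model, loglik = traj[length(traj)], trajectory = traj,
    n_iterations = length(traj), converged = converged, fallback = fallback,
    free = free, psi_tol = psi_tol
  )
  if (want_posterior) {
    tb <- representative_times(model, representative)
    q <- .cond_matrix_at(model, tb)
    ht <- .hmm_pieces(model, q, tb)
    fbp <- .fb_core(obs$symbols, ht$a, emission_matrix(model, tb),
                    ht$initial, obs$seg_starts, TRUE, FALSE)
    out$posterior_t <- fbp$posterior
  }
  structure(out, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> loglik = %.3f after %d EM iterations (%s)%s\n",
    x$loglik, x$n_iterations,
    if (x$converged) "converged" else "not converged",
    if (x$fallback) ", M-step fallback" else ""
  ))
  invisible(x)
}
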