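#' Structured (split-and-rejoin) demography
#'
#' Represents the pulse model of ancestral structure: a sampled population A
#' with piecewise-constant scaled size `n_A(t)`, a ghost population B of
#' constant scaled size `n_B` that exists between the admixture time `T1`
#' and the split time `T2`, and a pulse admixture fraction `gamma`: looking
#' backward in time, each uncoalesced lineage in A independently derives
#' from B with probability `gamma` at `T1`; A and B are isolated until `T2`,
#' when all lineages merge into the ancestral population (whose size is the
#' continuation of the `n_A` profile).
#'
#' All times are in units of `2 * N_ref` generations and sizes are relative
#' to `N_ref`; `theta = 4 * N_ref * mu * b` and `rho = 4 * N_ref * r * b`
#' are the scaled mutation and recombination rates per `b`-base window.
#'
#' @param grid a [build_time_grid()] object; `T1`/`T2` must lie on its
#'   boundaries (see [snap_times()]).
#' @param n_A scaled size of A per interval (scalar recycled).
#' @param n_B scaled size of the ghost deme B (scalar; an opt-in
#'   per-structured-interval vector is accepted for the relaxed model).
#' @param gamma pulse admixture fraction in `[0, 1]`.
#' @param T1_index,T2_index boundary indices of the admixture and split
#'   times, `1 < T1_index < T2_index <= n_intervals`.
#' @param theta,rho scaled mutation/recombination rate per window.
#' @return object of class `c("structured_demography", "demography")`.
#' @seealso [unstructured_demography()], [marginal_coalescence_profile()],
#'   [matched_unstructured()]
#' @export
structured_demography <- function(grid, n_A, n_B, gamma, T1_index, T2_index,
                                  theta, rho) {
  stopifnot(inherits(grid, "time_grid"))
  n <- grid$n_intervals
  if (length(n_A) == 1L) n_A <- rep(n_A, n)
  stopifnot(
    length(n_A) == n, all(n_A > 0), all(is.finite(n_A)),
    gamma >= 0, gamma <= 1,
    T1_index > 1L, T1_index < T2_index, T2_index <= n,
    theta > 0, rho >= 0
  )
  # n_B stays a scalar (one free parameter) unless the relaxed
  # per-structured-interval mode is requested with a full-length vector
  n_struct <- T2_index - T1_index
  stopifnot(length(n_B) %in% c(1L, n_struct),
            all(n_B > 0), all(is.finite(n_B)))
  nB_vec <- as.numeric(n_B)
  structure(
    list(
      grid = grid, n_A = as.numeric(n_A), n_B = as.numeric(nB_vec),
      gamma = gamma, T1_index = as.integer(T1_index),
      T2_index = as.integer(T2_index), theta = theta, rho = rho
    ),
    class = c("structured_demography", "demography")
  )
}

#' Unstructured (panmictic) demography
#'
#' The classic single-population model with piecewise-constant scaled size:
#' the special case `gamma = 0` of the structured model, and the model the
#' structured HMM nests.
#'
#' @inheritParams structured_demography
#' @param n scaled size per interval (scalar recycled).
#' @return object of class `c("unstructured_demography", "demography")`.
#' @export
unstructured_demography <- function(grid, n, theta, rho) {
  stopifnot(inherits(grid, "time_grid"))
  ni <- grid$n_intervals
  if (length(n) == 1L) n <- rep(n, ni)
  stopifnot(length(n) == ni, all(n > 0), all(is.finite(n)), theta > 0, rho >= 0)
  structure(
    list(grid = grid, n = as.numeric(n), theta = theta, rho = rho),
    class = c("unstructured_demography", "demography")
  )
}

#' @export
print.structured_demography <- function(x, ...) {
  b <- x$grid$boundaries
  cat(sprintf(
    paste0("<structured_demography> %d intervals, gamma = %.4g, ",
           "T1 = %.4g, T2 = %.4g, n_B = %s, theta = %.3g, rho = %.3g\n"),
    x$grid$n_intervals, x$gamma, b[x$T1_index], b[x$T2_index],
    paste(signif(unique(x$n_B), 4), collapse = "/"), x$theta, x$rho
  ))
  invisible(x)
}

#' @export
print.unstructured_demography <- function(x, ...) {
  cat(sprintf(
    "<unstructured_demography> %d intervals, theta = %.3g, rho = %.3g\n",
    x$grid$n_intervals, x$theta, x$rho
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Piecewise-exponential mixture representation of the pairwise TMRCA law.
#
# The marginal TMRCA distribution of two lineages sampled in A decomposes
# over the lineage-path choice made at T1 (AA / BB / AB with migration prior
# (1-g)^2 / g^2 / 2g(1-g)); each component is an inhomogeneous exponential
# with a piecewise-constant rate on the grid intervals:
#   AA: 1/n_A everywhere;
#   BB: 1/n_A before T1, 1/n_B during [T1, T2), 1/n_A after T2;
#   AB: 1/n_A before T1, 0 during [T1, T2) (demes apart), 1/n_A after T2.
# Everything downstream (survival, density, hazard, interval masses,
# conditional means, path priors) is closed-form in this representation.

tmrca_components <- function(model) {
  UseMethod("tmrca_components")
}

#' @export
tmrca_components.unstructured_demography <- function(model) {
  list(
    weights = 1,
    labels = "AA",
    rates = matrix(1 / model$n, nrow = 1)
  )
}

#' @export
tmrca_components.structured_demography <- function(model) {
  n <- model$grid$n_intervals
  g <- model$gamma
  struct <- seq(model$T1_index, model$T2_index - 1L)
  r_AA <- 1 / model$n_A
  r_BB <- r_AA; r_BB[struct] <- 1 / model$n_B
  r_AB <- r_AA; r_AB[struct] <- 0
  list(
    weights = c((1 - g)^2, g^2, 2 * g * (1 - g)),
    labels = c("AA", "BB", "AB"),
    rates = rbind(r_AA, r_BB, r_AB)
  )
}

# Cumulative hazard of each component at the grid boundaries
# (n_components x (n+1); last column Inf whenever the final rate > 0).
component_cumhaz <- function(model, comp = tmrca_components(model)) {
  b <- model$grid$boundaries
  n <- model$grid$n_intervals
  widths <- diff(b[seq_len(n)])
  H <- t(apply(comp$rates, 1, function(r) {
    c(0, cumsum(r[seq_len(n - 1L)] * widths), Inf)
  }))
  # last boundary is +Inf: cumulative hazard diverges iff the final rate > 0
  H[comp$rates[, n] == 0, n + 1L] <- H[comp$rates[, n] == 0, n]
  H
}

# Evaluate component cumulative hazards at arbitrary times (matrix
# n_components x length(t)).
component_cumhaz_at <- function(model, t, comp = tmrca_components(model),
                                H = component_cumhaz(model, comp)) {
  b <- model$grid$boundaries
  j <- findInterval(t, b, rightmost.closed = FALSE)
  j <- pmin(pmax(j, 1L), model$grid$n_intervals)
  out <- matrix(0, nrow = nrow(comp$rates), ncol = length(t))
  for (k in seq_len(nrow(comp$rates))) {
    out[k, ] <- H[k, j] + comp$rates[k, j] * (t - b[j])
  }
  out
}

#' Marginal pairwise coalescence-time profile
#'
#' Computes the density, survival, hazard (instantaneous coalescence rate)
#' and inverse coalescence rate (ICR, interpretable as a scaled effective
#' population size) of the TMRCA of two lineages sampled in A at time 0.
#'
#' @param model a structured or unstructured demography.
#' @param mesh evaluation times (coalescent units, `>= 0`).
#' @return object of class `rate_profile`: a data frame with columns
#'   `eval_times`, `density`, `survival`, `hazard`, `icr`.
#' @examples
#' g <- build_time_grid(16)
#' m <- unstructured_demography(g, n = 1, theta = 8e-4, rho = 6.4e-4)
#' p <- marginal_coalescence_profile(m, seq(0, 3, by = 0.01))
#' # constant-size coalescent: hazard 1, density exp(-t)
#' @export
marginal_coalescence_profile <- function(model, mesh) {
  stopifnot(inherits(model, "demography"), all(mesh >= 0), all(is.finite(mesh)))
  comp <- tmrca_components(model)
  Ht <- component_cumhaz_at(model, mesh, comp)
  b <- model$grid$boundaries
  j <- pmin(pmax(findInterval(mesh, b), 1L), model$grid$n_intervals)
  Sk <- exp(-Ht)                      # per-component survival
  S <- as.numeric(comp$weights %*% Sk)
  f <- as.numeric(comp$weights %*% (comp$rates[, j, drop = FALSE] * Sk))
  hz <- ifelse(S > 0, f / S, NA_real_)
  structure(
    data.frame(
      eval_times = mesh, density = f, survival = S,
      hazard = hz, icr = ifelse(is.na(hz) | hz <= 0, NA_real_, 1 / hz)
    ),
    class = c("rate_profile", "data.frame")
  )
}

# Probability mass of the TMRCA in each grid interval, per component
# (n_components x n matrix) and in total (length-n vector via colSums).
interval_masses <- function(model, comp = tmrca_components(model),
                            H = component_cumhaz(model, comp)) {
  n <- model$grid$n_intervals
  Sb <- exp(-H)
  comp$weights * (Sb[, seq_len(n), drop = FALSE] - Sb[, -1L, drop = FALSE])
}

# Conditional mean TMRCA within each grid interval under the model
# (the "representative time" t_bar used by emissions and transitions).
# Falls back to the interval midpoint where the interval mass underflows.
representative_times <- function(model, method = c("cond_mean", "midpoint")) {
  method <- match.arg(method)
  mid <- interval_midpoints(model$grid)
  if (method == "midpoint") return(mid)
  comp <- tmrca_components(model)
  H <- component_cumhaz(model, comp)
  b <- model$grid$boundaries
  n <- model$grid$n_intervals
  Sb <- exp(-H)
  num <- numeric(n); den <- numeric(n)
  for (k in seq_along(comp$weights)) {
    w <- comp$weights[k]
    if (w == 0) next
    for (jj in seq_len(n)) {
      r <- comp$rates[k, jj]
      a <- b[jj]; bb <- b[jj + 1L]
      Sa <- Sb[k, jj]
      if (r == 0 || Sa == 0) next
      if (is.finite(bb)) {
        d <- bb - a
        e <- exp(-r * d)
        m <- Sa * (1 - e)
        # int_a^b t f(t) dt for the exponential piece
        tmean_piece <- Sa * (a - bb * e + (1 - e) / r)
      } else {
        m <- Sa
        tmean_piece <- Sa * (a + 1 / r)
      }
      num[jj] <- num[jj] + w * tmean_piece
      den[jj] <- den[jj] + w * m
    }
  }
  out <- ifelse(den > 1e-300, num / den, mid)
  # guard against numerical escape from the interval
  hi <- ifelse(is.finite(b[-1]), b[-1], Inf)
  pmin(pmax(out, b[-(n + 1L)]), hi)
}

# Posterior over path components given coalescence at exact time t
# (vector over components, in the order of tmrca_components(model)).
component_posterior_at <- function(model, t, comp = tmrca_components(model)) {
  Ht <- component_cumhaz_at(model, t, comp)[, 1]
  b <- model$grid$boundaries
  j <- min(max(findInterval(t, b), 1L), model$grid$n_intervals)
  # log-space for robustness deep in the tail (survival underflow)
  lw <- log(comp$weights) + log(comp$rates[, j]) - Ht
  if (all(!is.finite(lw))) lw <- log(comp$weights) - Ht
  if (all(!is.finite(lw))) lw <- log(comp$weights)
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Rate-matched unstructured model
#'
#' Constructs a panmictic model whose piecewise-constant size profile equals
#' the structured model's inverse coalescence rate evaluated at the interval
#' midpoints of the target grid. Its coalescence rate profile matches the
#' structured one up to piecewise-constant discretization error; structure
#' then masquerades as pure size change, and only the transition kernel can
#' tell the two apart.
#'
#' @param model a structured demography.
#' @param grid target grid for the matched model (default: the model's own).
#' @return an unstructured demography on `grid`.
#' @export
matched_unstructured <- function(model, grid = model$grid) {
  stopifnot(inherits(model, "structured_demography"), inherits(grid, "time_grid"))
  mid <- interval_midpoints(grid)
  prof <- marginal_coalescence_profile(model, mid)
  if (anyNA(prof$hazard) || any(prof$hazard <= 0) ||
      any(prof$survival < 1e-300)) {
    keep <- which(!is.na(prof$hazard) & prof$hazard > 0 &
                    prof$survival >= 1e-300)
    if (length(keep) < 2L) stop("survival underflow on nearly all intervals",
                                call. = FALSE)
    ncut <- max(keep)
    warning(sprintf(
      "hazard numerically undefined beyond interval %d; truncating grid", ncut
    ), call. = FALSE)
    grid <- new_time_grid(c(grid$boundaries[seq_len(ncut)], Inf),
                          grid$groups[seq_len(ncut)])
    mid <- interval_midpoints(grid)
    prof <- marginal_coalescence_profile(model, mid)
  }
  unstructured_demography(grid, n = 1 / prof$hazard,
                          theta = model$theta, rho = model$rho)
}

# ---------------------------------------------------------------------------
# Units. N_ref is implied by theta = 4 N_ref mu b; coalescent times are in
# 2 N_ref generations.

#' Unit conversions between coalescent-scaled and natural units
#'
#' `n_ref_from_theta()` recovers the reference effective size implied by the
#' scaled mutation rate; `scaled_time_to_years()` and
#' `scaled_size_to_diploids()` convert model quantities for reporting.
#'
#' @param theta scaled mutation rate per window (`4 N_ref mu b`).
#' @param mu per-generation per-base mutation rate (default `1.25e-8`).
#' @param b window (bin) size in bases (default 100).
#' @param gen_time generation time in years (default 29).
#' @param t time in coalescent units; `n` size relative to `N_ref`.
#' @return a numeric scalar/vector in the requested units.
#' @export
n_ref_from_theta <- function(theta, mu = 1.25e-8, b = 100) {
  theta / (4 * mu * b)
}

#' @rdname n_ref_from_theta
#' @export
scaled_time_to_years <- function(t, theta, mu = 1.25e-8, b = 100,
                                 gen_time = 29) {
  t * 2 * n_ref_from_theta(theta, mu, b) * gen_time
}

#' @rdname n_ref_from_theta
#' @export
scaled_size_to_diploids <- function(n, theta, mu = 1.25e-8, b = 100) {
  n * n_ref_from_theta(theta, mu, b)
}

#' @rdname n_ref_from_theta
#' @param years time in years (converted back to coalescent units).
#' @export
years_to_scaled_time <- function(years, theta, mu = 1.25e-8, b = 100,
                                 gen_time = 29) {
  years / (2 * n_ref_from_theta(theta, mu, b) * gen_time)
}

# ---------------------------------------------------------------------------
# Model (de)serialization: plain JSON, round-trippable at full precision.

#' Write / read a demography as JSON
#'
#' The schema records the grid boundaries (both in coalescent units and in
#' years under the supplied `mu`/`gen_time`), per-interval sizes, and for
#' structured models `n_B`, `gamma` and the `T1`/`T2` boundary indices,
#' together with `theta` and `rho`. Round trip is exact to double precision.
#'
#' @param model a demography object.
#' @param path file path.
#' @inheritParams n_ref_from_theta
#' @return `read_model_json()` returns the demography; `write_model_json()`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path, mu = 1.25e-8, b = 100,
                             gen_time = 29) {
  stopifnot(inherits(model, "demography"))
  g <- model$grid
  fin <- g$boundaries[seq_len(g$n_intervals)]
  obj <- list(
    type = if (inherits(model, "structured_demography")) "structured" else "unstructured",
    boundaries = fin,
    boundaries_years = scaled_time_to_years(fin, model$theta, mu, b, gen_time),
    groups = g$groups,
    theta = model$theta,
    rho = model$rho
  )
  if (obj$type == "structured") {
    obj$n_A <- model$n_A
    obj$n_B <- model$n_B
    obj$gamma <- model$gamma
    obj$T1_index <- model$T1_index
    obj$T2_index <- model$T2_index
  } else {
    obj$n <- model$n
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- new_time_grid(c(obj$boundaries, Inf), obj$groups)
  if (identical(obj$type, "structured")) {
    structured_demography(grid, obj$n_A, obj$n_B, obj$gamma,
                          obj$T1_index, obj$T2_index, obj$theta, obj$rho)
  } else {
    unstructured_demography(grid, obj$n, obj$theta, obj$rho)
  }
}
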