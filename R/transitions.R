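# Analytic SMC transition kernels for structured and unstructured models.
#
# Generative process behind a transition, given the old TMRCA t at a locus:
# a recombination breakpoint falls at u ~ Uniform(0, t) on one of the two
# branches; the branch segment above u detaches ("floats"), restarts at u in
# the deme the broken branch occupied there, migrates A -> B with
# probability gamma if it crosses T1 going backward (fresh draw), and
# re-coalesces with the surviving lineage - the unbroken branch below t and
# the root lineage above t - at rate 1/n_A(s) while both are in A, 1/n_B
# while both are in B, 0 while split across demes, and unconditionally at
# rate 1/n_A(s) in the merged population beyond T2.  The surviving pair's
# deme path during [T1, T2) is the lineage-path label c (drawn from its
# posterior given coalescence at t for the marginal kernel; given explicitly
# for the path-augmented kernel).
#
# Key structural fact exploited throughout: within each stratum of the
# breakpoint position (u < T1, T1 <= u < T2, u >= T2) and conditional on the
# discrete migration/path choices, the re-coalescence rate trajectory
# lambda(s) is piecewise constant on the grid intervals and does not depend
# on u (u only sets the lower integration limit).  The u-integral therefore
# has a closed form, evaluated stably below with all exponentials of
# non-positive argument.

# -- scenario enumeration ----------------------------------------------------

# lambda per interval when the float's structured-period deme is d_f and the
# surviving partner's is D.
.lam_structured <- function(model, d_f, D) {
  lam <- 1 / model$n_A
  struct <- seq(model$T1_index, model$T2_index - 1L)
  if (d_f == D) {
    if (d_f == "B") lam[struct] <- 1 / model$n_B
  } else {
    lam[struct] <- 0
  }
  lam
}

# Enumerate scenarios for old TMRCA t and lineage-path label c_label
# ("AA"/"BB"/"AB" for structured models; ignored for unstructured).
# Each scenario: weight w (sums to 1 over the list), u-range (u0, u1),
# lambda vector over intervals, and the structured-period demes of the
# floating (d2) and surviving (d1) sequence lineages.
kernel_scenarios <- function(model, t, c_label = NULL) {
  if (inherits(model, "unstructured_demography")) {
    return(list(list(w = 1, u0 = 0, u1 = t, lam = 1 / model$n,
                     d2 = "A", d1 = "A")))
  }
  b <- model$grid$boundaries
  T1 <- b[model$T1_index]; T2 <- b[model$T2_index]
  g <- model$gamma
  pmig <- c(A = 1 - g, B = g)
  scen <- list()
  add <- function(w, u0, u1, d_f, D) {
    if (w > 0 && u1 > u0) {
      scen[[length(scen) + 1L]] <<- list(
        w = w, u0 = u0, u1 = u1,
        lam = .lam_structured(model, d_f, D), d2 = d_f, d1 = D
      )
    }
  }
  if (t < T1) {
    stopifnot(is.null(c_label) || c_label == "AA")
    for (Mf in c("A", "B")) for (Mr in c("A", "B")) {
      add(pmig[[Mf]] * pmig[[Mr]], 0, t, Mf, Mr)
    }
  } else if (t < T2) {
    d <- if (identical(c_label, "BB")) "B" else "A"
    for (Mf in c("A", "B")) add((T1 / t) * pmig[[Mf]], 0, T1, Mf, d)
    add((t - T1) / t, T1, t, d, d)
  } else {
    pairs <- switch(c_label,
      AA = list(list(dB = "A", dT = "A", w = 1)),
      BB = list(list(dB = "B", dT = "B", w = 1)),
      AB = list(list(dB = "A", dT = "B", w = 0.5),
                list(dB = "B", dT = "A", w = 0.5)),
      stop("unknown path label: ", c_label)
    )
    for (pr in pairs) {
      for (Mf in c("A", "B")) {
        add(pr$w * (T1 / t) * pmig[[Mf]], 0, T1, Mf, pr$dT)
      }
      add(pr$w * (T2 - T1) / t, T1, T2, pr$dB, pr$dT)
      # u beyond T2: float restarts in the merged population; the floating
      # sequence lineage's structured-period deme is the broken branch's.
      if (t > T2) {
        lam <- 1 / model$n_A
        lam[seq(model$T1_index, model$T2_index - 1L)] <- 0  # never visited
        scen[[length(scen) + 1L]] <- list(
          w = pr$w * (t - T2) / t, u0 = T2, u1 = t,
          lam = lam, d2 = pr$dB, d1 = pr$dT
        )
      }
    }
  }
  scen
}

# P(new TMRCA in each grid interval) for one scenario, the u-integral done
# in closed form. boundaries: length n+1 (last Inf); lam: length n.
# The compiled port is the hot path; this R body is the readable reference
# (kept in sync, exercised in the test suite).
.scenario_pvec <- function(boundaries, lam, u0, u1) {
  .scenario_pvec_cpp(boundaries, lam, u0, u1)
}

.scenario_pvec_r <- function(boundaries, lam, u0, u1) {
  b <- boundaries
  n <- length(lam)
  a <- b[seq_len(n)]
  bb2 <- b[-1L]
  widths <- bb2 - a
  dLam <- lam * widths                      # last entry Inf (lam[n] > 0)
  Lam <- c(0, cumsum(dLam))                 # cumulative hazard at boundaries
  # C(y) = int_{u0}^{y} exp(Lam(u) - Lam(y)) du at boundaries y <= u1
  j0 <- which(a == u0)[1]
  if (is.na(j0)) stop("internal: u0 is not a grid boundary")
  ju <- min(findInterval(u1, b), n)
  Cb <- numeric(n)
  if (ju > j0) {
    for (j in j0:(ju - 1L)) {
      E <- exp(-dLam[j])
      Cb[j + 1L] <- if (lam[j] > 0) {
        Cb[j] * E + (-expm1(-dLam[j])) / lam[j]
      } else {
        Cb[j] + widths[j]
      }
    }
  }
  rem <- u1 - b[ju]
  if (rem > 0) {
    Erem <- exp(-lam[ju] * rem)
    I_total <- if (lam[ju] > 0) {
      Cb[ju] * Erem + (-expm1(-lam[ju] * rem)) / lam[ju]
    } else {
      Cb[ju] + rem
    }
    Lam_u1 <- Lam[ju] + lam[ju] * rem
  } else {
    I_total <- Cb[ju]
    Lam_u1 <- Lam[ju]
  }
  # part 1: u below the interval (contributes exp-decayed entry mass)
  Jint <- numeric(n)
  hi <- a >= u1
  Jint[hi] <- I_total * exp(Lam_u1 - Lam[seq_len(n)][hi])
  mid <- !hi & a > u0
  Jint[mid] <- Cb[mid]
  w1 <- Jint * (-expm1(-dLam))
  # part 2: u inside the interval
  x2 <- pmax(u0, a)
  y2 <- pmin(u1, bb2)
  len <- pmax(0, y2 - x2)
  w2 <- numeric(n)
  pos <- len > 0 & lam > 0
  if (any(pos)) {
    w2[pos] <- len[pos] -
      exp(-lam[pos] * (bb2[pos] - y2[pos])) *
        (-expm1(-lam[pos] * len[pos])) / lam[pos]
  }
  (w1 + w2) / (u1 - u0)
}

# Row of the marginal (time-only) kernel at old TMRCA t.
.marginal_kernel_row <- function(model, t) {
  if (inherits(model, "unstructured_demography")) {
    sc <- kernel_scenarios(model, t)[[1]]
    return(.scenario_pvec(model$grid$boundaries, sc$lam, sc$u0, sc$u1))
  }
  b <- model$grid$boundaries
  T1 <- b[model$T1_index]
  comp <- tmrca_components(model)
  if (t < T1) {
    wc <- c(AA = 1)
  } else {
    post <- component_posterior_at(model, t, comp)
    names(post) <- comp$labels
    wc <- post[post > 0]
  }
  row <- numeric(model$grid$n_intervals)
  for (cl in names(wc)) {
    for (sc in kernel_scenarios(model, t, cl)) {
      row <- row + wc[[cl]] * sc$w *
        .scenario_pvec(b, sc$lam, sc$u0, sc$u1)
    }
  }
  row
}

#' Conditional SMC transition matrix
#'
#' Builds the row-stochastic matrix `q[beta, alpha] = P(new TMRCA in
#' interval alpha | recombination occurred, old TMRCA in interval beta)` by
#' exact integration of the generative recombination process. Each row is
#' conditioned at the interval's representative time (conditional mean TMRCA
#' under the model, the standard discretization; midpoints available).
#'
#' @param model structured or unstructured demography.
#' @param representative `"cond_mean"` (default) or `"midpoint"`.
#' @return object of class `transition_matrix`: fields `q` (n x n), `grid`,
#'   `kind` (`"structured"`/`"unstructured"`) and `t_bar`.
#' @export
conditional_transition_matrix <- function(model,
                                          representative = c("cond_mean",
                                                             "midpoint")) {
  stopifnot(inherits(model, "demography"))
  representative <- match.arg(representative)
  tb <- representative_times(model, representative)
  n <- model$grid$n_intervals
  q <- matrix(0, n, n)
  for (beta in seq_len(n)) q[beta, ] <- .marginal_kernel_row(model, tb[beta])
  rs <- rowSums(q)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("transition rows do not normalize (max |rowsum-1| = ",
         format(max(abs(rs - 1))), ")")
  }
  q <- q / rs
  structure(
    list(q = q, grid = model$grid,
         kind = if (inherits(model, "structured_demography"))
           "structured" else "unstructured",
         t_bar = tb),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s, %d x %d\n",
              x$kind, nrow(x$q), ncol(x$q)))
  invisible(x)
}

#' Per-window HMM transition
#'
#' Combines no-recombination persistence with the conditional kernel:
#' `a[beta, alpha] = (1 - p_rec(beta)) * I + p_rec(beta) * q[beta, alpha]`
#' with `p_rec(beta) = 1 - exp(-rho * t_bar_beta)`. The initial distribution
#' is the model's marginal TMRCA distribution over intervals (stationary
#' under the SMC kernel by construction).
#'
#' @param model the demography the kernel was built from.
#' @param cond a [conditional_transition_matrix()] on the same grid
#'   (built if missing).
#' @return object of class `hmm_transition`: fields `a`, `initial`, `p_rec`,
#'   `t_bar`, `grid`.
#' @export
hmm_transition <- function(model, cond = NULL) {
  if (is.null(cond)) cond <- conditional_transition_matrix(model)
  stopifnot(identical(cond$grid$boundaries, model$grid$boundaries))
  p_rec <- -expm1(-model$rho * cond$t_bar)
  a <- diag(1 - p_rec) + p_rec * cond$q
  initial <- colSums(interval_masses(model))
  initial <- initial / sum(initial)
  structure(
    list(a = a, initial = initial, p_rec = p_rec, t_bar = cond$t_bar,
         grid = model$grid),
    class = "hmm_transition"
  )
}

#' Relative difference between two conditional transition matrices
#'
#' `xi = (q_u - q_s) / q_s`, elementwise; entries where `q_s` is zero are
#' returned as `NA` (undefined) rather than infinite. Nonzero `xi` between a
#' structured model and its rate-matched unstructured model is the
#' identifiability signal: the two have identical coalescence rate profiles
#' but different conditional distributions of neighboring TMRCAs.
#'
#' @param q_u,q_s [conditional_transition_matrix()] objects on the same grid
#'   (conventionally unstructured and structured).
#' @return an n x n matrix of relative differences.
#' @export
xi_relative_difference <- function(q_u, q_s) {
  stopifnot(inherits(q_u, "transition_matrix"),
            inherits(q_s, "transition_matrix"))
  if (!identical(dim(q_u$q), dim(q_s$q)) ||
      !identical(q_u$grid$boundaries, q_s$grid$boundaries)) {
    stop("transition matrices are on different grids", call. = FALSE)
  }
  xi <- (q_u$q - q_s$q) / q_s$q
  xi[q_s$q == 0] <- NA_real_
  xi
}

#' Monte-Carlo oracle for the conditional transition kernel
#'
#' Estimates the kernel by direct event simulation of the generative
#' recombination process, independently of the closed-form integration:
#' for each row, the old TMRCA is fixed at the row's representative time,
#' the breakpoint `u`, path label, branch roles and migration choices are
#' sampled, and the re-coalescence time is simulated segment-by-segment with
#' exponential waiting times. Deterministic given `seed`.
#'
#' @param model structured or unstructured demography.
#' @param n_samples total number of draws (split evenly across rows;
#'   `>= 1e4`).
#' @param seed integer RNG seed.
#' @param paths if `TRUE` (structured models only) rows and columns are the
#'   path-augmented states of [path_state_space()] and draws are labelled
#'   with the new path.
#' @param condition_on_path with `paths = TRUE`: condition each row's draws
#'   on its explicit old path label (`TRUE`, the full generative process) or
#'   draw the old label from its posterior given the row time (`FALSE`,
#'   matching [path_transition_emission()]'s default construction).
#' @param representative row conditioning time, as in
#'   [conditional_transition_matrix()].
#' @return list with `q_hat` (empirical row-stochastic matrix), `se`
#'   (per-cell binomial standard errors), `n_per_row`.
#' @export
mc_transition_oracle <- function(model, n_samples = 1e6, seed = 1,
                                 paths = FALSE, condition_on_path = TRUE,
                                 representative = c("cond_mean", "midpoint")) {
  stopifnot(inherits(model, "demography"), n_samples >= 1e4)
  representative <- match.arg(representative)
  set.seed(seed)
  tb <- representative_times(model, representative)
  n <- model$grid$n_intervals
  if (paths) {
    stopifnot(inherits(model, "structured_demography"))
    space <- path_state_space(model$grid, model$T1_index, model$T2_index)
    m <- nrow(space)
    nper <- ceiling(n_samples / m)
    q_hat <- matrix(0, m, m, dimnames = list(state_names(space),
                                             state_names(space)))
    for (r in seq_len(m)) {
      beta <- space$interval[r]
      draws <- .mc_draws(model, tb[beta], nper,
                         c_label = if (condition_on_path) space$path[r])
      idx <- match(paste(draws$alpha, draws$c_new), paste(space$interval,
                                                          space$path))
      q_hat[r, ] <- tabulate(idx, nbins = m) / nper
    }
  } else {
    nper <- ceiling(n_samples / n)
    q_hat <- matrix(0, n, n)
    for (beta in seq_len(n)) {
      draws <- .mc_draws(model, tb[beta], nper, c_label = NULL)
      q_hat[beta, ] <- tabulate(draws$alpha, nbins = n) / nper
    }
  }
  list(q_hat = q_hat, se = sqrt(q_hat * (1 - q_hat) / nper), n_per_row = nper)
}

# Simulate nper transitions from old TMRCA t (path label c_label, or drawn
# from its posterior when NULL). Pure event simulation.
.mc_draws <- function(model, t, nper, c_label = NULL) {
  b <- model$grid$boundaries
  n <- model$grid$n_intervals
  unstruct <- inherits(model, "unstructured_demography")
  if (unstruct) {
    T1 <- Inf; T2 <- Inf; g <- 0
  } else {
    T1 <- b[model$T1_index]; T2 <- b[model$T2_index]; g <- model$gamma
  }
  u <- stats::runif(nper, 0, t)
  if (unstruct) {
    df <- rep("A", nper); d1 <- rep("A", nper)
  } else {
    # path label of the old pair
    if (is.null(c_label)) {
      if (t < T1) {
        cl <- rep("AA", nper)
      } else {
        comp <- tmrca_components(model)
        post <- component_posterior_at(model, t, comp)
        cl <- comp$labels[sample.int(3L, nper, replace = TRUE, prob = post)]
      }
    } else {
      cl <- rep(c_label, nper)
    }
    # broken/unbroken branch structured-period demes
    dB <- ifelse(cl == "BB", "B", "A")
    dT <- ifelse(cl == "AA", "A", "B")
    swap <- cl == "AB" & stats::runif(nper) < 0.5
    tmp <- dB[swap]; dB[swap] <- dT[swap]; dT[swap] <- tmp
    # floating sequence lineage's structured deme: fresh migration draw if
    # the breakpoint is below T1, else it continues the broken branch
    df <- ifelse(u < T1,
                 ifelse(stats::runif(nper) < g, "B", "A"),
                 dB)
    # surviving sequence lineage's structured deme
    if (t < T1) {
      d1 <- ifelse(stats::runif(nper) < g, "B", "A")  # root's fresh draw
    } else if (t < T2) {
      d1 <- ifelse(cl == "BB", "B", "A")
    } else {
      d1 <- dT
    }
  }
  # segment-wise exponential race from u upward
  s <- numeric(nper)
  for (grp in unique(paste(df, d1))) {
    sel <- which(paste(df, d1) == grp)
    parts <- strsplit(grp, " ")[[1]]
    lam <- if (unstruct) 1 / model$n else
      .lam_structured(model, parts[1], parts[2])
    cur <- u[sel]
    alive <- rep(TRUE, length(sel))
    j <- pmin(pmax(findInterval(cur, b), 1L), n)
    res <- numeric(length(sel))
    while (any(alive)) {
      ii <- which(alive)
      lj <- lam[j[ii]]
      dt <- stats::rexp(length(ii)) / lj            # Inf where rate 0
      hit <- cur[ii] + dt < b[j[ii] + 1L]
      res[ii[hit]] <- cur[ii][hit] + dt[hit]
      alive[ii[hit]] <- FALSE
      adv <- ii[!hit]
      cur[adv] <- b[j[adv] + 1L]
      j[adv] <- j[adv] + 1L
    }
    s[sel] <- res
  }
  alpha <- pmin(pmax(findInterval(s, b), 1L), n)
  if (unstruct) return(list(alpha = alpha, c_new = rep("AA", nper), s = s))
  c_new <- ifelse(s < T1, "AA",
                  ifelse(s < T2,
                         ifelse(df == "A", "AA", "BB"),
                         ifelse(df == d1,
                                ifelse(df == "A", "AA", "BB"),
                                "AB")))
  list(alpha = alpha, c_new = c_new, s = s)
}

#' Export a transition matrix as annotated TSV
#'
#' Writes the matrix with row/column interval lower boundaries, suitable for
#' plotting relative-difference heatmaps.
#'
#' @param q a [conditional_transition_matrix()] object or plain matrix.
#' @param path output file.
#' @param grid grid for the boundary annotations (taken from `q` if absent).
#' @return `path`, invisibly.
#' @export
write_transition_tsv <- function(q, path, grid = NULL) {
  if (inherits(q, "transition_matrix")) {
    grid <- q$grid
    q <- q$q
  }
  stopifnot(!is.null(grid))
  lb <- grid$boundaries[seq_len(grid$n_intervals)]
  df <- data.frame(from_boundary = lb, q)
  names(df) <- c("from_boundary", sprintf("to_%0.6g", lb))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
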