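test_that("conditional kernels are row-stochastic and nest the panmictic model", {
  models <- list(
    toy_structured(gamma = 0.3),
    toy_structured(gamma = 0.15, T1 = 0.3, T2 = 1.2, n_A = 0.6, n_B = 2.5),
    toy_unstructured(size = 2)
  )
  for (m in models) {
    q <- conditional_transition_matrix(m)
    expect_lt(max(abs(rowSums(q$q) - 1)), 1e-10)
    expect_true(all(q$q >= 0))
  }
  s0 <- toy_structured(gamma = 0, n_A = exp(seq(-0.3, 0.6, length.out = 16)))
  u <- unstructured_demography(s0$grid, s0$n_A, s0$theta, s0$rho)
  qs <- conditional_transition_matrix(s0)
  qu <- conditional_transition_matrix(u)
  expect_lt(max(abs(qs$q - qu$q)), 1e-10)
})

test_that("compiled kernel equals the R reference implementation", {
  set.seed(4)
  for (m in list(toy_structured(gamma = 0.4, n_A = exp(runif(16, -1, 1)),
                                n_B = 1.7),
                 toy_unstructured(size = exp(runif(16, -1, 1))))) {
    tb <- ghostpulse:::representative_times(m)
    expect_lt(max(abs(ghostpulse:::.cond_matrix_at(m, tb) -
                        ghostpulse:::.cond_matrix_at_r(m, tb))), 1e-13)
  }
})

test_that("constant-size kernel matches direct numerical integration", {
  # independent oracle: for the constant-size coalescent, integrate the SMC
  # kernel P(s in [a,b) | t) = (1/t) int_0^t [e^{-(max(a,u)-u)} - e^{-(max(b,u)-u)}] du
  # by quadrature, without the package's closed-form machinery
  m <- toy_unstructured(size = 1, n = 8)
  q <- conditional_transition_matrix(m)
  b <- m$grid$boundaries
  for (beta in c(2L, 5L, 8L)) {
    t <- q$t_bar[beta]
    for (alpha in c(1L, 4L, 8L)) {
      f <- function(u) {
        exp(-(pmax(b[alpha], u) - u)) -
          (if (is.finite(b[alpha + 1]))
             exp(-(pmax(b[alpha + 1], u) - u)) else 0)
      }
      ref <- stats::integrate(f, 0, t, rel.tol = 1e-10)$value / t
      expect_equal(q$q[beta, alpha], ref, tolerance = 1e-7)
    }
  }
})

test_that("analytic kernels agree with the Monte-Carlo event oracle", {
  settings <- list(
    toy_structured(gamma = 0.3, T1 = 0.1, T2 = 0.5),
    toy_structured(gamma = 0.15, T1 = 0.3, T2 = 1.2, n_A = 0.6, n_B = 2.5,
                   n = 12),
    toy_unstructured(size = 1)
  )
  for (k in seq_along(settings)) {
    m <- settings[[k]]
    q <- conditional_transition_matrix(m)
    mc <- mc_transition_oracle(m, n_samples = 1e6, seed = 40 + k)
    se <- sqrt(q$q * (1 - q$q) / mc$n_per_row)
    z <- abs(mc$q_hat - q$q) / ifelse(se > 0, se, 1)
    # per-cell 4 SE, allowing the small-count Poisson tail over many cells
    expect_lt(mean(z > 4), 0.005)
    expect_lt(max(z), 6)
    expect_true(all(mc$q_hat[q$q == 0] == 0))  # impossible cells never hit
  }
  # determinism
  m <- settings[[1]]
  a <- mc_transition_oracle(m, n_samples = 1e4, seed = 9)
  b <- mc_transition_oracle(m, n_samples = 1e4, seed = 9)
  expect_identical(a$q_hat, b$q_hat)
})

test_that("gamma = 1 sends all structured-period re-coalescence through B", {
  # with the old label drawn from its posterior (at gamma = 1 every
  # surviving pair migrated), no re-coalescence in (T1, T2) can occur in A
  m <- toy_structured(gamma = 1, T1 = 0.1, T2 = 0.5)
  mc <- mc_transition_oracle(m, n_samples = 5e4, seed = 3, paths = TRUE,
                             condition_on_path = FALSE)
  space <- path_state_space(m$grid, m$T1_index, m$T2_index)
  struct_cols <- which(space$interval >= m$T1_index &
                         space$interval < m$T2_index)
  labs <- space$path[struct_cols]
  mass <- colSums(mc$q_hat[, struct_cols, drop = FALSE])
  expect_true(all(mass[labs == "AA"] == 0))
  expect_gt(sum(mass[labs == "BB"]), 0)
})

test_that("per-window transition combines persistence and the kernel", {
  m <- toy_structured(gamma = 0.3)
  cond <- conditional_transition_matrix(m)
  # rho = 0: identity
  m0 <- m; m0$rho <- 0
  ht0 <- hmm_transition(m0, cond)
  expect_equal(ht0$a, diag(m$grid$n_intervals), tolerance = 1e-12)
  # rho > 0: row-stochastic, diagonal dominated by no-recombination mass
  m1 <- m; m1$rho <- 0.05
  ht <- hmm_transition(m1, cond)
  expect_lt(max(abs(rowSums(ht$a) - 1)), 1e-10)
  expect_true(all(diag(ht$a) >= 1 - ht$p_rec - 1e-12))
  expect_equal(sum(ht$initial), 1, tolerance = 1e-12)
})

test_that("xi highlights structure invisible to the rate profile", {
  s <- toy_structured(gamma = 0.3, n = 16)
  qs <- conditional_transition_matrix(s)
  # identical matrices give all-zero xi
  expect_equal(max(abs(xi_relative_difference(qs, qs)), na.rm = TRUE), 0)
  # rate-matched pair: clearly nonzero differences
  qu <- conditional_transition_matrix(matched_unstructured(s))
  xi <- xi_relative_difference(qu, qs)
  expect_gt(max(abs(xi), na.rm = TRUE), 0.01)
  # signal grows with the admixture fraction
  s05 <- toy_structured(gamma = 0.05, n = 16)
  xi05 <- xi_relative_difference(
    conditional_transition_matrix(matched_unstructured(s05)),
    conditional_transition_matrix(s05)
  )
  expect_gt(max(abs(xi), na.rm = TRUE), max(abs(xi05), na.rm = TRUE))
  # and does not vanish under grid refinement
  s32 <- toy_structured(gamma = 0.3, n = 32)
  xi32 <- xi_relative_difference(
    conditional_transition_matrix(matched_unstructured(s32)),
    conditional_transition_matrix(s32)
  )
  expect_gte(max(abs(xi32), na.rm = TRUE),
             0.5 * max(abs(xi), na.rm = TRUE))
  # shape mismatch is an error
  expect_error(xi_relative_difference(qs, conditional_transition_matrix(s32)),
               "different grids")
})
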