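test_that("a single scan cell reproduces a direct EM fit", {
  m <- toy_structured(gamma = 0.3, n = 12)
  sim <- simulate_sequence(m, 3e4, seed = 51)
  base <- structured_demography(m$grid, 1, 1, 0.1, m$T1_index, m$T2_index,
                                m$theta, m$rho)
  tab <- grid_scan(sim$obs, m$T1_index, m$T2_index, base, max_iter = 6,
                   psi_tol = 0.5)
  expect_s3_class(tab, "scan_table")
  expect_equal(nrow(tab), 1)
  direct <- em_fit(sim$obs, base, max_iter = 6, psi_tol = 0.5)
  expect_equal(tab$loglik, direct$loglik, tolerance = 1e-9)
  expect_equal(tab$gamma, direct$model$gamma, tolerance = 1e-9)
  sel <- cml_select(tab)
  expect_equal(sel$T1_index, m$T1_index)
})

test_that("scan cells are cached and re-runs are identical", {
  m <- toy_structured(gamma = 0.3, n = 12)
  sim <- simulate_sequence(m, 2e4, seed = 52)
  base <- structured_demography(m$grid, 1, 1, 0.1, m$T1_index, m$T2_index,
                                m$theta, m$rho)
  cache <- tempfile("scancache")
  t1s <- c(m$T1_index, m$T1_index + 1L)
  tab1 <- grid_scan(sim$obs, t1s, m$T2_index, base, max_iter = 3,
                    cache_dir = cache)
  tab2 <- grid_scan(sim$obs, t1s, m$T2_index, base, max_iter = 3,
                    cache_dir = cache)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 2)
})

test_that("CML tie-break fires toward smaller T2 then larger T1", {
  mk <- function(sample, i1, i2, ll) {
    data.frame(sample = sample, T1_index = i1, T2_index = i2,
               T1 = i1 / 10, T2 = i2 / 10, loglik = ll, gamma = 0.1,
               converged = TRUE, n_iter = 5L, ok = TRUE)
  }
  # two samples with opposite preferences of equal magnitude: both cells sum
  # to the same composite likelihood
  tab <- structure(rbind(
    mk("a", 3, 6, -100), mk("a", 4, 5, -110),
    mk("b", 3, 6, -110), mk("b", 4, 5, -100)
  ), class = c("scan_table", "data.frame"))
  sel <- cml_select(tab)
  expect_true(sel$tie)
  expect_equal(sel$T2_index, 5)   # smaller T2 wins
  expect_equal(sel$T1_index, 4)
  # single sample: plain argmax
  tab1 <- structure(rbind(mk("a", 3, 6, -100), mk("a", 4, 5, -110)),
                    class = c("scan_table", "data.frame"))
  expect_equal(cml_select(tab1)$T2_index, 6)
})

test_that("model comparison counts parameters as k_U = n+1, k_S = n+5", {
  g32 <- build_time_grid(32)
  fit_s <- structure(list(model = structured_demography(g32, 1, 1, 0.2, 10,
                                                        20, 0.08, 0.064),
                          loglik = -1000), class = "fit_result")
  fit_u <- structure(list(model = unstructured_demography(g32, 1, 0.08,
                                                          0.064),
                          loglik = -1000), class = "fit_result")
  cmp <- model_compare(fit_s, fit_u)
  expect_equal(cmp$k_U, 33)
  expect_equal(cmp$k_S, 37)
  expect_equal(cmp$delta_L, 0)
  expect_equal(cmp$AIC_S - cmp$AIC_U, 2 * (37 - 33))
  g16 <- build_time_grid(16)
  fit_u16 <- structure(list(model = unstructured_demography(g16, 1, 0.08,
                                                            0.064),
                            loglik = -1000), class = "fit_result")
  expect_error(model_compare(fit_s, fit_u16), "different grids")
})

test_that("likelihood evidence grows with the separation period", {
  # at fixed gamma, the structured-vs-matched-panmictic information grows
  # with T2 - T1: measured as the log-likelihood gap between the true
  # structured model and its rate-matched panmictic twin on simulated data
  seps <- c(0.6, 1.2, 2.4)
  gaps <- sapply(seps, function(T2) {
    mean(sapply(1:3, function(sd) {
      m <- toy_structured(gamma = 0.3, T1 = 0.3, T2 = T2)
      mu <- matched_unstructured(m)
      sim <- simulate_sequence(m, 1e5, seed = 1000 + round(100 * T2) + sd)
      log_likelihood(sim$obs, m) - log_likelihood(sim$obs, mu)
    }))
  })
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[3], 0)
})

test_that("minimal-T1 / maximal-T2 cells drive gamma toward zero", {
  m <- toy_structured(gamma = 0.3, T1 = 0.32, T2 = 1.62)
  sim <- simulate_sequence(m, 2e5, seed = 55)
  n <- m$grid$n_intervals
  base <- structured_demography(m$grid, 1, 1, 0.1, m$T1_index, m$T2_index,
                                m$theta, m$rho)
  tab <- grid_scan(sim$obs, c(2L, m$T1_index), c(m$T2_index, n - 1L), base,
                   free = c("n_A", "gamma"), max_iter = 30)
  truth_cell <- tab[tab$T1_index == m$T1_index & tab$T2_index == m$T2_index, ]
  extreme <- tab[tab$T1_index == 2L & tab$T2_index == n - 1L, ]
  expect_gt(truth_cell$gamma, 0.15)
  expect_lt(extreme$gamma, 0.1)
  expect_gt(truth_cell$loglik, extreme$loglik)
})
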