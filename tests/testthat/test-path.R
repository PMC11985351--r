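test_that("path state space contains exactly the legal (t, c) pairs", {
  g <- build_time_grid(4, t_max = 2)
  sp <- path_state_space(g, 2, 4)
  # 1 interval before T1, 2 in the structured period, 1 beyond T2
  expect_equal(nrow(sp), 1 + 2 * 2 + 3 * 1)
  expect_equal(sp$path[sp$interval == 1], "AA")
  expect_setequal(sp$path[sp$interval == 2], c("AA", "BB"))
  expect_setequal(sp$path[sp$interval == 4], c("AA", "BB", "AB"))
  # canonical order: intervals ascending, AA before BB before AB
  expect_equal(sp$path[sp$interval == 4], c("AA", "BB", "AB"))
  expect_error(path_state_space(g, 3, 3), "T1 must precede T2")
  expect_error(path_state_space(g, 1, 3))
  expect_error(path_state_space(g, 2, 9))
})

test_that("migration-choice prior over paths is (1-g)^2 / g^2 / 2g(1-g)", {
  pr <- path_choice_prior(0.2)
  expect_equal(unname(pr["BB"]), 0.04)
  expect_equal(unname(pr["AB"]), 0.32)
  expect_equal(sum(pr), 1)
  expect_equal(unname(path_choice_prior(toy_structured(gamma = 0.2))["BB"]),
               0.04)
  # empirically: in a regime of negligible structured-period coalescence the
  # path fractions among t >= T1 draws reproduce the prior
  m <- toy_structured(gamma = 0.2, T1 = 0.1, T2 = 0.15, n_A = 50, n_B = 50,
                      t_max = 40)
  dr <- sample_coalescence_times(m, 1e5, seed = 77)
  surv <- dr$path[dr$t >= 0.1]
  emp <- prop.table(table(factor(surv, c("AA", "BB", "AB"))))
  se <- sqrt(pr * (1 - pr) / length(surv))
  expect_true(all(abs(emp[names(pr)] - pr) < 3.5 * se))
})

test_that("path transitions are stochastic and marginalize to the time kernel", {
  m <- toy_structured(gamma = 0.25, T1 = 0.3, T2 = 1.2, n_B = 2)
  q <- conditional_transition_matrix(m)
  for (cp in c(FALSE, TRUE)) {
    pte <- path_transition_emission(m, condition_on_path = cp)
    expect_lt(max(abs(rowSums(pte$q) - 1)), 1e-10)
    expect_lt(max(abs(rowSums(pte$a) - 1)), 1e-10)
    expect_equal(sum(pte$initial), 1, tolerance = 1e-12)
    # averaging rows over the per-time path posterior and summing over the
    # new label recovers the time-only kernel
    sp <- pte$space
    comp <- ghostpulse:::tmrca_components(m)
    T1 <- m$grid$boundaries[m$T1_index]
    qm <- matrix(0, 16, 16)
    for (beta in 1:16) {
      wc <- if (pte$t_bar[beta] < T1) c(AA = 1, BB = 0, AB = 0) else {
        w <- ghostpulse:::component_posterior_at(m, pte$t_bar[beta], comp)
        names(w) <- comp$labels
        w
      }
      rows <- which(sp$interval == beta)
      mixed <- colSums(pte$q[rows, , drop = FALSE] * wc[sp$path[rows]])
      qm[beta, ] <- rowsum(mixed, sp$interval)
    }
    expect_lt(max(abs(qm - q$q)), 1e-8)
    # emissions depend on the time interval only
    expect_equal(pte$emit[, "K"],
                 emission_matrix(m, pte$t_bar)[sp$interval, "K"])
  }
})

test_that("explicit-label path kernel matches the labelled MC oracle", {
  m <- toy_structured(gamma = 0.3, T1 = 0.1, T2 = 0.5)
  pte <- path_transition_emission(m, condition_on_path = TRUE)
  mc <- mc_transition_oracle(m, n_samples = 1e6, seed = 8, paths = TRUE,
                             condition_on_path = TRUE)
  se <- sqrt(pte$q * (1 - pte$q) / mc$n_per_row)
  z <- abs(mc$q_hat - pte$q) / ifelse(se > 0, se, 1)
  expect_lt(mean(z > 4), 0.005)
  expect_lt(max(z), 7)
  expect_true(all(mc$q_hat[pte$q == 0] == 0))
})

test_that("time-marginals of path decoding equal the time-only HMM", {
  m <- toy_structured(gamma = 0.2, T1 = 0.32, T2 = 1.62)
  sim <- simulate_sequence(m, 2e4, seed = 11, missing_prob = 0.05)
  post <- decode_paths(sim$obs, m)
  fb <- forward_backward(sim$obs, hmm_transition(m), emission_matrix(m))
  expect_equal(post$loglik, fb$loglik, tolerance = 1e-6)
  expect_lt(max(abs(post$posterior_t - fb$posterior)), 1e-6)
  expect_equal(colSums(post$marginal_c), rep(1, 2e4), tolerance = 1e-10)
})

test_that("decoding recovers admixture tracks better than chance", {
  m <- toy_structured(gamma = 0.4, T1 = 0.32, T2 = 1.62)
  sim <- simulate_sequence(m, 2e5, seed = 12)
  post <- decode_paths(sim$obs, m)
  truth <- sim$truth
  for (lab in c("BB", "AB")) {
    sel <- truth$path == lab
    expect_gt(mean(post$conditional_c[lab, sel], na.rm = TRUE),
              mean(post$conditional_c[lab, ], na.rm = TRUE))
  }
})

test_that("gamma = 0 decodes every window as AA", {
  m <- toy_structured(gamma = 0)
  sim <- simulate_sequence(m, 5e3, seed = 3)
  post <- decode_paths(sim$obs, m)
  expect_gte(min(post$marginal_c["AA", ]), 1 - 1e-10)
})

test_that("H(x) follows its defining formula", {
  # hand-built posteriors: H = (BB + AB/2) / P(t > T1)
  fake <- function(bb, ab, pt1, miss = FALSE, T = 4) {
    structure(list(
      joint_c_gt_T1 = rbind(AA = pt1 - bb - ab, BB = rep(bb, T),
                            AB = rep(ab, T)),
      p_t_gt_T1 = rep(pt1, T),
      missing = rep(miss, T),
      bin_size = 100
    ), class = "path_posterior")
  }
  expect_equal(h_statistic(list(fake(bb = 0.3, ab = 0, pt1 = 0.3)),
                           stride = 100)$H,
               rep(1, 4))
  expect_equal(h_statistic(list(fake(bb = 0, ab = 0.4, pt1 = 0.4)),
                           stride = 100)$H,
               rep(0.5, 4))
  # two samples pool in the numerator and denominator
  trk <- h_statistic(list(fake(0.2, 0, 0.5), fake(0, 0.2, 0.5)), stride = 100)
  expect_equal(trk$H, rep((0.2 + 0.1) / 1, 4))
  # all-missing positions are uncallable
  trk2 <- h_statistic(list(fake(0.2, 0, 0.5, miss = TRUE)), stride = 100)
  expect_true(all(!trk2$callable) && all(is.na(trk2$H)))
  expect_error(h_statistic(list(fake(0.1, 0, 0.2), fake(0.1, 0, 0.2, T = 5))),
               "mismatched")
})

test_that("genome-wide H estimates the admixture fraction", {
  m <- toy_structured(gamma = 0.2, T1 = 0.32, T2 = 1.62)
  posts <- lapply(1:3, function(i) {
    decode_paths(simulate_sequence(m, 2e5, seed = i)$obs, m)
  })
  trk <- h_statistic(posts, stride = 1000)
  expect_true(all(trk$H[trk$callable] >= 0 & trk$H[trk$callable] <= 1))
  expect_lt(abs(mean(trk$H, na.rm = TRUE) - 0.2), 0.05)
})

test_that("windowed A-ancestry fraction behaves as an expectation", {
  T <- 40
  mk <- function(aa, ab) {
    structure(list(
      marginal_c = rbind(AA = rep(aa, T), BB = rep(1 - aa - ab, T),
                         AB = rep(ab, T)),
      bin_size = 100
    ), class = "path_posterior")
  }
  expect_equal(ancestry_fraction_windows(mk(1, 0), 1000)$a_fraction,
               rep(1, 4))
  expect_equal(ancestry_fraction_windows(mk(0, 1), 1000)$a_fraction,
               rep(0.5, 4))
  # A-fraction + B-fraction (the unconditional analogue) = 1
  p <- mk(0.55, 0.3)
  afrac <- ancestry_fraction_windows(p, 1000)$a_fraction
  bfrac <- (p$marginal_c["BB", 1] + p$marginal_c["AB", 1] / 2)
  expect_equal(afrac + bfrac, rep(1, 4))
})

test_that("tail enrichment selects, counts and tests correctly", {
  set.seed(8)
  n <- 5000
  H <- runif(n)
  trk <- structure(
    data.frame(pos = (seq_len(n) - 1L) * 1000, H = H, callable = TRUE),
    class = c("h_track", "data.frame"), stride = 1000, bin_size = 100
  )
  # intervals covering exactly the positions of the 50 largest H values
  top_pos <- trk$pos[order(-H)[1:50]]
  iv <- data.frame(start = top_pos, end = top_pos + 1)
  res <- enrichment_test(trk, iv, pct = 0.01, tail = "top")
  expect_equal(res$n_selected, 50)
  expect_equal(res$hits, 50)
  expect_equal(res$distinct_intervals, 50)
  expect_equal(res$p, 50 / n)
  expect_lt(res$p_value, 1e-50)
  # bottom tail misses them all
  resb <- enrichment_test(trk, iv, pct = 0.01, tail = "bottom")
  expect_equal(resb$hits, 0)
  # null: hits equal to expectation give fold 1 and p 1
  core <- binomial_enrichment(1000, 500, 0.5)
  expect_equal(core$fold, 1)
  expect_equal(core$p_value, 1)
  expect_error(enrichment_test(trk, iv, pct = 0.9), "pct")
  expect_error(enrichment_test(trk, data.frame(start = numeric(0),
                                               end = numeric(0))),
               "non-empty")
})
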