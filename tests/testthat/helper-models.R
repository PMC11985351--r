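# shared model builders (all fixtures are generated in code)

toy_structured <- function(n = 16, gamma = 0.3, T1 = 0.1, T2 = 0.5,
                           n_A = 1, n_B = 1, theta = 0.08, rho = 0.064,
                           t_max = 15) {
  sn <- snap_times(build_time_grid(n, t_max), T1, T2)
  structured_demography(sn$grid, n_A, n_B, gamma, sn$T1_index, sn$T2_index,
                        theta, rho)
}

toy_unstructured <- function(n = 16, size = 1, theta = 0.08, rho = 0.064,
                             t_max = 15) {
  unstructured_demography(build_time_grid(n, t_max), size, theta, rho)
}

# a hand-sized two-state HMM for exhaustive-enumeration checks
toy_chain <- function() {
  a <- matrix(c(0.9, 0.1,
                0.25, 0.75), 2, 2, byrow = TRUE)
  emit <- cbind(K = c(0.05, 0.6), T = c(0.95, 0.4), N = c(1, 1))
  list(a = a, initial = c(0.7, 0.3), emit = emit)
}

# brute-force likelihood by summing over all hidden paths
enumerate_loglik <- function(symbols, chain, seg_starts = 1L) {
  n <- nrow(chain$a)
  T <- length(symbols)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  tot <- 0
  for (k in seq_len(nrow(paths))) {
    st <- paths[k, ]
    p <- 1
    for (i in seq_len(T)) {
      p <- p * (if (i %in% seg_starts) chain$initial[st[i]]
                else chain$a[st[i - 1], st[i]]) *
        chain$emit[st[i], symbols[i]]
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# cache shared across expensive acceptance blocks
.acc_env <- new.env(parent = emptyenv())
acceptance_cache <- function(name, expr) {
  if (!exists(name, envir = .acc_env)) {
    assign(name, force(expr), envir = .acc_env)
  }
  get(name, envir = .acc_env)
}
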