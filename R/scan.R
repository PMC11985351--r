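#' Grid search over split and admixture times
#'
#' Runs an independent [em_fit()] for every admissible `(T1, T2)` candidate
#' pair (candidates are boundary indices; only `T1 < T2` cells are fitted)
#' and every sample, recording the converged log-likelihood and fitted
#' admixture fraction. Cell-level EM failures are recorded, not fatal.
#' Cells can be cached to disk (`cache_dir`) and are skipped on re-run, so
#' a scan is resumable and reproducible.
#'
#' @param obs_per_sample named list of [obs_sequence()] objects (one per
#'   sample/population); a single `obs_sequence` is accepted.
#' @param T1_candidates,T2_candidates boundary indices on `base$grid`.
#' @param base a structured demography template supplying the grid, sizes,
#'   `n_B`, `gamma`, `theta` and `rho` used to initialize every cell (theta
#'   is fixed across samples so all cells share boundaries).
#' @param free,psi_tol,max_iter,gamma_starts passed to [em_fit()].
#' @param cache_dir optional directory for per-cell fit caching.
#' @param verbose print per-cell progress.
#' @return object of class `scan_table`: a data frame with one row per
#'   (sample, T1, T2) cell: indices, times, `loglik`, `gamma`, `converged`,
#'   `n_iter`, `ok`.
#' @export
grid_scan <- function(obs_per_sample, T1_candidates, T2_candidates, base,
                      free = c("n_A", "n_B", "gamma", "rho"), psi_tol = 1,
                      max_iter = 200, gamma_starts = NULL, cache_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(base, "structured_demography"))
  if (inherits(obs_per_sample, "obs_sequence")) {
    obs_per_sample <- list(sample1 = obs_per_sample)
  }
  if (is.null(names(obs_per_sample))) {
    names(obs_per_sample) <- paste0("sample", seq_along(obs_per_sample))
  }
  n <- base$grid$n_intervals
  stopifnot(all(T1_candidates > 1 & T1_candidates <= n),
            all(T2_candidates > 1 & T2_candidates <= n))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  rows <- list()
  bdy <- base$grid$boundaries
  for (sm in names(obs_per_sample)) {
    for (i1 in sort(unique(T1_candidates))) {
      for (i2 in sort(unique(T2_candidates))) {
        if (i1 >= i2) next
        tag <- sprintf("%s_T1%02d_T2%02d", sm, i1, i2)
        cache_file <- if (!is.null(cache_dir)) {
          file.path(cache_dir, paste0(tag, ".rds"))
        }
        if (!is.null(cache_file) && file.exists(cache_file)) {
          rows[[tag]] <- readRDS(cache_file)
          next
        }
        init <- structured_demography(
          base$grid, base$n_A, base$n_B, base$gamma, i1, i2,
          base$theta, base$rho
        )
        fit <- tryCatch(
          em_fit(obs_per_sample[[sm]], init, free = free, psi_tol = psi_tol,
                 max_iter = max_iter, gamma_starts = gamma_starts),
          error = function(e) e
        )
        rec <- if (inherits(fit, "error")) {
          data.frame(sample = sm, T1_index = i1, T2_index = i2,
                     T1 = bdy[i1], T2 = bdy[i2], loglik = NA_real_,
                     gamma = NA_real_, converged = FALSE, n_iter = 0L,
                     ok = FALSE)
        } else {
          data.frame(sample = sm, T1_index = i1, T2_index = i2,
                     T1 = bdy[i1], T2 = bdy[i2], loglik = fit$loglik,
                     gamma = fit$model$gamma, converged = fit$converged,
                     n_iter = fit$n_iterations, ok = TRUE)
        }
        if (!is.null(cache_file)) saveRDS(rec, cache_file)
        if (verbose) {
          message(sprintf("cell %s: loglik %s", tag, format(rec$loglik)))
        }
        rows[[tag]] <- rec
      }
    }
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("scan_table", "data.frame"))
}

#' Composite-maximum-likelihood time pair
#'
#' Sums log-likelihoods across samples per `(T1, T2)` cell and returns the
#' argmax; ties are broken toward smaller `T2`, then larger `T1` (the most
#' conservative structured period), and reported.
#'
#' @param table a [grid_scan()] result.
#' @return list with `T1_index`, `T2_index`, `T1`, `T2`, the summed
#'   `loglik`, `tie` flag, and the per-cell composite table.
#' @export
cml_select <- function(table) {
  stopifnot(inherits(table, "scan_table"))
  ok <- table[table$ok & is.finite(table$loglik), , drop = FALSE]
  if (!nrow(ok)) stop("no successfully fitted cells", call. = FALSE)
  n_samples <- length(unique(table$sample))
  agg <- stats::aggregate(loglik ~ T1_index + T2_index + T1 + T2, data = ok,
                          FUN = sum)
  cnt <- stats::aggregate(loglik ~ T1_index + T2_index, data = ok,
                          FUN = length)
  names(cnt)[3] <- "n_fitted"
  agg <- merge(agg, cnt, by = c("T1_index", "T2_index"))
  agg <- agg[agg$n_fitted == n_samples, , drop = FALSE]
  if (!nrow(agg)) stop("no cell was fitted for every sample", call. = FALSE)
  best <- max(agg$loglik)
  cand <- agg[agg$loglik >= best - 1e-9, , drop = FALSE]
  cand <- cand[order(cand$T2_index, -cand$T1_index), , drop = FALSE]
  sel <- cand[1, ]
  list(T1_index = sel$T1_index, T2_index = sel$T2_index,
       T1 = sel$T1, T2 = sel$T2, loglik = sel$loglik,
       tie = nrow(cand) > 1, table = agg)
}

#' Structured versus unstructured model comparison
#'
#' Log-likelihood difference `delta_L = L_S - L_U` and AIC for both models.
#' Parameter counts: the unstructured model has `n_freeA` free sizes plus
#' the recombination rate (`k_U = n_freeA + 1`); the structured model adds
#' the admixture fraction, the ghost deme size and the two times
#' (`k_S = n_freeA + 5`). With 32 free sizes this gives 33 and 37.
#'
#' @param structured_fit,unstructured_fit [em_fit()] results on the same
#'   data and grid.
#' @param n_freeA number of free size parameters (default: the number of
#'   size groups on the shared grid).
#' @return list with `delta_L`, `AIC_S`, `AIC_U`, `k_S`, `k_U`.
#' @export
model_compare <- function(structured_fit, unstructured_fit, n_freeA = NULL) {
  stopifnot(inherits(structured_fit, "fit_result"),
            inherits(unstructured_fit, "fit_result"))
  gs <- structured_fit$model$grid
  gu <- unstructured_fit$model$grid
  if (!identical(gs$boundaries[c(1, gs$n_intervals)],
                 gu$boundaries[c(1, gu$n_intervals)]) ||
      gs$n_intervals != gu$n_intervals) {
    stop("fits are on different grids", call. = FALSE)
  }
  if (is.null(n_freeA)) n_freeA <- length(unique(gs$groups))
  k_U <- n_freeA + 1L
  k_S <- n_freeA + 5L
  L_S <- structured_fit$loglik
  L_U <- unstructured_fit$loglik
  list(delta_L = L_S - L_U,
       AIC_S = 2 * k_S - 2 * L_S, AIC_U = 2 * k_U - 2 * L_U,
       k_S = k_S, k_U = k_U)
}

#' Heatmap-ready composite log-likelihood matrix
#'
#' Sums log-likelihoods across samples per cell and pivots the scan table
#' into a T1-by-T2 matrix (rows: admixture-time index, columns: split-time
#' index), `NA` where a cell was not fitted for every sample.
#'
#' @param table a [grid_scan()] result.
#' @return a numeric matrix with dimnames giving the boundary indices.
#' @export
scan_matrix <- function(table) {
  stopifnot(inherits(table, "scan_table"))
  ok <- table[table$ok & is.finite(table$loglik), , drop = FALSE]
  n_samples <- length(unique(table$sample))
  agg <- stats::aggregate(loglik ~ T1_index + T2_index, data = ok, FUN = sum)
  cnt <- stats::aggregate(loglik ~ T1_index + T2_index, data = ok,
                          FUN = length)
  agg <- agg[cnt$loglik == n_samples, , drop = FALSE]
  i1s <- sort(unique(table$T1_index))
  i2s <- sort(unique(table$T2_index))
  m <- matrix(NA_real_, length(i1s), length(i2s),
              dimnames = list(T1 = i1s, T2 = i2s))
  m[cbind(match(agg$T1_index, i1s), match(agg$T2_index, i2s))] <- agg$loglik
  m
}

#' Export a scan table as TSV (with times in years)
#'
#' @param table a [grid_scan()] result.
#' @param path output file.
#' @param theta scaled mutation rate used for the year conversion.
#' @inheritParams n_ref_from_theta
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(table, path, theta, mu = 1.25e-8, b = 100,
                           gen_time = 29) {
  stopifnot(inherits(table, "scan_table"))
  out <- table
  out$T1_years <- scaled_time_to_years(out$T1, theta, mu, b, gen_time)
  out$T2_years <- scaled_time_to_years(out$T2, theta, mu, b, gen_time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
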