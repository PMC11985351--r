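#' Discretized coalescent time grid
#'
#' Builds the shared set of discrete time interval boundaries used by all
#' HMM states. Boundaries follow the PSMC-style log-spaced rule
#' `t_i = 0.1 * (exp((i/n) * log(1 + 10 * t_max)) - 1)` for `i = 0..n-1`,
#' with the final interval open-ended (`[t_{n-1}, Inf)`). Times are in
#' coalescent units of `2 * N_ref` generations.
#'
#' @param n_intervals number of atomic intervals (>= 2).
#' @param t_max scale of the most ancient finite boundary, in coalescent
#'   units; default 15.
#' @param pattern optional grouping of atomic intervals into free size
#'   parameters, in the PSMC `-p` dialect: terms separated by `+`, each
#'   either `k` (one group of `k` intervals) or `m*k` (`m` groups of `k`
#'   intervals each). `NULL` gives every interval its own group.
#' @return an object of class `time_grid` with fields `boundaries`
#'   (length `n_intervals + 1`, first 0, last `Inf`), `n_intervals`, and
#'   `groups` (integer group id per interval).
#' @examples
#' g <- build_time_grid(32, t_max = 15)
#' g2 <- build_time_grid(32, pattern = "4+28")
#' @export
build_time_grid <- function(n_intervals, t_max = 15, pattern = NULL) {
  stopifnot(n_intervals >= 2, t_max > 0)
  i <- seq_len(n_intervals) - 1L
  b <- 0.1 * (exp((i / n_intervals) * log(1 + 10 * t_max)) - 1)
  boundaries <- c(b, Inf)
  groups <- parse_group_pattern(pattern, n_intervals)
  new_time_grid(boundaries, groups)
}

new_time_grid <- function(boundaries, groups = NULL) {
  n <- length(boundaries) - 1L
  if (is.null(groups)) groups <- seq_len(n)
  stopifnot(
    boundaries[1] == 0,
    all(diff(boundaries) > 0),
    is.infinite(boundaries[n + 1L]),
    length(groups) == n
  )
  structure(
    list(boundaries = boundaries, n_intervals = n, groups = as.integer(groups)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d intervals, %d size groups, boundaries 0 .. %.4g, Inf\n",
    x$n_intervals, length(unique(x$groups)),
    x$boundaries[x$n_intervals]
  ))
  invisible(x)
}

# Parse a PSMC-style grouping pattern ("4+28", "1*4+25*2+1*6") into an
# integer group id per atomic interval.
parse_group_pattern <- function(pattern, n_intervals) {
  if (is.null(pattern)) return(seq_len(n_intervals))
  terms <- strsplit(trimws(pattern), "+", fixed = TRUE)[[1]]
  sizes <- integer(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (grepl("^\\d+\\*\\d+$", tm)) {
      mk <- as.integer(strsplit(tm, "*", fixed = TRUE)[[1]])
      sizes <- c(sizes, rep(mk[2], mk[1]))
    } else if (grepl("^\\d+$", tm)) {
      sizes <- c(sizes, as.integer(tm))
    } else {
      stop("malformed group pattern term: '", tm, "'", call. = FALSE)
    }
  }
  if (sum(sizes) != n_intervals) {
    stop(sprintf(
      "group pattern covers %d intervals but the grid has %d",
      sum(sizes), n_intervals
    ), call. = FALSE)
  }
  rep(seq_along(sizes), sizes)
}

#' Snap split and admixture times onto grid boundaries
#'
#' The split time `T2` and admixture time `T1` must coincide with interval
#' boundaries. This finds the nearest interior boundaries and (by default)
#' replaces them with the exact requested times, preserving monotonicity.
#'
#' @param grid a [build_time_grid()] object.
#' @param T1,T2 admixture and split times in coalescent units, `0 < T1 < T2`.
#' @param exact replace the nearest boundaries by the exact times (default);
#'   if `FALSE` the grid is untouched and the nearest indices are returned.
#' @return list with the (possibly adjusted) `grid` and boundary indices
#'   `T1_index`, `T2_index` such that
#'   `grid$boundaries[T1_index] == T1` when `exact`.
#' @export
snap_times <- function(grid, T1, T2, exact = TRUE) {
  stopifnot(inherits(grid, "time_grid"), T1 > 0, T2 > T1, is.finite(T2))
  b <- grid$boundaries
  n <- grid$n_intervals
  if (T2 > b[n]) {
    stop("T2 is too ancient for this grid; increase t_max or n_intervals",
         call. = FALSE)
  }
  interior <- 2:n  # cannot snap onto 0 or the last finite boundary's +Inf side
  i1 <- interior[which.min(abs(b[interior] - T1))]
  i2 <- interior[which.min(abs(b[interior] - T2))]
  if (i2 <= i1) i2 <- i1 + 1L
  if (i2 > n) stop("T2 is too ancient for this grid; increase t_max or n_intervals",
                   call. = FALSE)
  if (exact) {
    b[i1] <- T1
    b[i2] <- T2
    if (any(diff(b) <= 0)) {
      stop("snapping T1/T2 broke boundary monotonicity; use a finer grid",
           call. = FALSE)
    }
    grid <- new_time_grid(b, grid$groups)
  }
  list(grid = grid, T1_index = i1, T2_index = i2)
}

# Interval midpoints; the open-ended last interval uses its lower boundary
# plus half of the previous interval's width.
interval_midpoints <- function(grid) {
  b <- grid$boundaries
  n <- grid$n_intervals
  mid <- (b[-1] + b[-(n + 1L)]) / 2
  mid[n] <- b[n] + (b[n] - b[n - 1L]) / 2
  mid
}
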