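# Path-augmented HMM: hidden states are (coalescence-time interval, lineage
# path c), where c records which demes the two sampled lineages occupied
# during the structured period [T1, T2) before coalescing: AA (both stayed
# in A), BB (both migrated to B), AB (one each). Coalescence more recent
# than T1 forces c = AA; during [T1, T2) the demes must match (AA or BB);
# beyond T2 all three are possible.

#' Legal path-augmented state space
#'
#' @param grid a [build_time_grid()] object.
#' @param T1_index,T2_index boundary indices of the admixture and split
#'   times (`1 < T1_index < T2_index <= n_intervals`).
#' @return a data frame of class `path_state_space` with columns `interval`
#'   and `path`, in canonical order: intervals ascending, paths in the order
#'   AA, BB, AB within each interval.
#' @export
path_state_space <- function(grid, T1_index, T2_index) {
  stopifnot(inherits(grid, "time_grid"))
  n <- grid$n_intervals
  if (!(T1_index > 1L && T1_index < T2_index && T2_index <= n)) {
    stop("need 1 < T1_index < T2_index <= n_intervals (T1 must precede T2)",
         call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(j) {
    paths <- if (j < T1_index) "AA"
             else if (j < T2_index) c("AA", "BB")
             else c("AA", "BB", "AB")
    data.frame(interval = j, path = paths, stringsAsFactors = FALSE)
  }))
  structure(rows, class = c("path_state_space", "data.frame"),
            T1_index = as.integer(T1_index), T2_index = as.integer(T2_index),
            n_intervals = n)
}

state_names <- function(space) paste0("t", space$interval, ":", space$path)

#' Migration-choice prior over lineage paths
#'
#' The prior probability of each lineage-path choice made at the admixture
#' event for a pair of lineages that reaches `T1` uncoalesced: both stay in
#' A with probability `(1-gamma)^2`, both derive from B with `gamma^2`, one
#' each with `2*gamma*(1-gamma)`. (Conditioning on the coalescence time
#' additionally reweights these by survival through the structured period.)
#'
#' @param gamma admixture fraction, or a structured demography.
#' @return named numeric `c(AA=, BB=, AB=)` summing to 1.
#' @export
path_choice_prior <- function(gamma) {
  if (inherits(gamma, "structured_demography")) gamma <- gamma$gamma
  stopifnot(gamma >= 0, gamma <= 1)
  c(AA = (1 - gamma)^2, BB = gamma^2, AB = 2 * gamma * (1 - gamma))
}

# classify the new path label given the floating / surviving sequence
# lineages' structured-period demes and the new coalescence interval.
.new_path_label <- function(alpha, d2, d1, T1_index, T2_index) {
  if (alpha < T1_index) return("AA")
  if (alpha < T2_index) return(if (d2 == "A") "AA" else "BB")
  if (d2 == d1) (if (d2 == "A") "AA" else "BB") else "AB"
}

#' Transition and emission model over the path-augmented state space
#'
#' The transitions implement the same generative recombination process as
#' [conditional_transition_matrix()], extended with the new lineage-path
#' label. Two constructions are offered for how the surviving pair's deme
#' path during the structured period enters a transition:
#'
#' * `condition_on_path = FALSE` (default): the old path label is not used;
#'   the surviving pair's demes are drawn from their posterior given the
#'   old coalescence time, exactly as in the time-only kernel. The
#'   time-marginal of the augmented chain then reproduces the time-only HMM
#'   exactly (likelihood and posteriors), and path information accumulates
#'   through state persistence between recombinations.
#' * `condition_on_path = TRUE`: the surviving pair's demes are fixed by
#'   the explicit old label - the full generative conditioning, validated
#'   against the path-labelled Monte-Carlo oracle. The time-marginal is
#'   then only approximately the time-only HMM, because the label carries
#'   information across recombination events.
#'
#' In both cases, averaging rows over the per-time path posterior and
#' summing columns over the new label recovers the time-only kernel to
#' machine precision. Emissions depend on the coalescence time only and are
#' duplicated across path labels.
#'
#' @param model a structured demography.
#' @param representative row-conditioning rule.
#' @param condition_on_path see above.
#' @return list with `space`, the conditional kernel `q` (m x m), the
#'   per-window transition `a`, `emit` (m x 3), the joint `initial`
#'   distribution over (interval, path), `t_bar`, and `p_rec`.
#' @export
path_transition_emission <- function(model,
                                     representative = c("cond_mean",
                                                        "midpoint"),
                                     condition_on_path = FALSE) {
  stopifnot(inherits(model, "structured_demography"))
  representative <- match.arg(representative)
  space <- path_state_space(model$grid, model$T1_index, model$T2_index)
  m <- nrow(space)
  n <- model$grid$n_intervals
  i1 <- model$T1_index; i2 <- model$T2_index
  tb <- representative_times(model, representative)
  b <- model$grid$boundaries
  # column lookup: state index for (interval, path)
  col_of <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("AA", "BB", "AB")))
  for (k in seq_len(m)) col_of[space$interval[k], space$path[k]] <- k
  q <- matrix(0, m, m, dimnames = list(state_names(space), state_names(space)))
  for (r in seq_len(m)) {
    beta <- space$interval[r]
    for (sc in kernel_scenarios(model, tb[beta], space$path[r])) {
      pv <- .scenario_pvec(b, sc$lam, sc$u0, sc$u1)
      for (alpha in which(pv > 0)) {
        lab <- .new_path_label(alpha, sc$d2, sc$d1, i1, i2)
        k <- col_of[alpha, lab]
        q[r, k] <- q[r, k] + sc$w * pv[alpha]
      }
    }
  }
  q <- q / rowSums(q)
  if (!condition_on_path) {
    # average rows over the prior path posterior at the row's time, so the
    # transition does not use the previous locus's label
    comp <- tmrca_components(model)
    T1 <- b[i1]
    for (jj in seq_len(n)) {
      rows <- which(space$interval == jj)
      if (tb[jj] < T1) {
        wc <- c(AA = 1, BB = 0, AB = 0)
      } else {
        wc <- component_posterior_at(model, tb[jj], comp)
        names(wc) <- comp$labels
      }
      mixed <- colSums(q[rows, , drop = FALSE] * wc[space$path[rows]])
      for (r in rows) q[r, ] <- mixed
    }
  }
  # joint prior over (interval, path): path components of the marginal law
  im <- interval_masses(model)          # components AA/BB/AB x intervals
  init <- numeric(m)
  comp_labels <- tmrca_components(model)$labels
  for (jj in seq_len(n)) {
    for (k in seq_along(comp_labels)) {
      mass <- im[k, jj]
      if (mass <= 0) next
      lab <- if (jj < i1) "AA" else comp_labels[k]
      ki <- col_of[jj, lab]
      init[ki] <- init[ki] + mass
    }
  }
  init <- init / sum(init)
  p_rec <- -expm1(-model$rho * tb[space$interval])
  a <- diag(1 - p_rec) + p_rec * q
  emitt <- emission_matrix(model, tb)[space$interval, , drop = FALSE]
  list(space = space, q = q, a = a, emit = emitt, initial = init,
       t_bar = tb, p_rec = p_rec)
}

#' Posterior decoding of ancestral lineage paths
#'
#' Forward-backward over the path-augmented state space, returning per
#' window the marginal path posteriors `P(c | X)`, the probability that
#' coalescence predates the admixture event `P(t > T1 | X)`, the joint
#' `P(c, t > T1 | X)` and the conditional `P(c | X, t > T1)` used to reduce
#' confounding from recent coalescence.
#'
#' @param obs an [obs_sequence()].
#' @param model a structured demography on the same grid.
#' @param representative row-conditioning rule.
#' @param condition_on_path transition construction, see
#'   [path_transition_emission()]; the default keeps the time-marginal
#'   posterior identical to the time-only HMM.
#' @param keep_joint also keep the full joint posterior matrix
#'   (`n_states x n_windows`; may be large).
#' @return object of class `path_posterior` with fields `marginal_c`
#'   (3 x T, rows AA/BB/AB), `p_t_gt_T1`, `joint_c_gt_T1` (3 x T),
#'   `conditional_c` (3 x T, `NA` where `P(t > T1 | X) = 0`), `posterior_t`
#'   (n x T time-marginal), `missing` (logical, N windows), `loglik`,
#'   `bin_size`, `space`, and optionally `joint`.
#' @export
decode_paths <- function(obs, model,
                         representative = c("cond_mean", "midpoint"),
                         condition_on_path = FALSE, keep_joint = FALSE) {
  stopifnot(inherits(obs, "obs_sequence"),
            inherits(model, "structured_demography"))
  representative <- match.arg(representative)
  pte <- path_transition_emission(model, representative, condition_on_path)
  fb <- .fb_core(obs$symbols, pte$a, pte$emit, pte$initial, obs$seg_starts,
                 TRUE, FALSE)
  post <- fb$posterior
  space <- pte$space
  i1 <- attr(space, "T1_index")
  rows_of <- function(path) which(space$path == path)
  marg <- rbind(
    AA = colSums(post[rows_of("AA"), , drop = FALSE]),
    BB = colSums(post[rows_of("BB"), , drop = FALSE]),
    AB = colSums(post[rows_of("AB"), , drop = FALSE])
  )
  gt <- space$interval >= i1
  p_gt <- colSums(post[gt, , drop = FALSE])
  joint_gt <- rbind(
    AA = colSums(post[gt & space$path == "AA", , drop = FALSE]),
    BB = colSums(post[gt & space$path == "BB", , drop = FALSE]),
    AB = colSums(post[gt & space$path == "AB", , drop = FALSE])
  )
  cond <- sweep(joint_gt, 2, p_gt, "/")
  cond[, p_gt <= 0] <- NA_real_
  n <- model$grid$n_intervals
  post_t <- rowsum(post, group = space$interval)
  out <- list(
    marginal_c = marg, p_t_gt_T1 = p_gt, joint_c_gt_T1 = joint_gt,
    conditional_c = cond, posterior_t = post_t,
    missing = obs$symbols == 3L, loglik = fb$loglik,
    bin_size = obs$bin_size, space = space
  )
  if (keep_joint) out$joint <- post
  structure(out, class = "path_posterior")
}

#' @export
print.path_posterior <- function(x, ...) {
  cat(sprintf(
    "<path_posterior> %d windows; mean P(BB)=%.4f P(AB)=%.4f; loglik %.2f\n",
    ncol(x$marginal_c), mean(x$marginal_c["BB", ]),
    mean(x$marginal_c["AB", ]), x$loglik
  ))
  invisible(x)
}

#' Cross-sample expected admixture density H(x)
#'
#' At positions every `stride` bases, computes
#' `H(x) = [sum_j P(c=BB, t>T1 | X^j) + (1/2) P(c=AB, t>T1 | X^j)] /
#' sum_j P(t>T1 | X^j)`, the expected fraction of ancestry derived from the
#' ghost deme B at `x`, conditioned on coalescence predating the admixture
#' event; BB counts fully and AB half. Positions where every sample's
#' window is missing (or the denominator vanishes) are flagged uncallable.
#'
#' @param posteriors list of [decode_paths()] results on shared coordinates.
#' @param stride spacing of evaluated positions in bases (default 1000);
#'   must be a multiple of the bin size. Each position samples the
#'   posterior of the window containing it.
#' @return object of class `h_track`: data frame with `pos` (0-based),
#'   `H` in `[0, 1]` (`NA` where uncallable) and `callable`.
#' @export
h_statistic <- function(posteriors, stride = 1000) {
  stopifnot(length(posteriors) >= 1,
            all(vapply(posteriors, inherits, TRUE, "path_posterior")))
  b <- posteriors[[1]]$bin_size
  T <- length(posteriors[[1]]$p_t_gt_T1)
  for (p in posteriors) {
    if (length(p$p_t_gt_T1) != T || p$bin_size != b) {
      stop("samples have mismatched coordinates", call. = FALSE)
    }
  }
  if (stride %% b != 0) stop("stride must be a multiple of the bin size")
  idx <- seq(1L, T, by = stride %/% b)
  num <- numeric(length(idx)); den <- numeric(length(idx))
  all_missing <- rep(TRUE, length(idx))
  for (p in posteriors) {
    num <- num + p$joint_c_gt_T1["BB", idx] + 0.5 * p$joint_c_gt_T1["AB", idx]
    den <- den + p$p_t_gt_T1[idx]
    all_missing <- all_missing & p$missing[idx]
  }
  callable <- den > 0 & !all_missing
  H <- ifelse(callable, num / den, NA_real_)
  structure(
    data.frame(pos = (idx - 1L) * b, H = H, callable = callable),
    class = c("h_track", "data.frame"), stride = stride, bin_size = b
  )
}

#' Windowed fraction of ancestry from the sampled lineage A
#'
#' Mean of `P(c = AA) + P(c = AB) / 2` (unconditional marginals) in
#' consecutive windows of `window` bases - the expected fraction of the
#' region deriving from the A lineage.
#'
#' @param posterior a [decode_paths()] result.
#' @param window aggregation window in bases (multiple of the bin size).
#' @return data frame with `start`, `end` (0-based half-open) and
#'   `a_fraction` in `[0, 1]`.
#' @export
ancestry_fraction_windows <- function(posterior, window) {
  stopifnot(inherits(posterior, "path_posterior"))
  b <- posterior$bin_size
  if (window %% b != 0) stop("window must be a multiple of the bin size")
  k <- window %/% b
  T <- ncol(posterior$marginal_c)
  grp <- (seq_len(T) - 1L) %/% k
  af <- posterior$marginal_c["AA", ] + posterior$marginal_c["AB", ] / 2
  agg <- tapply(af, grp, mean)
  starts <- as.integer(names(agg)) * window
  data.frame(start = starts, end = pmin(starts + window, T * b),
             a_fraction = as.numeric(agg))
}

#' Binomial enrichment arithmetic
#'
#' Core arithmetic of the tail-enrichment test: with `n` selected positions
#' and background hit probability `p`, the expected number of hits is
#' `n * p`, the fold enrichment is `hits / (n * p)` and significance is the
#' two-sided exact binomial test (minimum-likelihood convention).
#'
#' @param n number of selected positions.
#' @param hits observed hits among them.
#' @param p background probability that a position is a hit.
#' @return list with `expected`, `fold`, `p_value`.
#' @export
binomial_enrichment <- function(n, hits, p) {
  stopifnot(n >= 1, hits >= 0, hits <= n, p > 0, p < 1)
  expected <- n * p
  list(
    expected = expected,
    fold = hits / expected,
    p_value = stats::binom.test(hits, n, p)$p.value
  )
}

# merge intervals (0-based half-open) into a sorted disjoint union
.interval_union <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- numeric(0); ue <- numeric(0)
  for (i in seq_along(start)) {
    if (length(us) && start[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], end[i])
    } else {
      us <- c(us, start[i]); ue <- c(ue, end[i])
    }
  }
  list(start = us, end = ue)
}

.positions_in_intervals <- function(pos, start, end) {
  u <- .interval_union(start, end)
  j <- findInterval(pos, u$start)
  j > 0 & pos < u$end[pmax(j, 1L)]
}

#' Tail enrichment of an H(x) track in genomic intervals
#'
#' Selects the top (or bottom) `pct` of callable positions by H value
#' (ties broken by H then coordinate; exactly `round(n_callable * pct)`
#' positions are taken) and tests whether they hit the supplied intervals
#' (e.g. protein-coding genes) more often than the background fraction of
#' callable positions inside intervals, using the two-sided exact binomial
#' test. A position is a hit if it lies in the union of the intervals
#' (closed-open `[start, end)` coordinates).
#'
#' @param track an [h_statistic()] result.
#' @param intervals data frame (or matrix) with `start` and `end` columns,
#'   0-based half-open, on the track's coordinate space.
#' @param pct tail fraction in `(0, 0.5]` (default 0.01).
#' @param tail `"top"` or `"bottom"`.
#' @param p background hit probability; default: the fraction of callable
#'   positions inside the intervals.
#' @return object of class `enrichment_result`: `n_selected`, `hits`,
#'   `expected`, `fold`, `p_value`, `p`, `distinct_intervals` (how many
#'   distinct intervals are hit), `tail`, `pct`.
#' @export
enrichment_test <- function(track, intervals, pct = 0.01,
                            tail = c("top", "bottom"), p = NULL) {
  tail <- match.arg(tail)
  stopifnot(inherits(track, "h_track"), pct > 0, pct <= 0.5)
  intervals <- as.data.frame(intervals)
  if (!all(c("start", "end") %in% names(intervals)) || nrow(intervals) == 0) {
    stop("intervals must be a non-empty table with start/end columns",
         call. = FALSE)
  }
  ok <- track$callable & !is.na(track$H)
  pos <- track$pos[ok]; H <- track$H[ok]
  n_call <- length(pos)
  if (n_call < 1 / pct) stop("too few callable positions for this tail fraction")
  k <- round(n_call * pct)
  o <- if (tail == "top") order(-H, pos) else order(H, pos)
  sel <- pos[o[seq_len(k)]]
  inside_all <- .positions_in_intervals(pos, intervals$start, intervals$end)
  if (is.null(p)) p <- mean(inside_all)
  inside_sel <- .positions_in_intervals(sel, intervals$start, intervals$end)
  hits <- sum(inside_sel)
  core <- binomial_enrichment(k, hits, p)
  sel_sorted <- sort(sel[inside_sel])
  n_distinct <- sum(
    findInterval(intervals$end - 1e-9, sel_sorted) -
      findInterval(intervals$start - 1e-9, sel_sorted) > 0
  )
  structure(
    list(n_selected = k, hits = hits, expected = core$expected,
         fold = core$fold, p_value = core$p_value, p = p,
         distinct_intervals = n_distinct, tail = tail, pct = pct),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    paste0("<enrichment_result> %s %.2g%%: %d/%d hits (expected %.1f), ",
           "fold %.3f, p = %.3g, %d distinct intervals\n"),
    x$tail, 100 * x$pct, x$hits, x$n_selected, x$expected, x$fold,
    x$p_value, x$distinct_intervals
  ))
  invisible(x)
}
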