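#' Variance of intake rates across patches
#'
#' Population-level deviation-from-IFD measure that remains meaningful
#' when the environment keeps changing and a time-to-IFD cannot be
#' defined: the (population) variance of realised per-capita intake
#' rates. By default it is taken over occupied patches only, each patch
#' weighted equally; empty patches have no realised intake. Both choices
#' are configurable: `patches = "all"` includes empty patches with
#' realised intake 0, `weights = "individual"` weights each patch by its
#' consumer count (the variance across individuals).
#'
#' The variance is 0 exactly when all (weighted) patches have equal
#' intake — in particular at any type-I input-matching state.
#'
#' @param x An `ifd_state` or `patch_landscape` with at least one
#'   occupied patch.
#' @param response A [functional_response()].
#' @param patches `"occupied"` (default) or `"all"`.
#' @param weights `"patch"` (default, unweighted) or `"individual"`.
#' @return Non-negative numeric scalar (variance with divisor `n`, not
#'   `n - 1`).
#' @examples
#' fr <- functional_response("type_I")
#' intake_variance(patch_landscape(c(12, 6), count = c(2, 1)), fr) # 0
#' intake_variance(patch_landscape(c(12, 6), count = c(1, 1)), fr) # 9
#' @export
intake_variance <- function(x, response,
                            patches = c("occupied", "all"),
                            weights = c("patch", "individual")) {
  L <- as_landscape(x)
  patches <- match.arg(patches)
  weights <- match.arg(weights)
  occ <- L$count >= 1L
  if (!any(occ))
    stop("intake variance is undefined: no occupied patch")
  intake <- numeric(length(L$quality))
  intake[occ] <- .intake(response, L$quality[occ], L$count[occ])
  if (patches == "occupied") {
    v <- intake[occ]
    w <- if (weights == "individual") L$count[occ] else rep(1, sum(occ))
  } else {
    v <- intake
    w <- if (weights == "individual") L$count else rep(1, length(v))
  }
  m <- sum(w * v) / sum(w)
  sum(w * (v - m)^2) / sum(w)
}

#' Log-log matching slope
#'
#' Conventional matching-law summary of how consumer numbers track patch
#' resource input: the ordinary least-squares slope of `log(n_p)` against
#' `log(Q_p)` over occupied patches (natural logs; empty patches are
#' excluded since `log 0` is undefined). Slope 1 is perfect input
#' matching; slope < 1 is undermatching (rich patches relatively
#' underexploited, poor patches relatively overexploited); slope 0 means
#' occupancy ignores quality.
#'
#' @param x An `ifd_state` or `patch_landscape`.
#' @return The slope, or `NA_real_` when fewer than 2 occupied patches
#'   with distinct qualities are available.
#' @examples
#' matching_slope(patch_landscape(c(16, 8, 4, 2), count = c(8, 4, 2, 1))) # 1
#' matching_slope(patch_landscape(c(16, 8, 4, 2), count = c(3, 3, 3, 3))) # 0
#' @export
matching_slope <- function(x) {
  L <- as_landscape(x)
  occ <- L$count >= 1L
  if (sum(occ) < 2L) return(NA_real_)
  lx <- log(L$quality[occ])
  ly <- log(L$count[occ])
  sxx <- sum((lx - mean(lx))^2)
  if (sxx == 0) return(NA_real_)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
}

#' Enumerate all ideal-free equilibria of a small landscape
#'
#' Brute-force oracle: enumerates every composition of `N` consumers over
#' the `P` patches of `Q` and returns those satisfying the exact IFD
#' inequalities ([is_ifd()]). Guarded to small instances
#' (`P <= 6`, `N <= 12`) where exhaustive enumeration is cheap; intended
#' for testing the predicate and the simulators' absorbing states.
#'
#' @param Q Positive quality vector (`length(Q) <= 6`).
#' @param N Population size (`0 <= N <= 12`).
#' @param response A [functional_response()].
#' @return Integer matrix, one row per equilibrium count vector (possibly
#'   zero rows, though a pure equilibrium always exists for positive `Q`).
#' @examples
#' enumerate_equilibria(c(12, 6), 3, functional_response("type_I")) # [2, 1]
#' @export
enumerate_equilibria <- function(Q, N, response = functional_response("type_I")) {
  P <- length(Q)
  if (P > 6L) stop("enumeration guard: at most 6 patches")
  if (N > 12L) stop("enumeration guard: at most 12 consumers")
  if (N < 0L) stop("`N` must be non-negative")
  if (any(Q <= 0)) stop("all qualities must be positive")
  comp <- .compositions(as.integer(N), P)
  dimnames(comp) <- NULL
  keep <- apply(comp, 1L, function(cnt) .ifd_counts(Q, cnt, response))
  comp[keep, , drop = FALSE]
}

# all compositions of n into k non-negative parts, one per row
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(0:n, function(j) cbind(j, .compositions(n - j, k - 1L))))
}

#' Summarise a batch of runs
#'
#' Collapses a collection of `ifd_run` results (or an already-tidy
#' per-run data frame, e.g. from [run_sweep()]) into a one-row-per-run
#' table plus per-setting aggregates: mean/median/quartiles of
#' time-to-IFD and time-to-stop, the proportion of runs whose final state
#' is a true IFD (`proportion_true_ifd`), mean final intake variance and
#' matching slope, and the distribution of per-consumer move counts.
#'
#' @param results Non-empty list of `ifd_run` objects, or a per-run
#'   `data.frame` with the columns produced by [as.data.frame.ifd_run()].
#' @param by Character vector of column names to aggregate within
#'   (empty = one overall summary row).
#' @return A list of class `ifd_batch` with elements `runs` (tidy per-run
#'   data frame) and `summary` (one row per setting).
#' @export
summarize_batch <- function(results, by = character()) {
  if (is.data.frame(results)) {
    runs <- results
  } else {
    if (length(results) == 0L) stop("empty batch: nothing to summarise")
    runs <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (nrow(runs) == 0L) stop("empty batch: nothing to summarise")
  groups <- if (length(by)) split(runs, runs[by], drop = TRUE) else list(all = runs)
  summary <- do.call(rbind, lapply(groups, function(g) {
    row <- data.frame(
      n_runs = nrow(g),
      proportion_true_ifd = mean(g$reached_true_ifd),
      mean_time_to_stop = mean(g$time_to_stop),
      mean_time_to_ifd = mean(g$time_to_ifd, na.rm = TRUE),
      median_time_to_ifd = stats::median(g$time_to_ifd, na.rm = TRUE),
      q25_time_to_ifd = unname(stats::quantile(g$time_to_ifd, 0.25, na.rm = TRUE)),
      q75_time_to_ifd = unname(stats::quantile(g$time_to_ifd, 0.75, na.rm = TRUE)),
      mean_intake_variance = mean(g$intake_variance),
      mean_matching_slope = mean(g$matching_slope, na.rm = TRUE),
      mean_max_moves = mean(g$max_moves),
      max_max_moves = max(g$max_moves),
      share_moved_at_most_once = mean(g$max_moves <= 1L)
    )
    if (length(by)) cbind(g[1L, by, drop = FALSE], row, row.names = NULL) else row
  }))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary), class = "ifd_batch")
}

#' @export
print.ifd_batch <- function(x, ...) {
  cat(sprintf("IFD batch: %d runs, %d summary setting(s)\n",
              nrow(x$runs), nrow(x$summary)))
  print(x$summary, ...)
  invisible(x)
}
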