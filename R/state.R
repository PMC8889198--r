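#' Place a consumer population on a landscape
#'
#' Creates the simulation state: a population of `N` consumers, each with
#' an activity level (its per-opportunity assessment probability in
#' discrete time, or assessment rate in continuous time), assigned to
#' patches according to a placement mode.
#'
#' Activity composition follows a deterministic mixture rule: the first
#' `round(proportion_active * N)` consumers receive `activity_high`, the
#' rest `activity_low` (base-R `round()`, i.e. half-to-even). Pass
#' `activities` for full per-consumer control.
#'
#' Placement modes:
#' * `uniform_random` — each consumer on an independently uniform patch;
#' * `one_per_patch` — `N` distinct patches chosen at random (requires
#'   `N <= P`), emulating very low initial density;
#' * `single_patch` — the whole population on one random patch.
#'
#' @param landscape A [patch_landscape()]; any existing counts are ignored
#'   and recomputed from the placement.
#' @param N Population size (ignored when `activities` is given).
#' @param activities Optional explicit per-consumer activity vector in
#'   \[0, 1\].
#' @param activity_high,activity_low Activity levels of the two
#'   personality types in the mixture.
#' @param proportion_active Fraction of the population at `activity_high`.
#' @param mode Placement mode, see above.
#' @param patch Optional explicit per-consumer patch assignment
#'   (overrides `mode`).
#' @return An object of class `ifd_state`: list with fields `landscape`
#'   (counts filled in), `activity`, `patch`, `moves`.
#' @examples
#' L <- generate_landscape(2, 2, function(n) c(12, 6, 3, 1))
#' set.seed(1)
#' place_population(L, N = 4, proportion_active = 0.5)
#' @export
place_population <- function(landscape, N = NULL, activities = NULL,
                             activity_high = 0.8, activity_low = 0.2,
                             proportion_active = 0.5,
                             mode = c("uniform_random", "one_per_patch",
                                      "single_patch"),
                             patch = NULL) {
  L <- as_landscape(landscape)
  P <- length(L$quality)
  mode <- match.arg(mode)
  if (is.null(activities)) {
    if (is.null(N)) stop("either `N` or `activities` must be supplied")
    N <- as.integer(N)
    if (N < 1L) stop("population size must be at least 1")
    n_active <- as.integer(round(proportion_active * N))
    activities <- c(rep(activity_high, n_active), rep(activity_low, N - n_active))
  } else {
    N <- length(activities)
  }
  if (any(activities < 0) || any(activities > 1))
    stop("activity levels must lie in [0, 1]")
  if (is.null(patch)) {
    patch <- switch(mode,
      uniform_random = sample.int(P, N, replace = TRUE),
      one_per_patch = {
        if (N > P) stop("one_per_patch placement requires N <= number of patches")
        sample.int(P, N, replace = FALSE)
      },
      single_patch = rep(sample.int(P, 1L), N)
    )
  } else {
    patch <- as.integer(patch)
    if (length(patch) != N) stop("`patch` must have one entry per consumer")
  }
  if (any(patch < 1L) || any(patch > P)) stop("patch assignment out of range")
  L$count <- tabulate(patch, nbins = P)
  structure(
    list(landscape = L, activity = as.numeric(activities),
         patch = as.integer(patch), moves = integer(N)),
    class = "ifd_state"
  )
}

#' @export
print.ifd_state <- function(x, ...) {
  cat(sprintf("IFD simulation state: %d consumers on %d patches\n",
              length(x$patch), length(x$landscape$quality)))
  cat(sprintf("  activity: [%g, %g]; moves so far: %d\n",
              min(x$activity), max(x$activity), sum(x$moves)))
  invisible(x)
}

#' Population size of a state
#' @param state An `ifd_state`.
#' @return Integer number of consumers.
#' @export
population_size <- function(state) {
  stopifnot(inherits(state, "ifd_state"))
  length(state$patch)
}
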