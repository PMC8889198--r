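#' Simulation configuration
#'
#' Bundles a full scenario description: landscape, population, functional
#' response, scheduler, stopping rule, environmental change, and seed.
#' The configuration is a plain validated list; [run_sim()] (or
#' [run_discrete()] / [run_gillespie()] directly) executes it.
#'
#' Exactly one stopping rule is active besides the `max_steps` /
#' `max_time` safeguard:
#' * `true_ifd` — stop as soon as the exact IFD predicate [is_ifd()]
#'   holds (checked at time 0 and after every accepted move or quality
#'   change; the state cannot change otherwise);
#' * `quiescence` — stop after `quiescence_K` consecutive time steps
#'   without a patch change (discrete scheduler only; a consumer that
#'   assessed but stayed counts as quiescent). This is the criterion that
#'   mistakes the inactivity of low-activity individuals for equilibrium.
#'
#' With `env_change_period = T > 0` (discrete only) the quality vector is
#' changed at the start of every `T`-th step, before that step's movement
#' decision: `permute` shuffles the existing qualities across patches
#' (total input conserved), `redraw` re-samples them from `quality_fn`.
#'
#' @param landscape Optional explicit [patch_landscape()]; if `NULL` one
#'   is generated from `n_rows`, `n_cols`, `quality_fn` using the run's
#'   seeded RNG stream.
#' @inheritParams generate_landscape
#' @inheritParams place_population
#' @param placement Placement mode passed to [place_population()].
#' @param initial_patch Optional explicit per-consumer initial patch.
#' @param response A [functional_response()], or `"type_I"` / `"type_II"`
#'   (then `attack_rate` and `handling_time` apply).
#' @param attack_rate,handling_time Type II parameters used when
#'   `response` is given as a character kind.
#' @param scheduler `"discrete"` (one uniformly chosen consumer per step,
#'   Bernoulli(activity) assessment) or `"gillespie"` (continuous time,
#'   independent assessment at rate = activity).
#' @param stopping `"true_ifd"` or `"quiescence"` (see above).
#' @param quiescence_K Quiescence window in steps (default 50).
#' @param max_steps,max_time Safeguard bounds for the two schedulers.
#' @param env_change_period Steps between quality changes; 0 = static.
#' @param env_change_mode `"permute"` or `"redraw"`.
#' @param seed Integer seed for the run (landscape draw, placement, and
#'   dynamics all flow from it); `NULL` uses the current RNG state.
#' @param record_moves If `TRUE` the result carries a per-move event log
#'   (`time, consumer, from, to`).
#' @param state Optional pre-built `ifd_state`; overrides all landscape
#'   and population fields (the seed then drives only the dynamics).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(N = 20, seed = 1)
#' res <- run_sim(cfg)
#' res$time_to_stop
#' @export
sim_config <- function(landscape = NULL,
                       n_rows = 7L, n_cols = 7L, quality_fn = NULL,
                       N = 40L,
                       activities = NULL,
                       activity_high = 0.8, activity_low = 0.2,
                       proportion_active = 0.5,
                       placement = c("uniform_random", "one_per_patch",
                                     "single_patch"),
                       initial_patch = NULL,
                       response = functional_response("type_I"),
                       attack_rate = 1, handling_time = 1,
                       scheduler = c("discrete", "gillespie"),
                       stopping = c("true_ifd", "quiescence"),
                       quiescence_K = 50L,
                       max_steps = 1e6, max_time = 1e5,
                       env_change_period = 0L,
                       env_change_mode = c("permute", "redraw"),
                       seed = NULL,
                       record_moves = FALSE,
                       state = NULL) {
  placement <- match.arg(placement)
  scheduler <- match.arg(scheduler)
  stopping <- match.arg(stopping)
  env_change_mode <- match.arg(env_change_mode)
  if (is.character(response))
    response <- functional_response(response, attack_rate = attack_rate,
                                    handling_time = handling_time)
  stopifnot(inherits(response, "functional_response"))
  if (scheduler == "gillespie") {
    if (stopping == "quiescence")
      stop("the quiescence stopping rule is defined for the discrete scheduler only")
    if (env_change_period > 0)
      stop("environmental change is supported by the discrete scheduler only")
  }
  if (quiescence_K < 1L) stop("`quiescence_K` must be a positive integer")
  if (env_change_period < 0) stop("`env_change_period` must be >= 0")
  if (!is.null(state)) stopifnot(inherits(state, "ifd_state"))
  if (!is.null(landscape)) stopifnot(inherits(landscape, "patch_landscape"))
  structure(
    list(landscape = landscape, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), quality_fn = quality_fn,
         N = as.integer(N), activities = activities,
         activity_high = activity_high, activity_low = activity_low,
         proportion_active = proportion_active, placement = placement,
         initial_patch = initial_patch, response = response,
         scheduler = scheduler, stopping = stopping,
         quiescence_K = as.integer(quiescence_K),
         max_steps = max_steps, max_time = max_time,
         env_change_period = as.integer(env_change_period),
         env_change_mode = env_change_mode,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         record_moves = isTRUE(record_moves), state = state),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("IFD simulation config: %s scheduler, %s stopping, N = %s, seed = %s\n",
              x$scheduler, x$stopping,
              if (is.null(x$state)) x$N else length(x$state$patch),
              if (is.null(x$seed)) "<current RNG>" else x$seed))
  invisible(x)
}

# seed the run RNG and build the initial state from a config
.init_run <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(config$state)) return(config$state)
  L <- config$landscape %||%
    generate_landscape(config$n_rows, config$n_cols, config$quality_fn)
  place_population(L, N = config$N, activities = config$activities,
                   activity_high = config$activity_high,
                   activity_low = config$activity_low,
                   proportion_active = config$proportion_active,
                   mode = config$placement, patch = config$initial_patch)
}

#' Run a configured simulation
#'
#' Dispatches to [run_discrete()] or [run_gillespie()] according to
#' `config$scheduler`.
#'
#' @param config A [sim_config()].
#' @return An `ifd_run` result, see [run_discrete()].
#' @export
run_sim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scheduler == "discrete") run_discrete(config) else run_gillespie(config)
}

# shared RunResult builder; metrics are evaluated on the final state
.new_run <- function(config, quality, count, initial_quality, initial_count,
                     activity, moves, time_to_stop, stop_reason, t_last_move,
                     n_decisions, move_log) {
  resp <- config$response
  reached <- .ifd_counts(quality, count, resp)
  final <- patch_landscape(quality, n_rows = 1L, n_cols = length(quality),
                           count = count)
  structure(
    list(
      scheduler = config$scheduler,
      stopping = config$stopping,
      N = length(activity),
      seed = config$seed,
      time_to_stop = time_to_stop,
      stop_reason = stop_reason,
      reached_true_ifd = reached,
      time_to_ifd = if (reached) t_last_move else NA_real_,
      n_decisions = n_decisions,
      moves = moves,
      max_moves = if (length(moves)) max(moves) else 0L,
      total_moves = sum(moves),
      activity = activity,
      initial_count = initial_count,
      final_count = count,
      initial_quality = initial_quality,
      quality = quality,
      intake_variance = intake_variance(final, resp),
      matching_slope = matching_slope(final),
      move_log = move_log,
      config = config
    ),
    class = "ifd_run"
  )
}

#' @export
print.ifd_run <- function(x, ...) {
  cat(sprintf("IFD run (%s scheduler, %s stopping): stopped at %g (%s)\n",
              x$scheduler, x$stopping, x$time_to_stop, x$stop_reason))
  cat(sprintf("  reached true IFD: %s; moves: %d total, max %d per consumer\n",
              x$reached_true_ifd, x$total_moves, x$max_moves))
  cat(sprintf("  intake variance %.4g; matching slope %s\n",
              x$intake_variance,
              if (is.na(x$matching_slope)) "NA" else sprintf("%.3f", x$matching_slope)))
  invisible(x)
}

#' One row per run, for tidy aggregation
#' @param x An `ifd_run`.
#' @param ... Unused.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.ifd_run <- function(x, ...) {
  data.frame(
    scheduler = x$scheduler, stopping = x$stopping, N = x$N,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    time_to_stop = x$time_to_stop, stop_reason = x$stop_reason,
    reached_true_ifd = x$reached_true_ifd, time_to_ifd = x$time_to_ifd,
    total_moves = x$total_moves, max_moves = x$max_moves,
    intake_variance = x$intake_variance, matching_slope = x$matching_slope,
    stringsAsFactors = FALSE
  )
}
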