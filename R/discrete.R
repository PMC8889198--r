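#' Discrete-time sequential-decision scheduler
#'
#' One time step = one decision opportunity: a single consumer is chosen
#' uniformly at random; with probability equal to its activity it assesses
#' its situation ([best_move()]) and relocates if a strictly better patch
#' exists. Time advances by exactly 1 per step, so larger populations
#' mechanically need more steps per capita — the time-scale property this
#' scheduler exists to expose (contrast [run_gillespie()]).
#'
#' Stopping: under `true_ifd` the run stops at the first step after which
#' [is_ifd()] holds (checked at step 0 and after every accepted move or
#' quality change — between those events the state is unchanged); under
#' `quiescence` it stops once `quiescence_K` consecutive steps pass
#' without a patch change. `max_steps` always applies as a safeguard and
#' yields `stop_reason = "max_bound"` rather than an error.
#'
#' @param config A [sim_config()] with `scheduler = "discrete"`.
#' @return An object of class `ifd_run` with fields `time_to_stop`,
#'   `stop_reason` (`"true_ifd"`, `"quiescence"` or `"max_bound"`),
#'   `reached_true_ifd` (always evaluated with the exact predicate at
#'   stop, whatever the stopping rule), `time_to_ifd` (time of the last
#'   accepted move if the final state is a true IFD, else `NA`),
#'   per-consumer move counts, initial/final counts and qualities,
#'   final-state metrics (`intake_variance`, `matching_slope`), the seed,
#'   and (if requested) a `move_log` data frame.
#' @examples
#' res <- run_discrete(sim_config(N = 10, seed = 7))
#' res$time_to_stop; res$reached_true_ifd
#' @export
run_discrete <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scheduler != "discrete")
    stop("`run_discrete()` requires a config with scheduler = \"discrete\"")
  state <- .init_run(config)
  resp <- config$response
  quality <- state$landscape$quality
  count <- state$landscape$count
  patch <- state$patch
  activity <- state$activity
  N <- length(patch)
  P <- length(quality)
  initial_quality <- quality
  initial_count <- count
  moves <- integer(N)
  qfn <- config$quality_fn %||% function(n) stats::runif(n, 1, 10)
  env_T <- config$env_change_period
  check_ifd <- config$stopping == "true_ifd"
  K <- config$quiescence_K
  rec <- config$record_moves
  if (rec) {
    cap <- 256L
    lg_t <- numeric(cap); lg_i <- integer(cap); lg_from <- integer(cap)
    lg_to <- integer(cap); n_log <- 0L
  }

  t <- 0
  quiescent <- 0L
  env_clock <- 0L
  t_last_move <- 0
  n_decisions <- 0L
  stop_reason <- NULL
  if (check_ifd && .ifd_counts(quality, count, resp)) stop_reason <- "true_ifd"

  while (is.null(stop_reason)) {
    if (t >= config$max_steps) { stop_reason <- "max_bound"; break }
    # environmental change precedes the step's movement decision
    changed_env <- FALSE
    if (env_T > 0L) {
      env_clock <- env_clock + 1L
      if (env_clock >= env_T) {
        quality <- if (config$env_change_mode == "permute")
          quality[sample.int(P)] else qfn(P)
        env_clock <- 0L
        changed_env <- TRUE
      }
    }
    i <- sample.int(N, 1L)
    moved <- FALSE
    if (stats::runif(1L) < activity[i]) {
      n_decisions <- n_decisions + 1L
      tgt <- .best_target(quality, count, patch[i], resp)
      if (!is.na(tgt)) {
        count[patch[i]] <- count[patch[i]] - 1L
        count[tgt] <- count[tgt] + 1L
        if (rec) {
          n_log <- n_log + 1L
          if (n_log > cap) {
            cap <- cap * 2L
            length(lg_t) <- cap; length(lg_i) <- cap
            length(lg_from) <- cap; length(lg_to) <- cap
          }
          lg_t[n_log] <- t + 1; lg_i[n_log] <- i
          lg_from[n_log] <- patch[i]; lg_to[n_log] <- tgt
        }
        patch[i] <- tgt
        moves[i] <- moves[i] + 1L
        moved <- TRUE
      }
    }
    t <- t + 1
    if (moved) {
      quiescent <- 0L
      t_last_move <- t
    } else {
      quiescent <- quiescent + 1L
    }
    if (check_ifd && (moved || changed_env) &&
        .ifd_counts(quality, count, resp)) {
      stop_reason <- "true_ifd"
    } else if (!check_ifd && quiescent >= K) {
      stop_reason <- "quiescence"
    }
  }

  move_log <- NULL
  if (rec) {
    idx <- seq_len(n_log)
    move_log <- data.frame(time = lg_t[idx], consumer = lg_i[idx],
                           from = lg_from[idx], to = lg_to[idx])
  }
  .new_run(config, quality, count, initial_quality, initial_count,
           activity, moves, time_to_stop = t, stop_reason = stop_reason,
           t_last_move = t_last_move, n_decisions = n_decisions,
           move_log = move_log)
}

#' Apply one scheduled environmental change to a state
#'
#' Exposed for stepwise experimentation with temporally varying patch
#' quality: `permute` shuffles the existing quality vector across patches
#' (the multiset of qualities, hence total resource input, is conserved);
#' `redraw` replaces it with a fresh draw from `quality_fn`. Consumer
#' counts are untouched, so [is_ifd()] may flip from `TRUE` to `FALSE`
#' (or back) without any movement.
#'
#' @param state An `ifd_state`.
#' @param mode `"permute"` or `"redraw"`.
#' @param quality_fn Sampler for `redraw`, defaulting to `runif(n, 1, 10)`.
#' @return The state with its quality vector changed.
#' @export
apply_env_change <- function(state, mode = c("permute", "redraw"),
                             quality_fn = NULL) {
  stopifnot(inherits(state, "ifd_state"))
  mode <- match.arg(mode)
  P <- length(state$landscape$quality)
  qfn <- quality_fn %||% function(n) stats::runif(n, 1, 10)
  q <- if (mode == "permute") state$landscape$quality[sample.int(P)] else qfn(P)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("quality distribution produced non-positive or non-finite values")
  state$landscape$quality <- q
  state
}
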