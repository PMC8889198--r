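#' Continuous-time event-based scheduler (Gillespie algorithm)
#'
#' Reformulates the discrete scheduler on a natural time scale: each
#' consumer assesses its situation independently in continuous time at a
#' rate equal to its activity level. Waiting times between assessment
#' events are exponential with the summed rate `Lambda = sum(activity)`,
#' and the assessing consumer is drawn with probability proportional to
#' its own rate — the selected consumer assesses unconditionally (the
#' rate *is* the activity; there is no second Bernoulli trial). The
#' movement rule, tie-breaking, and IFD predicate are shared verbatim
#' with the discrete scheduler; only the clock differs.
#'
#' Stopping: `true_ifd` (checked at time 0 and after every accepted move),
#' with `max_time` as safeguard; `time_to_stop` is the event time of the
#' last accepted move (0 if the initial state is already an IFD).
#'
#' @param config A [sim_config()] with `scheduler = "gillespie"`.
#' @return An `ifd_run`, as for [run_discrete()]; `time_to_stop` is
#'   continuous time and `n_decisions` counts assessment events.
#' @examples
#' res <- run_gillespie(sim_config(N = 10, scheduler = "gillespie", seed = 7))
#' res$time_to_stop
#' @export
run_gillespie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scheduler != "gillespie")
    stop("`run_gillespie()` requires a config with scheduler = \"gillespie\"")
  state <- .init_run(config)
  resp <- config$response
  quality <- state$landscape$quality
  count <- state$landscape$count
  patch <- state$patch
  activity <- state$activity
  N <- length(patch)
  Lambda <- sum(activity)
  if (Lambda <= 0)
    stop("all activities are zero: no assessment event can ever occur")
  cum <- cumsum(activity) / Lambda
  initial_quality <- quality
  initial_count <- count
  moves <- integer(N)
  rec <- config$record_moves
  if (rec) {
    cap <- 256L
    lg_t <- numeric(cap); lg_i <- integer(cap); lg_from <- integer(cap)
    lg_to <- integer(cap); n_log <- 0L
  }

  t <- 0
  t_last_move <- 0
  n_decisions <- 0L
  stop_reason <- NULL
  time_to_stop <- 0
  if (.ifd_counts(quality, count, resp)) stop_reason <- "true_ifd"

  while (is.null(stop_reason)) {
    wt <- stats::rexp(1L, rate = Lambda)
    if (t + wt > config$max_time) {
      stop_reason <- "max_bound"
      time_to_stop <- config$max_time
      break
    }
    t <- t + wt
    i <- findInterval(stats::runif(1L), cum) + 1L
    if (i > N) i <- N
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
        lg_t[n_log] <- t; lg_i[n_log] <- i
        lg_from[n_log] <- patch[i]; lg_to[n_log] <- tgt
      }
      patch[i] <- tgt
      moves[i] <- moves[i] + 1L
      t_last_move <- t
      if (.ifd_counts(quality, count, resp)) {
        stop_reason <- "true_ifd"
        time_to_stop <- t_last_move
      }
    }
  }

  move_log <- NULL
  if (rec) {
    idx <- seq_len(n_log)
    move_log <- data.frame(time = lg_t[idx], consumer = lg_i[idx],
                           from = lg_from[idx], to = lg_to[idx])
  }
  .new_run(config, quality, count, initial_quality, initial_count,
           activity, moves, time_to_stop = time_to_stop,
           stop_reason = stop_reason, t_last_move = t_last_move,
           n_decisions = n_decisions, move_log = move_log)
}

#' Draw the next assessment event
#'
#' One Gillespie draw: an exponential waiting time with rate
#' `Lambda = sum(activity)` and a consumer selected with probability
#' `activity[i] / Lambda`. Exposed for testing and for building custom
#' event loops.
#'
#' @param state An `ifd_state` (only the `activity` field is used).
#' @return A list with `waiting_time` and `consumer`.
#' @export
next_event <- function(state) {
  stopifnot(inherits(state, "ifd_state"))
  activity <- state$activity
  Lambda <- sum(activity)
  if (Lambda <= 0)
    stop("all activities are zero: no assessment event can ever occur")
  wt <- stats::rexp(1L, rate = Lambda)
  i <- findInterval(stats::runif(1L), cumsum(activity) / Lambda) + 1L
  if (i > length(activity)) i <- length(activity)
  list(waiting_time = wt, consumer = i)
}
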