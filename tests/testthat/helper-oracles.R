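# Independent oracles, deliberately written in a different style from the
# package internals (explicit double loops, normal equations) so that they
# cannot share a bug with the code paths they check.

# intake formula restated from first principles
oracle_intake <- function(kind, Q, n, a = 1, h = 1) {
  x <- Q / n
  if (kind == "type_I") x else a * x / (1 + a * h * x)
}

# IFD predicate by exhaustive pairwise comparison
oracle_is_ifd <- function(Q, count, kind = "type_I", a = 1, h = 1) {
  P <- length(Q)
  for (p in seq_len(P)) {
    if (count[p] < 1) next
    here <- oracle_intake(kind, Q[p], count[p], a, h)
    for (q in seq_len(P)) {
      if (q == p) next
      if (oracle_intake(kind, Q[q], count[q] + 1, a, h) > here) return(FALSE)
    }
  }
  TRUE
}

# all count vectors summing to N over P patches, built via expand.grid
# (different construction from the package's recursive compositions)
oracle_count_vectors <- function(N, P) {
  g <- do.call(expand.grid, rep(list(0:N), P))
  m <- as.matrix(g[rowSums(g) == N, , drop = FALSE])
  dimnames(m) <- NULL
  m
}

# OLS slope via the normal equations
oracle_slope <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))[2]
}

# compact comparable fingerprint of a run for seed-matched equivalence
run_fingerprint <- function(res) {
  list(
    time = res$time_to_stop,
    reason = res$stop_reason,
    final = res$final_count,
    moves = res$moves,
    log = res$move_log
  )
}

# a random mixed-activity scenario on a 7x7 grid, shared by equivalence
# and move-bound tests
random_config <- function(seed, N, scheduler = "discrete",
                          response = functional_response("type_I"),
                          proportion_active = 0.5,
                          activity_high = 0.8, activity_low = 0.2) {
  sim_config(N = N, scheduler = scheduler, response = response,
             proportion_active = proportion_active,
             activity_high = activity_high, activity_low = activity_low,
             stopping = "true_ifd", seed = seed, record_moves = TRUE)
}
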