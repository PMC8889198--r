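fr1 <- functional_response("type_I")

state_on <- function(Q, patch, activities) {
  place_population(patch_landscape(Q), activities = activities, patch = patch)
}

test_that("a fully inactive population never moves and stops by quiescence", {
  s <- state_on(c(12, 6), c(2, 2, 2), activities = rep(0, 3))
  res <- run_discrete(sim_config(state = s, stopping = "quiescence",
                                 quiescence_K = 50, seed = 4))
  expect_identical(res$stop_reason, "quiescence")
  expect_equal(res$time_to_stop, 50)
  expect_identical(res$total_moves, 0L)
  expect_identical(res$final_count, s$landscape$count)
  # three consumers piled on the poor patch are far from the IFD
  expect_false(res$reached_true_ifd)
})

test_that("a lone always-active consumer relocates to the best patch in one step", {
  s <- state_on(c(12, 6), 2L, activities = 1)
  res <- run_discrete(sim_config(state = s, stopping = "true_ifd", seed = 1,
                                 record_moves = TRUE))
  expect_identical(res$stop_reason, "true_ifd")
  expect_equal(res$time_to_stop, 1)
  expect_identical(res$final_count, c(1L, 0L))
  expect_identical(res$move_log$from, 2L)
  expect_identical(res$move_log$to, 1L)
})

test_that("an initial IFD stops immediately at time 0", {
  s <- state_on(c(12, 6), c(1, 1, 2), activities = rep(0.5, 3))
  res <- run_discrete(sim_config(state = s, stopping = "true_ifd", seed = 1))
  expect_equal(res$time_to_stop, 0)
  expect_identical(res$stop_reason, "true_ifd")
  expect_true(res$reached_true_ifd)
  expect_equal(res$time_to_ifd, 0)
})

test_that("stopping by the exact predicate always certifies a true IFD", {
  set.seed(20)
  for (seed in sample.int(1e6, 25)) {
    res <- run_discrete(random_config(seed, N = 12))
    expect_identical(res$stop_reason, "true_ifd")
    expect_true(res$reached_true_ifd)
    expect_true(oracle_is_ifd(res$quality, res$final_count))
  }
})

test_that("runs are reproducible from the config seed alone", {
  cfg <- sim_config(N = 15, proportion_active = 0.4, seed = 91,
                    record_moves = TRUE)
  a <- run_discrete(cfg)
  b <- run_discrete(cfg)
  expect_equal(run_fingerprint(a), run_fingerprint(b))
  expect_equal(a$quality, b$quality)
})

test_that("max_steps safeguard reports max_bound instead of erroring", {
  s <- state_on(c(12, 6), c(2, 2, 2), activities = rep(0, 3))
  res <- run_discrete(sim_config(state = s, stopping = "true_ifd",
                                 max_steps = 25, seed = 1))
  expect_identical(res$stop_reason, "max_bound")
  expect_equal(res$time_to_stop, 25)
  expect_false(res$reached_true_ifd)
})

test_that("quiescence counter counts still steps, resetting on each move", {
  # one active consumer that must make exactly one move early on
  s <- state_on(c(12, 6), c(2L, 1L, 1L), activities = c(1, 0, 0))
  res <- run_discrete(sim_config(state = s, stopping = "quiescence",
                                 quiescence_K = 30, seed = 2,
                                 record_moves = TRUE))
  expect_identical(res$stop_reason, "quiescence")
  if (res$total_moves > 0) {
    expect_equal(res$time_to_stop, max(res$move_log$time) + 30)
  } else {
    expect_equal(res$time_to_stop, 30)
  }
})

test_that("permuting qualities conserves the multiset and can break an IFD", {
  s <- state_on(c(12, 6), c(1, 1, 2), activities = rep(1, 3))
  expect_true(is_ifd(s, fr1))
  set.seed(1)
  out <- replicate(50, sort(apply_env_change(s, "permute")$landscape$quality))
  expect_true(all(out == c(6, 12)))
  # the swap leaves counts [2,1] facing Q [6,12]: patch 1 pays 3 < 12/2
  s$landscape$quality <- c(6, 12)
  expect_false(is_ifd(s, fr1))
})

test_that("redraw resamples qualities from the configured distribution", {
  s <- state_on(c(12, 6), c(1, 2), activities = c(1, 1))
  set.seed(5)
  s2 <- apply_env_change(s, "redraw", quality_fn = function(n) rep(3, n))
  expect_equal(s2$landscape$quality, c(3, 3))
  expect_identical(s2$landscape$count, s$landscape$count)
})

test_that("periodic environmental change keeps runs alive past each change", {
  res <- run_discrete(sim_config(N = 12, n_rows = 2, n_cols = 2,
                                 stopping = "quiescence", quiescence_K = 50,
                                 env_change_period = 10,
                                 env_change_mode = "permute",
                                 max_steps = 5000, seed = 33,
                                 record_moves = TRUE))
  expect_true(res$stop_reason %in% c("quiescence", "max_bound"))
  # total resource input is conserved under permutation
  expect_equal(sort(res$quality), sort(res$initial_quality))
})

test_that("exact stopping is never slower in distribution for all-active populations", {
  times_for <- function(prop) {
    vapply(1:40, function(k) {
      run_discrete(sim_config(N = 20, proportion_active = prop,
                              activity_high = 0.8, activity_low = 0.2,
                              stopping = "true_ifd",
                              seed = child_seed(77, round(prop * 10) + 1, k)
                              ))$time_to_stop
    }, numeric(1))
  }
  t_active <- times_for(1)
  t_mixed <- times_for(0.25)
  expect_lt(median(t_active), median(t_mixed))
})
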