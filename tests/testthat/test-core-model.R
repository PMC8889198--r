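fr1 <- functional_response("type_I")

test_that("intake rate matches the closed forms and rejects empty patches", {
  expect_equal(intake_rate(fr1, 10, 2), 5)
  expect_equal(intake_rate(functional_response("type_II", 1, 0), 10, 2), 5)
  expect_equal(intake_rate(functional_response("type_II", 1, 1), 10, 2), 5 / 6)
  # vectorised and strictly decreasing in n for fixed Q
  for (fr in list(fr1, functional_response("type_II", 2, 0.5))) {
    v <- intake_rate(fr, 7, 1:10)
    expect_length(v, 10)
    expect_true(all(diff(v) < 0))
  }
  expect_error(intake_rate(fr1, 10, 0), "empty patch")
  expect_error(intake_rate(fr1, -1, 1), "positive")
})

test_that("intake is strictly increasing in Q/n for both response kinds", {
  ratios <- sort(runif(50, 0.01, 50))
  for (fr in list(fr1, functional_response("type_II", 0.7, 2.3))) {
    v <- intake_rate(fr, ratios, 1)
    expect_true(all(diff(v) > 0))
  }
})

test_that("best_move picks the strictly better patch and stays on ties", {
  s <- place_population(patch_landscape(c(12, 6)), activities = rep(1, 3),
                        patch = c(1, 1, 1))
  # current 4, prospective on patch 2 = 6/1: move
  expect_identical(best_move(s, 1, fr1), 2L)
  # Q=[10,10], counts=[2,1]: current 5, prospective 10/2 = 5, not strict: stay
  s2 <- place_population(patch_landscape(c(10, 10)), activities = rep(1, 3),
                         patch = c(1, 1, 2))
  expect_identical(best_move(s2, 1, fr1), NA_integer_)
  # single patch: no alternative
  s3 <- place_population(patch_landscape(5), activities = 1, patch = 1)
  expect_identical(best_move(s3, 1, fr1), NA_integer_)
})

test_that("tied best destinations are chosen uniformly from the RNG stream", {
  s <- place_population(patch_landscape(c(1, 8, 8)), activities = 1, patch = 1)
  set.seed(42)
  picks <- replicate(400, best_move(s, 1, fr1))
  expect_setequal(unique(picks), c(2L, 3L))
  expect_gt(mean(picks == 2L), 0.4)
  expect_lt(mean(picks == 2L), 0.6)
})

test_that("apply_move conserves the population and updates bookkeeping", {
  s <- place_population(patch_landscape(c(12, 6)), activities = rep(1, 3),
                        patch = c(1, 1, 1))
  s2 <- apply_move(s, 1, 2L)
  expect_identical(s2$landscape$count, c(2L, 1L))
  expect_identical(sum(s2$landscape$count), 3L)
  expect_identical(s2$patch[1], 2L)
  expect_identical(s2$moves, c(1L, 0L, 0L))
  expect_error(apply_move(s, 1, 5L), "out of range")
  expect_error(apply_move(s, 1, 1L), "current patch")
})

test_that("is_ifd agrees with direct inequality checks on known cases", {
  expect_true(is_ifd(patch_landscape(c(10, 10), count = c(1, 1)), fr1))
  expect_true(is_ifd(patch_landscape(c(12, 6), count = c(2, 1)), fr1))
  expect_false(is_ifd(patch_landscape(c(12, 6), count = c(3, 0)), fr1))
  # empty landscape is vacuously at equilibrium
  expect_true(is_ifd(patch_landscape(c(3, 2), count = c(0, 0)), fr1))
})

test_that("is_ifd matches the brute-force oracle across small instances", {
  set.seed(11)
  for (rep in 1:60) {
    P <- sample(1:4, 1)
    Q <- runif(P, 0.5, 12)
    count <- as.integer(rmultinom(1, sample(0:7, 1), rep(1, P)))
    for (kind in c("type_I", "type_II")) {
      fr <- functional_response(kind, attack_rate = 1.3, handling_time = 0.4)
      expect_identical(is_ifd(patch_landscape(Q, count = count), fr),
                       oracle_is_ifd(Q, count, kind, a = 1.3, h = 0.4))
    }
  }
})

test_that("potential sums per-capita intakes and tracks move gains exactly", {
  expect_equal(potential(patch_landscape(c(3, 2), count = c(0, 0)), fr1), 0)
  expect_equal(potential(patch_landscape(c(12, 6), count = c(2, 1)), fr1), 24)
  # delta-potential identity on random single moves
  set.seed(3)
  for (rep in 1:40) {
    P <- sample(2:5, 1)
    Q <- runif(P, 1, 10)
    N <- sample(1:8, 1)
    patch <- sample.int(P, N, replace = TRUE)
    s <- place_population(patch_landscape(Q), activities = rep(1, N), patch = patch)
    i <- sample.int(N, 1)
    cand <- setdiff(seq_len(P), s$patch[i])
    tgt <- cand[sample.int(length(cand), 1)]
    fr <- functional_response("type_II", 0.9, 1.7)
    gain <- intake_rate(fr, Q[tgt], s$landscape$count[tgt] + 1L) -
      intake_rate(fr, Q[s$patch[i]], s$landscape$count[s$patch[i]])
    expect_equal(potential(apply_move(s, i, tgt), fr) - potential(s, fr), gain)
  }
})

test_that("landscape CSV round-trips through the documented dialect", {
  set.seed(9)
  L <- generate_landscape(3, 4)
  L$count <- tabulate(sample.int(12, 20, replace = TRUE), 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(L, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "patch_id,row,col,quality,count")
  L2 <- read_landscape(path)
  expect_equal(L2$quality, L$quality)
  expect_identical(L2$count, L$count)
  expect_identical(c(L2$n_rows, L2$n_cols), c(3L, 4L))
})

test_that("landscape construction rejects invalid inputs", {
  expect_error(patch_landscape(c(1, -2)), "positive")
  expect_error(patch_landscape(1:3, n_rows = 2, n_cols = 2), "patches")
  expect_error(patch_landscape(c(1, 2), count = c(-1, 3)), "non-negative")
})
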