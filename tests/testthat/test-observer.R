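test_that("materialize_scale evaluates the exponential model", {
  ss <- default_stimuli()
  flat <- materialize_scale(scale_params(a1 = 0, b1 = 0, a3 = 0, b3 = 0), ss)
  expect_equal(flat, rep(0, 11))
  p <- scale_params()
  s <- materialize_scale(p, ss)
  expect_equal(s[ss$is_reference], 0)
  expect_equal(s[ss$sph == 0 & ss$add == 1], p$a1 + p$b1)
  expect_equal(s[ss$sph == 0 & ss$add == 3], p$a3 + p$b3)
  # add-compensation at negative sph: add 3 strictly closer to zero
  expect_lt(abs(s[ss$sph == -5 & ss$add == 3]),
            abs(s[ss$sph == -5 & ss$add == 1]))
  # amplification at positive sph and global maximum at (5, 3)
  expect_gt(s[ss$sph == 5 & ss$add == 3], s[ss$sph == 5 & ss$add == 1])
  expect_equal(which.max(s), which(ss$sph == 5 & ss$add == 3))
  bad <- data.frame(sph = 1, add = 2, is_reference = FALSE)
  expect_error(materialize_scale(p, bad), "no scale parameters")
})

test_that("noiseless observers answer by argmin and pass every catch trial", {
  sub <- noiseless_subject()
  d1 <- abs(sub$truth[sub$trials$choice1] - sub$truth[sub$trials$anchor])
  d2 <- abs(sub$truth[sub$trials$choice2] - sub$truth[sub$trials$anchor])
  expect_equal(sub$responses$answer, ifelse(d1 < d2, 1L, 2L))
  # catch trials: the non-catch choice always wins
  catch_idx <- nrow(attr(sub$trials, "stimuli"))
  tri <- response_triplets(sub$trials, sub$responses, include_catch = TRUE)
  touched <- tri$winner == catch_idx | tri$loser == catch_idx
  expect_equal(sum(touched), 83L)
  expect_true(all(tri$winner[touched] != catch_idx))
  # flipped-pair consistency: mirrored answers within each core pair
  core <- merge(sub$trials[!sub$trials$is_catch, ], sub$responses,
                by = "trial_index")
  by_pair <- split(core, core$pair_id.x)
  expect_true(all(vapply(by_pair, function(p) sum(p$answer) == 3L,
                         logical(1))))
})

test_that("logistic decision noise matches its closed form", {
  # d2 - d1 = 0.1 at sigma = 0.1 -> P(choice 1) = plogis(1)
  trials <- data.frame(trial_index = seq_len(1e5), pair_id = seq_len(1e5),
                       choice1 = 1L, anchor = 2L, choice2 = 3L,
                       is_catch = FALSE)
  sc <- c(1.0, 1.2, 1.5)   # d1 = 0.2, d2 = 0.3
  prof <- observer_profile(sigma = 0.1, lapse = 0, seed = 77)
  resp <- answer_trials(trials, sc, prof)
  expect_equal(mean(resp$answer == 1L), plogis(1), tolerance = 0.015)
  # lapse shrinks the choice probability towards 1/2
  prof_l <- observer_profile(sigma = 0.1, lapse = 0.3, seed = 78)
  resp_l <- answer_trials(trials, sc, prof_l)
  expect_equal(mean(resp_l$answer == 1L), 0.15 + 0.7 * plogis(1),
               tolerance = 0.015)
  # exact distance tie: fair coin
  resp_t <- answer_trials(trials, c(1, 1.25, 1.5),
                          observer_profile(sigma = 0, seed = 79))
  expect_equal(mean(resp_t$answer == 1L), 0.5, tolerance = 0.01)
})

test_that("head traces have the designed velocity structure", {
  prof <- observer_profile(strategy = "dynamic-pitch", amplitude = 15,
                           frequency = 0.5, seed = 4)
  tr <- simulate_head_trace(prof, duration = 20, rate = 90)
  expect_equal(nrow(tr), 1800L)
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(abs(sqrt(rowSums(as.matrix(tr[, 2:5])^2)) - 1) < 1e-9))
  mv <- mean_abs_velocity(tr)
  expect_equal(unname(mv["pitch"]), 4 * 15 * 0.5, tolerance = 0.02)
  expect_lt(mv["yaw"], 10)
  expect_lt(mv["roll"], 10)
  mv_static <- mean_abs_velocity(simulate_head_trace(
    observer_profile(strategy = "static", seed = 4), 20, 90))
  expect_true(all(mv_static < 10))
  mv_yaw <- mean_abs_velocity(simulate_head_trace(
    observer_profile(strategy = "dynamic-yaw", seed = 4), 20, 90))
  expect_equal(unname(mv_yaw["yaw"]), 30, tolerance = 0.02)
  # determinism
  tr2 <- simulate_head_trace(prof, duration = 20, rate = 90)
  expect_identical(tr, tr2)
})

test_that("gaze clouds have the requested center, spread and geometry", {
  prof <- observer_profile(gaze_sd = 5, gaze_center = c(0, -10), seed = 21)
  g <- simulate_gaze(prof, n = 1e4)
  expect_true(all(abs(sqrt(g$lx^2 + g$ly^2 + g$lz^2) - 1) < 1e-12))
  ll <- palscale:::binocular_lonlat(g)
  expect_equal(mean(ll[, 2]), -10, tolerance = 0.2)
  expect_equal(mean(ll[, 1]), 0, tolerance = 0.2)
  expect_equal(sd(ll[, 2]), 5, tolerance = 0.15)
  # degenerate spread collapses onto the center
  g0 <- simulate_gaze(observer_profile(gaze_sd = 1e-6,
                                       gaze_center = c(3, -2), seed = 5),
                      n = 100)
  ll0 <- palscale:::binocular_lonlat(g0)
  expect_equal(max(abs(ll0[, 1] - 3)), 0, tolerance = 1e-4)
  expect_equal(max(abs(ll0[, 2] + 2)), 0, tolerance = 1e-4)
})

test_that("responses round-trip through CSV with validation", {
  sub <- noiseless_subject()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_responses_csv(sub$responses, path, subject_id = 4L)
  r <- load_responses(path)
  expect_equal(nrow(r), 413L)
  expect_equal(r$answer, sub$responses$answer)
  # corrupt one answer and expect a located error
  d <- read.csv(path)
  d$answer[5] <- 3L
  write.csv(d, path, row.names = FALSE)
  expect_error(load_responses(path), "line 6")
  d$answer <- NULL
  write.csv(d, path, row.names = FALSE)
  expect_error(load_responses(path), "answer")
  write.csv(read.csv(text = "subject_id,trial_index,pair_id,answer,is_catch,n_repeats"),
            path, row.names = FALSE)
  expect_warning(load_responses(path), "no rows")
})
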