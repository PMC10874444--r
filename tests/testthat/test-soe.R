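test_that("SOE recovers the order of a small configuration (grid oracle)", {
  # 4 stimuli at true 1-D positions; all 8 noiseless core responses
  truth <- c(0, 1, 2, 4)
  stimuli <- build_stimulus_set(c(1, 2, 3), 1, include_reference = TRUE)
  trials <- build_trial_list(stimuli, catch_fraction = 0, seed = 3)
  responses <- answer_trials(trials, truth,
                             observer_profile(sigma = 0, seed = 1))
  tri <- response_triplets(trials, responses)
  expect_equal(nrow(tri), 8L)
  fit <- soe_embed(tri, 4, dim = 1, seed = 2)
  expect_equal(triplet_accuracy(fit, tri), 1.0)
  expect_equal(abs(cor(as.vector(fit$X), truth, method = "spearman")), 1.0)
  # independent oracle: exhaustive 1-D grid search confirms that all
  # constraints are simultaneously satisfiable, i.e. the gradient fit
  # attains the oracle's maximum satisfied-constraint count
  oracle <- brute_force_1d(tri, 4)
  expect_equal(triplet_accuracy(oracle, tri), 1.0)
  expect_equal(triplet_accuracy(fit, tri), triplet_accuracy(oracle, tri))
})

test_that("degenerate and contradictory inputs behave as documented", {
  expect_warning(fit <- soe_embed(data.frame(anchor = integer(0),
                                             winner = integer(0),
                                             loser = integer(0)),
                                  n_stimuli = 2, seed = 1),
                 "convention")
  expect_equal(fit$loss, 0)
  expect_equal(fit$accuracy, 1)
  # equal numbers of contradictory constraints cap accuracy at 1/2
  contra <- data.frame(anchor = c(1, 1), winner = c(2, 3), loser = c(3, 2))
  fit2 <- soe_embed(contra, 3, dim = 1, seed = 4)
  expect_lte(triplet_accuracy(fit2, contra), 0.5)
  expect_error(soe_embed(data.frame(anchor = 1, winner = 2, loser = 9),
                         n_stimuli = 3), "outside")
  expect_error(triplet_accuracy(matrix(0, 3, 1),
                                data.frame(anchor = integer(0),
                                           winner = integer(0),
                                           loser = integer(0))), "non-empty")
})

test_that("accuracy is invariant under similarity transforms and ties give 1/2", {
  sub <- noiseless_subject()
  fit <- soe_embed(sub$triplets, 11, dim = 1, seed = 6)
  a0 <- triplet_accuracy(fit, sub$triplets)
  for (tr in list(c(2, 0.5), c(-3, 2), c(10, -1))) {
    expect_equal(triplet_accuracy(tr[1] + tr[2] * fit$X, sub$triplets), a0)
  }
  expect_equal(triplet_accuracy(matrix(0, 11, 1), sub$triplets), 0.5)
})

test_that("best-of-restarts returns the lowest converged loss", {
  sub <- noiseless_subject()
  multi <- soe_embed(sub$triplets, 11, dim = 1, restarts = 8, seed = 9)
  expect_length(multi$restart_losses, 8L)
  expect_equal(multi$loss, min(multi$restart_losses))
  expect_equal(multi$restart_losses[multi$best_restart], multi$loss)
})

test_that("cross-validation selects one dimension for 1-D observers", {
  sub <- noiseless_subject()
  cv <- cv_dimension_select(sub$triplets, 11, dims = 1:3, folds = 10,
                            seed = 3)
  expect_equal(cv$selected, 1L)
  expect_equal(cv_dimension_select(sub$triplets, 11, dims = 1, folds = 5,
                                   seed = 1)$selected, 1L)
})

test_that("a genuinely two-dimensional observer is detected as such", {
  ss <- build_stimulus_set()
  tl <- build_trial_list(ss, catch_fraction = 0, seed = 3)
  set.seed(9)
  X2 <- cbind(runif(11, -1, 1), runif(11, -1, 1)) * 1.5
  d <- function(i, a) sqrt(rowSums((X2[i, , drop = FALSE] -
                                      X2[a, , drop = FALSE])^2))
  p1 <- plogis((d(tl$choice2, tl$anchor) - d(tl$choice1, tl$anchor)) / 0.05)
  ans <- ifelse(runif(nrow(tl)) < p1, 1L, 2L)
  tri <- data.frame(anchor = tl$anchor,
                    winner = ifelse(ans == 1, tl$choice1, tl$choice2),
                    loser = ifelse(ans == 1, tl$choice2, tl$choice1))
  cv <- cv_dimension_select(tri, 11, dims = 1:3, folds = 10, seed = 4)
  expect_equal(cv$selected, 2L)
  # the 1-D fit falls far short of the 2-D fit for such data
  expect_gt(cv$table$mean_accuracy[2] - cv$table$mean_accuracy[1], 0.05)
})

test_that("pure-noise responses give chance-level held-out accuracy", {
  sub <- noiseless_subject()
  tri <- sub$triplets
  set.seed(42)
  flip <- runif(nrow(tri)) < 0.5    # coin-flip observer: shuffle winners
  tmp <- tri$winner[flip]
  tri$winner[flip] <- tri$loser[flip]
  tri$loser[flip] <- tmp
  cv <- cv_dimension_select(tri, 11, dims = 1:2, folds = 5, seed = 8)
  # binomial null: accuracy ~ 0.5 with se ~ sqrt(.25/66) per fold
  for (k in seq_len(nrow(cv$table))) {
    expect_lt(abs(cv$table$mean_accuracy[k] - 0.5), 3 * 0.062)
  }
})

test_that("bootstrap spread is small for consistent data and grows with noise", {
  sub <- noiseless_subject()
  bs <- bootstrap_scales(sub$triplets, 11, B = 30, seed = 12)
  # normalize by the fitted scale's span before judging spread
  span <- diff(range(bs$point$X))
  expect_lt(max(bs$spread) / span, 0.05)
  one <- bootstrap_scales(sub$triplets, 11, B = 1, seed = 5)
  expect_equal(one$spread, rep(0, 11))
  # noisier observers have larger mean spread
  stim <- attr(sub$trials, "stimuli")
  noisy_tri <- function(sigma, seed) {
    r <- answer_trials(sub$trials, materialize_scale(scale_params(), stim),
                       observer_profile(sigma = sigma, seed = seed))
    response_triplets(sub$trials, r)
  }
  b_lo <- bootstrap_scales(noisy_tri(0.05, 31), 11, B = 20, seed = 7)
  b_hi <- bootstrap_scales(noisy_tri(0.3, 31), 11, B = 20, seed = 7)
  # spreads are comparable after removing the embeddings' arbitrary
  # overall scale (noisy fits compress their configurations)
  rel <- function(b) mean(b$spread) / diff(range(b$point$X))
  expect_gt(rel(b_hi), rel(b_lo))
})
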