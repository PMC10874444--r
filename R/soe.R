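## Per-subject perceptual scales by soft ordinal embedding (SOE).
##
## Each triplet response constrains the embedding: the answered choice
## (winner) must lie closer to the anchor than the other choice (loser).
## SOE minimizes the squared hinge loss
##   L(X) = sum max(0, margin + ||x_a - x_w||^2 - ||x_a - x_l||^2)^2
## by full-batch gradient descent with backtracking line search from
## several seeded random initializations, keeping the best restart.
## The margin fixes the embedding's otherwise arbitrary scale; the
## embedding remains defined only up to a similarity transform, which
## downstream alignment removes.

#' Convert trials plus answers to triplet constraints
#'
#' @param trials A [build_trial_list()] result.
#' @param responses An [answer_trials()] result (or any data frame with
#'   `trial_index` and `answer` in \{1, 2\}).
#' @param include_catch Keep catch trials?  They are excluded by
#'   default: catch trials validate attention and do not enter the
#'   embedding.
#' @return Data frame with columns `anchor`, `winner`, `loser`
#'   (stimulus indices).
#' @export
response_triplets <- function(trials, responses, include_catch = FALSE) {
  m <- merge(as.data.frame(trials), as.data.frame(responses)[
    , c("trial_index", "answer")], by = "trial_index")
  if (!include_catch) m <- m[!m$is_catch, , drop = FALSE]
  data.frame(anchor = m$anchor,
             winner = ifelse(m$answer == 1L, m$choice1, m$choice2),
             loser = ifelse(m$answer == 1L, m$choice2, m$choice1))
}

check_triplets <- function(triplets, n_stimuli) {
  idx <- c(triplets$anchor, triplets$winner, triplets$loser)
  if (length(idx) && (any(idx < 1L) || any(idx > n_stimuli))) {
    stopf("triplet references a stimulus outside 1..%d", n_stimuli)
  }
}

#' Fit a perceptual scale by soft ordinal embedding
#'
#' @param triplets Data frame of constraints with columns `anchor`,
#'   `winner`, `loser` (see [response_triplets()]).
#' @param n_stimuli Number of stimuli (embedding rows).
#' @param dim Embedding dimensionality.
#' @param margin Hinge margin; fixes the scale of the solution.
#' @param restarts Number of seeded random initializations.
#' @param seed Integer seed.
#' @param tol Relative loss-change stopping tolerance.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `perceptual_scale`: list with `X`
#'   (`n_stimuli` x `dim` coordinate matrix), `loss`, `accuracy`
#'   (triplet accuracy on the fitting data), `dim`, `seed`,
#'   `best_restart`, `restart_losses` (final loss of every restart),
#'   `converged`.
#' @examples
#' tri <- data.frame(anchor = c(2, 2), winner = c(1, 1), loser = c(3, 3))
#' fit <- soe_embed(tri, n_stimuli = 3, dim = 1, seed = 1)
#' triplet_accuracy(fit, tri)
#' @export
soe_embed <- function(triplets, n_stimuli, dim = 1, margin = 1,
                      restarts = 10, seed = 1L, tol = 1e-8,
                      max_iter = 2000) {
  if (n_stimuli < 2) stopf("`n_stimuli` must be at least 2")
  if (dim < 1) stopf("`dim` must be at least 1")
  if (margin <= 0) stopf("`margin` must be positive")
  check_triplets(triplets, n_stimuli)
  seeds <- derive_seeds(seed, restarts)
  if (nrow(triplets) == 0L) {
    warning("no triplet constraints: any configuration is valid; ",
            "accuracy reported as 1 by convention")
    X <- with_seed(seeds[1], matrix(rnorm(n_stimuli * dim), ncol = dim))
    return(structure(list(X = X, loss = 0, accuracy = 1, dim = dim,
                          seed = as.integer(seed), best_restart = 1L,
                          converged = TRUE),
                     class = "perceptual_scale"))
  }
  trip <- as.matrix(triplets[, c("anchor", "winner", "loser")]) - 1L
  storage.mode(trip) <- "integer"
  best <- NULL
  restart_losses <- numeric(restarts)
  for (r in seq_len(restarts)) {
    X0 <- with_seed(seeds[r], matrix(rnorm(n_stimuli * dim), ncol = dim))
    fit <- .soe_fit_cpp(X0, trip, margin, tol, as.integer(max_iter))
    restart_losses[r] <- fit$loss
    if (is.null(best) || fit$loss < best$loss) {
      best <- fit
      best$restart <- r
    }
  }
  out <- structure(list(X = best$X, loss = best$loss, accuracy = NA_real_,
                        dim = dim, seed = as.integer(seed),
                        best_restart = best$restart,
                        restart_losses = restart_losses,
                        converged = best$converged),
                   class = "perceptual_scale")
  out$accuracy <- triplet_accuracy(out, triplets)
  out
}

#' @export
print.perceptual_scale <- function(x, ...) {
  cat(sprintf("perceptual scale: %d stimuli in %d dimension(s)\n",
              nrow(x$X), x$dim))
  cat(sprintf("  loss %.4g, triplet accuracy %.3f (restart %d)\n",
              x$loss, x$accuracy, x$best_restart))
  invisible(x)
}

#' Triplet accuracy of an embedding
#'
#' Fraction of responses whose winner lies strictly closer to the
#' anchor than the loser; exact distance ties count 0.5.
#'
#' @param scale A `perceptual_scale`, or a numeric matrix/vector of
#'   coordinates (rows = stimuli).
#' @param triplets Constraint data frame (`anchor`, `winner`, `loser`);
#'   must be non-empty.
#' @return Proportion in `[0, 1]`.
#' @export
triplet_accuracy <- function(scale, triplets) {
  X <- if (inherits(scale, "perceptual_scale")) scale$X else scale
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (nrow(triplets) == 0L) stopf("`triplets` must be non-empty")
  check_triplets(triplets, nrow(X))
  dw <- rowSums((X[triplets$anchor, , drop = FALSE] -
                   X[triplets$winner, , drop = FALSE])^2)
  dl <- rowSums((X[triplets$anchor, , drop = FALSE] -
                   X[triplets$loser, , drop = FALSE])^2)
  mean(ifelse(dw < dl, 1, ifelse(dw > dl, 0, 0.5)))
}

#' Select embedding dimensionality by cross-validation
#'
#' k-fold cross-validation over triplet constraints: for each candidate
#' dimension, the embedding is fit on the training folds and scored by
#' triplet accuracy on the held-out fold.  The selected dimension is
#' the smallest whose mean held-out accuracy lies within the
#' equivalence band of the best mean: a higher dimension is adopted
#' only when it beats a lower one by more than one standard error AND
#' more than `practical_margin` accuracy points.  The practical margin
#' matters because response noise around near-tied stimuli lets
#' higher-dimensional embeddings absorb inconsistent answers and gain a
#' few accuracy points that do not reflect additional perceptual
#' dimensions; a genuinely multidimensional percept yields much larger
#' gains.
#'
#' @param triplets Constraint data frame.
#' @param n_stimuli Number of stimuli.
#' @param dims Candidate dimensionalities.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold split and the fits.
#' @param restarts,margin,tol,max_iter Passed to [soe_embed()]; fewer
#'   restarts than the final fit are enough for fold-level scoring.
#' @param practical_margin Accuracy difference below which two
#'   dimensionalities are treated as equivalent predictors.
#' @return An object of class `cv_report`: list with `table` (data
#'   frame `dim`, `mean_accuracy`, `se`), `selected`, `folds`, `seed`.
#' @export
cv_dimension_select <- function(triplets, n_stimuli, dims = 1:3,
                                folds = 10, seed = 1L, restarts = 3,
                                margin = 1, tol = 1e-7, max_iter = 1000,
                                practical_margin = 0.05) {
  if (folds < 2) stopf("`folds` must be at least 2")
  n <- nrow(triplets)
  if (n < folds) stopf("need at least as many responses as folds")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  seeds <- derive_seeds(seed + 1L, length(dims) * folds)
  acc <- matrix(NA_real_, nrow = folds, ncol = length(dims))
  for (j in seq_along(dims)) {
    for (f in seq_len(folds)) {
      train <- triplets[fold_id != f, , drop = FALSE]
      test <- triplets[fold_id == f, , drop = FALSE]
      if (nrow(train) == 0L) stopf("fold %d has an empty training set", f)
      fit <- soe_embed(train, n_stimuli, dim = dims[j], margin = margin,
                       restarts = restarts,
                       seed = seeds[(j - 1L) * folds + f],
                       tol = tol, max_iter = max_iter)
      acc[f, j] <- triplet_accuracy(fit, test)
    }
  }
  means <- colMeans(acc)
  ses <- apply(acc, 2L, sd) / sqrt(folds)
  best <- which.max(means)
  ok <- means >= means[best] - max(ses[best], practical_margin)
  selected <- dims[which(ok)[1]]
  structure(list(table = data.frame(dim = dims, mean_accuracy = means,
                                    se = ses),
                 selected = selected, folds = folds,
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected dimension: %d (equivalence band, %d folds)\n",
              x$selected, x$folds))
  invisible(x)
}

#' Bootstrap the robustness of a perceptual scale
#'
#' Refits the 1-D embedding on `B` bootstrap resamples of the triplet
#' constraints (with replacement, same size), aligns each resampled
#' scale to the point estimate by a 1-D Procrustes transform
#' (shift, positive scale, sign), and reports the per-stimulus spread.
#'
#' @param triplets Constraint data frame.
#' @param n_stimuli Number of stimuli.
#' @param dim Embedding dimensionality (only 1 supported, scales being
#'   one-dimensional after selection).
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param restarts,margin,tol,max_iter Passed to [soe_embed()].
#' @return An object of class `bootstrap_ensemble`: list with `point`
#'   (the point-estimate `perceptual_scale`), `samples` (`n_stimuli` x
#'   `B` matrix of aligned scale values), `spread` (per-stimulus sd).
#' @export
bootstrap_scales <- function(triplets, n_stimuli, dim = 1, B = 50,
                             seed = 1L, restarts = 3, margin = 1,
                             tol = 1e-7, max_iter = 1000) {
  if (B < 1) stopf("`B` must be at least 1")
  if (dim != 1) stopf("bootstrap alignment is defined for 1-D scales only")
  point <- soe_embed(triplets, n_stimuli, dim = dim, margin = margin,
                     restarts = max(restarts, 10), seed = seed,
                     tol = tol, max_iter = max_iter)
  ref <- as.vector(point$X)
  seeds <- derive_seeds(seed + 1L, 2L * B)
  samples <- matrix(NA_real_, nrow = n_stimuli, ncol = B)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(nrow(triplets), replace = TRUE))
    fit <- soe_embed(triplets[idx, , drop = FALSE], n_stimuli, dim = dim,
                     margin = margin, restarts = restarts,
                     seed = seeds[B + b], tol = tol, max_iter = max_iter)
    samples[, b] <- procrustes_1d(as.vector(fit$X), ref)$aligned
  }
  spread <- if (B == 1L) rep(0, n_stimuli) else apply(samples, 1L, sd)
  structure(list(point = point, samples = samples, spread = spread,
                 B = B, seed = as.integer(seed)),
            class = "bootstrap_ensemble")
}

#' Serialize a perceptual scale to JSON
#'
#' @param scale A `perceptual_scale`.
#' @param stimuli The stimulus table the scale indexes.
#' @param path Output JSON path.
#' @export
write_scale_json <- function(scale, stimuli, path) {
  obj <- list(stimuli = data.frame(sph = stimuli$sph, add = stimuli$add),
              coordinates = unname(as.matrix(scale$X)),
              dim = scale$dim, loss = scale$loss,
              accuracy = scale$accuracy, seed = scale$seed,
              package_version = as.character(utils::packageVersion("palscale")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
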