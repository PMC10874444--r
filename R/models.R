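## Predictive models of scale value as a function of lens parameters.
##
## The perceived-distortion scale as a function of Sph is modeled per
## Add group by the exponential s(Sph) = a + b * c^Sph.  For a fixed
## base c the model is linear in (a, b), so the nonlinear least-squares
## problem reduces to profiling the residual sum of squares over c --
## a robust one-dimensional search that avoids the b/c exchange
## degeneracy of joint descent.  Leave-one-subject-out evaluation
## compares it against a linear baseline and a random-forest ceiling.

#' Fit the exponential scale model for one Add group
#'
#' Minimizes `sum((value - a - b * c^sph)^2)` by profiling over the
#' base `c` (inner linear solve for `a`, `b`; grid search plus local
#' refinement over `c` in `(0, c_max]`).
#'
#' @param points Data frame with columns `sph` and `value` (>= 3
#'   distinct `sph` values unless degenerate).
#' @param c_max Upper bound for the base.
#' @param c_grid Coarse profile grid over the base.
#' @return An object of class `exponential_fit`: list with `a`, `b`,
#'   `c`, `rss`, `degenerate`, `converged`.
#' @examples
#' pts <- data.frame(sph = c(-5, -2.5, 0, 2.5, 5))
#' pts$value <- 0.1 + 0.2 * 1.5^pts$sph
#' fit_exponential(pts)
#' @export
fit_exponential <- function(points, c_max = 5,
                            c_grid = seq(0.1, 5, by = 0.05)) {
  stopifnot(all(c("sph", "value") %in% names(points)))
  y <- points$value
  sph <- points$sph
  if (length(unique(y)) == 1L) {
    return(structure(list(a = y[1], b = 0, c = 1, rss = 0,
                          degenerate = TRUE, converged = TRUE),
                     class = "exponential_fit"))
  }
  if (length(unique(sph)) < 3L) {
    stopf("need at least 3 distinct sph values")
  }
  c_grid <- c_grid[c_grid > 0 & c_grid <= c_max]
  solve_ab <- function(cc) {
    x <- cc^sph
    fit <- lm(y ~ x)
    list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         rss = sum(fit$residuals^2))
  }
  rss_c <- vapply(c_grid, function(cc) solve_ab(cc)$rss, numeric(1))
  k <- which.min(rss_c)
  lo <- c_grid[max(1L, k - 1L)]
  hi <- c_grid[min(length(c_grid), k + 1L)]
  refine <- optimize(function(cc) solve_ab(cc)$rss, c(lo, hi),
                     tol = 1e-10)
  cc <- if (refine$objective < rss_c[k]) refine$minimum else c_grid[k]
  ab <- solve_ab(cc)
  structure(list(a = ab$a, b = ab$b, c = cc, rss = ab$rss,
                 degenerate = FALSE, converged = TRUE),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("s(Sph) = %.4g + %.4g * %.4g^Sph   (rss %.3g%s)\n",
              x$a, x$b, x$c, x$rss,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @rdname fit_exponential
#' @param fit An `exponential_fit`.
#' @param sph Spherical powers to predict at.
#' @export
predict_exponential <- function(fit, sph) {
  fit$a + fit$b * fit$c^sph
}

# Long-format table (subject, sph, add, value, is_reference) from a
# stimuli x subjects value matrix.
scales_long <- function(values, stimuli) {
  ns <- ncol(values)
  do.call(rbind, lapply(seq_len(ns), function(j) {
    data.frame(subject = j, sph = stimuli$sph, add = stimuli$add,
               is_reference = stimuli$is_reference, value = values[, j])
  }))
}

#' Leave-one-subject-out evaluation of scale models
#'
#' For each held-out subject, each model family is trained on the
#' remaining subjects' normalized scale values and scored on the
#' held-out subject by out-of-sample R-squared (1 - SSE/SST, SST about
#' the held-out subject's mean; negative values are reported
#' unclipped).  Families: `"linear"` -- ordinary least squares on
#' `sph`, `add` and their interaction, pooled over training rows;
#' `"exponential"` -- per-Add exponential fits on the training-mean
#' scale, with the undistorted reference predicted as 0 (its normalized
#' cross-subject mean); `"tree-ensemble"` -- a seeded random forest of
#' 100 trees on `(sph, add)`, a flexibility ceiling rather than a
#' substantive model.
#'
#' @param normalized An `aligned_scales` object after
#'   [normalize_scales()] (or a stimuli x subjects matrix).
#' @param stimuli The stimulus table the rows index.
#' @param families Character vector of model families to evaluate.
#' @param seed Seed for the tree ensemble.
#' @return Data frame of class `loso_report` with columns `subject`,
#'   `family`, `r2`.
#' @export
loso_evaluate <- function(normalized, stimuli,
                          families = c("linear", "exponential",
                                       "tree-ensemble"),
                          seed = 1L) {
  values <- if (inherits(normalized, "aligned_scales")) normalized$values
            else as.matrix(normalized)
  ns <- ncol(values)
  if (ns < 2) stopf("leave-one-subject-out needs at least 2 subjects")
  known <- c("linear", "exponential", "tree-ensemble")
  if (!all(families %in% known)) {
    stopf("unknown model family: %s",
          paste(setdiff(families, known), collapse = ", "))
  }
  long <- scales_long(values, stimuli)
  rows <- list()
  for (j in seq_len(ns)) {
    train <- long[long$subject != j, , drop = FALSE]
    test <- long[long$subject == j, , drop = FALSE]
    sst <- sum((test$value - mean(test$value))^2)
    for (fam in families) {
      pred <- switch(
        fam,
        "linear" = {
          fit <- lm(value ~ sph + add + sph:add, data = train)
          predict(fit, newdata = test)
        },
        "exponential" = {
          means <- aggregate(value ~ sph + add + is_reference, train, mean)
          p <- numeric(nrow(test))
          for (ad in unique(test$add[!test$is_reference])) {
            grp <- means[!means$is_reference & means$add == ad, ]
            fit <- fit_exponential(grp)
            sel <- !test$is_reference & test$add == ad
            p[sel] <- predict_exponential(fit, test$sph[sel])
          }
          p[test$is_reference] <- 0
          p
        },
        "tree-ensemble" = {
          rf <- with_seed(seed + j, randomForest::randomForest(
            value ~ sph + add, data = train, ntree = 100))
          predict(rf, newdata = test)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        subject = j, family = fam, r2 = 1 - sum((test$value - pred)^2) / sst)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("loso_report", "data.frame")
  out
}

#' @importFrom stats aggregate
NULL
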