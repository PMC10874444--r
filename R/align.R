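## Cross-subject alignment of 1-D perceptual scales.
##
## An embedding is defined only up to shift, positive scaling and sign;
## generalized Procrustes analysis (GPA) iteratively aligns every
## subject's scale to the evolving mean scale by exactly those
## transforms.  A final common affine map pins the cross-subject mean
## of the undistorted reference at 0 and of the strongest lens
## (Sph 5, Add 3 by convention) at +1, so scale values are comparable
## across subjects and cohorts.

# Least-squares similarity alignment of 1-D configuration x to ref:
# aligned = shift + signed_scale * x.  The sign comes from the
# correlation sign, the magnitude from the regression coefficient.
procrustes_1d <- function(x, ref) {
  vx <- var(x)
  if (!is.finite(vx) || vx == 0) {
    stopf("cannot align a constant (zero-variance) scale")
  }
  b <- cov(x, ref) / vx
  a <- mean(ref) - b * mean(x)
  list(aligned = a + b * x, shift = a, scale = abs(b),
       sign = if (b >= 0) 1 else -1)
}

#' Generalized Procrustes alignment of 1-D scales
#'
#' Iterates two steps until the reference stabilizes: (i) align every
#' subject's scale to the current reference by least squares over shift
#' and signed scale; (ii) replace the reference by the mean of the
#' aligned scales, re-standardized to zero mean and unit root mean
#' square (preventing the classical GPA collapse towards zero).
#'
#' @param scales List (or matrix columns) of per-subject scale value
#'   vectors, all of the same length and each with nonzero variance.
#' @param tol Convergence tolerance on the reference change.
#' @param max_iter Iteration cap.
#' @return An object of class `aligned_scales`: list with `values`
#'   (stimuli x subjects matrix of aligned values), `mean_scale`,
#'   `transforms` (data frame `subject`, `shift`, `scale`, `sign`),
#'   `iterations`.
#' @examples
#' y <- c(0, 0.2, 0.5, 1.2)
#' fit <- gpa_align_1d(list(y, 3 - 2 * y))
#' max(abs(fit$values[, 1] - fit$values[, 2]))  # ~0
#' @export
gpa_align_1d <- function(scales, tol = 1e-10, max_iter = 100) {
  if (is.matrix(scales)) scales <- lapply(seq_len(ncol(scales)),
                                          function(j) scales[, j])
  ns <- length(scales)
  if (ns < 1) stopf("need at least one scale")
  len <- unique(vapply(scales, length, integer(1)))
  if (length(len) != 1L) stopf("all scales must have the same length")
  for (j in seq_len(ns)) {
    if (var(scales[[j]]) == 0) {
      stopf("subject %d has a constant (zero-variance) scale", j)
    }
  }
  standardize <- function(v) {
    v <- v - mean(v)
    v / sqrt(mean(v^2))
  }
  ref <- standardize(scales[[1]])
  aligned <- matrix(NA_real_, nrow = len, ncol = ns)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (j in seq_len(ns)) {
      aligned[, j] <- procrustes_1d(scales[[j]], ref)$aligned
    }
    new_ref <- standardize(rowMeans(aligned))
    # the standardized mean is sign-ambiguous; keep it pointing along ref
    if (sum(new_ref * ref) < 0) new_ref <- -new_ref
    delta <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol || iter >= max_iter) break
  }
  # canonical orientation, independent of subject order and input signs:
  # the largest-magnitude reference coordinate is made positive
  if (ref[which.max(abs(ref))] < 0) ref <- -ref
  transforms <- do.call(rbind, lapply(seq_len(ns), function(j) {
    tr <- procrustes_1d(scales[[j]], ref)
    aligned[, j] <<- tr$aligned
    data.frame(subject = j, shift = tr$shift, scale = tr$scale,
               sign = tr$sign)
  }))
  structure(list(values = aligned, mean_scale = rowMeans(aligned),
                 transforms = transforms, iterations = iter),
            class = "aligned_scales")
}

#' Normalize aligned scales to the 0/1 convention
#'
#' Applies one common affine map to all subjects: subtract the
#' cross-subject mean value of the undistorted reference stimulus, then
#' divide by the cross-subject mean of the designated unit stimulus
#' (the Sph 5, Add 3 lens).  Afterwards those two cross-subject means
#' are exactly 0 and +1; individual subjects need not hit 0/1.
#'
#' @param aligned An `aligned_scales` object (or plain matrix,
#'   stimuli x subjects).
#' @param zero_stimulus Row index of the undistorted reference.
#' @param unit_stimulus Row index of the unit lens.
#' @return An `aligned_scales` object with normalized `values`,
#'   `mean_scale`, the indices used, and the common `affine` map
#'   (`shift`, `scale`).
#' @export
normalize_scales <- function(aligned, zero_stimulus, unit_stimulus) {
  values <- if (inherits(aligned, "aligned_scales")) aligned$values
            else as.matrix(aligned)
  n <- nrow(values)
  if (zero_stimulus < 1 || zero_stimulus > n ||
      unit_stimulus < 1 || unit_stimulus > n) {
    stopf("reference stimulus index outside 1..%d", n)
  }
  m0 <- mean(values[zero_stimulus, ])
  m1 <- mean(values[unit_stimulus, ])
  if (m1 == m0) {
    stopf("degenerate normalization: unit and zero stimuli have equal mean")
  }
  out <- (values - m0) / (m1 - m0)
  structure(list(values = out, mean_scale = rowMeans(out),
                 transforms = if (inherits(aligned, "aligned_scales"))
                   aligned$transforms else NULL,
                 zero_stimulus = zero_stimulus,
                 unit_stimulus = unit_stimulus,
                 affine = c(shift = -m0 / (m1 - m0), scale = 1 / (m1 - m0))),
            class = "aligned_scales")
}

#' Write aligned scales as long-format CSV
#'
#' @param aligned An `aligned_scales` object.
#' @param stimuli The stimulus table the rows index.
#' @param path Output CSV path.
#' @export
write_aligned_csv <- function(aligned, stimuli, path) {
  ns <- ncol(aligned$values)
  out <- do.call(rbind, lapply(seq_len(ns), function(j) {
    data.frame(subject_id = j, sph = stimuli$sph, add = stimuli$add,
               value = aligned$values[, j])
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
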