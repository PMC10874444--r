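## Stimulus set and triplet trial-list construction.
##
## The triplet paradigm presents three stimuli per trial -- choice 1,
## anchor, choice 2 -- and the observer reports which choice appears
## more similar to the anchor.  Every unordered 3-subset of the stimulus
## set appears twice among the core trials, the second presentation with
## choice 1 and choice 2 swapped; catch (trivial) trials containing an
## exaggeratedly distorted lens are mixed in for attention checking.

#' Build the stimulus set
#'
#' Constructs the full factorial grid of lens conditions
#' (every `sph` crossed with every `add`), optionally preceded by the
#' undistorted reference.  The default arguments give the 11-condition
#' design: Sph from -5 to +5 dpt in 2.5 dpt steps, Add 1 and 3 dpt,
#' plus the reference.
#'
#' @param sph_values Spherical powers in diopters.
#' @param add_values Addition powers in diopters.
#' @param include_reference Prepend the undistorted reference condition?
#' @return A data frame of class `stimulus_set` with columns `sph`,
#'   `add`, `is_reference`; the reference, when present, is row 1.
#' @examples
#' nrow(build_stimulus_set())  # 11
#' @export
build_stimulus_set <- function(sph_values = c(-5, -2.5, 0, 2.5, 5),
                               add_values = c(1, 3),
                               include_reference = TRUE) {
  if (length(sph_values) > 0 && length(add_values) > 0) {
    if (!all(is.finite(sph_values)) || !all(is.finite(add_values))) {
      stopf("lens powers must be finite")
    }
    grid <- expand.grid(add = add_values, sph = sph_values)[, c("sph", "add")]
    if (anyDuplicated(grid)) {
      stopf("duplicate (sph, add) pairs in the requested grid")
    }
    grid$is_reference <- FALSE
  } else {
    grid <- data.frame(sph = numeric(0), add = numeric(0),
                       is_reference = logical(0))
  }
  if (include_reference) {
    grid <- rbind(data.frame(sph = 0, add = 0, is_reference = TRUE), grid)
  }
  if (any(duplicated(grid[, c("sph", "add")]))) {
    stopf("reference duplicates a requested (sph = 0, add = 0) lens")
  }
  rownames(grid) <- NULL
  class(grid) <- c("stimulus_set", "data.frame")
  grid
}

#' Build a per-subject triplet trial list
#'
#' Core trials enumerate every unordered 3-subset of the stimuli twice,
#' with choice 1 and choice 2 swapped in the second presentation (the
#' two share a `pair_id`); the anchor for each subset is drawn uniformly
#' at random and is identical in both presentations.  Catch trials pair
#' an exaggeratedly distorted lens with mildly or undistorted stimuli so
#' the odd one out is unambiguous; their count is
#' `ceiling(core * f / (1 - f))` so catch trials make up fraction `f`
#' of the list.  The full list order is randomized.  With the default
#' 11-stimulus set and `catch_fraction = 0.2` this gives 413 trials, 83
#' of them catch trials.
#'
#' @param stimuli A [build_stimulus_set()] result (>= 3 stimuli).
#' @param catch_fraction Target proportion of catch trials in `[0, 1)`.
#' @param catch_lens A [lens_spec()] for the exaggerated lens; default
#'   Sph 8 dpt, Add 3 dpt.
#' @param seed Integer seed; the same seed reproduces the list exactly.
#' @return A data frame of class `trial_list` with columns
#'   `trial_index`, `pair_id`, `choice1`, `anchor`, `choice2`
#'   (row indices into an augmented stimulus table), `is_catch`, plus
#'   attributes `stimuli` (the stimulus table, catch lens appended as
#'   the last row), `seed`, `n_core`, `n_catch`.
#' @examples
#' tl <- build_trial_list(build_stimulus_set(), seed = 1)
#' nrow(tl)                 # 413
#' sum(tl$is_catch)         # 83
#' @export
build_trial_list <- function(stimuli, catch_fraction = 0.2,
                             catch_lens = lens_spec(8, 3), seed = 1L) {
  stopifnot(inherits(stimuli, "data.frame"))
  n <- nrow(stimuli)
  if (n < 3L) stopf("need at least 3 stimuli, got %d", n)
  if (catch_fraction < 0 || catch_fraction >= 1) {
    stopf("`catch_fraction` must lie in [0, 1)")
  }
  subsets <- combn(n, 3L)
  n_sub <- ncol(subsets)
  n_core <- 2L * n_sub
  n_catch <- if (catch_fraction > 0) {
    as.integer(ceiling(n_core * catch_fraction / (1 - catch_fraction)))
  } else 0L

  stim_tab <- as.data.frame(stimuli)
  catch_idx <- NA_integer_
  if (n_catch > 0) {
    stim_tab <- rbind(stim_tab,
                      data.frame(sph = catch_lens$sph, add = catch_lens$add,
                                 is_reference = FALSE))
    catch_idx <- nrow(stim_tab)
    # mild partners: undistorted reference and the weakest distorted lenses
    mild <- which(stimuli$is_reference | abs(stimuli$sph) <= 2.5)
    if (length(mild) < 2L) {
      stopf("catch trials need at least two mildly distorted stimuli")
    }
  }

  with_seed(seed, {
    anchors <- apply(subsets, 2L, function(s) s[sample.int(3L, 1L)])
    core <- do.call(rbind, lapply(seq_len(n_sub), function(k) {
      s <- subsets[, k]
      a <- anchors[k]
      ch <- setdiff(s, a)
      data.frame(pair_id = c(k, k),
                 choice1 = c(ch[1], ch[2]),
                 anchor = a,
                 choice2 = c(ch[2], ch[1]),
                 is_catch = FALSE)
    }))
    catch <- NULL
    if (n_catch > 0) {
      catch <- do.call(rbind, lapply(seq_len(n_catch), function(k) {
        partners <- sample(mild, 2L)           # anchor + the honest choice
        ch <- c(catch_idx, partners[2])[sample.int(2L)]
        data.frame(pair_id = n_sub + k,
                   choice1 = ch[1], anchor = partners[1], choice2 = ch[2],
                   is_catch = TRUE)
      }))
    }
    trials <- rbind(core, catch)
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  })
  trials$trial_index <- seq_len(nrow(trials))
  trials <- trials[, c("trial_index", "pair_id", "choice1", "anchor",
                       "choice2", "is_catch")]
  rownames(trials) <- NULL
  structure(trials,
            stimuli = stim_tab, seed = as.integer(seed),
            n_core = n_core, n_catch = n_catch,
            class = c("trial_list", "data.frame"))
}

#' Write or read a trial list as CSV
#'
#' The CSV stores one trial per row with the lens parameters of all
#' three stimuli spelled out, preceded by `#`-comment lines recording
#' the seed and counts.
#'
#' @param trials A [build_trial_list()] result.
#' @param path Output CSV path.
#' @export
write_trial_list <- function(trials, path) {
  stopifnot(inherits(trials, "trial_list"))
  stim <- attr(trials, "stimuli")
  out <- data.frame(
    trial_index = trials$trial_index,
    pair_id = trials$pair_id,
    choice1_sph = stim$sph[trials$choice1],
    choice1_add = stim$add[trials$choice1],
    anchor_sph = stim$sph[trials$anchor],
    anchor_add = stim$add[trials$anchor],
    choice2_sph = stim$sph[trials$choice2],
    choice2_add = stim$add[trials$choice2],
    is_catch = trials$is_catch
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", attr(trials, "seed")), con)
  writeLines(sprintf("# n_core: %d n_catch: %d",
                     attr(trials, "n_core"), attr(trials, "n_catch")), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_list
#' @param path CSV path written by [write_trial_list()].
#' @export
read_trial_list_csv <- function(path) {
  read.csv(path, comment.char = "#")
}
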