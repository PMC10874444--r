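## End-to-end pipeline: simulate a cohort, embed every subject's
## responses, select dimensionality, align and normalize scales, fit
## predictive models, and analyze head/gaze behavior.  Every stage is
## driven by one explicit configuration whose seed fully determines the
## outputs; artifacts are stamped with a hash of that configuration.

#' Build a pipeline run configuration
#'
#' All tunable parameters of the end-to-end analysis in one validated
#' list.  Unknown arguments are rejected.
#'
#' @param sph_values,add_values Stimulus grid (diopters).
#' @param catch_fraction Proportion of catch trials.
#' @param n_subjects Cohort size.
#' @param subject_sd Per-subject ground-truth perturbation sd.
#' @param sigma,lapse Observer decision-noise and lapse parameters.
#' @param dims Candidate embedding dimensionalities.
#' @param folds Cross-validation folds for dimension selection.
#' @param restarts Optimizer restarts for the final per-subject fit.
#' @param cv_restarts Optimizer restarts inside cross-validation.
#' @param margin SOE hinge margin.
#' @param families Model families for leave-one-subject-out evaluation.
#' @param head_duration,head_rate Simulated head-trace length (s) and
#'   sampling rate (Hz).
#' @param gaze_n Simulated gaze samples per subject.
#' @param velocity_threshold Dynamic/static classification threshold
#'   (deg/s).
#' @param kde_bandwidth,kde_mass,kde_spacing Gaze-area KDE settings.
#' @param out_dir Output directory (`NULL` for no file output).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sph_values = c(-5, -2.5, 0, 2.5, 5),
                       add_values = c(1, 3),
                       catch_fraction = 0.2,
                       n_subjects = 13,
                       subject_sd = 0.05,
                       sigma = 0.05,
                       lapse = 0,
                       dims = 1:3,
                       folds = 10,
                       restarts = 10,
                       cv_restarts = 3,
                       margin = 1,
                       families = c("linear", "exponential",
                                    "tree-ensemble"),
                       head_duration = 20,
                       head_rate = 90,
                       gaze_n = 2000,
                       velocity_threshold = 10,
                       kde_bandwidth = 2,
                       kde_mass = 0.95,
                       kde_spacing = 0.5,
                       out_dir = NULL,
                       seed = 1L) {
  if (n_subjects < 1) stopf("configuration invalid: need at least 1 subject")
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  # hash the scientific configuration only; the output location does
  # not change what is computed
  cfg <- config[setdiff(names(config), "out_dir")]
  fnv1a_hash(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

#' Read triplet responses from CSV
#'
#' Validates the schema and values, reporting offending line numbers.
#'
#' @param path CSV written by [write_responses_csv()].
#' @return A `triplet_responses` data frame (with `subject_id` column).
#' @export
load_responses <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.csv(path)
  need <- c("subject_id", "trial_index", "pair_id", "answer", "is_catch",
            "n_repeats")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- which(!d$answer %in% c(1L, 2L))
  if (length(bad)) {
    stopf("invalid answer (not 1 or 2) on line %d", bad[1] + 1L)
  }
  if (nrow(d) == 0L) warning("response file contains no rows")
  class(d) <- c("triplet_responses", "data.frame")
  d
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> embed (per subject) -> cross-validated
#' dimension selection -> generalized Procrustes alignment ->
#' normalization -> predictive models -> behavior analysis, and
#' (optionally) writes all artifacts plus a machine-readable summary.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with elements `stimuli`,
#'   `subjects` (per-subject fit summaries), `aligned`, `normalized`,
#'   `exponential_fits`, `loso`, `behavior`, `ols`, `group_tests`,
#'   `summary` (the JSON-ready summary list).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  stage <- "design"
  res <- tryCatch({
    stimuli <- build_stimulus_set(config$sph_values, config$add_values,
                                  include_reference = TRUE)
    seeds <- derive_seeds(config$seed, 4L + config$n_subjects)
    trials <- build_trial_list(stimuli, config$catch_fraction,
                               seed = seeds[1])
    stim_aug <- attr(trials, "stimuli")
    n_stim <- nrow(stimuli)

    stage <- "simulate"
    cohort <- make_cohort(config$n_subjects, stim_aug,
                          subject_sd = config$subject_sd,
                          sigma = config$sigma, lapse = config$lapse,
                          seed = seeds[2])
    responses <- lapply(seq_len(config$n_subjects), function(j) {
      answer_trials(trials, cohort$true_scales[, j], cohort$profiles[[j]])
    })

    stage <- "embed"
    subjects <- vector("list", config$n_subjects)
    raw_scales <- matrix(NA_real_, nrow = n_stim, ncol = config$n_subjects)
    for (j in seq_len(config$n_subjects)) {
      tri <- response_triplets(trials, responses[[j]])
      cv <- cv_dimension_select(tri, n_stim, dims = config$dims,
                                folds = config$folds,
                                seed = seeds[4L + j],
                                restarts = config$cv_restarts,
                                margin = config$margin)
      # the aligned scale is 1-D by design; the CV-selected dimension is
      # recorded (and expected to be 1 for consistent observers)
      fit <- soe_embed(tri, n_stim, dim = 1L,
                       margin = config$margin, restarts = config$restarts,
                       seed = seeds[4L + j])
      catch <- responses[[j]][responses[[j]]$is_catch, , drop = FALSE]
      catch_tri <- response_triplets(trials, catch, include_catch = TRUE)
      # a catch answer is correct iff the winner is not the catch lens
      catch_lens <- nrow(stim_aug)
      catch_score <- if (nrow(catch_tri)) {
        mean(catch_tri$winner != catch_lens)
      } else NA_real_
      raw_scales[, j] <- as.vector(fit$X)
      subjects[[j]] <- list(subject = j, cv = cv, fit = fit,
                            accuracy = fit$accuracy,
                            catch_score = catch_score,
                            selected_dim = cv$selected)
    }

    stage <- "align"
    aligned <- gpa_align_1d(raw_scales)
    zero_idx <- which(stimuli$is_reference)
    unit_idx <- which(stimuli$sph == 5 & stimuli$add == 3)
    if (length(zero_idx) != 1L || length(unit_idx) != 1L) {
      stopf("normalization stimuli (reference, Sph 5 / Add 3) not found")
    }
    normalized <- normalize_scales(aligned, zero_idx, unit_idx)

    stage <- "fit"
    mean_scale <- normalized$mean_scale
    exp_fits <- lapply(config$add_values, function(ad) {
      sel <- !stimuli$is_reference & stimuli$add == ad
      fit_exponential(data.frame(sph = stimuli$sph[sel],
                                 value = mean_scale[sel]))
    })
    names(exp_fits) <- paste0("add", config$add_values)
    loso <- loso_evaluate(normalized, stimuli, families = config$families,
                          seed = seeds[3])

    stage <- "behavior"
    behavior <- do.call(rbind, lapply(seq_len(config$n_subjects),
                                      function(j) {
      prof <- cohort$profiles[[j]]
      trace <- simulate_head_trace(prof, duration = config$head_duration,
                                   rate = config$head_rate)
      mv <- mean_abs_velocity(trace)
      gaze <- simulate_gaze(prof, n = config$gaze_n)
      data.frame(subject_id = j,
                 mean_vyaw = mv["yaw"], mean_vpitch = mv["pitch"],
                 mean_vroll = mv["roll"],
                 class = classify_movement(mv, config$velocity_threshold),
                 gaze_area_pct = gaze_area(gaze,
                                           bandwidth = config$kde_bandwidth,
                                           mass = config$kde_mass,
                                           grid_spacing = config$kde_spacing),
                 row.names = NULL)
    }))
    acc <- vapply(subjects, function(s) s$accuracy, numeric(1))
    catch_scores <- vapply(subjects, function(s) s$catch_score, numeric(1))
    dyn <- behavior$class == "dynamic"
    group_tests <- if (any(dyn) && any(!dyn)) {
      list(accuracy = mann_whitney_u(acc[dyn], acc[!dyn]),
           catch = mann_whitney_u(catch_scores[dyn], catch_scores[!dyn]))
    } else NULL
    ols_table <- scales_long(normalized$values, stimuli)
    ols_table$movement_class <- behavior$class[ols_table$subject]
    ols_table$gaze_area <- behavior$gaze_area_pct[ols_table$subject]
    ols <- behavior_ols(ols_table)

    summary <- list(
      config_hash = hash, seed = config$seed,
      n_trials = nrow(trials), n_catch = sum(trials$is_catch),
      n_stimuli = n_stim,
      selected_dims = vapply(subjects, function(s) s$selected_dim,
                             integer(1)),
      accuracies = acc, catch_scores = catch_scores,
      mean_scale = mean_scale,
      exponential_fits = lapply(exp_fits, function(f)
        list(a = f$a, b = f$b, c = f$c, rss = f$rss)),
      loso = loso, behavior = behavior,
      ols = ols,
      group_tests = if (!is.null(group_tests)) {
        list(accuracy_p = group_tests$accuracy$p,
             catch_p = group_tests$catch$p)
      } else NULL
    )

    list(stimuli = stimuli, trials = trials, cohort = cohort,
         responses = responses, subjects = subjects, aligned = aligned,
         normalized = normalized, exponential_fits = exp_fits,
         loso = loso, behavior = behavior, ols = ols,
         group_tests = group_tests, summary = summary,
         config = config, hash = hash)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("%s_seed%d", hash, config$seed)
    for (j in seq_len(config$n_subjects)) {
      write_responses_csv(res$responses[[j]],
                          file.path(config$out_dir,
                                    sprintf("responses_s%02d_%s.csv",
                                            j, stamp)), subject_id = j)
    }
    write_aligned_csv(res$normalized, res$stimuli,
                      file.path(config$out_dir,
                                sprintf("scales_%s.csv", stamp)))
    write.csv(res$loso, file.path(config$out_dir,
                                  sprintf("loso_%s.csv", stamp)),
              row.names = FALSE)
    write.csv(res$behavior, file.path(config$out_dir,
                                      sprintf("behavior_%s.csv", stamp)),
              row.names = FALSE)
    write.csv(res$ols, file.path(config$out_dir,
                                 sprintf("ols_%s.csv", stamp)),
              row.names = FALSE)
    jsonlite::write_json(res$summary,
                         file.path(config$out_dir,
                                   sprintf("summary_%s.json", stamp)),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d subjects, %d stimuli, %d trials\n",
              length(x$subjects), nrow(x$stimuli), nrow(x$trials)))
  cat(sprintf("  selected dimensions: %s\n",
              paste(x$summary$selected_dims, collapse = " ")))
  cat(sprintf("  mean triplet accuracy: %.3f\n",
              mean(x$summary$accuracies)))
  invisible(x)
}
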