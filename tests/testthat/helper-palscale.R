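# Shared fixtures, built in code.

default_stimuli <- function() build_stimulus_set()

# Trial list + noiseless responses for one synthetic subject on the
# 11-stimulus design.
noiseless_subject <- function(design_seed = 7, answer_seed = 3,
                              params = scale_params()) {
  stimuli <- default_stimuli()
  trials <- build_trial_list(stimuli, seed = design_seed)
  truth <- materialize_scale(params, attr(trials, "stimuli"))
  responses <- answer_trials(trials, truth,
                             observer_profile(sigma = 0, lapse = 0,
                                              seed = answer_seed))
  list(stimuli = stimuli, trials = trials, truth = truth,
       responses = responses,
       triplets = response_triplets(trials, responses))
}

# Independent oracle for 1-D ordinal embedding: exhaustive grid search
# over small 1-D configurations, scoring the number of satisfied
# constraints (no gradients, no margin).
brute_force_1d <- function(triplets, n_stimuli, grid = seq(-2, 2, by = 0.25)) {
  configs <- do.call(expand.grid, rep(list(grid), n_stimuli))
  score <- apply(configs, 1L, function(x) {
    dw <- abs(x[triplets$anchor] - x[triplets$winner])
    dl <- abs(x[triplets$anchor] - x[triplets$loser])
    sum(ifelse(dw < dl, 1, ifelse(dw > dl, 0, 0.5)))
  })
  as.numeric(configs[which.max(score), ])
}

# Rotation matrix oracle for the intrinsic y-x-z Tait-Bryan sequence.
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}
yxz_matrix <- function(yaw, pitch, roll) rot_y(yaw) %*% rot_x(pitch) %*% rot_z(roll)

# Closed-form area of the `mass` superlevel set of an isotropic 2-D
# Gaussian of sd `sigma` (deg), as percent of the half-sphere.
gauss_disc_area_pct <- function(sigma, mass = 0.95) {
  planar <- pi * qchisq(mass, df = 2) * sigma^2      # deg^2
  100 * planar * (pi / 180)^2 / (2 * pi)
}
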