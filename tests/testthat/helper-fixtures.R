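# Shared fixtures. The printed 11-deg field cannot geometrically contain the
# printed dot areas (see vignette), so array-generating tests use a 30-deg
# placement field; all analytic area/diameter checks are field-independent.

feasible_spec <- function(...) stimulus_spec(field_diameter = 30, ...)

# Small cohort simulated through the full raw-trace pipeline.
make_cohort <- function(n_participants = 2, reps = 2, seed = 42,
                        params = sim_params(n_participants = n_participants),
                        experiment = 1L) {
  params$n_participants <- n_participants
  profiles <- participant_profiles(params, seed = derive_seed(seed, "prof"))
  design <- build_design(profiles$participant_id, experiment = experiment,
                         reps_per_numerosity_per_session = reps,
                         seed = derive_seed(seed, "design"))
  sessions <- lapply(seq_len(n_participants), function(p) {
    pid <- profiles$participant_id[p]
    lapply(1:4, function(s)
      simulate_session(design[design$participant_id == pid &
                                design$session == s, ],
                       params, profiles[p, ],
                       seed = derive_seed(seed, "sess", pid, s)))
  })
  list(params = params, profiles = profiles, design = design,
       sessions = sessions)
}

# Noise-free parameters: every stochastic nuisance off.
noiseless_params <- function(n_participants = 1, ...) {
  sim_params(n_participants = n_participants, drift_amplitude_mm = 0,
             amp_trial_cv = 0, k_sd = 0, estimate_cv = 0, noise_sd_mm = 0,
             blink_rate_hz = 0, spike_rate_hz = 0, saccade_trial_prob = 0,
             gaze_noise_sd_deg = 0, ...)
}
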