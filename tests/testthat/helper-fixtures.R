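# Shared fixtures: small simulated datasets built in code at test time.

grid_offers <- function(step = 10) grid_design(step)

# One subject with known CES parameters and mild noise, for recovery tests.
make_subject <- function(alpha = 0.6, delta = 1.5, temperature = 8,
                         rating_noise = 1, force_noise = 8, seed = 101,
                         n_choice = 200) {
  set.seed(seed)
  cfg <- cohort_config(n_subjects = 1, seed = seed)
  pars <- list(
    value_params = list(alpha = alpha, delta = delta),
    temperature = temperature,
    rating = list(slope = 0.1, intercept = 0, noise_sd = rating_noise),
    force = list(slope = 1, intercept = 20, noise_sd = force_noise))
  list(subject = 1, params = pars,
       rating = simulate_task(pars, "rating", grid_design(10, TRUE), cfg),
       force  = simulate_task(pars, "force", grid_design(10, TRUE), cfg),
       choice = simulate_task(pars, "choice", random_choice_design(n_choice),
                              cfg))
}

small_cohort <- function(n = 3, seed = 5, ...) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}
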