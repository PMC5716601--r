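#' Factorial offer grid for the rating and force tasks
#'
#' All combinations of gain and donation from 0 to 100 euros in `step`-euro
#' increments. At the default 10-euro step this is the 11 x 11 = 121-offer
#' design, presented once each in randomized order across three sessions of
#' 40, 41 and 40 trials.
#'
#' @param step Euro step; must divide 100.
#' @param randomize Randomize trial order and assign sessions (uses the
#'   current RNG state).
#' @return A data.frame with columns `gain`, `donation` and, when
#'   `randomize = TRUE` and the grid has 121 offers, `session` and `trial`.
#' @export
grid_design <- function(step = 10, randomize = FALSE) {
  if (100 %% step != 0) stop("step must divide 100")
  amounts <- seq(0, 100, by = step)
  g <- expand.grid(gain = amounts, donation = amounts,
                   KEEP.OUT.ATTRS = FALSE)
  if (!randomize) return(g)
  g <- g[sample.int(nrow(g)), , drop = FALSE]
  rownames(g) <- NULL
  g$trial <- seq_len(nrow(g))
  if (nrow(g) == 121L) {
    g$session <- rep(1:3, c(40L, 41L, 40L))
  } else {
    g$session <- 1L
  }
  g
}

#' Random informative choice pairs on a fine euro grid
#'
#' Draws `n` unordered offer pairs subject to the informativeness
#' constraints: the two offers differ on both dimensions, neither dominates
#' the other (gains and donations are crossed), and no pair repeats. Sides
#' are assigned at random. Used as the default (non-adaptive) choice design
#' for simulation.
#'
#' @param n Number of trials.
#' @param step Euro grid step (default 1).
#' @return Data.frame with columns `gain_left`, `donation_left`,
#'   `gain_right`, `donation_right`.
#' @export
random_choice_design <- function(n = 200, step = 1) {
  amounts <- seq(0, 100, by = step)
  seen <- character(0)
  out <- matrix(NA_real_, n, 4)
  i <- 1L
  while (i <= n) {
    gs <- sort(sample(amounts, 2L))
    ds <- sort(sample(amounts, 2L))
    if (gs[1] == gs[2] || ds[1] == ds[2]) next
    # crossed: higher gain paired with lower donation
    a <- c(gs[2], ds[1]); b <- c(gs[1], ds[2])
    key <- paste(a[1], a[2], b[1], b[2], sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (stats::runif(1) < 0.5) out[i, ] <- c(a, b) else out[i, ] <- c(b, a)
    i <- i + 1L
  }
  out <- as.data.frame(out)
  names(out) <- c("gain_left", "donation_left", "gain_right", "donation_right")
  out$trial <- seq_len(n)
  out$session <- 1L
  out
}

#' Synthetic-cohort configuration
#'
#' Population-level settings for simulating a cohort performing the three
#' tasks. Subject-level generative parameters are drawn on their natural
#' scales: the CES selfishness share from a logistic-normal centred at 0.58,
#' the concavity from a log-normal centred at 1.5 (the group means reported
#' for this design), the softmax temperature from a log-normal, and the
#' rating/force scaling parameters from normals. Force scaling defaults put
#' the average simulated force near 70% of maximum, matching the grip
#' literature this design builds on.
#'
#' @param n_subjects Number of subjects (default 19).
#' @param model Generative value model (default `"ces"`).
#' @param alpha_mean,alpha_sd Logit-scale mean is `qlogis(alpha_mean)`;
#'   `alpha_sd` is the logit-scale SD. One selfishness value per subject,
#'   shared by the three tasks.
#' @param delta_mean,delta_sd Log-scale mean is `log(delta_mean)`;
#'   `delta_sd` is the log-scale SD of the subject-level concavity effect.
#' @param delta_task_ratio Named multipliers applied to each subject's
#'   concavity in the three tasks (CES generative model only). The defaults
#'   reproduce the task ordering observed with this design — strongest
#'   curvature under effort, none under choice — around the 1.5 centre;
#'   set all to 1 for a single concavity across tasks.
#' @param temperature_mean,temperature_sd Log-normal softmax temperature
#'   (utility units); the default mean yields a simulated balanced accuracy
#'   near 0.8.
#' @param rating_slope,rating_intercept,rating_noise_sd Rating scaling
#'   (mean slope/intercept, between-subject SDs fixed internally) and
#'   Gaussian response noise in scale units.
#' @param force_slope,force_intercept,force_noise_sd Force scaling and
#'   response noise in percent of maximal force.
#' @param n_choice_trials Choice-task length (default 200).
#' @param choice_step Euro grid step for choice offers (default 1).
#' @param extra_params Optional named list of native-scale value parameters
#'   for non-CES generative models (fixed across subjects unless drawn).
#' @param seed Master seed controlling all randomness in
#'   [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 19,
                          model = "ces",
                          alpha_mean = 0.58, alpha_sd = 0.5,
                          delta_mean = 1.5, delta_sd = 0.5,
                          delta_task_ratio = c(force = 1.32, rating = 1.07,
                                               choice = 0.73),
                          temperature_mean = 8, temperature_sd = 0.3,
                          rating_slope = 0.1, rating_intercept = 0,
                          rating_noise_sd = 1.0,
                          force_slope = 1.0, force_intercept = 15,
                          force_noise_sd = 8,
                          n_choice_trials = 200, choice_step = 1,
                          extra_params = NULL,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, alpha_mean > 0, alpha_mean < 1,
            delta_mean > 0, temperature_mean > 0,
            rating_noise_sd >= 0, force_noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 delta_task_ratio = delta_task_ratio,
                 temperature_mean = temperature_mean,
                 temperature_sd = temperature_sd,
                 rating_slope = rating_slope,
                 rating_intercept = rating_intercept,
                 rating_noise_sd = rating_noise_sd,
                 force_slope = force_slope,
                 force_intercept = force_intercept,
                 force_noise_sd = force_noise_sd,
                 n_choice_trials = as.integer(n_choice_trials),
                 choice_step = choice_step,
                 extra_params = extra_params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw one subject's generative parameters
#'
#' Uses the current RNG state; [simulate_cohort()] seeds it once from the
#' master seed so the whole cohort is reproducible.
#'
#' @param config A [cohort_config()].
#' @return A list with `value_params` (native scale), `temperature`,
#'   `rating` (slope, intercept, noise_sd) and `force` components.
#' @export
sample_subject_params <- function(config) {
  spec <- value_model(config$model)
  vp <- list()
  for (nm in names(spec$params)) {
    vp[[nm]] <- switch(nm,
      alpha = if (spec$params[[nm]] == "logit")
                stats::plogis(stats::rnorm(1, stats::qlogis(config$alpha_mean),
                                           config$alpha_sd))
              else exp(stats::rnorm(1, log(1), 0.2)),
      beta  = exp(stats::rnorm(1, log(1), 0.2)),
      delta = if (spec$params[[nm]] == "logit")
                stats::plogis(stats::rnorm(1, 0, 0.4))
              else exp(stats::rnorm(1, log(config$delta_mean),
                                    config$delta_sd)),
      epsilon = exp(stats::rnorm(1, log(config$delta_mean), config$delta_sd)),
      gamma = stats::rnorm(1, 0, 0.002),
      stats::rnorm(1, 0, 0.2))
    if (!is.null(config$extra_params[[nm]])) vp[[nm]] <- config$extra_params[[nm]]
  }
  # Task-wise concavities are drawn independently around task-specific
  # centres: elicitation mode shifts the typical curvature (strongest under
  # effort, none under choice) and concavity does not correlate across
  # tasks within subjects, unlike selfishness which is a single trait.
  delta_by_task <- NULL
  if (config$model == "ces" && !is.null(config$delta_task_ratio) &&
      is.null(config$extra_params[["delta"]])) {
    delta_by_task <- exp(stats::rnorm(
      length(config$delta_task_ratio),
      log(config$delta_mean * config$delta_task_ratio),
      config$delta_sd))
    names(delta_by_task) <- names(config$delta_task_ratio)
  }
  list(value_params = vp, delta_by_task = delta_by_task,
       temperature = exp(stats::rnorm(1, log(config$temperature_mean),
                                      config$temperature_sd)),
       rating = list(slope = stats::rnorm(1, config$rating_slope,
                                          config$rating_slope * 0.1),
                     intercept = stats::rnorm(1, config$rating_intercept, 0.25),
                     noise_sd = config$rating_noise_sd),
       force = list(slope = stats::rnorm(1, config$force_slope,
                                         config$force_slope * 0.08),
                    intercept = stats::rnorm(1, config$force_intercept, 3),
                    noise_sd = config$force_noise_sd))
}

#' Simulate one task for one subject
#'
#' Ratings and forces are the linearly scaled value plus Gaussian noise,
#' clipped to the task bounds; choices are Bernoulli draws from the softmax
#' probability. Feedback is Bernoulli(0.7) in the rating and choice tasks
#' and Bernoulli(force / 100) in the force task.
#'
#' @param params Subject parameters from [sample_subject_params()].
#' @param task `"rating"`, `"force"` or `"choice"`.
#' @param design Trial design: offers from [grid_design()] (rating/force)
#'   or pairs from [random_choice_design()] (choice).
#' @param config A [cohort_config()] (for the generative model name).
#' @param tc A [task_config()].
#' @return Data.frame of trial records.
#' @export
simulate_task <- function(params, task, design, config, tc = task_config()) {
  task <- match.arg(task, c("rating", "force", "choice"))
  n <- nrow(design)
  vp <- params$value_params
  if (!is.null(params$delta_by_task) && !is.null(vp$delta))
    vp$delta <- unname(params$delta_by_task[[task]])
  if (task == "choice") {
    vl <- value_function(config$model, vp,
                         design$gain_left, design$donation_left)
    vr <- value_function(config$model, vp,
                         design$gain_right, design$donation_right)
    p <- choice_probability(vl, vr, params$temperature)
    resp <- stats::rbinom(n, 1L, p)
    fb <- stats::rbinom(n, 1L, tc$win_probability)
    out <- data.frame(task = task, session = design$session,
                      trial = design$trial,
                      gain_left = design$gain_left,
                      donation_left = design$donation_left,
                      gain_right = design$gain_right,
                      donation_right = design$donation_right,
                      response = resp, feedback = fb)
  } else {
    V <- value_function(config$model, vp,
                        design$gain, design$donation)
    sc <- params[[task]]
    bounds <- if (task == "rating") tc$rating_bounds else tc$force_bounds
    resp <- pmin(pmax(sc$slope * V + sc$intercept +
                        stats::rnorm(n, 0, sc$noise_sd),
                      bounds[1]), bounds[2])
    fb <- if (task == "force") stats::rbinom(n, 1L, pmin(resp / 100, 1))
          else stats::rbinom(n, 1L, tc$win_probability)
    out <- data.frame(task = task, session = design$session,
                      trial = design$trial,
                      gain_left = design$gain, donation_left = design$donation,
                      gain_right = NA_real_, donation_right = NA_real_,
                      response = resp, feedback = fb)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Each subject performs the 121-offer rating and force tasks (all grid
#' offers exactly once, randomized into sessions of 40/41/40) and a
#' choice task over informative offer pairs. True generative
#' parameters are retained per subject for closed-loop recovery tests.
#'
#' @param config A [cohort_config()].
#' @param file Optional path; if given, the combined trial table is written
#'   as CSV.
#' @return An object of class `cohort`: a list of per-subject datasets, each
#'   with elements `subject`, `params`, `rating`, `force`, `choice`.
#' @export
simulate_cohort <- function(config = cohort_config(), file = NULL) {
  set.seed(config$seed)
  tc <- task_config()
  cohort <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    pars <- sample_subject_params(config)
    rat_design <- grid_design(10, randomize = TRUE)
    frc_design <- grid_design(10, randomize = TRUE)
    cho_design <- random_choice_design(config$n_choice_trials,
                                       config$choice_step)
    cohort[[s]] <- list(
      subject = s,
      params = pars,
      rating = simulate_task(pars, "rating", rat_design, config, tc),
      force  = simulate_task(pars, "force",  frc_design, config, tc),
      choice = simulate_task(pars, "choice", cho_design, config, tc))
  }
  cohort <- structure(cohort, class = "cohort", config = config)
  if (!is.null(file)) {
    tab <- cohort_table(cohort)
    ok <- tryCatch(utils::write.csv(tab, file, row.names = FALSE, na = ""),
                   error = function(e)
                     stop(sprintf("failed to write trial table to '%s': %s",
                                  file, conditionMessage(e))))
  }
  cohort
}

#' Flatten a cohort to a single trial table
#'
#' @param cohort A `cohort` object.
#' @return Data.frame with one row per trial and columns
#'   `subject,task,session,trial,gain_left,donation_left,gain_right,`
#'   `donation_right,response,feedback`.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    tab <- rbind(s$rating, s$force, s$choice)
    cbind(subject = s$subject, tab)
  })
  do.call(rbind, rows)
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic cohort: %d subjects, generative model '%s'\n",
              length(x), cfg$model))
  cat(sprintf("  per subject: %d rating + %d force + %d choice trials\n",
              nrow(x[[1]]$rating), nrow(x[[1]]$force), nrow(x[[1]]$choice)))
  invisible(x)
}
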