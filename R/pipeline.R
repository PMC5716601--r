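## End-to-end analysis pipeline over a (synthetic) cohort: model-free
## regressions, full Bayesian model comparison across the twelve value
## functions and three tasks, parameter-sharing comparison, cross-task
## choice prediction and convergence analysis.

#' Model-free regressions per subject and task
#'
#' For every subject: linear regressions of ratings and forces, and a
#' logistic regression of choices, on gain, donation and their interaction
#' (choice regressors are left-minus-right differences); a fatigue check
#' regressing the residuals on trial and session number; and a quadratic
#' fit to the (normalized) response distribution of the rating and force
#' tasks. Group-level one-sample t-tests summarize each coefficient.
#'
#' @param cohort A `cohort` (or any list of subject datasets with
#'   `rating`, `force`, `choice` tables).
#' @return List of class `model_free_result` with `coefficients` (one row
#'   per subject x task), `fatigue`, `quadratic` and `group` (t-test
#'   summary table).
#' @export
model_free_analysis <- function(cohort) {
  co <- list(); fat <- list(); quad <- list()
  for (s in seq_along(cohort)) {
    sub <- cohort[[s]]
    for (tk in c("rating", "force", "choice")) {
      d <- sub[[tk]]
      if (tk == "choice") {
        dg <- d$gain_left - d$gain_right
        dd <- d$donation_left - d$donation_right
        dgd <- d$gain_left * d$donation_left -
               d$gain_right * d$donation_right
        m <- tryCatch(stats::glm(d$response ~ dg + dd + dgd,
                                 family = stats::binomial()),
                      warning = function(w) suppressWarnings(
                        stats::glm(d$response ~ dg + dd + dgd,
                                   family = stats::binomial())))
      } else {
        m <- stats::lm(response ~ gain_left * donation_left, data = d)
      }
      cf <- stats::coef(m)
      co[[length(co) + 1]] <- data.frame(
        subject = s, task = tk,
        b_gain = cf[[2]], b_donation = cf[[3]], b_interaction = cf[[4]])
      has_sessions <- length(unique(d$session)) > 1
      fm <- if (has_sessions)
        stats::lm(stats::resid(m) ~ d$trial + d$session)
      else stats::lm(stats::resid(m) ~ d$trial)
      cm <- summary(fm)$coefficients
      fat[[length(fat) + 1]] <- data.frame(
        subject = s, task = tk,
        b_trial = cm[2, 1], p_trial = cm[2, 4],
        b_session = if (has_sessions) cm[3, 1] else NA_real_,
        p_session = if (has_sessions) cm[3, 4] else NA_real_)
      if (tk != "choice") {
        r01 <- (d$response - min(d$response)) /
               max(diff(range(d$response)), 1e-9)
        h <- graphics::hist(r01, breaks = seq(0, 1, by = 0.1), plot = FALSE)
        qm <- stats::lm(h$density ~ h$mids + I(h$mids^2))
        quad[[length(quad) + 1]] <- data.frame(
          subject = s, task = tk, b_quadratic = stats::coef(qm)[[3]])
      }
    }
  }
  co <- do.call(rbind, co); fat <- do.call(rbind, fat)
  quad <- do.call(rbind, quad)
  group <- do.call(rbind, lapply(split(co, co$task), function(dd) {
    do.call(rbind, lapply(c("b_gain", "b_donation", "b_interaction"),
      function(v) {
        tt <- stats::t.test(dd[[v]])
        data.frame(task = dd$task[1], coefficient = v,
                   mean = mean(dd[[v]]),
                   se = stats::sd(dd[[v]]) / sqrt(nrow(dd)),
                   t = unname(tt$statistic), p = tt$p.value)
      }))
  }))
  rownames(group) <- NULL
  structure(list(coefficients = co, fatigue = fat, quadratic = quad,
                 group = group),
            class = "model_free_result")
}

#' Full Bayesian model comparison over the cohort
#'
#' Fits every value model in `models` to every subject and task, builds the
#' combined task-wise model space (one column per model triple), runs the
#' family inference "same value function in all tasks" versus "different
#' functions", and — pooling evidences over tasks — a model-level
#' comparison within the `same` family.
#'
#' @param cohort A `cohort`.
#' @param models Vector of model ids/names (default all 12).
#' @param n_restarts Optimizer restarts per fit.
#' @param seed Base seed for fitting.
#' @param xp_samples,bms_seed Group-level BMS settings.
#' @return List of class `model_comparison` with per-task evidence matrices
#'   `E` (list), `combined` ([build_combined_space()] output), `family`
#'   (same-vs-different [family_inference()]), and `within_same`
#'   ([rfx_bms()] over pooled evidences).
#' @export
full_model_comparison <- function(cohort, models = 1:12, n_restarts = 3,
                                  seed = 1L, xp_samples = 1e6,
                                  bms_seed = 1L) {
  tasks <- c("force", "rating", "choice")
  model_names <- vapply(models, function(m) value_model(m)$name, "")
  n <- length(cohort)
  E <- lapply(stats::setNames(tasks, tasks), function(tk)
    matrix(NA_real_, n, length(models),
           dimnames = list(NULL, model_names)))
  failures <- list()
  for (s in seq_len(n)) {
    for (tk in tasks) {
      for (j in seq_along(models)) {
        f <- tryCatch(
          fit_value_model(cohort[[s]][[tk]], models[[j]], tk,
                          n_restarts = n_restarts, seed = seed + s),
          error = function(e) e)
        if (inherits(f, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(subject = s, task = tk, model = model_names[j],
                       message = conditionMessage(f))
        } else {
          E[[tk]][s, j] <- f$log_evidence
        }
      }
    }
  }
  # listwise exclusion of subjects with any failed fit
  ok <- Reduce(`&`, lapply(E, function(m) apply(is.finite(m), 1, all)))
  if (!any(ok)) stop("no subject has a complete set of fits")
  E <- lapply(E, function(m) m[ok, , drop = FALSE])
  comb <- build_combined_space(E$force, E$rating, E$choice)
  fam_part <- list(same = comb$same_family,
                   different = setdiff(seq_along(comb$labels),
                                       comb$same_family))
  family <- family_inference(comb$E, fam_part, xp_samples = xp_samples,
                             seed = bms_seed)
  pooled <- E$force + E$rating + E$choice
  within <- rfx_bms(pooled, xp_samples = xp_samples, seed = bms_seed)
  structure(list(E = E, combined = comb, family = family,
                 within_same = within, included = which(ok),
                 failures = if (length(failures)) do.call(rbind, failures)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Combined-space family inference (same vs different value function):\n")
  print(round(rbind(Ef = x$family$family_ef, Xp = x$family$family_xp), 3))
  best <- names(which.max(x$within_same$ef))
  cat(sprintf("Winning model within the 'same' family: '%s' (Ef = %.2f)\n",
              best, max(x$within_same$ef)))
  invisible(x)
}

#' Parameter-sharing comparison across tasks
#'
#' For each subject, fits the five sharing partitions of the three tasks
#' for the given parameter role(s) of the winning model on the pooled data,
#' then compares the five variants at the group level by RFX-BMS. Also
#' reports the per-task parameter estimates of the unconstrained
#' (all-distinct) fit with their cross-task Pearson and Spearman
#' correlations.
#'
#' @param cohort A `cohort`.
#' @param model Winning value model (default `"ces"`).
#' @param roles Parameter roles to examine.
#' @param n_restarts,seed Fitting settings.
#' @param xp_samples,bms_seed Group BMS settings.
#' @return List of class `sharing_comparison`, one element per role:
#'   `bms` (over the 5 partitions), `evidence` (subjects x 5),
#'   `estimates` (per-task parameter values from the all-distinct fit),
#'   `correlations` (task-pair Pearson/Spearman).
#' @export
parameter_sharing_comparison <- function(cohort, model = "ces",
                                         roles = c("alpha", "delta"),
                                         n_restarts = 2, seed = 1L,
                                         xp_samples = 1e6, bms_seed = 1L) {
  parts <- sharing_partitions()
  tasks <- c("force", "rating", "choice")
  task_fit_cache <- lapply(seq_along(cohort), function(s)
    lapply(stats::setNames(tasks, tasks), function(tk) tryCatch(
      fit_value_model(cohort[[s]][[tk]], model, tk,
                      n_restarts = 2, seed = seed + s),
      error = function(e) NULL)))
  out <- list()
  for (role in roles) {
    Em <- matrix(NA_real_, length(cohort), length(parts),
                 dimnames = list(NULL, names(parts)))
    est <- list()
    for (s in seq_along(cohort)) {
      tf <- task_fit_cache[[s]]
      for (pn in names(parts)) {
        f <- fit_shared(cohort[[s]], model, role, parts[[pn]],
                        n_restarts = n_restarts, seed = seed + s,
                        task_fits = tf)
        Em[s, pn] <- f$log_evidence
        if (pn == "all_distinct") {
          lbl <- vapply(parts[[pn]], function(cl)
            paste0(role, "[", substr(cl, 1, 1), "]"), "")
          est[[s]] <- data.frame(
            subject = s,
            force = f$par[[lbl[1]]], rating = f$par[[lbl[2]]],
            choice = f$par[[lbl[3]]])
        }
      }
    }
    est <- do.call(rbind, est)
    pairs <- utils::combn(c("force", "rating", "choice"), 2)
    cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- est[[pairs[1, i]]]; b <- est[[pairs[2, i]]]
      data.frame(task_1 = pairs[1, i], task_2 = pairs[2, i],
                 pearson = stats::cor(a, b),
                 spearman = stats::cor(a, b, method = "spearman"))
    }))
    out[[role]] <- list(
      bms = rfx_bms(Em, xp_samples = xp_samples, seed = bms_seed),
      evidence = Em, estimates = est, correlations = cors)
  }
  structure(out, class = "sharing_comparison")
}

#' @export
print.sharing_comparison <- function(x, ...) {
  for (role in names(x)) {
    best <- names(which.max(x[[role]]$bms$ef))
    cat(sprintf("Role '%s': winning partition '%s' (Ef = %.2f, Xp = %.2f)\n",
                role, best, max(x[[role]]$bms$ef),
                x[[role]]$bms$xp[best]))
  }
  invisible(x)
}

#' Predict choices from rating- and force-derived value functions
#'
#' For each subject, evaluates the value difference of every choice pair
#' under the CES parameters fitted to the rating task and to the force
#' task, classifies choices at the 0.5 probability threshold (i.e. by the
#' sign of the value difference), and reports the balanced accuracy (mean
#' of sensitivity and specificity). A logistic regression of the observed
#' choices on each value difference yields a temperature estimate (inverse
#' slope).
#'
#' @param cohort A `cohort`.
#' @param model Value model (default `"ces"`).
#' @param n_restarts,seed Fitting settings.
#' @param fits Optional list of precomputed per-subject fits:
#'   `fits[[s]]$rating`, `fits[[s]]$force` (`value_fit` objects).
#' @return Data.frame of class `cross_task_prediction` with one row per
#'   subject x source task: balanced accuracy and logistic temperature.
#' @export
cross_task_prediction <- function(cohort, model = "ces", n_restarts = 3,
                                  seed = 1L, fits = NULL) {
  rows <- list()
  for (s in seq_along(cohort)) {
    ch <- cohort[[s]]$choice
    y <- as.numeric(ch$response)
    if (length(unique(y)) < 2) {
      warning(sprintf("subject %d: all choices on one side; balanced accuracy undefined", s))
      next
    }
    for (src in c("rating", "force")) {
      f <- if (!is.null(fits)) fits[[s]][[src]]
           else fit_value_model(cohort[[s]][[src]], model, src,
                                n_restarts = n_restarts, seed = seed + s)
      vp <- as.list(coef(f)[names(value_model(model)$params)])
      dv <- value_function(model, vp, ch$gain_left, ch$donation_left) -
            value_function(model, vp, ch$gain_right, ch$donation_right)
      pred <- as.numeric(dv > 0)
      sens <- mean(pred[y == 1] == 1)
      spec <- mean(pred[y == 0] == 0)
      lr <- suppressWarnings(stats::glm(y ~ dv, family = stats::binomial()))
      slope <- stats::coef(lr)[["dv"]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, source = src,
        balanced_accuracy = (sens + spec) / 2,
        temperature = if (slope > 0) 1 / slope else NA_real_)
    }
  }
  structure(do.call(rbind, rows),
            class = c("cross_task_prediction", "data.frame"))
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param models Model-space subset for the comparison stage.
#' @param n_restarts Optimizer restarts used by the fitting stages.
#' @param xp_samples Monte-Carlo samples for exceedance probabilities.
#' @param convergence_subjects Number of subjects entering the (costly)
#'   convergence stage; 0 disables it.
#' @param convergence_step Refit stride for the convergence stage.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            models = 1:12, n_restarts = 3,
                            xp_samples = 1e6,
                            convergence_subjects = 0,
                            convergence_step = 5,
                            seed = 1L) {
  structure(list(cohort = cohort, models = models, n_restarts = n_restarts,
                 xp_samples = xp_samples,
                 convergence_subjects = convergence_subjects,
                 convergence_step = convergence_step,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, then run the model-free regressions, the
#' full model comparison, the parameter-sharing comparison, the cross-task
#' choice prediction and (optionally) the convergence analysis, writing CSV
#' and JSON artifacts plus a human-readable summary to `out_dir`. Fully
#' reproducible from the master seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param cohort Optional pre-simulated `cohort` (otherwise simulated from
#'   `config$cohort` with the master seed).
#' @return List of class `pipeline_result` with all stage outputs,
#'   invisibly writing artifacts as a side effect when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit_csv <- function(x, nm) if (!is.null(out_dir))
    utils::write.csv(x, file.path(out_dir, nm), row.names = FALSE, na = "")
  emit_json <- function(x, nm) if (!is.null(out_dir))
    jsonlite::write_json(x, file.path(out_dir, nm), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  cfg <- config$cohort
  cfg$seed <- config$seed
  if (is.null(cohort))
    cohort <- stage("simulate", simulate_cohort(cfg))
  emit_csv(cohort_table(cohort), "trials.csv")

  mf <- stage("model-free", model_free_analysis(cohort))
  emit_csv(mf$coefficients, "model_free_coefficients.csv")
  emit_csv(mf$group, "model_free_group.csv")

  cmp <- stage("model-comparison",
               full_model_comparison(cohort, config$models,
                                     n_restarts = config$n_restarts,
                                     seed = config$seed,
                                     xp_samples = config$xp_samples,
                                     bms_seed = config$seed))
  for (tk in names(cmp$E))
    emit_csv(as.data.frame(cmp$E[[tk]]), sprintf("evidence_%s.csv", tk))
  emit_json(list(family_ef = as.list(cmp$family$family_ef),
                 family_xp = as.list(cmp$family$family_xp),
                 within_same_ef = as.list(cmp$within_same$ef),
                 within_same_xp = as.list(cmp$within_same$xp)),
            "model_comparison.json")

  winner <- names(which.max(cmp$within_same$ef))
  shr <- NULL
  if (winner %in% c("ces")) {
    shr <- stage("parameter-sharing",
                 parameter_sharing_comparison(cohort, winner,
                                              n_restarts = max(2, config$n_restarts - 1),
                                              seed = config$seed,
                                              xp_samples = config$xp_samples,
                                              bms_seed = config$seed))
    emit_json(lapply(shr, function(r)
      list(ef = as.list(r$bms$ef), xp = as.list(r$bms$xp),
           correlations = r$correlations)), "parameter_sharing.json")
  }

  pred <- stage("cross-task-prediction",
                cross_task_prediction(cohort, "ces",
                                      n_restarts = config$n_restarts,
                                      seed = config$seed))
  emit_csv(pred, "cross_task_prediction.csv")

  conv <- NULL
  if (config$convergence_subjects > 0) {
    conv <- stage("convergence", {
      ns <- min(config$convergence_subjects, length(cohort))
      rows <- list()
      for (s in seq_len(ns)) for (tk in c("rating", "force")) {
        d <- cohort[[s]][[tk]]
        nat <- convergence_analysis(d, "ces", tk,
                                    step = config$convergence_step,
                                    seed = config$seed + s)
        set.seed(config$seed + s)
        opt <- convergence_analysis(
          optimized_order(d, "ces", tk, seed = config$seed + s), "ces", tk,
          step = config$convergence_step, seed = config$seed + s)
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, task = tk,
          native_threshold = nat$threshold_trial,
          optimized_threshold = opt$threshold_trial)
      }
      do.call(rbind, rows)
    })
    emit_csv(conv, "convergence.csv")
  }

  res <- structure(list(cohort = cohort, model_free = mf, comparison = cmp,
                        sharing = shr, prediction = pred,
                        convergence = conv, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    summ <- c(
      sprintf("Subjects: %d", length(cohort)),
      sprintf("Same-family Ef = %.3f, Xp = %.3f",
              cmp$family$family_ef[["same"]], cmp$family$family_xp[["same"]]),
      sprintf("Winning model within 'same': %s (Ef = %.3f)",
              winner, max(cmp$within_same$ef)),
      if (!is.null(shr)) sprintf(
        "Winning alpha partition: %s; delta partition: %s",
        names(which.max(shr$alpha$bms$ef)),
        names(which.max(shr$delta$bms$ef))),
      sprintf("Mean balanced accuracy (rating) = %.3f, (force) = %.3f",
              mean(pred$balanced_accuracy[pred$source == "rating"]),
              mean(pred$balanced_accuracy[pred$source == "force"])))
    writeLines(summ, file.path(out_dir, "summary.txt"))
  }
  res
}
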