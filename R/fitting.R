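## MAP fitting of (value model x observation model) pairs with a Laplace
## approximation to the log model evidence.

.obs_param_defs <- function(task) {
  switch(task,
         choice = c(temperature = "log"),
         rating = ,
         force  = c(slope = "identity", intercept = "identity",
                    noise_sd = "log"))
}

# Normalize trial data to the internal layout for one task.
.task_data <- function(data, task) {
  gl <- if ("gain_left" %in% names(data)) data$gain_left else data$gain
  dl <- if ("donation_left" %in% names(data)) data$donation_left else data$donation
  if (task == "choice") {
    list(GL = gl, DL = dl, GR = data$gain_right, DR = data$donation_right,
         y = as.numeric(data$response))
  } else {
    list(G = gl, D = dl, y = as.numeric(data$response))
  }
}

# Log-likelihood of one task's data given native value params `vp` and
# observation params `op`.
.task_loglik <- function(task, td, model, vp, op, bounds) {
  if (task == "choice") {
    vl <- value_function(model, vp, td$GL, td$DL)
    vr <- value_function(model, vp, td$GR, td$DR)
    x <- (vl - vr) / op$temperature
    ll <- sum(td$y * stats::plogis(x, log.p = TRUE) +
                (1 - td$y) * stats::plogis(-x, log.p = TRUE))
  } else {
    V <- value_function(model, vp, td$G, td$D)
    mu <- pmin(pmax(op$slope * V + op$intercept, bounds[1]), bounds[2])
    ll <- sum(stats::dnorm(td$y, mu, op$noise_sd, log = TRUE))
  }
  ll
}

# Assemble the free-parameter bookkeeping for a single-task fit.
.fit_problem <- function(model, task, data, obs_fixed, tc, bounds) {
  spec <- value_model(model)
  obs_def <- .obs_param_defs(task)
  obs_free <- setdiff(names(obs_def), names(obs_fixed))
  free <- c(names(spec$params), obs_free)
  trans <- c(unname(spec$params), unname(obs_def[obs_free]))
  names(trans) <- free
  td <- .task_data(data, task)
  if (is.null(bounds))
    bounds <- if (task == "rating") tc$rating_bounds else tc$force_bounds

  to_native <- function(theta) {
    nat <- mapply(.apply_transform, theta, trans, MoreArgs = list(inverse = TRUE))
    names(nat) <- free
    nat
  }
  split_params <- function(nat) {
    vp <- as.list(nat[names(spec$params)])
    op <- as.list(nat[intersect(free, obs_free)])
    op[names(obs_fixed)] <- obs_fixed
    list(vp = vp, op = op)
  }
  loglik <- function(theta) {
    pr <- split_params(to_native(theta))
    .task_loglik(task, td, model, pr$vp, pr$op, bounds)
  }
  list(spec = spec, task = task, free = free, trans = trans, td = td,
       bounds = bounds, to_native = to_native, split_params = split_params,
       loglik = loglik, n = length(td$y))
}

#' Gaussian prior over unconstrained parameters
#'
#' Independent normals on the unconstrained (log / logit / identity
#' transformed) scale. The default is mean 0, variance 3 for every free
#' parameter, weakly informative across the native domains.
#'
#' @param names Character vector of free-parameter names.
#' @param mean,var Scalars or named vectors (partial naming allowed;
#'   unnamed entries fall back to the defaults).
#' @return List with aligned `mean` and `var` vectors.
#' @export
default_prior <- function(names, mean = 0, var = 3) {
  m <- rep_len(if (length(mean) == 1L) mean else 0, length(names))
  v <- rep_len(if (length(var) == 1L) var else 3, length(names))
  names(m) <- names(v) <- names
  if (!is.null(names(mean))) m[names(mean)] <- mean
  if (!is.null(names(var))) v[names(var)] <- var
  if (any(v <= 0)) stop("prior variances must be > 0")
  list(mean = m, var = v)
}

.log_prior <- function(theta, prior)
  sum(stats::dnorm(theta, prior$mean, sqrt(prior$var), log = TRUE))

#' Log joint density (log-likelihood plus log-prior)
#'
#' @param problem Internal fit problem (exposed for testing via
#'   [fit_value_model()]'s return value).
#' @param theta Unconstrained parameter vector.
#' @param prior Prior from [default_prior()].
#' @return Scalar log joint; `-Inf`-producing parameter regions are mapped
#'   to a large negative value so optimizers can recover.
#' @keywords internal
.log_joint <- function(problem, theta, prior) {
  lj <- tryCatch(problem$loglik(theta) + .log_prior(theta, prior),
                 error = function(e) -Inf)
  if (!is.finite(lj)) -1e10 else lj
}

# Multistart BFGS maximization of fn; returns best (par, value).
.multistart <- function(fn, k, n_restarts, seed, start_mean, control,
                        extra_starts = list()) {
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  starts <- c(list(start_mean), extra_starts,
              lapply(seq_len(max(0L, n_restarts - 1L)),
                     function(i) start_mean + stats::rnorm(k)))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, function(p) -fn(p), method = "BFGS",
                          control = ctl),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all optimizer restarts failed")
  vals <- vapply(fits, `[[`, 0, "value")
  nrm <- vapply(fits, function(f) sum(f$par^2), 0)
  best <- order(vals, nrm)[1]  # highest log joint, then smallest norm
  fits[[best]]
}

# Symmetrize and, if needed, jitter-repair a Hessian of the negative log
# joint so that its Cholesky factor exists.
.repair_spd <- function(H) {
  H <- (H + t(H)) / 2
  eps <- 0
  for (i in 0:12) {
    ch <- tryCatch(chol(H + diag(eps, nrow(H))), error = function(e) NULL)
    if (!is.null(ch)) return(list(H = H + diag(eps, nrow(H)), chol = ch,
                                  jitter = eps))
    eps <- if (eps == 0) 1e-8 * max(1, max(abs(diag(H)))) else eps * 10
  }
  stop("posterior covariance repair failed: Hessian is not positive definite")
}

#' Fit a value model to one subject's task data
#'
#' Maximum a posteriori estimation of a candidate value function combined
#' with the task's observation model: Bernoulli-softmax for choices,
#' Gaussian noise around a clipped linear scaling for ratings and forces
#' (observation noise SD is fitted as a log-transformed parameter unless
#' fixed). Optimization is multistart quasi-Newton (BFGS) on the
#' unconstrained scale under independent Gaussian priors; the log model
#' evidence is the Laplace free energy
#' `log p(y | theta*) + log p(theta*) + (k/2) log 2*pi + (1/2) log det(Sigma)`
#' with `Sigma` the inverse Hessian of the negative log joint at the mode.
#'
#' @param data Trial data.frame for a single task (columns `gain_left`,
#'   `donation_left`, `response`, plus `gain_right`/`donation_right` for
#'   choices; plain `gain`/`donation` also accepted).
#' @param model Value model id or name (see [value_model_space()]).
#' @param task `"rating"`, `"force"` or `"choice"`.
#' @param prior `NULL` for the default N(0, 3) prior, or a list as returned
#'   by [default_prior()].
#' @param obs_fixed Named list of observation parameters to hold fixed
#'   (e.g. `list(slope = 1, intercept = 0, noise_sd = 1)`).
#' @param n_restarts Number of optimizer restarts (first start at the prior
#'   mean, the rest randomized).
#' @param seed Seed for the restart draws (restored afterwards).
#' @param bounds Optional response-bound override for rating/force
#'   likelihood clipping.
#' @param tc A [task_config()].
#' @param control Passed to [stats::optim()] (`maxit`, `reltol`).
#' @return An object of class `value_fit`.
#' @examples
#' cfg <- cohort_config(n_subjects = 1, seed = 42)
#' coh <- simulate_cohort(cfg)
#' fit <- fit_value_model(coh[[1]]$rating, "ces", "rating", n_restarts = 2)
#' coef(fit)
#' @export
fit_value_model <- function(data, model = "ces",
                            task = c("rating", "force", "choice"),
                            prior = NULL, obs_fixed = list(),
                            n_restarts = 8, seed = 1L, bounds = NULL,
                            tc = task_config(), control = list()) {
  task <- match.arg(task)
  prob <- .fit_problem(model, task, data, obs_fixed, tc, bounds)
  k <- length(prob$free)
  if (prob$n < k)
    stop(sprintf("need at least %d observations to fit %d parameters", k, k))
  if (is.null(prior)) prior <- default_prior(prob$free)
  fn <- function(theta) .log_joint(prob, theta, prior)
  # Data-informed start: the clipped linear observation model has a flat
  # likelihood region when a*V + b sits entirely below the response floor
  # (all predictions pinned at the bound), so seed one start from an OLS
  # scaling of the responses on prior-mean values.
  extra <- list()
  if (task != "choice") {
    nat0 <- prob$to_native(prior$mean)
    vp0 <- prob$split_params(nat0)$vp
    V0 <- value_function(model, vp0, prob$td$G, prob$td$D)
    if (stats::sd(V0) > 0) {
      ols <- stats::lm.fit(cbind(1, V0), prob$td$y)
      st <- prior$mean
      if ("slope" %in% prob$free) st[["slope"]] <- ols$coefficients[2]
      if ("intercept" %in% prob$free) st[["intercept"]] <- ols$coefficients[1]
      if ("noise_sd" %in% prob$free)
        st[["noise_sd"]] <- log(max(stats::sd(ols$residuals), 1e-3))
      extra <- list(st)
    }
  }
  opt <- .multistart(fn, k, n_restarts, seed, prior$mean, control, extra)
  theta <- opt$par
  names(theta) <- prob$free
  H <- stats::optimHess(theta, function(p) -fn(p))
  rep <- .repair_spd(H)
  Sigma <- chol2inv(rep$chol)
  dimnames(Sigma) <- list(prob$free, prob$free)
  logdet_H <- 2 * sum(log(diag(rep$chol)))
  lj <- fn(theta)
  logev <- lj + (k / 2) * log(2 * pi) - 0.5 * logdet_H
  nat <- prob$to_native(theta)
  fit <- structure(list(
    model = prob$spec$name, model_id = prob$spec$id, task = task,
    theta = theta, par = nat, vcov = Sigma,
    log_joint = lj, log_evidence = logev,
    prior = prior, obs_fixed = obs_fixed, bounds = prob$bounds,
    n = prob$n, k = k, data = data,
    convergence = opt$convergence, counts = opt$counts,
    problem = prob), class = "value_fit")
  fit$r_squared <- r_squared(fit)
  fit
}

#' Explained variance of a fitted model
#'
#' `1 - SS_res / SS_tot` on the response scale; for choices the binary
#' outcome is compared with the predicted choice probability.
#'
#' @param fit A `value_fit`.
#' @param data Optional data to evaluate on (defaults to the fitted data).
#' @return Scalar in (-Inf, 1\].
#' @export
r_squared <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  y <- as.numeric(data$response)
  if (stats::var(y) == 0)
    stop("explained variance undefined: responses have zero variance")
  pred <- predict(fit, data)
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' @export
predict.value_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  td <- .task_data(newdata, object$task)
  pr <- object$problem$split_params(unlist(object$par))
  if (object$task == "choice") {
    vl <- value_function(object$model, pr$vp, td$GL, td$DL)
    vr <- value_function(object$model, pr$vp, td$GR, td$DR)
    choice_probability(vl, vr, pr$op$temperature)
  } else {
    V <- value_function(object$model, pr$vp, td$G, td$D)
    expected_scaled_response(V, pr$op$slope, pr$op$intercept, object$bounds)
  }
}

#' @export
residuals.value_fit <- function(object, ...) {
  as.numeric(object$data$response) - predict(object)
}

#' @export
coef.value_fit <- function(object, ...) unlist(object$par)

#' @export
vcov.value_fit <- function(object, ...) object$vcov

#' @export
logLik.value_fit <- function(object, ...) {
  ll <- object$log_joint - .log_prior(object$theta, object$prior)
  structure(ll, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.value_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Value-model fit: '%s' (model %d), %s task, n = %d\n",
              x$model, x$model_id, x$task, x$n))
  cat("  MAP estimates (native scale):\n")
  print(round(unlist(x$par), digits))
  cat(sprintf("  log evidence (Laplace): %.2f   R^2: %.3f\n",
              x$log_evidence, x$r_squared))
  invisible(x)
}

#' @export
summary.value_fit <- function(object, ...) {
  se_u <- sqrt(diag(object$vcov))
  tab <- data.frame(native = unlist(object$par),
                    unconstrained = object$theta,
                    se_unconstrained = se_u)
  out <- list(model = object$model, task = object$task, n = object$n,
              coefficients = tab, log_evidence = object$log_evidence,
              r_squared = object$r_squared)
  class(out) <- "summary.value_fit"
  out
}

#' @export
print.summary.value_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Model '%s', %s task (n = %d trials)\n", x$model, x$task, x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("log evidence %.2f, R^2 %.3f\n", x$log_evidence, x$r_squared))
  invisible(x)
}

#' @export
simulate.value_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pred <- predict(object)
  out <- replicate(nsim, {
    if (object$task == "choice") stats::rbinom(length(pred), 1L, pred)
    else pmin(pmax(pred + stats::rnorm(length(pred), 0,
                                       object$par[["noise_sd"]]),
                   object$bounds[1]), object$bounds[2])
  }, simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.value_fit <- function(x, ...) {
  y <- as.numeric(x$data$response)
  p <- predict(x)
  plot(p, y, xlab = "predicted", ylab = "observed",
       main = sprintf("'%s' fit, %s task (R^2 = %.2f)",
                      x$model, x$task, x$r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Evaluate the log joint density for a task dataset
#'
#' Sum of the task log-likelihood and the Gaussian log-prior, evaluated at
#' native-scale parameters. Exposed mainly for checking fitted objectives
#' against hand computations.
#'
#' @param data Trial data.frame for one task.
#' @param model Value model id or name.
#' @param task `"rating"`, `"force"` or `"choice"`.
#' @param params Named list/vector of native-scale parameters (value
#'   parameters plus free observation parameters).
#' @param prior `NULL` for the default prior, or from [default_prior()].
#' @param obs_fixed Named list of fixed observation parameters.
#' @param bounds Optional response-bound override.
#' @param tc A [task_config()].
#' @return Scalar log joint.
#' @export
log_joint <- function(data, model, task, params, prior = NULL,
                      obs_fixed = list(), bounds = NULL, tc = task_config()) {
  task <- match.arg(task, c("rating", "force", "choice"))
  prob <- .fit_problem(model, task, data, obs_fixed, tc, bounds)
  theta <- vapply(prob$free, function(nm)
    .apply_transform(params[[nm]], prob$trans[[nm]]), numeric(1))
  if (is.null(prior)) prior <- default_prior(prob$free)
  prob$loglik(theta) + .log_prior(theta, prior)
}
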