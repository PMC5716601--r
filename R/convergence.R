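## Convergence of parameter estimation as trials accumulate: the relative
## per-trial gain in estimation precision, thresholded at 5%, gives the
## minimum informative trial count for each task; trials can be replayed in
## their native order or reordered to be maximally informative.

#' Per-trial convergence measure from a posterior-variance series
#'
#' Given the mean posterior variance `sigma_t` after fitting trials
#' `1..t`, the gain at trial t is
#' `gamma_t = (sigma_{t-1} - sigma_t) / sigma_{t-1}`. The threshold trial is
#' the last t whose gain exceeds `threshold` (5% by default) — the minimum
#' number of trials after which no later trial is worth more than the
#' criterion.
#'
#' @param sigma Numeric vector of mean posterior variances (t = 1, 2, ...).
#' @param threshold Relative-gain criterion (default 0.05).
#' @return List of class `convergence_trace` with `sigma`, `gamma`
#'   (aligned to trials `2..length(sigma)`), `threshold` and
#'   `threshold_trial` (`NA` if no gain ever exceeds the criterion).
#' @examples
#' convergence_trace(c(10, 8, 7.8))$gamma        # 0.200 0.025
#' convergence_trace(c(10, 8, 7.8))$threshold_trial  # 2
#' @export
convergence_trace <- function(sigma, threshold = 0.05) {
  if (length(sigma) < 2) stop("need at least 2 trials")
  if (any(sigma <= 0)) stop("posterior variances must be positive")
  gamma <- (sigma[-length(sigma)] - sigma[-1]) / sigma[-length(sigma)]
  above <- which(gamma > threshold)
  structure(list(sigma = sigma, gamma = gamma, threshold = threshold,
                 threshold_trial = if (length(above)) max(above) + 1L
                                   else NA_integer_),
            class = "convergence_trace")
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("Convergence trace over %d trials; threshold %.0f%% crossed last at trial %s\n",
              length(x$sigma), 100 * x$threshold,
              ifelse(is.na(x$threshold_trial), "none", x$threshold_trial)))
  invisible(x)
}

# Jacobian of the predicted response w.r.t. the unconstrained parameters at
# theta, one row per trial (central finite differences).
.pred_jacobian <- function(prob, theta, model, h = 1e-5) {
  predict_at <- function(th) {
    pr <- prob$split_params(prob$to_native(th))
    if (prob$task == "choice") {
      vl <- value_function(model, pr$vp, prob$td$GL, prob$td$DL)
      vr <- value_function(model, pr$vp, prob$td$GR, prob$td$DR)
      (vl - vr) / pr$op$temperature  # linear predictor of the logistic
    } else {
      V <- value_function(model, pr$vp, prob$td$G, prob$td$D)
      pmin(pmax(pr$op$slope * V + pr$op$intercept, prob$bounds[1]),
           prob$bounds[2])
    }
  }
  k <- length(theta)
  J <- matrix(0, prob$n, k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- h
    J[, j] <- (predict_at(theta + e) - predict_at(theta - e)) / (2 * h)
  }
  J
}

#' Reorder trials by expected informativeness
#'
#' Produces the "optimized order" used in the convergence analysis: the
#' first eleven trials are a seeded random draw from the offers whose gain
#' and donation both lie in \{0, 30, 50, 70, 100\} euros (coverage of the
#' amount range); every subsequent trial is appended greedily so as to
#' minimize the trace of the (local Laplace) posterior covariance given the
#' trials already placed. Information is accumulated as squared prediction
#' Jacobians at the full-data MAP estimate, scaled by the observation noise
#' — the standard local A-optimality criterion.
#'
#' @param data Trial data.frame for one task.
#' @param model Value model (default `"ces"`).
#' @param task `"rating"`, `"force"` or `"choice"`.
#' @param fit Optional full-data `value_fit` (computed if missing).
#' @param n_coverage Number of leading coverage trials (default 11).
#' @param coverage_amounts Amount set defining coverage offers.
#' @param ... Passed to [fit_value_model()] when `fit` is missing.
#' @return `data` with rows reordered.
#' @export
optimized_order <- function(data, model = "ces",
                            task = c("rating", "force", "choice"),
                            fit = NULL, n_coverage = 11,
                            coverage_amounts = c(0, 30, 50, 70, 100), ...) {
  task <- match.arg(task)
  if (is.null(fit))
    fit <- fit_value_model(data, model, task, n_restarts = 4, ...)
  prob <- fit$problem
  J <- .pred_jacobian(prob, fit$theta, model)
  noise_var <- if (task == "choice") {
    p <- predict(fit)
    1 / pmax(p * (1 - p), 1e-6)  # logistic Fisher weight
  } else rep(fit$par[["noise_sd"]]^2, prob$n)
  n <- nrow(data)
  P0 <- diag(1 / fit$prior$var)

  if (task == "choice") {
    elig <- which(data$gain_left %in% coverage_amounts &
                  data$donation_left %in% coverage_amounts &
                  data$gain_right %in% coverage_amounts &
                  data$donation_right %in% coverage_amounts)
  } else {
    gl <- if ("gain_left" %in% names(data)) data$gain_left else data$gain
    dl <- if ("donation_left" %in% names(data)) data$donation_left else data$donation
    elig <- which(gl %in% coverage_amounts & dl %in% coverage_amounts)
  }
  n_cov <- min(n_coverage, length(elig))
  if (n_cov < n_coverage)
    message(sprintf("only %d coverage-eligible trials available", n_cov))
  order_idx <- if (n_cov > 0) sample(elig, n_cov) else integer(0)

  P <- P0
  for (i in order_idx) P <- P + tcrossprod(J[i, ]) / noise_var[i]
  remaining <- setdiff(seq_len(n), order_idx)
  while (length(remaining) > 0) {
    tr <- vapply(remaining, function(i) {
      Pi <- P + tcrossprod(J[i, ]) / noise_var[i]
      sum(diag(chol2inv(chol(Pi))))
    }, numeric(1))
    pick <- remaining[which.min(tr)]
    order_idx <- c(order_idx, pick)
    P <- P + tcrossprod(J[pick, ]) / noise_var[pick]
    remaining <- setdiff(remaining, pick)
  }
  data[order_idx, , drop = FALSE]
}

#' Convergence analysis by incremental refits
#'
#' Refits the value model to trials `1..t` for increasing t and records the
#' mean posterior variance over all fitted parameters, then derives the
#' relative gain and the 5% threshold trial via [convergence_trace()].
#' Fits are warm-started from the previous step's mode for speed.
#'
#' @param data Trial data.frame for one task (in the order to analyse; use
#'   [optimized_order()] first for the optimized variant).
#' @param model Value model (default `"ces"`).
#' @param task Task name.
#' @param threshold Convergence criterion (default 0.05).
#' @param t_min First trial count to fit (defaults to the number of free
#'   parameters plus one).
#' @param step Refit every `step` trials (1 = every trial).
#' @param ... Passed to [fit_value_model()].
#' @return A `convergence_trace` with an extra `trials` element giving the
#'   trial counts the variance series refers to.
#' @export
convergence_analysis <- function(data, model = "ces",
                                 task = c("rating", "force", "choice"),
                                 threshold = 0.05, t_min = NULL, step = 1,
                                 ...) {
  task <- match.arg(task)
  tcfg <- task_config()
  prob <- .fit_problem(model, task, data, list(), tcfg, NULL)
  k <- length(prob$free)
  if (is.null(t_min)) t_min <- k + 1
  ts <- seq(t_min, nrow(data), by = step)
  sigma <- numeric(length(ts))
  prev_theta <- NULL
  prior <- default_prior(prob$free)
  for (i in seq_along(ts)) {
    sub <- data[seq_len(ts[i]), , drop = FALSE]
    f <- if (is.null(prev_theta)) {
      fit_value_model(sub, model, task, n_restarts = 3, ...)
    } else {
      subprob <- .fit_problem(model, task, sub, list(), tcfg, NULL)
      fn <- function(th) .log_joint(subprob, th, prior)
      opt <- .multistart(fn, k, 1, NULL, prev_theta, list())
      H <- stats::optimHess(opt$par, function(p) -fn(p))
      rp <- .repair_spd(H)
      list(theta = opt$par, vcov = chol2inv(rp$chol))
    }
    prev_theta <- f$theta
    sigma[i] <- mean(diag(f$vcov))
  }
  out <- convergence_trace(sigma, threshold)
  out$trials <- ts
  if (!is.na(out$threshold_trial))
    out$threshold_trial <- ts[out$threshold_trial]
  out
}
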