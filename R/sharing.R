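#' The five parameter-sharing partitions of the three tasks
#'
#' All set partitions of \{force, rating, choice\} into equality classes for
#' one named parameter: one common value, three task-specific values, and
#' the three variants where exactly one task differs from the other two.
#'
#' @return Named list of 5 partitions; each partition is a list of character
#'   vectors of task names.
#' @export
sharing_partitions <- function() {
  list(
    all_shared      = list(c("force", "rating", "choice")),
    force_distinct  = list("force", c("rating", "choice")),
    rating_distinct = list("rating", c("force", "choice")),
    choice_distinct = list("choice", c("force", "rating")),
    all_distinct    = list("force", "rating", "choice"))
}

.check_partition <- function(partition) {
  tasks <- sort(unlist(partition))
  if (!identical(tasks, sort(c("choice", "force", "rating"))))
    stop("partition must cover exactly the tasks force, rating, choice")
  invisible(TRUE)
}

#' Fit a value model jointly to three tasks with one parameter tied
#'
#' Pools a subject's rating, force and choice data and fits a single value
#' model whose likelihood is the sum of the three task log-likelihoods. One
#' named value parameter (`role`) is constrained to be equal within the
#' classes of a task partition; every other value parameter and all
#' observation parameters remain task-specific. Evidence is the Laplace
#' free energy, as in [fit_value_model()].
#'
#' @param data List with elements `rating`, `force`, `choice` (trial
#'   data.frames), e.g. one subject of [simulate_cohort()].
#' @param model Value model id or name (default `"ces"`).
#' @param role Name of the tied parameter (e.g. `"alpha"` or `"delta"`).
#' @param partition One element of [sharing_partitions()].
#' @param prior `NULL` for defaults.
#' @param n_restarts,seed,control As in [fit_value_model()].
#' @param warm_start Initialize from quick per-task fits (recommended).
#' @param task_fits Optional named list of precomputed per-task `value_fit`
#'   objects (`force`, `rating`, `choice`) to warm-start from, saving the
#'   internal refits when several partitions are fitted to the same data.
#' @param tc A [task_config()].
#' @return An object of class `c("value_fit_shared", "value_fit")`.
#' @export
fit_shared <- function(data, model = "ces", role = "alpha",
                       partition = sharing_partitions()$all_shared,
                       prior = NULL, n_restarts = 4, seed = 1L,
                       warm_start = TRUE, task_fits = NULL,
                       tc = task_config(), control = list()) {
  if (!all(c("rating", "force", "choice") %in% names(data)))
    stop("data must contain rating, force and choice tables for one subject")
  .check_partition(partition)
  spec <- value_model(model)
  if (!role %in% names(spec$params))
    stop(sprintf("model '%s' has no parameter '%s'", spec$name, role))
  tasks <- c("force", "rating", "choice")

  class_label <- vapply(partition, function(cl)
    paste0(role, "[", paste(substr(cl, 1, 1), collapse = ""), "]"), "")
  class_of <- stats::setNames(rep(seq_along(partition),
                                  lengths(partition)), unlist(partition))

  free <- character(0); trans <- character(0)
  for (i in seq_along(partition)) {
    free <- c(free, class_label[i]); trans <- c(trans, spec$params[[role]])
  }
  other_vp <- setdiff(names(spec$params), role)
  for (tk in tasks) for (nm in other_vp) {
    free <- c(free, paste0(nm, ".", tk)); trans <- c(trans, spec$params[[nm]])
  }
  for (tk in tasks) {
    od <- .obs_param_defs(tk)
    free <- c(free, paste0(names(od), ".", tk)); trans <- c(trans, unname(od))
  }
  names(trans) <- free

  tds <- lapply(stats::setNames(tasks, tasks),
                function(tk) .task_data(data[[tk]], tk))
  bounds <- list(rating = tc$rating_bounds, force = tc$force_bounds,
                 choice = NULL)

  to_native <- function(theta) {
    nat <- mapply(.apply_transform, theta, trans,
                  MoreArgs = list(inverse = TRUE))
    names(nat) <- free
    nat
  }
  task_params <- function(nat, tk) {
    vp <- stats::setNames(vector("list", length(spec$params)),
                          names(spec$params))
    vp[[role]] <- nat[[class_label[class_of[[tk]]]]]
    for (nm in other_vp) vp[[nm]] <- nat[[paste0(nm, ".", tk)]]
    od <- .obs_param_defs(tk)
    op <- lapply(names(od), function(nm) nat[[paste0(nm, ".", tk)]])
    names(op) <- names(od)
    list(vp = vp, op = op)
  }
  loglik <- function(theta) {
    nat <- to_native(theta)
    sum(vapply(tasks, function(tk) {
      pr <- task_params(nat, tk)
      .task_loglik(tk, tds[[tk]], model, pr$vp, pr$op, bounds[[tk]])
    }, numeric(1)))
  }
  prob <- list(spec = spec, free = free, trans = trans,
               to_native = to_native, loglik = loglik,
               n = sum(vapply(tds, function(d) length(d$y), 0L)))
  k <- length(free)
  if (is.null(prior)) prior <- default_prior(free)
  fn <- function(theta) .log_joint(prob, theta, prior)

  start <- prior$mean
  if (warm_start) {
    sf <- if (!is.null(task_fits)) task_fits
    else lapply(stats::setNames(tasks, tasks), function(tk)
      tryCatch(fit_value_model(data[[tk]], model, tk, n_restarts = 2,
                               seed = seed, tc = tc),
               error = function(e) NULL))
    for (tk in tasks) {
      f <- sf[[tk]]
      if (is.null(f)) next
      for (nm in other_vp)
        start[paste0(nm, ".", tk)] <- f$theta[[nm]]
      od <- .obs_param_defs(tk)
      for (nm in names(od)) start[paste0(nm, ".", tk)] <- f$theta[[nm]]
    }
    for (i in seq_along(partition)) {
      ths <- vapply(partition[[i]], function(tk)
        if (!is.null(sf[[tk]])) sf[[tk]]$theta[[role]] else NA_real_,
        numeric(1))
      if (any(is.finite(ths)))
        start[class_label[i]] <- mean(ths[is.finite(ths)])
    }
  }
  opt <- .multistart(fn, k, n_restarts, seed, start, control)
  theta <- opt$par; names(theta) <- free
  H <- stats::optimHess(theta, function(p) -fn(p))
  rep <- .repair_spd(H)
  Sigma <- chol2inv(rep$chol)
  dimnames(Sigma) <- list(free, free)
  lj <- fn(theta)
  logev <- lj + (k / 2) * log(2 * pi) - sum(log(diag(rep$chol)))
  structure(list(model = spec$name, model_id = spec$id, task = "pooled",
                 role = role, partition = partition,
                 theta = theta, par = as.list(to_native(theta)),
                 vcov = Sigma, log_joint = lj, log_evidence = logev,
                 prior = prior, n = prob$n, k = k, data = data,
                 convergence = opt$convergence),
            class = c("value_fit_shared", "value_fit"))
}

#' @export
print.value_fit_shared <- function(x, digits = 3, ...) {
  part <- paste(vapply(x$partition, function(cl)
    paste(cl, collapse = "="), ""), collapse = " | ")
  cat(sprintf("Shared-parameter fit: '%s', tied '%s' over {%s}, n = %d\n",
              x$model, x$role, part, x$n))
  print(round(unlist(x$par), digits))
  cat(sprintf("  log evidence (Laplace): %.2f\n", x$log_evidence))
  invisible(x)
}
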