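#' Random-effects Bayesian model selection over subjects
#'
#' Variational Dirichlet-multinomial scheme for inferring population model
#' frequencies from a subjects-by-models matrix of log evidences. Each
#' subject's model assignment is a multinomial latent variable; the
#' fixed-point iteration alternates posterior assignments
#' `u_nk ∝ exp(log evidence_nk + digamma(alpha_k) - digamma(sum(alpha)))`
#' with the Dirichlet update `alpha = alpha0 + colSums(u)` until the change
#' in `alpha` falls below `tol`. Expected frequencies are
#' `Ef = alpha / sum(alpha)`; exceedance probabilities are the posterior
#' probabilities that each model is the most frequent.
#'
#' @param E Numeric matrix, subjects in rows, models in columns (log
#'   evidences); column names label the models.
#' @param prior_count Dirichlet prior count(s) `alpha0`: scalar or one per
#'   model (default 1).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap; exceeding it is an error (with trace).
#' @param xp_samples Monte-Carlo sample count for exceedance probabilities
#'   (the 2-model case uses the exact Beta form).
#' @param seed Seed for the Monte-Carlo draw.
#' @param compute_xp Set `FALSE` to skip exceedance probabilities (useful
#'   for very large model spaces where only aggregated families are of
#'   interest).
#' @return Object of class `bms_result`: list with `alpha`, `ef`, `xp`,
#'   `assignments` (posterior model attribution per subject), `iterations`.
#' @export
rfx_bms <- function(E, prior_count = 1, tol = 1e-6, max_iter = 500,
                    xp_samples = 1e6, seed = 1L, compute_xp = TRUE) {
  E <- as.matrix(E)
  if (ncol(E) < 2) stop("need at least 2 models")
  if (!all(is.finite(E))) stop("log evidences must be finite")
  K <- ncol(E); n <- nrow(E)
  alpha0 <- rep_len(prior_count, K)
  alpha <- alpha0 + n / K
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lu <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu); u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    d <- max(abs(alpha_new - alpha))
    trace <- c(trace, d)
    alpha <- alpha_new
    if (d < tol) break
    if (it == max_iter)
      stop(sprintf("RFX-BMS did not converge in %d iterations (last delta %.3g)",
                   max_iter, d))
  }
  xp <- if (compute_xp)
    exceedance_probability(alpha, n_samples = xp_samples, seed = seed)
  else rep(NA_real_, K)
  nm <- colnames(E)
  if (!is.null(nm)) names(alpha) <- names(xp) <- nm
  ef <- alpha / sum(alpha)
  structure(list(alpha = alpha, ef = ef, xp = xp, assignments = u,
                 iterations = it, prior_count = alpha0),
            class = "bms_result")
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability that each component frequency is the largest. The two-model
#' case is exact via the regularized incomplete Beta function
#' (`Xp_1 = P(Beta(alpha_1, alpha_2) > 1/2)`); otherwise a seeded
#' Monte-Carlo estimate is used.
#'
#' @param alpha Positive Dirichlet parameters.
#' @param n_samples Monte-Carlo samples (K > 2 only).
#' @param seed RNG seed (restored afterwards).
#' @return Vector of exceedance probabilities summing to 1.
#' @export
exceedance_probability <- function(alpha, n_samples = 1e6, seed = 1L) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  K <- length(alpha)
  if (K == 2)
    return(c(1 - stats::pbeta(0.5, alpha[1], alpha[2]),
             stats::pbeta(0.5, alpha[1], alpha[2])))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # Dirichlet draws via normalized gammas; only the argmax is needed.
  counts <- integer(K)
  block <- max(1, floor(1e7 / K))  # cap the draw matrix at ~80 MB
  done <- 0
  while (done < n_samples) {
    m <- min(block, n_samples - done)
    g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    w <- max.col(g, ties.method = "random")
    counts <- counts + tabulate(w, K)
    done <- done + m
  }
  counts / n_samples
}

#' Family-wise group-level inference
#'
#' Random-effects BMS over families of models. The Dirichlet prior is
#' rescaled so every family carries equal prior mass regardless of size
#' (per-model prior count = family prior mass / family size), without which
#' comparisons between families of very different sizes are biased toward
#' the larger family. Family frequencies aggregate the Dirichlet mass of
#' their members (aggregation of a Dirichlet is Dirichlet), so the 2-family
#' exceedance probability is again an exact Beta tail.
#'
#' @param E Subjects-by-models log-evidence matrix.
#' @param partition Named list of integer (or column-name) vectors, a
#'   disjoint exhaustive partition of the model columns.
#' @param family_prior_mass Prior Dirichlet mass per family (default 1).
#' @param tol,max_iter,xp_samples,seed As in [rfx_bms()].
#' @return Object of class `bms_family_result`: the model-level
#'   `bms_result` plus `family_alpha`, `family_ef`, `family_xp`.
#' @export
family_inference <- function(E, partition, family_prior_mass = 1,
                             tol = 1e-6, max_iter = 500, xp_samples = 1e6,
                             seed = 1L) {
  E <- as.matrix(E)
  K <- ncol(E)
  idx <- lapply(partition, function(f) {
    if (is.character(f)) match(f, colnames(E)) else as.integer(f)
  })
  if (any(lengths(idx) == 0)) stop("empty family in partition")
  flat <- sort(unname(unlist(idx)))
  if (!identical(flat, seq_len(K)))
    stop("partition must cover every model exactly once")
  prior <- numeric(K)
  for (f in idx) prior[f] <- family_prior_mass / length(f)
  fit <- rfx_bms(E, prior_count = prior, tol = tol, max_iter = max_iter,
                 xp_samples = xp_samples, seed = seed,
                 compute_xp = ncol(E) <= 64)
  fa <- vapply(idx, function(f) sum(fit$alpha[f]), numeric(1))
  fe <- fa / sum(fa)
  fx <- exceedance_probability(fa, n_samples = xp_samples, seed = seed)
  names(fx) <- names(fa)
  structure(list(model_level = fit, family_alpha = fa, family_ef = fe,
                 family_xp = fx, partition = partition),
            class = "bms_family_result")
}

#' Combined model space across the three tasks
#'
#' Builds the task-wise combination space from per-task evidence matrices
#' over the 12 value functions: one column per (force, rating, choice)
#' model triple, with per-subject log evidence the sum of the three
#' task-specific log evidences (fits are independent across tasks). With 12
#' models per task this yields 12^3 = 1728 combinations, of which the 12
#' "diagonal" triples using the same function in every task form the
#' `same` family.
#'
#' @param E_force,E_rating,E_choice Subjects-by-models log-evidence
#'   matrices with identical row order and the same columns.
#' @return List with `E` (subjects x combinations), `labels`
#'   (force/rating/choice triple per column) and `same_family` (column
#'   indices of the diagonal triples).
#' @export
build_combined_space <- function(E_force, E_rating, E_choice) {
  mats <- list(force = as.matrix(E_force), rating = as.matrix(E_rating),
               choice = as.matrix(E_choice))
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("evidence matrices must share subjects and models")
  n <- nrow(mats$force); K <- ncol(mats$force)
  nm <- colnames(mats$force)
  if (is.null(nm)) nm <- as.character(seq_len(K))
  combos <- expand.grid(force = seq_len(K), rating = seq_len(K),
                        choice = seq_len(K), KEEP.OUT.ATTRS = FALSE)
  E <- mats$force[, combos$force, drop = FALSE] +
       mats$rating[, combos$rating, drop = FALSE] +
       mats$choice[, combos$choice, drop = FALSE]
  labels <- paste(nm[combos$force], nm[combos$rating], nm[combos$choice],
                  sep = "|")
  colnames(E) <- labels
  same <- which(combos$force == combos$rating & combos$rating == combos$choice)
  list(E = E, labels = labels, same_family = same,
       combos = combos)
}

#' @export
print.bms_result <- function(x, digits = 3, top = 5, ...) {
  K <- length(x$alpha)
  ord <- order(x$ef, decreasing = TRUE)[seq_len(min(top, K))]
  cat(sprintf("RFX-BMS over %d models (%d iterations)\n", K, x$iterations))
  tab <- data.frame(Ef = round(x$ef[ord], digits),
                    Xp = round(x$xp[ord], digits))
  rownames(tab) <- if (!is.null(names(x$alpha))) names(x$alpha)[ord] else ord
  print(tab)
  invisible(x)
}

#' @export
print.bms_family_result <- function(x, digits = 3, ...) {
  cat("Family-wise RFX-BMS\n")
  tab <- data.frame(Ef = round(x$family_ef, digits),
                    Xp = round(x$family_xp, digits))
  rownames(tab) <- names(x$partition)
  print(tab)
  invisible(x)
}
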