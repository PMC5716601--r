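## A-optimal adaptive design of binary-choice offers: the next offer pair
## minimizes the expected trace of the posterior covariance over the
## parameters of the a-priori value function
## V(G, D) = bG * G + bD * D + bGD * G * D (linear integration with
## interaction), observed through a softmax with fixed temperature.

#' Enumerate informative choice pairs on a euro grid
#'
#' Unordered pairs of offers that are informative for value estimation:
#' the options differ on both dimensions, neither dominates the other
#' (the higher gain comes with the lower donation), and each pair occurs
#' once. On the 10-euro grid this leaves choose(11, 2)^2 = 3025 of the
#' 121^2 = 14641 ordered combinations.
#'
#' @param step Euro step; must divide 100.
#' @return Data.frame with columns `gain_1`, `donation_1`, `gain_2`,
#'   `donation_2`, where offer 1 has the higher gain and lower donation.
#' @export
informative_pairs <- function(step = 10) {
  if (100 %% step != 0) stop("step must divide 100")
  amounts <- seq(0, 100, by = step)
  gp <- t(utils::combn(amounts, 2))  # gain pairs, ascending
  dp <- t(utils::combn(amounts, 2))  # donation pairs, ascending
  ng <- nrow(gp); nd <- nrow(dp)
  gi <- rep(seq_len(ng), each = nd); di <- rep(seq_len(nd), ng)
  data.frame(gain_1 = gp[gi, 2], donation_1 = dp[di, 1],
             gain_2 = gp[gi, 1], donation_2 = dp[di, 2])
}

#' Gaussian posterior over the a-priori design model
#'
#' @param mean Length-3 mean of (bG, bD, bGD).
#' @param cov 3x3 symmetric positive-definite covariance.
#' @param temperature Fixed softmax temperature of the design model.
#' @return Object of class `design_posterior`.
#' @export
design_posterior <- function(mean = c(0.5, 0.5, 0),
                             cov = diag(c(1, 1, 0.01)),
                             temperature = 10) {
  stopifnot(length(mean) == 3, all(dim(cov) == c(3, 3)), temperature > 0)
  cov <- (cov + t(cov)) / 2
  if (inherits(tryCatch(chol(cov), error = function(e) e), "error"))
    stop("cov must be positive definite")
  structure(list(mean = as.numeric(mean), cov = cov,
                 temperature = temperature,
                 prior_mean = as.numeric(mean), prior_prec = chol2inv(chol(cov)),
                 X = matrix(numeric(0), 0, 3), y = numeric(0)),
            class = "design_posterior")
}

# Feature difference (left minus right) of a pair on the design model,
# already divided by the softmax temperature.
.pair_features <- function(pair, temperature) {
  c(pair$gain_1 - pair$gain_2,
    pair$donation_1 - pair$donation_2,
    pair$gain_1 * pair$donation_1 - pair$gain_2 * pair$donation_2) /
    temperature
}

#' Sequential Laplace update of the design posterior
#'
#' Incorporates one observed binary choice by a Newton (Laplace) refresh of
#' the Gaussian posterior over the design-model weights: the new trial is
#' appended to the accumulated logistic likelihood, a few damped Newton
#' steps warm-started from the previous mode relocate the MAP estimate, and
#' the covariance is the inverse Hessian there, symmetrized. Because the
#' refresh operates on the full accumulated likelihood, the sequential
#' posterior coincides with a batch Laplace refit up to Newton convergence.
#'
#' @param posterior A [design_posterior()].
#' @param pair One row of [informative_pairs()] (offer 1 is "side 1").
#' @param choice 1 if option 1 was chosen, 0 otherwise.
#' @param n_newton Maximum Newton iterations (the objective is concave; a
#'   handful suffice).
#' @return Updated `design_posterior`.
#' @export
update_design_posterior <- function(posterior, pair, choice, n_newton = 25) {
  x <- .pair_features(pair, posterior$temperature)
  X <- rbind(posterior$X, x)
  y <- c(posterior$y, choice)
  P0 <- posterior$prior_prec
  m0 <- posterior$prior_mean
  obj <- function(w) {
    eta <- as.numeric(X %*% w)
    -sum(y * stats::plogis(eta, log.p = TRUE) +
           (1 - y) * stats::plogis(-eta, log.p = TRUE)) +
      0.5 * sum((w - m0) * (P0 %*% (w - m0)))
  }
  w <- posterior$mean
  f <- obj(w)
  for (i in seq_len(n_newton)) {
    eta <- as.numeric(X %*% w)
    p <- stats::plogis(eta)
    g <- P0 %*% (w - m0) - crossprod(X, y - p)
    H <- P0 + crossprod(X * (p * (1 - p)), X)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("design posterior covariance repair failed"))
    # backtracking line search keeps the concave objective decreasing
    lam <- 1
    repeat {
      w_new <- w - lam * as.numeric(step)
      f_new <- obj(w_new)
      if (f_new <= f + 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    moved <- max(abs(w_new - w))
    w <- w_new; f <- f_new
    if (moved < 1e-10) break
  }
  p <- stats::plogis(as.numeric(X %*% w))
  H <- P0 + crossprod(X * (p * (1 - p)), X)
  S <- chol2inv(chol((H + t(H)) / 2))
  out <- posterior
  out$mean <- as.numeric(w)
  out$cov <- (S + t(S)) / 2
  out$X <- X
  out$y <- y
  out
}

# Expected posterior trace after presenting `pair`, averaging the two
# possible choices under the current predictive probability (one-step
# Bayesian preposterior for the A-optimality criterion).
.expected_trace <- function(posterior, pair) {
  x <- .pair_features(pair, posterior$temperature)
  p <- stats::plogis(sum(x * posterior$mean))
  P0 <- chol2inv(chol(posterior$cov))
  tr <- 0
  for (y in c(1, 0)) {
    S <- chol2inv(chol(P0 + p * (1 - p) * tcrossprod(x)))
    tr <- tr + (if (y == 1) p else 1 - p) * sum(diag(S))
  }
  tr
}

#' Select the next choice pair by A-optimality
#'
#' Evaluates the expected (choice-probability-weighted) post-update trace of
#' the posterior covariance for each candidate pair and returns the
#' minimizer. Mirroring the task design, the search is restricted to
#' candidates that differ from the previous pair along a single dimension
#' (the pair of gains or the pair of donations is retained), with the
#' varied dimension alternating across trials; pass `vary = "none"` to
#' search all candidates. Ties are broken uniformly at random with the
#' current RNG state.
#'
#' @param posterior A [design_posterior()].
#' @param candidates Data.frame of candidate pairs ([informative_pairs()]
#'   layout).
#' @param previous Previously presented pair (single row) or `NULL`.
#' @param vary `"gain"`, `"donation"` or `"none"`: which dimension must
#'   differ from `previous` (the other is held fixed).
#' @return List with `pair` (the selected row), `index` into `candidates`,
#'   and `expected_trace`.
#' @export
select_next_pair <- function(posterior, candidates, previous = NULL,
                             vary = c("none", "gain", "donation")) {
  vary <- match.arg(vary)
  if (nrow(candidates) == 0) stop("no candidate pairs")
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(previous) && vary != "none") {
    if (vary == "gain")
      keep <- candidates$donation_1 == previous$donation_1 &
              candidates$donation_2 == previous$donation_2 &
              (candidates$gain_1 != previous$gain_1 |
               candidates$gain_2 != previous$gain_2)
    else
      keep <- candidates$gain_1 == previous$gain_1 &
              candidates$gain_2 == previous$gain_2 &
              (candidates$donation_1 != previous$donation_1 |
               candidates$donation_2 != previous$donation_2)
    if (!any(keep)) keep <- rep(TRUE, nrow(candidates))  # graceful fallback
  }
  idx <- which(keep)
  tr <- vapply(idx, function(i) .expected_trace(posterior, candidates[i, ]),
               numeric(1))
  best <- idx[which(tr <= min(tr) + 1e-12)]
  pick <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
  list(pair = candidates[pick, ], index = pick,
       expected_trace = tr[match(pick, idx)])
}

#' Run a simulated adaptive choice session
#'
#' Alternates gain- and donation-varying trials, selecting each offer pair
#' by [select_next_pair()], simulating the subject's choice from a true
#' value function, and updating the design posterior.
#'
#' @param n_trials Session length.
#' @param true_value Function `(G, D) -> utility` of the simulated subject.
#' @param temperature Softmax temperature of the simulated subject.
#' @param posterior Starting [design_posterior()].
#' @param candidates Candidate pairs (default: informative pairs, 5-euro
#'   grid).
#' @param alternate Alternate the varied dimension (otherwise free search).
#' @return List with the final `posterior`, per-trial `trace` of the
#'   posterior covariance, and the presented `pairs`.
#' @export
run_adaptive_session <- function(n_trials, true_value, temperature = 10,
                                 posterior = design_posterior(),
                                 candidates = informative_pairs(5),
                                 alternate = TRUE) {
  used <- integer(0)
  prev <- NULL
  traces <- numeric(n_trials)
  pairs <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    vary <- if (!alternate || is.null(prev)) "none"
            else if (t %% 2 == 0) "gain" else "donation"
    avail <- candidates[setdiff(seq_len(nrow(candidates)), used), ,
                        drop = FALSE]
    sel <- select_next_pair(posterior, avail, prev, vary)
    pair <- sel$pair
    used <- c(used, as.integer(rownames(pair)))
    v1 <- true_value(pair$gain_1, pair$donation_1)
    v2 <- true_value(pair$gain_2, pair$donation_2)
    y <- stats::rbinom(1, 1, choice_probability(v1, v2, temperature))
    posterior <- update_design_posterior(posterior, pair, y)
    traces[t] <- sum(diag(posterior$cov))
    pairs[[t]] <- pair
    prev <- pair
  }
  list(posterior = posterior, trace = traces,
       pairs = do.call(rbind, pairs))
}
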