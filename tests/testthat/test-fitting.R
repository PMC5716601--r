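test_that("log joint matches a term-by-term hand computation", {
  # three rating trials, CES alpha=0.5 delta=1, slope 0.1, intercept 0, sd 1
  d <- data.frame(gain = c(0, 50, 100), donation = c(100, 50, 0),
                  response = c(4, 6, 5))
  pars <- list(alpha = 0.5, delta = 1, slope = 0.1, intercept = 0,
               noise_sd = 1)
  V <- c(50, 50, 50)                  # CES values
  mu <- 0.1 * V                       # scaled predictions: 5, 5, 5
  ll <- sum(dnorm(c(4, 6, 5), mu, 1, log = TRUE))
  theta <- c(qlogis(0.5), log(1), 0.1, 0, log(1))
  lp <- sum(dnorm(theta, 0, sqrt(3), log = TRUE))
  expect_equal(log_joint(d, "ces", "rating", pars), ll + lp)

  # choice data at equal values: likelihood is n * log(0.5)
  dc <- data.frame(gain_left = c(60, 30), donation_left = c(40, 70),
                   gain_right = c(40, 70), donation_right = c(60, 30),
                   response = c(1, 0))
  pc <- list(alpha = 0.5, delta = 1, temperature = 2)
  lpc <- sum(dnorm(c(qlogis(0.5), 0, log(2)), 0, sqrt(3), log = TRUE))
  expect_equal(log_joint(dc, "ces", "choice", pc), 2 * log(0.5) + lpc)
})

test_that("Laplace evidence equals the conjugate closed form on a linear-Gaussian fit", {
  # Fehr-Schmidt is linear in its (identity-transformed) parameters, so with
  # fixed scaling and known noise the posterior is exactly Gaussian and the
  # marginal likelihood has a closed form.
  set.seed(8)
  n <- 12
  G <- runif(n, 0, 100); D <- runif(n, 0, 100)
  u <- pmax(D - G, 0); v <- pmax(G - D, 0)
  a_true <- 0.4; b_true <- 0.2; sigma <- 2
  y <- G - a_true * u - b_true * v + rnorm(n, 0, sigma)
  d <- data.frame(gain = G, donation = D, response = y)
  fit <- fit_value_model(d, "fehr-schmidt", "rating",
                         obs_fixed = list(slope = 1, intercept = 0,
                                          noise_sd = sigma),
                         bounds = c(-Inf, Inf), n_restarts = 2)
  X <- cbind(-u, -v)
  S0 <- diag(3, 2)
  C <- X %*% S0 %*% t(X) + diag(sigma^2, n)
  r <- y - G
  ch <- chol(C)
  closed <- -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
  expect_equal(fit$log_evidence, closed, tolerance = 1e-6)
  # and the MAP equals the ridge (GLS) posterior mean
  m_post <- solve(crossprod(X) / sigma^2 + solve(S0), crossprod(X, r) / sigma^2)
  expect_equal(unname(coef(fit)[c("alpha", "beta")]), as.numeric(m_post),
               tolerance = 1e-5)
})

test_that("Laplace evidence agrees with grid quadrature on a 2-parameter CES fit", {
  sub <- make_subject(alpha = 0.6, delta = 1.5, seed = 31)
  d <- sub$rating
  fit <- fit_value_model(d, "ces", "rating",
                         obs_fixed = list(slope = 0.1, intercept = 0,
                                          noise_sd = 1),
                         n_restarts = 3)
  # brute-force quadrature of the joint over the unconstrained plane
  prob <- fit$problem
  prior <- fit$prior
  gr <- seq(-6, 6, length.out = 200)
  h <- diff(gr[1:2])
  lj <- outer(gr, gr, Vectorize(function(a, b)
    valuelicit:::.log_joint(prob, c(a, b), prior)))
  m <- max(lj)
  quad <- m + log(sum(exp(lj - m))) + 2 * log(h)
  expect_lt(abs(fit$log_evidence - quad), 0.5)
})

test_that("noiseless linear rating data pin down the weights exactly", {
  g <- grid_design(10)
  V <- 0.7 * g$gain + 0.3 * g$donation
  d <- data.frame(gain = g$gain, donation = g$donation, response = 0.05 * V)
  fit <- fit_value_model(d, "linear-independent", "rating",
                         obs_fixed = list(slope = 0.05, intercept = 0,
                                          noise_sd = 0.01),
                         bounds = c(-Inf, Inf), n_restarts = 4)
  expect_equal(unname(coef(fit)["alpha"]), 0.7, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["beta"]), 0.3, tolerance = 1e-3)
})

test_that("CES parameters are recovered from one subject's rating data", {
  sub <- make_subject(alpha = 0.6, delta = 1.5, seed = 55)
  fit <- fit_value_model(sub$rating, "ces", "rating", n_restarts = 4)
  expect_lt(abs(coef(fit)[["alpha"]] - 0.6), 0.1)
  expect_equal(coef(fit)[["delta"]], 1.5, tolerance = 0.35)
  expect_gt(fit$r_squared, 0.5)
})

test_that("explained variance follows its definition", {
  sub <- make_subject(seed = 19)
  fit <- fit_value_model(sub$rating, "ces", "rating", n_restarts = 2)
  y <- sub$rating$response
  pred <- predict(fit)
  expect_equal(fit$r_squared, 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_equal(fit$r_squared, r_squared(fit, sub$rating))
  # hand example via a synthetic 'fit' prediction: R^2 of constant mean is 0
  expect_equal(1 - sum((y - mean(y))^2) / sum((y - mean(y))^2), 0)
  d0 <- sub$rating; d0$response <- 5
  expect_error(r_squared(fit, d0), "zero variance")
})

test_that("fits fail cleanly with fewer observations than parameters", {
  d <- data.frame(gain = c(10, 20), donation = c(30, 40),
                  response = c(1, 2))
  expect_error(fit_value_model(d, "ces", "rating"), "observations")
})

test_that("evidence penalizes superfluous interaction parameters (Occam)", {
  # data generated from the purely linear model: the interactive variant can
  # only match the fit, so its evidence should not be higher on average
  diffs <- vapply(1:4, function(i) {
    set.seed(100 + i)
    g <- grid_design(10, randomize = TRUE)
    V <- 0.6 * g$gain + 0.4 * g$donation
    d <- data.frame(gain = g$gain, donation = g$donation, trial = g$trial,
                    session = g$session,
                    response = pmin(pmax(0.08 * V + rnorm(121), 0), 10))
    f_lin <- fit_value_model(d, "linear-independent", "rating",
                             n_restarts = 3)
    f_int <- fit_value_model(d, "linear-interactive", "rating",
                             n_restarts = 3)
    f_int$log_evidence - f_lin$log_evidence
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("value_fit methods expose the fit coherently", {
  sub <- make_subject(seed = 77)
  fit <- fit_value_model(sub$rating, "ces", "rating", n_restarts = 2)
  expect_s3_class(fit, "value_fit")
  expect_named(coef(fit), c("alpha", "delta", "slope", "intercept",
                            "noise_sd"))
  expect_equal(dim(vcov(fit)), c(5, 5))
  expect_true(isSymmetric(vcov(fit)))
  expect_true(all(eigen(vcov(fit), only.values = TRUE)$values > 0))
  expect_lte(fit$r_squared, 1)
  expect_equal(length(residuals(fit)), 121)
  expect_equal(attr(logLik(fit), "df"), 5)
  set.seed(1)
  sim <- simulate(fit, nsim = 2)
  expect_equal(dim(sim), c(121, 2))
  expect_true(all(sim >= 0 & sim <= 10))
  expect_output(print(fit), "ces")
  expect_output(print(summary(fit)), "log evidence")
})

test_that("shared-parameter fits enumerate five partitions and favor truth", {
  parts <- sharing_partitions()
  expect_length(parts, 5)
  canon <- lapply(parts, function(p) sort(vapply(p, function(cl)
    paste(sort(cl), collapse = "+"), "")))
  expect_equal(anyDuplicated(canon), 0)
  expect_error(fit_shared(list(rating = data.frame())), "force")

  # common alpha across tasks: the all-shared partition should win the
  # evidence comparison for most subjects
  wins <- vapply(1:3, function(i) {
    sub <- make_subject(alpha = 0.65, delta = 1.4, seed = 200 + i)
    f_sh <- fit_shared(sub, "ces", "alpha", parts$all_shared,
                       n_restarts = 2, seed = i)
    f_di <- fit_shared(sub, "ces", "alpha", parts$all_distinct,
                       n_restarts = 2, seed = i)
    f_sh$log_evidence > f_di$log_evidence
  }, logical(1))
  expect_gte(sum(wins), 2)
})
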