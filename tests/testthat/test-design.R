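test_that("informative pairs match the combinatorial count and brute force", {
  p10 <- informative_pairs(10)
  expect_equal(nrow(p10), 3025)           # choose(11, 2)^2
  expect_equal(nrow(p10), choose(11, 2)^2)
  for (s in c(20, 25, 50)) {
    n_amt <- 100 / s + 1
    expect_equal(nrow(informative_pairs(s)), choose(n_amt, 2)^2)
  }
  # exhaustive oracle: filter all ordered pairs of grid offers
  g <- grid_design(10)
  idx <- expand.grid(i = seq_len(121), j = seq_len(121))
  expect_equal(nrow(idx), 14641)          # all ordered binary choices
  keep <- with(idx, {
    g1 <- g$gain[i]; d1 <- g$donation[i]
    g2 <- g$gain[j]; d2 <- g$donation[j]
    g1 != g2 & d1 != d2 & sign(g1 - g2) == -sign(d1 - d2)
  })
  expect_equal(sum(keep) / 2, 3025)       # unordered: each pair counted twice
  # the filtered set and the enumeration agree element-wise
  key_brute <- with(idx[keep, ], {
    g1 <- g$gain[i]; d1 <- g$donation[i]
    g2 <- g$gain[j]; d2 <- g$donation[j]
    hi <- g1 > g2  # orient: offer with higher gain first
    paste(ifelse(hi, g1, g2), ifelse(hi, d1, d2),
          ifelse(hi, g2, g1), ifelse(hi, d2, d1))
  })
  key_enum <- paste(p10$gain_1, p10$donation_1, p10$gain_2, p10$donation_2)
  expect_setequal(unique(key_brute), key_enum)
  # dominated pair is excluded
  expect_false(any(p10$gain_1 == 60 & p10$donation_1 == 60 &
                   p10$gain_2 == 50 & p10$donation_2 == 50))
})

test_that("sequential Laplace updates keep the posterior sane", {
  post <- design_posterior()
  pair <- data.frame(gain_1 = 60, donation_1 = 20,
                     gain_2 = 30, donation_2 = 80)
  up <- update_design_posterior(post, pair, 1)
  expect_s3_class(up, "design_posterior")
  expect_true(isSymmetric(up$cov))
  expect_true(all(eigen(up$cov, only.values = TRUE)$values > 0))
  # observing a choice can only reduce (or keep) the trace
  expect_lte(sum(diag(up$cov)), sum(diag(post$cov)) + 1e-12)
  # an uninformative pair (identical utilities under the mean) at most
  # weakly decreases the trace
  flat <- data.frame(gain_1 = 50, donation_1 = 30,
                     gain_2 = 30, donation_2 = 50)
  # make utilities equal under the mean: symmetric weights, no interaction
  post_s <- design_posterior(mean = c(0.5, 0.5, 0), cov = diag(c(1, 1, .01)))
  up_s <- update_design_posterior(post_s, flat, 1)
  expect_lte(sum(diag(up_s$cov)), sum(diag(post_s$cov)) + 1e-12)
})

test_that("repeated informative trials strictly shrink the trace", {
  set.seed(6)
  post <- design_posterior()
  truth <- function(G, D) 0.6 * G + 0.4 * D
  pairs <- informative_pairs(10)
  traces <- numeric(50)
  for (t in 1:50) {
    pr <- pairs[sample.int(nrow(pairs), 1), ]
    v1 <- truth(pr$gain_1, pr$donation_1); v2 <- truth(pr$gain_2, pr$donation_2)
    y <- rbinom(1, 1, choice_probability(v1, v2, 10))
    post <- update_design_posterior(post, pr, y)
    traces[t] <- sum(diag(post$cov))
  }
  expect_lt(traces[50], traces[1] / 2)
  # decreasing along the sequence; curvature re-evaluation at the moving
  # mode allows transient upticks, largest early on while the mode settles
  expect_true(all(diff(traces) <= 0.15 * traces[-50]))
  expect_lt(median(diff(traces)), 0)
})

test_that("sequential updates agree with a batch MAP refit", {
  set.seed(16)
  prior <- design_posterior(mean = c(0, 0, 0), cov = diag(c(1, 1, 0.01)))
  truth <- function(G, D) 0.5 * G + 0.5 * D
  pairs <- informative_pairs(10)[sample.int(3025, 40), ]
  post <- prior
  ys <- integer(40)
  for (t in 1:40) {
    pr <- pairs[t, ]
    ys[t] <- rbinom(1, 1, choice_probability(
      truth(pr$gain_1, pr$donation_1), truth(pr$gain_2, pr$donation_2), 10))
    post <- update_design_posterior(post, pr, ys[t])
  }
  # batch Laplace at the same logistic model
  X <- cbind(pairs$gain_1 - pairs$gain_2,
             pairs$donation_1 - pairs$donation_2,
             pairs$gain_1 * pairs$donation_1 -
               pairs$gain_2 * pairs$donation_2) / prior$temperature
  P0 <- solve(prior$cov)
  nlp <- function(w) {
    eta <- X %*% w
    -sum(ys * plogis(eta, log.p = TRUE) +
           (1 - ys) * plogis(-eta, log.p = TRUE)) +
      0.5 * t(w) %*% P0 %*% w
  }
  opt <- optim(c(0, 0, 0), nlp, method = "BFGS",
               control = list(reltol = 1e-12))
  H <- optimHess(opt$par, nlp)
  batch_cov <- solve(H)
  expect_lt(abs(sum(diag(post$cov)) - sum(diag(batch_cov))) /
              sum(diag(batch_cov)), 0.1)
})

test_that("pair selection minimizes expected trace and honors constraints", {
  post <- design_posterior(mean = c(0.6, 0.4, 0), cov = diag(c(2, 2, 0.02)))
  # two candidates: one highly informative, one nearly uninformative
  cands <- data.frame(gain_1 = c(100, 51), donation_1 = c(0, 49),
                      gain_2 = c(0, 49), donation_2 = c(100, 51))
  sel <- select_next_pair(post, cands)
  expect_equal(sel$index, 1)
  # exact tie: seeded choice is reproducible
  tie <- data.frame(gain_1 = c(60, 60), donation_1 = c(40, 40),
                    gain_2 = c(40, 40), donation_2 = c(60, 60))
  set.seed(10); a <- select_next_pair(post, tie)$index
  set.seed(10); b <- select_next_pair(post, tie)$index
  expect_identical(a, b)
  # single-dimension constraint: donations held fixed on a gain-varying trial
  prev <- data.frame(gain_1 = 60, donation_1 = 20,
                     gain_2 = 30, donation_2 = 80)
  cands2 <- informative_pairs(10)
  sel2 <- select_next_pair(post, cands2, prev, vary = "gain")
  expect_equal(sel2$pair$donation_1, 20)
  expect_equal(sel2$pair$donation_2, 80)
  sel3 <- select_next_pair(post, cands2, prev, vary = "donation")
  expect_equal(sel3$pair$gain_1, 60)
  expect_equal(sel3$pair$gain_2, 30)
  expect_error(select_next_pair(post, cands2[0, ]), "candidate")
})

test_that("optimized selection beats random informative pairs on final trace", {
  set.seed(77)
  pairs <- informative_pairs(10)
  final_opt <- numeric(6); final_rnd <- numeric(6)
  for (r in 1:6) {
    truth_a <- runif(1, 0.3, 0.7)
    truth <- function(G, D) truth_a * G + (1 - truth_a) * D
    ses <- run_adaptive_session(30, truth, temperature = 10,
                                candidates = pairs, alternate = TRUE)
    final_opt[r] <- ses$trace[30]
    post <- design_posterior()
    for (t in 1:30) {
      pr <- pairs[sample.int(nrow(pairs), 1), ]
      y <- rbinom(1, 1, choice_probability(
        truth(pr$gain_1, pr$donation_1), truth(pr$gain_2, pr$donation_2), 10))
      post <- update_design_posterior(post, pr, y)
    }
    final_rnd[r] <- sum(diag(post$cov))
  }
  expect_lt(mean(final_opt), mean(final_rnd))
})

test_that("the convergence measure follows its definition", {
  tr <- convergence_trace(c(10, 8, 7.8))
  expect_equal(tr$gamma, c(0.2, 0.025))
  expect_equal(tr$threshold_trial, 2L)
  # constant series: no gain anywhere
  tr0 <- convergence_trace(rep(4, 6))
  expect_equal(tr0$gamma, rep(0, 5))
  expect_true(is.na(tr0$threshold_trial))
  # halving series: gamma is 0.5 throughout, threshold at the end
  trh <- convergence_trace(2^-(0:6))
  expect_equal(trh$gamma, rep(0.5, 6))
  expect_equal(trh$threshold_trial, 7L)
  expect_error(convergence_trace(5), "2 trials")
  expect_error(convergence_trace(c(1, -1)), "positive")
  # hand arithmetic on an arbitrary series
  s <- c(9, 6, 5.9, 5.5, 5.49)
  expect_equal(convergence_trace(s)$gamma,
               (s[-5] - s[-1]) / s[-5])
})

test_that("optimized trial order starts with range-covering offers", {
  sub <- make_subject(seed = 61)
  set.seed(2)
  fit <- fit_value_model(sub$rating, "ces", "rating", n_restarts = 2)
  ord <- optimized_order(sub$rating, "ces", "rating", fit = fit)
  expect_equal(sort(ord$trial), sort(sub$rating$trial))  # a permutation
  cov_amt <- c(0, 30, 50, 70, 100)
  expect_true(all(ord$gain_left[1:11] %in% cov_amt))
  expect_true(all(ord$donation_left[1:11] %in% cov_amt))
  expect_equal(nrow(ord), 121)
})
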