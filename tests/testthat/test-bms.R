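test_that("symmetric evidences yield uniform frequencies", {
  E <- matrix(0, 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  res <- rfx_bms(E, xp_samples = 2e5)
  expect_equal(unname(res$ef), rep(0.25, 4), tolerance = 1e-8)
  expect_equal(unname(res$xp), rep(0.25, 4), tolerance = 0.01)
  expect_equal(sum(res$ef), 1)
  expect_equal(sum(res$xp), 1)
})

test_that("a dominant model is detected with near-certain exceedance", {
  # every subject favors model 1 by 20 nats: alpha -> (11, 1), whose
  # exceedance probability is the Beta(11, 1) tail above 1/2
  E <- cbind(m1 = rep(20, 10), m2 = rep(0, 10))
  res <- rfx_bms(E)
  expect_equal(unname(res$alpha), c(11, 1), tolerance = 1e-4)
  expect_equal(unname(res$xp[1]), 1 - pbeta(0.5, 11, 1), tolerance = 1e-4)
  expect_gt(res$xp[1], 0.99)
  expect_equal(unname(res$ef), c(11, 1) / 12, tolerance = 1e-4)
})

test_that("BMS is equivariant under column permutation", {
  set.seed(4)
  E <- matrix(rnorm(15 * 3, sd = 3), 15, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  perm <- c(3, 1, 2)
  r1 <- rfx_bms(E, xp_samples = 2e5)
  r2 <- rfx_bms(E[, perm], xp_samples = 2e5)
  expect_equal(unname(r2$ef), unname(r1$ef[perm]), tolerance = 1e-6)
  expect_equal(unname(r2$xp), unname(r1$xp[perm]), tolerance = 0.01)
})

test_that("a flat-evidence subject adds one attribution unit and barely moves Ef", {
  E <- cbind(rep(3, 8), rep(0, 8))
  base <- rfx_bms(E)
  grown <- rfx_bms(rbind(E, c(0, 0)))
  # the new subject contributes exactly one unit of attributed mass ...
  expect_equal(sum(grown$alpha) - sum(base$alpha), 1)
  # ... split according to the inferred frequencies (the variational
  # attribution follows the digamma weighting, so an uninformative subject
  # is mostly credited to the more frequent model), leaving the expected
  # frequencies nearly unchanged
  expect_lt(max(abs(grown$ef - base$ef)), 0.01)
  expect_gt(grown$assignments[9, 1], 0.5)
})

test_that("non-finite input and non-convergence are signalled", {
  expect_error(rfx_bms(cbind(c(1, NA), c(0, 0))), "finite")
  expect_error(rfx_bms(matrix(0, 3, 1)), "2 models")
  E <- matrix(rnorm(20), 10, 2)
  expect_error(rfx_bms(E, max_iter = 1), "converge")
})

test_that("Monte-Carlo exceedance matches the Beta closed form", {
  a <- c(11, 1)
  exact <- c(1 - pbeta(0.5, 11, 1), pbeta(0.5, 11, 1))
  expect_equal(exceedance_probability(a), exact)   # K = 2 is closed form
  # force the Monte-Carlo path by adding a negligible third component
  mc <- exceedance_probability(c(a, 1e-3), n_samples = 2e5, seed = 42)
  se <- sqrt(exact[1] * (1 - exact[1]) / 2e5)
  expect_lt(abs(mc[1] - exact[1]), 3 * se + 1e-4)
  expect_equal(exceedance_probability(c(1, 1)), c(0.5, 0.5))
  expect_equal(exceedance_probability(c(2, 2, 2), n_samples = 2e5),
               rep(1 / 3, 3), tolerance = 0.02)
  expect_error(exceedance_probability(c(0, 1)), "alpha")
})

test_that("family inference aggregates Dirichlet mass with equal priors", {
  # two equal families, symmetric evidences
  E <- matrix(0, 6, 4, dimnames = list(NULL, paste0("m", 1:4)))
  fam <- family_inference(E, list(A = 1:2, B = 3:4), xp_samples = 1e5)
  expect_equal(unname(fam$family_ef), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(unname(fam$family_xp), c(0.5, 0.5), tolerance = 1e-8)
  # singleton families reduce to the model-level result
  r <- rfx_bms(E, prior_count = 1, xp_samples = 1e5)
  fam1 <- family_inference(E, list(a = 1, b = 2, c = 3, d = 4),
                           xp_samples = 1e5)
  expect_equal(unname(fam1$family_ef), unname(r$ef), tolerance = 1e-8)
  # unequal family sizes get size-corrected prior counts so each family
  # carries the same prior mass (1/3 per model in the 3-model family, 1 in
  # the singleton)
  fam2 <- family_inference(E, list(big = 1:3, small = 4), xp_samples = 1e5)
  expect_equal(unname(fam2$model_level$prior_count), c(1/3, 1/3, 1/3, 1))
  expect_error(family_inference(E, list(A = 1:2, B = integer(0))), "empty")
  expect_error(family_inference(E, list(A = 1:2, B = 2:4)), "exactly once")
})

test_that("the combined space sums task evidences per triple", {
  # toy: 2 models x 2 tasks-wise combination, hand-checkable sums
  Ef <- matrix(c(1, 2, 10, 20), 2, 2, dimnames = list(NULL, c("A", "B")))
  Er <- matrix(c(100, 200, 1000, 2000), 2, 2, dimnames = list(NULL, c("A", "B")))
  Ec <- matrix(0, 2, 2, dimnames = list(NULL, c("A", "B")))
  comb <- build_combined_space(Ef, Er, Ec)
  expect_equal(ncol(comb$E), 8)
  expect_equal(unname(comb$E[1, "A|A|A"]), 1 + 100)
  expect_equal(unname(comb$E[2, "B|A|B"]), 20 + 200)
  expect_equal(unname(comb$E[1, "B|B|A"]), 10 + 1000)
  expect_length(comb$same_family, 2)
  expect_identical(comb$labels[comb$same_family], c("A|A|A", "B|B|B"))
  expect_error(build_combined_space(Ef, Er[1, , drop = FALSE], Ec), "share")
})

test_that("the full space has 1728 combinations with a 12-member diagonal", {
  set.seed(9)
  Es <- replicate(3, matrix(rnorm(2 * 12), 2, 12,
                            dimnames = list(NULL, paste0("m", 1:12))),
                  simplify = FALSE)
  comb <- build_combined_space(Es[[1]], Es[[2]], Es[[3]])
  expect_equal(ncol(comb$E), 1728)
  expect_length(comb$same_family, 12)
  expect_equal(length(setdiff(seq_len(1728), comb$same_family)), 1716)
})
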