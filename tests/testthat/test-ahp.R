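test_that("consistent matrices are exact ratio grids", {
  a <- build_consistent_matrix(c(0.5, 0.3, 0.2))
  expect_equal(a[1, 3], 2.5)
  expect_equal(a[3, 1], 0.4)
  expect_equal(build_consistent_matrix(c(1, 1, 1)),
               matrix(1, 3, 3))
  w5 <- ncd_criteria_weights()
  a5 <- build_consistent_matrix(w5)
  expect_equal(a5[3, 5], 0.337 / 0.077)
  ## scale invariance: only ratios enter
  expect_equal(unname(build_consistent_matrix(10 * w5)), unname(a5))
  expect_error(build_consistent_matrix(c(1, 0)), "positive")
})

test_that("weights from a 2x2 matrix match the closed form", {
  a <- matrix(c(1, 1 / 3, 3, 1), 2, 2)
  d <- derive_weights(a)
  expect_equal(unname(d$weights), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(d$lambda_max, 2, tolerance = 1e-12)
})

test_that("consistent 5x5 recovers its weights with lambda_max = n", {
  w <- ncd_criteria_weights()
  for (method in c("eigenvector", "geometric_mean")) {
    d <- derive_weights(build_consistent_matrix(w), method = method)
    expect_lt(max(abs(d$weights - w)), 1e-9)
    expect_equal(d$lambda_max, 5, tolerance = 1e-9)
  }
})

test_that("power iteration matches the dense eigensolver on noisy matrices", {
  for (seed in 1:10) {
    a <- random_reciprocal(5, noise_sd = 0.5, seed = seed)
    d <- derive_weights(a)
    o <- eigen_oracle(a)
    expect_lt(max(abs(d$weights - o$weights)), 1e-8)
    expect_lt(abs(d$lambda_max - o$lambda_max), 1e-8)
    ## reciprocal positive matrices always have lambda_max >= n
    expect_gte(d$lambda_max, 5 - 1e-9)
  }
})

test_that("invalid pairwise matrices are rejected", {
  bad <- matrix(c(1, 2, 3, 1), 2, 2)       # not reciprocal
  expect_error(derive_weights(bad), "reciprocal")
  expect_error(derive_weights(matrix(c(1, -1, -1, 1), 2, 2)), "positive")
  expect_error(derive_weights(matrix(1, 2, 3)), "square")
})

test_that("consistency ratio follows CI/RI with the Saaty table", {
  ## consistent -> CR = 0, pass
  r <- consistency_ratio(build_consistent_matrix(ncd_criteria_weights()))
  expect_equal(r$cr, 0, tolerance = 1e-9)
  expect_true(r$pass)
  ## 2x2 is consistent by definition
  expect_equal(consistency_ratio(matrix(c(1, 0.2, 5, 1), 2, 2))$cr, 0)
  ## perturbed matrices: CR > 0 and equal to the brute-force
  ## (lambda_max - n)/(n - 1)/RI recomputed with the dense eigensolver
  for (seed in 1:8) {
    set.seed(seed)
    a <- build_consistent_matrix(ncd_criteria_weights())
    for (i in 1:4) for (j in (i + 1):5) {
      a[i, j] <- a[i, j] * exp(rnorm(1, 0, 0.3))
      a[j, i] <- 1 / a[i, j]
    }
    r <- consistency_ratio(a)
    lam <- eigen_oracle(a)$lambda_max
    expect_equal(r$cr, ((lam - 5) / 4) / 1.12, tolerance = 1e-8)
    expect_gt(r$cr, 0)
  }
  expect_error(saaty_random_index(11), "n > 10")
  expect_equal(saaty_random_index(c(3, 5)), c(0.58, 1.12))
})

test_that("geometric-mean aggregation preserves reciprocity exactly", {
  set.seed(21)
  for (rep in 1:20) {
    mats <- lapply(1:4, function(i) random_reciprocal(5, noise_sd = 0.4))
    agg <- aggregate_expert_matrices(mats)
    expect_true(all(abs(agg * t(agg) - 1) < 1e-12))
    expect_true(all(diag(agg) == 1))
  }
  ## identity on a single matrix; a and 1/a average to all ones
  a <- random_reciprocal(4, noise_sd = 0.3, seed = 3)
  expect_equal(aggregate_expert_matrices(list(a)), a)
  expect_equal(aggregate_expert_matrices(list(a, t(a))),
               matrix(1, 4, 4))
  expect_error(aggregate_expert_matrices(list()), "non-empty")
  expect_error(aggregate_expert_matrices(
    list(a, random_reciprocal(3, seed = 4))), "dimension")
})

test_that("eigenvector and geometric-mean methods agree when CR = 0", {
  set.seed(5)
  for (rep in 1:10) {
    a <- build_consistent_matrix(rlnorm(5))
    we <- derive_weights(a, "eigenvector")$weights
    wg <- derive_weights(a, "geometric_mean")$weights
    expect_lt(max(abs(we - wg)), 1e-9)
  }
})

test_that("weight recovery error shrinks as expert noise shrinks", {
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(sd) {
    e <- vapply(1:5, function(seed) {
      ms <- gen_expert_matrices(synth_config(seed = seed,
                                             expert_noise_sd = sd))
      max(abs(coef(ahp(ms)) - ncd_criteria_weights()))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the ahp fit object carries weights and consistency", {
  ms <- gen_expert_matrices(synth_config(seed = 2))
  fit <- ahp(ms)
  expect_s3_class(fit, "ahp")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(fit$n_experts, 8L)
  expect_s3_class(fit$consistency, "consistency_report")
  expect_output(print(fit), "CR")
  expect_output(summary(fit), "lambda_max")
})
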