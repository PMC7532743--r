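test_that("bias vectors follow the factor algebra", {
  ti0 <- theory_input(c(2, 1), c(1, -1), 0)
  for (e in c("MLE", "PRRE", "AUPRRE", "MAUPRRE")) {
    expect_equal(bias_vector(ti0, e), c(0, 0))
  }
  ti <- theory_input(1, 1, 1)
  expect_equal(bias_vector(ti, "PRRE"), -1 / 2)
  expect_equal(bias_vector(ti, "AUPRRE"), -1 / 4)
  # bias correction: AUPRRE bias strictly smaller in magnitude for k > 0
  for (seed in 1:20) {
    rc <- random_canonical(4, seed)
    for (k in c(0.1, 1, 5)) {
      ti <- theory_input(rc$lambdas, rc$alpha, k)
      expect_true(all(abs(bias_vector(ti, "AUPRRE")) < abs(bias_vector(ti, "PRRE"))))
    }
  }
})

test_that("scalar MSE closed forms match hand values and limits", {
  ti0 <- theory_input(c(2, 4), c(1, 1), 0)
  for (e in c("MLE", "PRRE", "AUPRRE", "MAUPRRE")) {
    expect_equal(scalar_mse(ti0, e), 0.75)
  }
  expect_equal(scalar_mse(theory_input(c(1, 1), c(1, 1), 1), "PRRE"), 1)
  # k -> infinity: ridge MSE tends to the squared coefficient norm
  rc <- random_canonical(3, 7)
  big <- theory_input(rc$lambdas, rc$alpha, 1e9)
  expect_equal(scalar_mse(big, "PRRE"), sum(rc$alpha^2), tolerance = 1e-6)
})

test_that("matrix MSE decomposes as covariance plus squared bias", {
  for (seed in 1:10) {
    rc <- random_canonical(4, seed)
    ti <- theory_input(rc$lambdas, rc$alpha, runif(1, 0.01, 5))
    for (e in c("PRRE", "AUPRRE", "MAUPRRE")) {
      mm <- matrix_mse(ti, e)
      b <- bias_vector(ti, e)
      expect_equal(mm, ridge_covariance(ti, e) + tcrossprod(b), tolerance = 1e-12)
      expect_equal(scalar_mse(ti, e), sum(diag(mm)), tolerance = 1e-10)
    }
    # printed summation forms, recomputed independently here
    lam <- ti$lambdas; a <- ti$alpha; k <- ti$k
    expect_equal(scalar_mse(ti, "PRRE"),
                 sum((lam + k^2 * a^2) / (lam + k)^2), tolerance = 1e-10)
    expect_equal(scalar_mse(ti, "AUPRRE"),
                 sum((1 / lam) * (1 - k^2 / (lam + k)^2)^2) +
                   sum(k^4 * a^2 / (lam + k)^4), tolerance = 1e-10)
  }
})

test_that("the as-printed MAUPRRE summation diverges from the trace", {
  rc <- random_canonical(3, 5)
  ti <- theory_input(rc$lambdas, rc$alpha, 1)
  expect_gt(abs(scalar_mse(ti, "MAUPRRE", as_printed = TRUE) -
                scalar_mse(ti, "MAUPRRE")), 1e-6)
  # the literal summation does not even reduce to the MLE value at k = 0:
  # its variance term carries an extra squared ridge ratio, 1/lambda^2 there
  ti0 <- theory_input(rc$lambdas, rc$alpha, 0)
  expect_equal(scalar_mse(ti0, "MAUPRRE", as_printed = TRUE),
               sum(1 / rc$lambdas^3), tolerance = 1e-12)
  expect_equal(scalar_mse(ti0, "MAUPRRE"), scalar_mse(ti0, "MLE"), tolerance = 1e-12)
})

test_that("MSE differences are consistent and vanish at k = 0", {
  rc <- random_canonical(4, 9)
  ti0 <- theory_input(rc$lambdas, rc$alpha, 0)
  pairs <- list(c("MLE", "PRRE"), c("MLE", "AUPRRE"), c("PRRE", "MAUPRRE"))
  for (p in pairs) expect_equal(mse_difference(ti0, p[1], p[2]), 0)
  expect_error(mse_difference(ti0, "PRRE", "PRRE"), "different")
  for (seed in 1:10) {
    rc <- random_canonical(3, seed + 100)
    ti <- theory_input(rc$lambdas, rc$alpha, runif(1, 0.1, 3))
    lam <- ti$lambdas; a <- ti$alpha; k <- ti$k
    direct <- sum((lam + k^2 * a^2) / (lam + k)^2) -
      (sum((1 / lam) * (1 - k^2 / (lam + k)^2)^2) + sum(k^4 * a^2 / (lam + k)^4))
    expect_equal(mse_difference(ti, "PRRE", "AUPRRE"), direct, tolerance = 1e-12)
  }
})

test_that("dominance thresholds bracket the sign change of the MSE difference", {
  th <- theorem_thresholds(1, 1)
  expect_equal(th$k_lower_auprre_vs_prre, (2 + sqrt(20)) / 4)
  expect_true(is.infinite(theorem_thresholds(1, 0.5)$k_upper_auprre_vs_mle))
  set.seed(55)
  for (i in 1:50) {
    lam <- exp(runif(1, -2, 3)); a <- runif(1, 0.3, 2)
    th <- theorem_thresholds(lam, a)
    kstar <- th$k_lower_auprre_vs_prre
    below <- mse_difference(theory_input(lam, a, kstar * 0.99), "PRRE", "AUPRRE")
    above <- mse_difference(theory_input(lam, a, kstar * 1.01), "PRRE", "AUPRRE")
    expect_lt(below, 0)
    expect_gt(above, 0)
    # AUPRRE beats the MLE below its upper threshold, loses above it
    ku <- th$k_upper_auprre_vs_mle
    if (is.finite(ku)) {
      expect_gt(mse_difference(theory_input(lam, a, ku * 0.99), "MLE", "AUPRRE"), 0)
      expect_lt(mse_difference(theory_input(lam, a, ku * 1.01), "MLE", "AUPRRE"), 0)
    }
  }
})

test_that("AUPRRE dominates the MLE for every k when lambda alpha^2 <= 1", {
  set.seed(65)
  for (i in 1:20) {
    p <- sample(2:5, 1)
    lam <- exp(runif(p, -2, 2))
    a <- runif(p, 0.05, 1) / sqrt(lam)  # forces lambda * alpha^2 <= 1
    for (k in c(0.01, 0.1, 1, 10, 1000)) {
      expect_gt(mse_difference(theory_input(lam, a, k), "MLE", "AUPRRE"), 0)
    }
  }
})

test_that("quadratic-form condition certifies MAUPRRE matrix-MSE dominance", {
  set.seed(75)
  n_checked <- 0
  for (i in 1:200) {
    rc <- random_canonical(sample(2:4, 1), i + 200)
    ti <- theory_input(rc$lambdas, rc$alpha, runif(1, 0.01, 2))
    for (base in c("MLE", "PRRE", "AUPRRE")) {
      chk <- mauprre_dominance_condition(ti, base)
      if (isTRUE(chk$condition_holds)) {
        n_checked <- n_checked + 1
        expect_gte(chk$min_eigen_mmse_difference, -1e-8)
      }
    }
  }
  expect_gt(n_checked, 20)  # the condition must actually fire on random draws
})

test_that("MSE curves are self-consistent and ordered in squared bias", {
  rc <- random_canonical(3, 77)
  grid <- seq(0, 2, by = 0.25)
  curves <- mse_curve(rc$lambdas, rc$alpha, grid)
  at0 <- curves[curves$k == 0, ]
  expect_true(all(abs(at0$scalar_mse - at0$scalar_mse[1]) < 1e-12))
  expect_true(all(at0$squared_bias == 0))
  pos <- curves[curves$k > 0, ]
  au <- pos[pos$estimator == "AUPRRE", ]
  pr <- pos[pos$estimator == "PRRE", ]
  expect_true(all(au$squared_bias < pr$squared_bias))
  k1 <- curves[curves$k == 1 & curves$estimator == "MAUPRRE", ]
  expect_equal(k1$scalar_mse, scalar_mse(theory_input(rc$lambdas, rc$alpha, 1), "MAUPRRE"))
  expect_error(mse_curve(rc$lambdas, rc$alpha, numeric(0)), "nonempty")
  expect_error(mse_curve(rc$lambdas, rc$alpha, c(1, 0.5)), "sorted")
})
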