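test_that("pearson_r handles exact linear relations and degenerate input", {
  x <- c(1, 3, 4, 8, 9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  expect_error(pearson_r(rep(2, 5), x), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("noise-free data is fit exactly with r = 1", {
  d <- data.frame(phi = c(0.1, 0.5, 1.2, 2.0, 2.7, 3.1))
  d$log_kfw <- 1.5 + 2 * d$phi
  m <- kfw_fit(log_kfw ~ phi, d)
  expect_equal(m$intercept, 1.5, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[["phi"]]), 2, tolerance = 1e-10)
  expect_equal(m$r, 1, tolerance = 1e-10)
})

test_that("coefficients are recovered on noisy synthetic data within 3 SE", {
  set.seed(2024)
  g <- generate_linear_dataset(200, c(a = 0.8, b = -1.3, c = 0.05),
                               sigma = 0.4, intercept = 2)
  m <- kfw_fit(y ~ a + b + c, g$data)
  se <- summary(m$fit)$coefficients[names(g$beta), "Std. Error"]
  expect_true(all(abs(m$coefficients - g$beta) < 3 * se))
  # noise-free: exact recovery
  g0 <- generate_linear_dataset(50, c(a = 0.8, b = -1.3), sigma = 0)
  m0 <- kfw_fit(y ~ a + b, g0$data)
  expect_equal(unname(m0$coefficients), unname(g0$beta), tolerance = 1e-9)
})

test_that("residuals are orthogonal to the design and the fit passes the centroid", {
  tr <- kfw_training()
  m <- kfw_fit(log_kfw ~ phi + chi1 + indicator, tr)
  X <- stats::model.matrix(~ phi + chi1 + indicator, tr)
  expect_true(all(abs(crossprod(X, residuals(m))) < 1e-9))
  expect_equal(mean(predict(m, tr)), mean(tr$log_kfw), tolerance = 1e-10)
})

test_that("collinear designs error naming the offending column", {
  d <- data.frame(phi = c(1, 2, 3, 4, 5, 6), log_kfw = c(1, 2, 3, 4, 5, 7))
  d$twice_phi <- 2 * d$phi
  expect_error(kfw_fit(log_kfw ~ phi + twice_phi, d), "twice_phi")
})

test_that("simple-regression slope relates to r through the sd ratio", {
  tab <- single_parameter_models(kfw_training())
  tr <- kfw_training()
  for (v in names(tab)) {
    m <- tab[[v]]
    implied_r <- unname(m$coefficients[[v]]) *
      stats::sd(tr[[v]]) / stats::sd(tr$log_kfw)
    expect_equal(m$r_signed, implied_r, tolerance = 1e-9)
    expect_equal(m$r, abs(implied_r), tolerance = 1e-9)
    expect_true(m$p < 0.05)
  }
})

test_that("the published-model registry returns printed coefficients verbatim", {
  eq6 <- kfw_published("eq6")
  expect_equal(eq6$intercept, 1.502)
  expect_equal(eq6$coefficients, c(phi = 0.918, chi1 = 0.177))
  mw <- kfw_published("table1_mw")
  expect_equal(coef(mw), c("(Intercept)" = 1.859, mw = 0.017))
  eq4 <- kfw_published("eq4")
  expect_equal(length(eq4$coefficients), 4L)
  expect_equal(unname(eq4$coefficients[["ws"]]), 0.001)
  expect_error(kfw_published("eq7"))
})

test_that("prediction is the linear form of the descriptors", {
  benzene <- data.frame(phi = 0.165, chi1 = 2, indicator = 1)
  expect_equal(predict(kfw_published("eq5"), benzene),
               1.447 + 0.728 * 0.165 + 0.316 * 2 - 0.224, tolerance = 1e-12)
  expect_equal(predict(kfw_published("eq6"), benzene),
               1.502 + 0.918 * 0.165 + 0.177 * 2, tolerance = 1e-12)
  expect_equal(predict(kfw_published("eq5"), benzene, type = "kfw"),
               10^predict(kfw_published("eq5"), benzene), tolerance = 1e-12)
  zero <- data.frame(phi = 0, chi1 = 0, indicator = 0)
  expect_equal(predict(kfw_published("eq5"), zero), 1.447)
  # eq4 needs water solubility
  expect_error(predict(kfw_published("eq4"), benzene), "ws")
})

test_that("validation of a model against its own noise-free data is perfect", {
  set.seed(5)
  g <- generate_linear_dataset(30, c(phi = 1, chi1 = 0.5), sigma = 0,
                               intercept = 2)
  g$data$kfw <- 10^g$data$y
  m <- kfw_fit(y ~ phi + chi1, g$data)
  v <- kfw_validate(m, g$data)
  expect_equal(v$r, 1, tolerance = 1e-9)
  expect_equal(v$slope, 1, tolerance = 1e-9)
  expect_equal(v$intercept, 0, tolerance = 1e-9)
})

test_that("forward selection enters polarizability first", {
  sel <- forward_selection(kfw_training())
  expect_equal(sel$path[1], "phi")
  expect_true(all(c("chi1", "indicator") %in% sel$path))
})

test_that("grouped molecular-weight correlation rejects tiny groups", {
  tr <- kfw_training()
  expect_error(
    grouped_mw_correlation(tr, groups = c("a", rep("b", nrow(tr) - 1L))),
    "fewer than 3")
})
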