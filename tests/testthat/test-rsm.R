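test_that("model matrix columns follow the fixed quadratic-term order", {
  X <- build_model_matrix(coded_design(c(-1, -1, -1)))
  expect_equal(colnames(X),
               c("(Intercept)", "Cd", "Pb", "Cr",
                 "Cd:Pb", "Cd:Cr", "Pb:Cr", "Cd^2", "Pb^2", "Cr^2"))
  expect_equal(unname(X[1, ]), c(1, -1, -1, -1, 1, 1, 1, 1, 1, 1))

  X0 <- build_model_matrix(coded_design(c(0, 0, 0)))
  expect_equal(unname(X0[1, ]), c(1, rep(0, 9)))

  # the true coded central point: entries are the pairwise products/squares
  ctr <- c(-0.08, -0.07, -0.18)
  Xc <- build_model_matrix(coded_design(ctr))
  expect_equal(unname(Xc[1, ]),
               c(1, ctr, ctr[1] * ctr[2], ctr[1] * ctr[3], ctr[2] * ctr[3],
                 ctr^2))

  # generalizes beyond three factors
  X4 <- build_model_matrix(matrix(1, 1, 4))
  expect_equal(ncol(X4), 1 + 4 + 6 + 4)
})

test_that("noise-free data reproduce the generating coefficients exactly", {
  design <- replicate_design(full_factorial(aviculare_factors()), 3)
  X <- build_model_matrix(design)
  b_true <- aviculare_coefficients()$Cd
  fit <- fit_rsm(X, drop(X %*% b_true), response_name = "Cd")
  expect_equal(unname(fit$coefficients), unname(b_true), tolerance = 1e-10)
  expect_equal(fit$df_residual, 81 - 10)
  expect_lt(fit$residual_sd, 1e-10)
})

test_that("fit matches the brute-force normal-equation oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(12:50, 1)
    X <- build_model_matrix(toy_coded(n, 3, seed = 1000 + rep))
    y <- stats::rnorm(n)
    fit <- fit_rsm(X, y)
    expect_equal(unname(fit$coefficients), unname(oracle_ols(X, y)),
                 tolerance = 1e-8)
    # and against lm() as a second, library-based cross-check
    ref <- stats::lm.fit(X, y)
    expect_equal(unname(fit$coefficients), unname(ref$coefficients),
                 tolerance = 1e-10)
  }
})

test_that("standard errors and p-values match the closed-form OLS formulas", {
  set.seed(11)
  X <- build_model_matrix(toy_coded(30, 3))
  y <- stats::rnorm(30, mean = X[, 2])
  fit <- fit_rsm(X, y)
  dof <- 30 - 10
  res <- y - drop(X %*% oracle_ols(X, y))
  s2 <- sum(res^2) / dof
  se_ref <- sqrt(s2 * diag(solve(t(X) %*% X)))
  expect_equal(unname(fit$se), unname(se_ref), tolerance = 1e-8)
  expect_equal(unname(fit$p_value),
               unname(2 * stats::pt(-abs(fit$coefficients / se_ref), dof)),
               tolerance = 1e-10)
})

test_that("fit is invariant to observation order and shifts only b0 under y + c", {
  set.seed(21)
  X <- build_model_matrix(toy_coded(20, 3))
  y <- stats::rnorm(20)
  fit <- fit_rsm(X, y)
  perm <- sample(20)
  fit_p <- fit_rsm(X[perm, ], y[perm])
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$se, fit$se, tolerance = 1e-10)

  fit_s <- fit_rsm(X, y + 5)
  expect_equal(unname(fit_s$coefficients["(Intercept)"]),
               unname(fit$coefficients["(Intercept)"]) + 5, tolerance = 1e-10)
  expect_equal(fit_s$coefficients[-1], fit$coefficients[-1],
               tolerance = 1e-10)
})

test_that("residuals are orthogonal to every model column", {
  for (rep in 1:10) {
    X <- build_model_matrix(toy_coded(25, 3, seed = 300 + rep))
    set.seed(400 + rep)
    y <- stats::rnorm(25)
    fit <- fit_rsm(X, y)
    expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8)
  }
})

test_that("a singular design is reported with the aliased columns named", {
  # two-level design cannot identify squared terms: x^2 aliases the intercept
  d2 <- full_factorial(aviculare_factors(), c("low", "high"))
  X <- build_model_matrix(replicate_design(d2, 3))
  expect_error(fit_rsm(X, stats::rnorm(nrow(X))), "singular design.*\\^2")
  expect_error(fit_rsm(build_model_matrix(coded_design(c(0, 0, 0))), 1),
               "degrees of freedom")
})

test_that("significance stars and alpha flags follow the conventional bands", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
  # boundary values are not starred at their own threshold
  expect_equal(p_stars(c(0.001, 0.01, 0.05)), c("**", "*", ""))

  fit <- coefficient_tests(reference_fit("Cd"), alpha = 0.05)
  expect_identical(unname(fit$significant), unname(fit$p_value < 0.05))
  expect_equal(fit$alpha, 0.05)
  expect_error(coefficient_tests(fit, alpha = 1.5), "alpha")
})

test_that("prediction returns x0'b with the mean-response standard error", {
  s <- simulate_study(seed = 5)
  fit <- fit_uptake_models(s$design, s$uptake)$Cd
  pts <- rbind(c(0, 0, 0), c(-1, 1, 0.3), c(0.5, -0.2, -0.9))
  pred <- predict(fit, pts)
  X0 <- build_model_matrix(coded_design(pts))
  expect_equal(pred$fit, unname(drop(X0 %*% fit$coefficients)),
               tolerance = 1e-10)
  se_ref <- fit$residual_sd *
    sqrt(diag(X0 %*% fit$xtx_inv %*% t(X0)))
  expect_equal(pred$se_fit, unname(se_ref), tolerance = 1e-10)
  # prediction interval se is strictly larger
  pred_new <- predict(fit, pts, interval = "prediction")
  expect_true(all(pred_new$se_fit > pred$se_fit))
  expect_warning(predict(fit, c(2, 0, 0)), "outside the coded cube")
  expect_error(predict(fit, c(0, 0)), "coded coordinates")

  # zero-residual fit predicts with zero uncertainty at any point
  exact <- reference_fit("Cd")
  expect_equal(predict(exact, c(0.3, -0.4, 0.1))$se_fit, 0,
               tolerance = 1e-8)
})

test_that("run-mean fitting gives the same coefficients on balanced data", {
  s <- simulate_study(seed = 9)
  fit_all <- fit_uptake_models(s$design, s$uptake)$Cd
  fit_mean <- fit_uptake_models(s$design, s$uptake, use_run_means = TRUE)$Cd
  # balanced replication: run means give identical point estimates
  expect_equal(fit_mean$coefficients, fit_all$coefficients, tolerance = 1e-10)
  expect_equal(fit_mean$df_residual, 27 - 10)
  expect_equal(fit_all$df_residual, 81 - 10)
})

test_that("coefficient se matches a parametric-bootstrap spread", {
  design <- replicate_design(full_factorial(aviculare_factors()), 3)
  X <- build_model_matrix(design)
  b_true <- aviculare_coefficients()$Cd
  mu <- drop(X %*% b_true)
  sigma <- 0.31
  set.seed(2024)
  ests <- replicate(400, {
    fit_rsm(X, mu + stats::rnorm(length(mu), 0, sigma))$coefficients[["Cd"]]
  })
  # analytic se at the true sigma
  se_true <- sigma * sqrt(diag(solve(t(X) %*% X))[["Cd"]])
  expect_equal(stats::sd(ests), se_true, tolerance = 0.15)
})
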