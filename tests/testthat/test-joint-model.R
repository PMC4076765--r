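make_tiny_trips <- function(n = 20, seed = 5) {
  cpmap:::with_seed(seed, {
    df <- data.frame(
      person_id = sprintf("p%03d", seq_len(n)),
      mode = sample(cpm_modes(), n, replace = TRUE),
      distance_m = exp(rnorm(n, 7, 1)),
      x = rnorm(n), y = rnorm(n), cbd_km = runif(n, 0, 10),
      income = sample(c("low", "mid", "high", "top"), n, TRUE),
      vehicles = sample(c("none", "one", "twoplus"), n, TRUE),
      street_density = runif(n, 0, 20))
    cpm_trips(df, tiny_schema())
  })
}

test_that("MNL probabilities are a safeguarded softmax", {
  pars <- tiny_joint_params()
  p <- ncol <- length(pars$distance_coefs$walk)
  ## equal utilities -> uniform
  pars0 <- pars
  for (m in cpm_modes()) pars0$utility_coefs[[m]][] <- 0
  x <- c(1, rep(0, p - 1))
  expect_equal(unname(mnl_probabilities(x, pars0)), rep(1 / 3, 3),
               tolerance = 1e-12)
  ## utilities (0, 0, ln 2) -> (0.25, 0.25, 0.5)
  pars2 <- pars0
  pars2$utility_coefs$walk["(Intercept)"] <- log(2)
  pr <- mnl_probabilities(x, pars2)
  expect_equal(unname(pr[c("car", "transit", "walk")]),
               c(0.25, 0.25, 0.5), tolerance = 1e-12)
  ## extreme utility -> degenerate limit without NaN
  pars3 <- pars0
  pars3$utility_coefs$walk["(Intercept)"] <- 1000
  pr3 <- mnl_probabilities(x, pars3)
  expect_false(anyNA(pr3))
  expect_lt(abs(pr3[["walk"]] - 1), 1e-10)
  ## normalization property under random designs
  X <- cpmap:::with_seed(2, matrix(rnorm(50 * p, 0, 2), 50, p))
  P <- mnl_probabilities(X, pars)
  expect_true(all(P > 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
})

test_that("joint loglik factorizes into MNL + log-normal at rho = 0", {
  trips <- make_tiny_trips(40)
  pars <- tiny_joint_params(sigma = 0.9, rho = 0)
  ll <- joint_loglik(trips, pars)
  X <- cbind(`(Intercept)` = 1,
             cpmap:::table_design(trips, pars$schema, pars$scaler))
  P <- mnl_probabilities(X, pars)
  pm <- P[cbind(seq_len(nrow(X)), match(trips$mode, cpm_modes()))]
  meanlog <- vapply(seq_len(nrow(X)), function(i)
    sum(pars$distance_coefs[[trips$mode[i]]] * X[i, ]), 0)
  ll_indep <- sum(log(pm)) +
    sum(dlnorm(trips$distance_m, meanlog, 0.9, log = TRUE))
  expect_equal(ll, ll_indep, tolerance = 1e-12)
})

test_that("joint loglik matches the quadrature oracle and is additive", {
  trips <- make_tiny_trips(15)
  pars <- tiny_joint_params(sigma = 1.1, rho = -0.6)
  X <- cbind(`(Intercept)` = 1,
             cpmap:::table_design(trips, pars$schema, pars$scaler))
  ll <- joint_loglik(trips, pars)
  oracle <- sum(vapply(seq_len(nrow(X)), function(i)
    joint_ll_oracle(trips$distance_m[i], X[i, ], pars$utility_coefs,
                    pars$distance_coefs[[trips$mode[i]]], 1.1, -0.6,
                    trips$mode[i]), 0))
  expect_equal(ll, oracle, tolerance = 1e-6 * nrow(X))
  ## duplicating every trip doubles the loglik exactly
  dup <- cpm_trips(rbind(as.data.frame(trips), as.data.frame(trips)),
                   tiny_schema())
  expect_equal(joint_loglik(dup, pars), 2 * ll, tolerance = 1e-12)
})

test_that("parameter domain violations are rejected", {
  sch <- tiny_schema()
  pars <- tiny_joint_params()
  expect_error(joint_model_params(pars$utility_coefs, pars$distance_coefs,
                                  sigma = -1, rho = 0, sch, unit_scaler()),
               "sigma")
  expect_error(joint_model_params(pars$utility_coefs, pars$distance_coefs,
                                  sigma = 1, rho = 1.2, sch, unit_scaler()),
               "rho")
  uc <- pars$utility_coefs
  uc$car["(Intercept)"] <- 5
  expect_error(joint_model_params(uc, pars$distance_coefs, 1, 0, sch,
                                  unit_scaler()), "reference mode")
})

test_that("predicted distance is the log-normal mean and is monotone", {
  pars <- tiny_joint_params(sigma = 0.5)
  p <- length(pars$distance_coefs$walk)
  design <- rep(0, p - 7)  # covariate block of zeros
  trend <- rep(0, 6)
  pars$distance_coefs$walk[] <- 0
  ## theta'x = 0, sigma -> 0 gives 1 metre
  pars_eps <- pars
  pars_eps$sigma[] <- 1e-9
  expect_equal(predict_distance(design, trend, pars_eps, "walk"), 1,
               tolerance = 1e-9)
  ## theta'x = ln 500, sigma 0.5 -> 500 * exp(0.125)
  pars$distance_coefs$walk["(Intercept)"] <- log(500)
  expect_equal(predict_distance(design, trend, pars, "walk"),
               500 * exp(0.125))
  expect_equal(predict_distance(design, trend, pars, "walk",
                                type = "median"), 500)
  ## increasing a coefficient on a positive covariate raises the mean
  pars2 <- pars
  pars2$distance_coefs$walk["cbd_km"] <- 0.2
  trend2 <- trend; trend2[6] <- 2
  expect_gt(predict_distance(design, trend2, pars2, "walk"),
            predict_distance(design, trend2, pars, "walk"))
})

test_that("fit_joint requires every mode and flags collinear designs", {
  trips <- make_tiny_trips(30)
  only2 <- cpm_trips(as.data.frame(trips)[trips$mode != "walk", ],
                     tiny_schema())
  expect_error(fit_joint(only2, tiny_schema()), "walk")
})

test_that("fitted joint model beats the constants-only benchmark", {
  cfg <- make_default_config(400, seed = 8)
  sv <- simulate_survey(cfg)
  fit <- fit_joint(sv$trips, cfg$schema, scaler = cfg$true_joint$scaler,
                   control = list(maxit = 60))
  expect_gt(fit$loglik, fit$loglik_null)
  expect_true(is.finite(fit$mcfadden_adj_rho2))
  expect_equal(fit$n_obs, nrow(sv$trips))
  expect_equal(length(fit$std_errors),
               5 * (1 + length(cfg$schema$design_names) + 6) + 2)
  ## serialization round trip preserves the fitted parameters
  path <- tempfile(fileext = ".json")
  write_joint_model(fit, path)
  back <- read_joint_model(path)
  expect_equal(back$distance_coefs$walk, fit$params$distance_coefs$walk,
               tolerance = 1e-12)
  expect_equal(unname(back$rho[[1]]), unname(fit$params$rho[[1]]),
               tolerance = 1e-12)
})
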