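make_tiny_persons <- function(n = 30, seed = 6) {
  cpmap:::with_seed(seed, {
    df <- data.frame(
      person_id = sprintf("q%03d", seq_len(n)),
      n_walk = sample(0:3, n, TRUE), n_car = sample(0:4, n, TRUE),
      n_transit = sample(0:3, n, TRUE),
      x = rnorm(n), y = rnorm(n), cbd_km = runif(n, 0, 8),
      income = sample(c("low", "mid", "high", "top"), n, TRUE),
      vehicles = sample(c("none", "one", "twoplus"), n, TRUE),
      street_density = runif(n, 0, 15))
    cpm_persons(df, tiny_schema())
  })
}

test_that("marginal class probabilities follow the threshold formula", {
  pars <- tiny_freq_params()
  pars$thresholds$walk <- c(-1, 0, 1)
  pars$coefs$walk <- c(street_density = 0)
  design <- encode_covariates(list(income = "low", vehicles = "none",
                                   street_density = 0), tiny_schema())
  trend <- rep(0, 6); names(trend) <- cpmap:::trend_names()
  pr <- marginal_class_probs(design, trend, pars, "walk")
  expect_equal(unname(pr),
               c(pnorm(-1), pnorm(0) - pnorm(-1), pnorm(1) - pnorm(0),
                 1 - pnorm(1)))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  ## a huge linear predictor pushes all mass to the open class
  pars$coefs$walk <- c(street_density = 100)
  design["street_density"] <- 10
  pr2 <- marginal_class_probs(design, trend, pars, "walk")
  expect_equal(unname(pr2[["3+"]]), 1, tolerance = 1e-12)
  ## random-parameter normalization property
  for (s in 1:20) {
    th <- sort(cpmap:::with_seed(s, rnorm(3)))
    pars$thresholds$walk <- th + c(0, 0.01, 0.02)
    pars$coefs$walk <- c(street_density = cpmap:::with_seed(s + 100,
                                                            rnorm(1)))
    pr <- marginal_class_probs(design, trend, pars, "walk")
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-10)
  }
})

test_that("trivariate loglik factorizes at R = identity, exactly", {
  per <- make_tiny_persons(40)
  pars <- tiny_freq_params(corr = diag(3))
  ll <- trivariate_loglik(per, pars)
  D <- cpmap:::table_design(per, pars$schema, pars$scaler)
  classes <- cpmap:::person_classes(per)
  ll_uni <- 0
  for (i in 1:3) {
    m <- cpm_modes()[i]
    b <- pars$coefs[[m]]
    eta <- drop(D[, names(b), drop = FALSE] %*% b)
    cuts <- c(-Inf, pars$thresholds[[m]], Inf)
    pk <- pnorm(cuts[classes[, i] + 2] - eta) -
      pnorm(cuts[classes[, i] + 1] - eta)
    ll_uni <- ll_uni + sum(log(pk))
  }
  expect_equal(ll, ll_uni, tolerance = 1e-13)
})

test_that("exact trivariate loglik is deterministic and permutation-invariant", {
  per <- make_tiny_persons(25)
  pars <- tiny_freq_params()
  ll1 <- trivariate_loglik(per, pars)
  ll2 <- trivariate_loglik(per, pars)
  expect_identical(ll1, ll2)
  perm <- cpmap:::with_seed(3, sample(nrow(per)))
  per_shuffled <- cpm_persons(as.data.frame(per)[perm, ], tiny_schema())
  expect_equal(trivariate_loglik(per_shuffled, pars), ll1,
               tolerance = 1e-12)
})

test_that("GHK likelihood agrees with exact within Monte-Carlo error", {
  per <- make_tiny_persons(50, seed = 12)
  pars <- tiny_freq_params()
  D <- cpmap:::table_design(per, pars$schema, pars$scaler)
  eta <- cpmap:::freq_eta(D, pars$coefs)
  b <- cpmap:::freq_bounds(eta, cpmap:::person_classes(per),
                           pars$thresholds)
  exact <- pmvn3_rect(b$lower, b$upper, pars$corr)
  gh <- ghk_probs(b$lower, b$upper, pars$corr, draws = 500, seed = 2)
  expect_lt(max(abs(gh$prob - exact) / pmax(gh$se, 1e-12)), 3)
})

test_that("marginalizing the trivariate model recovers univariate probabilities", {
  pars <- tiny_freq_params()
  per1 <- make_tiny_persons(1, seed = 30)
  D <- cpmap:::table_design(per1, pars$schema, pars$scaler)
  eta <- cpmap:::freq_eta(D, pars$coefs)
  ## walk marginal by summing exact box probabilities over all classes of
  ## the other two modes
  cuts <- function(m) c(-Inf, pars$thresholds[[m]], Inf)
  marg <- numeric(4)
  for (ow in 0:3) {
    tot <- 0
    for (oc in 0:3) for (ot in 0:3) {
      lo <- c(cuts("walk")[ow + 1], cuts("car")[oc + 1],
              cuts("transit")[ot + 1]) - eta[1, ]
      up <- c(cuts("walk")[ow + 2], cuts("car")[oc + 2],
              cuts("transit")[ot + 2]) - eta[1, ]
      tot <- tot + pmvn3_rect(matrix(lo, 1), matrix(up, 1), pars$corr)
    }
    marg[ow + 1] <- tot
  }
  design <- cpmap:::design_matrix(per1, tiny_schema())[1, ]
  trend <- cpmap:::trend_terms_matrix(cbind(per1$x, per1$y), pars$scaler,
                                      cbd_km = per1$cbd_km)[1, ]
  expect_equal(marg,
               unname(marginal_class_probs(design, trend, pars, "walk")),
               tolerance = 1e-8)
})

test_that("fit_frequency demands every class for every mode", {
  per <- make_tiny_persons(30)
  df <- as.data.frame(per)
  df$n_walk[df$n_walk >= 3] <- 2  # remove the open walk class
  expect_error(fit_frequency(cpm_persons(df, tiny_schema()), tiny_schema()),
               "walk.*3|3.*walk")
})

test_that("fitted thresholds are increasing and loglik beats thresholds-only", {
  cfg <- make_default_config(400, seed = 14)
  per <- simulate_persons(cfg)
  fit <- fit_frequency(per, cfg$schema, exclude = cfg$freq_exclude,
                       scaler = cfg$true_freq$scaler,
                       control = list(maxit = 40))
  for (m in cpm_modes()) expect_true(all(diff(fit$params$thresholds[[m]]) > 0))
  expect_gt(fit$loglik, fit$loglik_null)
  ## serialization round trip
  path <- tempfile(fileext = ".json")
  write_frequency_model(fit, path)
  back <- read_frequency_model(path)
  expect_equal(back$corr, fit$params$corr, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$coefs$walk, fit$params$coefs$walk, tolerance = 1e-12)
})
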