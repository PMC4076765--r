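## Shared test fixtures: a miniature schema, hand-set parameters and a
## few construction helpers. All randomized tests fix their own seeds.

tiny_schema <- function() {
  covariate_schema(list(
    income = list(type = "categorical",
                  levels = c("low", "mid", "high", "top"),
                  reference = "low"),
    vehicles = list(type = "categorical", levels = c("none", "one", "twoplus"),
                    reference = "none"),
    street_density = list(type = "continuous")))
}

unit_scaler <- function() {
  structure(list(center = c(0, 0), scale = c(1, 1)), class = "cpm_scaler")
}

## joint model params over the tiny schema with hand-set values
tiny_joint_params <- function(sigma = 0.8, rho = -0.4) {
  sch <- tiny_schema()
  cols <- c("(Intercept)", sch$design_names, cpmap:::trend_names())
  zero <- stats::setNames(numeric(length(cols)), cols)
  uw <- zero; uw["(Intercept)"] <- -1; uw["vehicles:one"] <- -0.5
  ut <- zero; ut["(Intercept)"] <- -1.2; ut["street_density"] <- 0.05
  dw <- zero; dw["(Intercept)"] <- 6.2; dw["income:top"] <- 0.3
  dw["cbd_km"] <- -0.05
  dc <- zero; dc["(Intercept)"] <- 8
  dt <- zero; dt["(Intercept)"] <- 8.1
  joint_model_params(list(walk = uw, car = zero, transit = ut),
                     list(walk = dw, car = dc, transit = dt),
                     sigma = sigma, rho = rho, schema = sch,
                     scaler = unit_scaler(), reference_mode = "car")
}

tiny_freq_params <- function(corr = NULL) {
  sch <- tiny_schema()
  if (is.null(corr))
    corr <- matrix(c(1, -0.4, -0.2, -0.4, 1, -0.5, -0.2, -0.5, 1), 3L)
  coefs <- list(
    walk = c(`vehicles:one` = -0.4, `vehicles:twoplus` = -0.7,
             street_density = 0.02, cbd_km = -0.04),
    car = c(`vehicles:one` = 0.9, `vehicles:twoplus` = 1.2,
            cbd_km = 0.05),
    transit = c(`income:top` = -0.2, `vehicles:one` = -0.8,
                street_density = 0.03))
  thresholds <- list(walk = c(0.1, 0.6, 1.1), car = c(-0.2, 0.5, 1.3),
                     transit = c(0.5, 1.0, 1.5))
  ordered_probit_params(coefs, thresholds, corr, sch, unit_scaler())
}

## random admissible boxes for rectangle-probability checks
random_boxes <- function(n, seed = 1, p_inf = 0.2) {
  cpmap:::with_seed(seed, {
    lo <- matrix(stats::rnorm(n * 3, -1), n, 3)
    up <- lo + matrix(stats::rexp(n * 3, 0.7), n, 3)
    for (j in 1:3) {
      lo[stats::runif(n) < p_inf, j] <- -Inf
      up[stats::runif(n) < p_inf, j] <- Inf
    }
    list(lower = lo, upper = up)
  })
}

random_corr3 <- function(seed = 1) {
  cpmap:::with_seed(seed, {
    repeat {
      r <- stats::runif(3, -0.8, 0.8)
      R <- matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3L)
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0.05) return(R)
    }
  })
}

## named truth/estimate vectors aligned with fit_frequency std_errors
freq_param_vector <- function(p) {
  out <- c()
  for (m in cpm_modes()) {
    v <- p$coefs[[m]]
    if (length(v)) names(v) <- paste0(m, ".", names(v))
    th <- p$thresholds[[m]]
    names(th) <- paste0(m, ".threshold", 1:3)
    out <- c(out, v, th)
  }
  c(out, corr.walk.car = unname(p$corr[1, 2]),
    corr.walk.transit = unname(p$corr[1, 3]),
    corr.car.transit = unname(p$corr[2, 3]))
}

## named truth/estimate vectors aligned with fit_joint std_errors
joint_param_vector <- function(p) {
  nonref <- setdiff(cpm_modes(), p$reference_mode)
  out <- c()
  for (m in nonref) {
    v <- p$utility_coefs[[m]]
    names(v) <- paste0("utility.", m, ".", names(v))
    out <- c(out, v)
  }
  for (m in cpm_modes()) {
    v <- p$distance_coefs[[m]]
    names(v) <- paste0("distance.", m, ".", names(v))
    out <- c(out, v)
  }
  c(out, sigma = unname(p$sigma[[1]]), rho = unname(p$rho[[1]]))
}

## default-config variant with zero selectivity / independent errors
null_corr_config <- function(n, seed) {
  cfg <- make_default_config(n, seed)
  tj <- cfg$true_joint
  cfg$true_joint <- joint_model_params(tj$utility_coefs, tj$distance_coefs,
                                       tj$sigma, rho = 0, tj$schema,
                                       tj$scaler, tj$reference_mode)
  tf <- cfg$true_freq
  cfg$true_freq <- ordered_probit_params(tf$coefs, tf$thresholds, diag(3),
                                         tf$schema, tf$scaler)
  cfg
}

## independent slow oracle for one joint-likelihood contribution:
## (1/(sigma d)) * integral_{-inf}^{J1} phi2(e, u; rho) de, with the
## bivariate density written out directly and integrated numerically.
joint_ll_oracle <- function(d, x, utility, theta_m, sigma, rho, mode) {
  eta <- vapply(cpm_modes(), function(m) sum(utility[[m]] * x), 0)
  pm <- exp(eta[mode] - max(eta)) / sum(exp(eta - max(eta)))
  j1 <- stats::qnorm(pm)
  u <- (log(d) - sum(theta_m * x)) / sigma
  phi2 <- function(e) exp(-(e^2 - 2 * rho * e * u + u^2) /
                            (2 * (1 - rho^2))) /
    (2 * pi * sqrt(1 - rho^2))
  ## split the range at the integrand's peak (e = rho*u) so integrate()
  ## keeps full relative precision even for spiked integrands
  sc <- sqrt(1 - rho^2)
  cuts <- sort(c(rho * u - 6 * sc, rho * u, rho * u + 6 * sc))
  cuts <- c(cuts[cuts < j1], j1)
  lo <- c(-Inf, cuts[-length(cuts)])
  I <- sum(vapply(seq_along(cuts), function(i)
    stats::integrate(phi2, lo[i], cuts[i], rel.tol = 1e-12,
                     abs.tol = 0, subdivisions = 2000L)$value, 0))
  log(I / (sigma * d))
}
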