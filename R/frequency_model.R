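## Trivariate ordered probit model of per-mode trip frequency.
##
## Each person p has a latent propensity t*_j = beta_j' x_j + eps_j per
## mode j, with (eps_walk, eps_car, eps_transit) ~ N(0, R). Observed
## weekly trip counts fall in ordered classes {0, 1, 2, 3+} cut by
## strictly increasing thresholds mu_j (length 3; the latent scale is
## fixed by unit error variance and thresholds absorb the intercept).
## The likelihood of a person is the probability that eps lies in the
## box formed by the per-mode threshold intervals shifted by beta_j'x_j;
## off-diagonal elements of R capture common unobserved factors across
## the three count decisions.

#' Parameters of the trivariate ordered probit frequency model
#'
#' @param coefs Named list per mode of named coefficient vectors; names
#'   must be a subset of the schema design columns plus trend terms.
#'   Columns absent from a mode's vector are structurally excluded from
#'   that mode's design (a coefficient fixed at zero).
#' @param thresholds Named list per mode of strictly increasing numeric
#'   vectors of length 3, cutting classes `{0, 1, 2, 3+}`.
#' @param corr 3x3 correlation matrix (mode order walk, car, transit).
#' @param schema A [covariate_schema()].
#' @param scaler A [fit_scaler()] result.
#' @return Object of class `ordered_probit_params`.
#' @export
ordered_probit_params <- function(coefs, thresholds, corr, schema, scaler) {
  modes <- cpm_modes()
  stopifnot(setequal(names(coefs), modes), setequal(names(thresholds), modes))
  corr <- validate_corr3(corr)
  all_cols <- c(schema$design_names, trend_names())
  for (m in modes) {
    if (length(coefs[[m]]) && (is.null(names(coefs[[m]])) ||
                               !all(names(coefs[[m]]) %in% all_cols)))
      stop("coefficients for mode '", m,
           "' must be named by design columns", call. = FALSE)
    mu <- thresholds[[m]]
    if (length(mu) != 3L || any(diff(mu) <= 0))
      stop("thresholds for mode '", m,
           "' must be strictly increasing, length 3", call. = FALSE)
  }
  validate_scaler(scaler)
  structure(list(coefs = coefs[modes], thresholds = thresholds[modes],
                 corr = corr, schema = schema, scaler = scaler),
            class = "ordered_probit_params")
}

#' Marginal ordered-class probabilities for one mode
#'
#' `P(class = o) = Phi(mu_{o+1} - eta) - Phi(mu_o - eta)` with
#' `mu_0 = -Inf`, `mu_4 = Inf` and `eta = beta' x`; the marginal of the
#' trivariate model for a single mode.
#'
#' @param design Encoded covariate vector ([encode_covariates()]).
#' @param trend Trend-surface terms ([trend_terms()]).
#' @param params An [ordered_probit_params()].
#' @param mode One of [cpm_modes()].
#' @return Probability vector over classes `c("0","1","2","3+")`,
#'   summing to 1.
#' @export
marginal_class_probs <- function(design, trend, params, mode) {
  stopifnot(mode %in% cpm_modes())
  x <- c(design, trend)
  b <- params$coefs[[mode]]
  if (length(b) && !all(names(b) %in% names(x)))
    stop("design does not provide all coefficient columns", call. = FALSE)
  eta <- if (length(b)) sum(b * x[names(b)]) else 0
  cuts <- c(-Inf, params$thresholds[[mode]], Inf)
  p <- diff(stats::pnorm(cuts - eta))
  names(p) <- freq_class_labels()
  p
}

person_classes <- function(persons) {
  cbind(walk = pmin(persons$n_walk, 3L),
        car = pmin(persons$n_car, 3L),
        transit = pmin(persons$n_transit, 3L))
}

## Linear predictors (n x 3) given full design matrix and per-mode
## named coefficient vectors.
freq_eta <- function(D, coefs) {
  out <- matrix(0, nrow(D), 3L)
  for (i in 1:3) {
    b <- coefs[[cpm_modes()[i]]]
    if (length(b)) out[, i] <- D[, names(b), drop = FALSE] %*% b
  }
  out
}

freq_bounds <- function(eta, classes, thresholds) {
  n <- nrow(eta)
  lower <- upper <- matrix(0, n, 3L)
  for (i in 1:3) {
    cuts <- c(-Inf, thresholds[[cpm_modes()[i]]], Inf)
    o <- classes[, i] + 1L  # class 0 -> interval (cuts[1], cuts[2])
    lower[, i] <- cuts[o] - eta[, i]
    upper[, i] <- cuts[o + 1L] - eta[, i]
  }
  list(lower = lower, upper = upper)
}

#' Trivariate ordered probit log-likelihood
#'
#' Sum over persons of the log probability that the trivariate normal
#' error vector falls in the person's box of threshold intervals.
#' `method = "exact"` uses deterministic quadrature
#' ([pmvn3_rect()]); `method = "ghk"` uses the GHK simulator with a
#' fixed seed. With `corr = I` the exact method factorizes into the sum
#' of the three univariate ordered-probit log-likelihoods.
#'
#' @param persons A [cpm_persons()] table.
#' @param params An [ordered_probit_params()].
#' @param method `"exact"` (default) or `"ghk"`.
#' @param nodes Quadrature order for the exact method.
#' @param ghk_draws,ghk_seed GHK simulator settings.
#' @return Scalar log-likelihood.
#' @export
trivariate_loglik <- function(persons, params, method = c("exact", "ghk"),
                              nodes = 24L, ghk_draws = 500L, ghk_seed = 1L) {
  method <- match.arg(method)
  D <- table_design(persons, params$schema, params$scaler)
  eta <- freq_eta(D, params$coefs)
  b <- freq_bounds(eta, person_classes(persons), params$thresholds)
  p <- if (method == "exact") {
    pmvn3_rect(b$lower, b$upper, params$corr, nodes = nodes)
  } else {
    ghk_probs(b$lower, b$upper, params$corr, draws = ghk_draws,
              seed = ghk_seed)$prob
  }
  sum(log(pmax(p, 1e-300)))
}

## --- unconstrained parameterizations ------------------------------------

## thresholds: (mu1, log(mu2-mu1), log(mu3-mu2))
thr_pack <- function(mu) c(mu[1L], log(diff(mu)))
## tiny floor keeps cuts strictly increasing even when a line-search
## step drives a log-increment far negative
thr_unpack <- function(v) cumsum(c(v[1L], exp(v[2L]) + 1e-9,
                                   exp(v[3L]) + 1e-9))

## correlation matrix via spherical Cholesky angles in (0, pi);
## gamma = 0 gives R = I
corr_from_gamma <- function(g) {
  ## angles bounded away from 0/pi keep R safely positive definite for
  ## any gamma the optimizer proposes (|r| <= cos(0.01 pi) ~ 0.9995)
  a <- pi * (0.01 + 0.98 * stats::plogis(g))
  L <- rbind(c(1, 0, 0),
             c(cos(a[1L]), sin(a[1L]), 0),
             c(cos(a[2L]), sin(a[2L]) * cos(a[3L]), sin(a[2L]) * sin(a[3L])))
  R <- L %*% t(L)
  diag(R) <- 1
  R
}

gamma_from_corr <- function(R) {
  a1 <- acos(min(max(R[1L, 2L], -1 + 1e-9), 1 - 1e-9))
  a2 <- acos(min(max(R[1L, 3L], -1 + 1e-9), 1 - 1e-9))
  c3 <- (R[2L, 3L] - cos(a1) * cos(a2)) / (sin(a1) * sin(a2))
  a3 <- acos(min(max(c3, -1 + 1e-9), 1 - 1e-9))
  f <- pmin(pmax((c(a1, a2, a3) / pi - 0.01) / 0.98, 1e-6), 1 - 1e-6)
  stats::qlogis(f)
}

## d(r12, r13, r23) / d gamma, 3x3, by central differences of the map
corr_gamma_jacobian <- function(g, eps = 1e-6) {
  J <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    gp <- gm <- g
    gp[j] <- gp[j] + eps; gm[j] <- gm[j] - eps
    Rp <- corr_from_gamma(gp); Rm <- corr_from_gamma(gm)
    J[, j] <- c(Rp[1L, 2L] - Rm[1L, 2L], Rp[1L, 3L] - Rm[1L, 3L],
                Rp[2L, 3L] - Rm[2L, 3L]) / (2 * eps)
  }
  J
}

## packed parameter vector: for each mode (coefs_j, mu1, log d2, log d3),
## then gamma (3)
freq_pack_info <- function(included) {
  p <- vapply(included, length, 1L)
  offs <- cumsum(c(0L, (p + 3L)[-3L]))
  list(p = p, offsets = offs, npar = sum(p + 3L) + 3L)
}

freq_unpack <- function(par, included) {
  info <- freq_pack_info(included)
  modes <- cpm_modes()
  coefs <- thresholds <- list()
  for (i in 1:3) {
    o <- info$offsets[i]; pj <- info$p[i]
    b <- par[o + seq_len(pj)]
    names(b) <- included[[i]]
    coefs[[modes[i]]] <- b
    thresholds[[modes[i]]] <- thr_unpack(par[o + pj + 1:3])
  }
  g <- par[info$npar - 2:0]
  list(coefs = coefs, thresholds = thresholds, corr = corr_from_gamma(g),
       gamma = g)
}

## negative loglik and per-person score matrix on packed parameters
freq_ll_core <- function(par, D, classes, included, nodes, scores = FALSE) {
  pr <- freq_unpack(par, included)
  eta <- freq_eta(D, pr$coefs)
  b <- freq_bounds(eta, classes, pr$thresholds)
  if (!scores) {
    p <- pmvn3_rect(b$lower, b$upper, pr$corr, nodes = nodes)
    return(sum(log(pmax(p, 1e-300))))
  }
  g <- pmvn3_rect_grad(b$lower, b$upper, pr$corr, nodes = nodes)
  p <- pmax(g$p, 1e-300)
  n <- nrow(D)
  info <- freq_pack_info(included)
  S <- matrix(0, n, info$npar)
  modes <- cpm_modes()
  for (i in 1:3) {
    o <- info$offsets[i]; pj <- info$p[i]
    dl <- g$dlower[, i] / p
    du <- g$dupper[, i] / p
    if (pj > 0L)
      S[, o + seq_len(pj)] <- -(dl + du) *
        D[, included[[i]], drop = FALSE]
    ## thresholds: person in class o uses mu_o as lower (o >= 1) and
    ## mu_{o+1} as upper (o <= 2)
    tpar <- par[o + pj + 1:3]
    mu <- thr_unpack(tpar)
    dmu <- matrix(0, n, 3L)
    oi <- classes[, i]
    for (k in 1:3) dmu[, k] <- dl * (oi == k) + du * (oi + 1L == k)
    ## chain to (mu1, log d2, log d3)
    S[, o + pj + 1L] <- rowSums(dmu)
    S[, o + pj + 2L] <- (dmu[, 2L] + dmu[, 3L]) * exp(tpar[2L])
    S[, o + pj + 3L] <- dmu[, 3L] * exp(tpar[3L])
  }
  J <- corr_gamma_jacobian(pr$gamma)
  S[, info$npar - 2:0] <- (g$dr / p) %*% J
  ll <- sum(log(p))
  attr(ll, "scores") <- S
  ll
}

#' Fit the trivariate ordered probit frequency model
#'
#' Simultaneous maximum likelihood over per-mode coefficients,
#' thresholds (reparameterized as first cut plus positive increments)
#' and the error correlation matrix (spherical-Cholesky
#' parameterization, always positive definite), using the exact
#' rectangle likelihood with analytic gradients under a BHHH
#' (outer-product Fisher scoring) maximizer. Starting values come
#' from independent univariate ordered probit fits (`MASS::polr`) and a
#' residual-score estimate of `R`. Standard errors are outer-product-
#' of-gradients at the optimum; correlation and threshold standard
#' errors are delta-method transforms.
#'
#' @param persons A [cpm_persons()] table; every class must be observed
#'   at least once for every mode.
#' @param schema A [covariate_schema()].
#' @param exclude Named list (per mode) of design columns structurally
#'   excluded from that mode's model, in the spirit of coefficient
#'   tables that print "-" for variables dropped from one equation.
#' @param scaler Optional pre-fitted [fit_scaler()].
#' @param nodes Quadrature order for the exact likelihood during
#'   optimization.
#' @param control List with `maxit` and/or `reltol` for the maximizer.
#' @return Object of class `cpm_fit`; `params` is an
#'   [ordered_probit_params()], `std_errors` covers coefficients,
#'   thresholds and the three correlations.
#' @export
fit_frequency <- function(persons, schema, exclude = list(), scaler = NULL,
                          nodes = 16L, control = list()) {
  modes <- cpm_modes()
  classes <- person_classes(persons)
  for (i in 1:3) {
    tab <- tabulate(classes[, i] + 1L, 4L)
    if (any(tab == 0L))
      stop("mode '", modes[i], "' has no persons in class '",
           freq_class_labels()[which(tab == 0L)[1L]], "'", call. = FALSE)
  }
  if (is.null(scaler)) scaler <- fit_scaler(cbind(persons$x, persons$y))
  D <- table_design(persons, schema, scaler)
  all_cols <- colnames(D)
  included <- lapply(modes, function(m) setdiff(all_cols, exclude[[m]]))
  names(included) <- modes
  ## per-mode rank check and univariate starting fits
  par0 <- numeric(0)
  ebar <- matrix(0, nrow(D), 3L)
  for (i in 1:3) {
    cols <- included[[i]]
    Dm <- D[, cols, drop = FALSE]
    if (length(cols)) {
      qrD <- qr(cbind(1, Dm))
      if (qrD$rank < ncol(Dm) + 1L)
        stop("rank-deficient design for mode '", modes[i], "'",
             call. = FALSE)
    }
    st <- freq_uni_start(Dm, classes[, i])
    par0 <- c(par0, st$b, thr_pack(st$mu))
    ## truncated-normal mean of the latent error, for the R start
    l <- c(-Inf, st$mu, Inf)[classes[, i] + 1L] - st$eta
    u <- c(-Inf, st$mu, Inf)[classes[, i] + 2L] - st$eta
    pint <- pmax(stats::pnorm(u) - stats::pnorm(l), 1e-12)
    ebar[, i] <- (stats::dnorm(l) - stats::dnorm(u)) / pint
  }
  R0 <- stats::cor(ebar)
  ## attenuation: scores have variance < 1; rescale toward a proper start
  R0 <- R0 * 0.9
  diag(R0) <- 1
  par0 <- c(par0, gamma_from_corr(R0))
  fscore <- function(par) {
    ll <- freq_ll_core(par, D, classes, included, nodes, scores = TRUE)
    out <- sum(ll)
    attr(out, "scores") <- attr(ll, "scores")
    out
  }
  ctl <- utils::modifyList(list(maxit = 150L, reltol = 1e-10), control)
  opt <- maximize_bhhh(par0, fscore, maxit = ctl$maxit, reltol = ctl$reltol)
  pr <- freq_unpack(opt$par, included)
  params <- ordered_probit_params(pr$coefs, pr$thresholds, pr$corr, schema,
                                  scaler)
  ## thresholds-only benchmark
  inc0 <- list(walk = character(0), car = character(0),
               transit = character(0))
  st0 <- numeric(0)
  for (i in 1:3) st0 <- c(st0, thr_pack(freq_uni_start(
    D[, 0, drop = FALSE], classes[, i])$mu))
  st0 <- c(st0, 0, 0, 0)
  opt0 <- maximize_bhhh(st0, function(q) {
    l0 <- freq_ll_core(q, D, classes, inc0, nodes, scores = TRUE)
    out <- sum(l0)
    attr(out, "scores") <- attr(l0, "scores")
    out
  }, maxit = 100L)
  k <- length(opt$par)
  se <- freq_se(opt$scores, opt$par, included)
  structure(list(params = params, loglik = opt$loglik,
                 loglik_null = opt0$loglik,
                 mcfadden_adj_rho2 = 1 - (opt$loglik - k) / opt0$loglik,
                 n_obs = nrow(D), std_errors = se,
                 converged = opt$converged, model = "mvoprobit"),
            class = "cpm_fit")
}

## univariate ordered probit start: polr when it cooperates, otherwise
## zero coefficients with empirical-frequency thresholds
freq_uni_start <- function(Dm, cl) {
  y <- factor(cl, levels = 0:3, ordered = TRUE)
  mu_emp <- stats::qnorm(cumsum(tabulate(cl + 1L, 4L) / length(cl))[1:3])
  mu_emp <- cummax(mu_emp + c(0, 1e-6, 2e-6))
  if (ncol(Dm) == 0L)
    return(list(b = numeric(0), mu = mu_emp, eta = rep(0, length(cl))))
  st <- tryCatch({
    df <- data.frame(.y = y, Dm, check.names = FALSE)
    fit <- MASS::polr(.y ~ ., data = df, method = "probit")
    list(b = unname(coef(fit)), mu = unname(fit$zeta),
         eta = drop(Dm %*% coef(fit)))
  }, error = function(e) NULL)
  if (is.null(st) || any(diff(st$mu) <= 0))
    st <- list(b = numeric(ncol(Dm)), mu = mu_emp, eta = rep(0, length(cl)))
  st
}

freq_se <- function(S, par, included) {
  V <- tryCatch(solve(crossprod(S)), error = function(e) {
    warning("singular information matrix; standard errors unavailable")
    matrix(NA_real_, ncol(S), ncol(S))
  })
  info <- freq_pack_info(included)
  modes <- cpm_modes()
  se <- numeric(0)
  for (i in 1:3) {
    o <- info$offsets[i]; pj <- info$p[i]
    if (pj > 0L) {
      s <- sqrt(pmax(diag(V)[o + seq_len(pj)], 0))
      names(s) <- paste0(modes[i], ".", included[[i]])
      se <- c(se, s)
    }
    ## delta method for (mu1, mu2, mu3) from (mu1, log d2, log d3)
    tpar <- par[o + pj + 1:3]
    Jt <- rbind(c(1, 0, 0),
                c(1, exp(tpar[2L]), 0),
                c(1, exp(tpar[2L]), exp(tpar[3L])))
    Vt <- Jt %*% V[o + pj + 1:3, o + pj + 1:3] %*% t(Jt)
    s <- sqrt(pmax(diag(Vt), 0))
    names(s) <- paste0(modes[i], ".threshold", 1:3)
    se <- c(se, s)
  }
  g <- par[info$npar - 2:0]
  Jr <- corr_gamma_jacobian(g)
  Vr <- Jr %*% V[info$npar - 2:0, info$npar - 2:0] %*% t(Jr)
  s <- sqrt(pmax(diag(Vr), 0))
  names(s) <- c("corr.walk.car", "corr.walk.transit", "corr.car.transit")
  c(se, s)
}
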