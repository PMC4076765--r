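## Joint discrete-continuous model of mode choice and trip distance.
##
## The discrete part is a multinomial logit (MNL) over walk/car/transit;
## the continuous part is a log-normal model of trip distance given the
## chosen mode. The two are coupled through a Gaussian copula on the
## standard-normal transforms of each margin: with
##   u  = (ln d - theta_m' x) / sigma_m        (log-distance score)
##   J1 = qnorm(P_m)                           (selection score)
## the contribution of a trip with chosen mode m and distance d is
##   (1 / (sigma_m d)) phi(u) * Phi((J1 - rho_m u) / sqrt(1 - rho_m^2)),
## so rho_m captures selectivity: unobservables that make a mode more
## attractive also shift the distances travelled by it. At rho = 0 the
## likelihood factorizes into the MNL log-probability plus the
## log-normal density.

#' Parameters of the joint mode-choice / trip-distance model
#'
#' @param utility_coefs Named list (one element per mode) of named MNL
#'   utility coefficient vectors over `(Intercept)`, covariate design
#'   columns and trend terms. The reference mode's vector must be all
#'   zeros.
#' @param distance_coefs Named list per mode of log-distance coefficient
#'   vectors (same columns); distances are in metres, so the linear
#'   predictor is the mean of `ln(distance_m)`.
#' @param sigma Named numeric per mode, log-distance scale(s), > 0.
#' @param rho Named numeric per mode, discrete-continuous error
#'   correlation(s) in (-1, 1).
#' @param schema A [covariate_schema()].
#' @param scaler A [fit_scaler()] result.
#' @param reference_mode Mode whose utility is normalized to zero
#'   (default `"car"`, the most frequent mode).
#' @return Object of class `joint_model_params`.
#' @export
joint_model_params <- function(utility_coefs, distance_coefs, sigma, rho,
                               schema, scaler, reference_mode = "car") {
  modes <- cpm_modes()
  stopifnot(reference_mode %in% modes,
            setequal(names(utility_coefs), modes),
            setequal(names(distance_coefs), modes))
  sigma <- rep_len(as.numeric(sigma), 3L); names(sigma) <- modes
  rho <- rep_len(as.numeric(rho), 3L); names(rho) <- modes
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(abs(rho) >= 1)) stop("rho must lie in (-1, 1)", call. = FALSE)
  if (any(utility_coefs[[reference_mode]] != 0))
    stop("reference mode utility coefficients must all be zero",
         call. = FALSE)
  p <- length(distance_coefs[[1L]])
  if (!all(vapply(utility_coefs, length, 1L) == p) ||
      !all(vapply(distance_coefs, length, 1L) == p))
    stop("coefficient vectors must share one length", call. = FALSE)
  validate_scaler(scaler)
  structure(list(utility_coefs = utility_coefs,
                 distance_coefs = distance_coefs,
                 sigma = sigma, rho = rho, schema = schema, scaler = scaler,
                 reference_mode = reference_mode),
            class = "joint_model_params")
}

joint_design_names <- function(schema) c("(Intercept)", schema$design_names,
                                         trend_names())

#' Multinomial logit mode probabilities
#'
#' Softmax of the linear utilities; the reference mode's utility is zero
#' by normalization. Numerically safeguarded by max-subtraction, so
#' extreme utilities never yield NaN.
#'
#' @param design Numeric design vector (or matrix, one row per
#'   observation) matching the coefficient vectors of `params`.
#' @param params A [joint_model_params()].
#' @return Named probability vector over modes (or matrix), strictly
#'   positive, summing to 1.
#' @export
mnl_probabilities <- function(design, params) {
  X <- if (is.matrix(design)) design else matrix(design, 1L)
  B <- matrix(unlist(params$utility_coefs[cpm_modes()]), ncol(X), 3L)
  eta <- X %*% B
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  P <- ex / rowSums(ex)
  colnames(P) <- cpm_modes()
  if (!is.matrix(design)) P[1L, ] else P
}

## Core likelihood/score evaluation on prebuilt design matrix.
## par packing: [beta_j for non-ref modes] [theta_m, all modes]
##              [lnsigma (1 or 3)] [atanh rho (1 or 3)]
joint_pack_dim <- function(p, pooled) 2L * p + 3L * p + 2L * (if (pooled) 1L else 3L)

joint_unpack <- function(par, p, pooled, reference_mode) {
  modes <- cpm_modes()
  nonref <- setdiff(modes, reference_mode)
  beta <- list()
  beta[[reference_mode]] <- numeric(p)
  beta[[nonref[1L]]] <- par[1:p]
  beta[[nonref[2L]]] <- par[(p + 1L):(2L * p)]
  theta <- list()
  for (i in 1:3) theta[[modes[i]]] <- par[(2L * p + (i - 1L) * p + 1L):(2L * p + i * p)]
  off <- 5L * p
  if (pooled) {
    lnsig <- rep(par[off + 1L], 3L)
    arho <- rep(par[off + 2L], 3L)
  } else {
    lnsig <- par[off + 1:3]
    arho <- par[off + 4:6]
  }
  names(lnsig) <- names(arho) <- modes
  list(beta = beta[modes], theta = theta, sigma = exp(lnsig),
       rho = tanh(arho))
}

## Per-trip loglik and (optionally) per-trip score matrix in packed order.
joint_ll_core <- function(par, X, mode_idx, lnd, pooled, reference_mode,
                          scores = FALSE) {
  p <- ncol(X)
  n <- nrow(X)
  modes <- cpm_modes()
  pr <- joint_unpack(par, p, pooled, reference_mode)
  B <- matrix(unlist(pr$beta[modes]), p, 3L)
  TH <- matrix(unlist(pr$theta[modes]), p, 3L)
  eta <- X %*% B
  eta <- eta - pmax(eta[, 1L], eta[, 2L], eta[, 3L])
  ex <- exp(eta)
  P <- ex / (ex[, 1L] + ex[, 2L] + ex[, 3L])
  Pm <- clamp_prob(P[cbind(seq_len(n), mode_idx)])
  sig <- pr$sigma[mode_idx]
  rho <- pr$rho[mode_idx]
  MU <- X %*% TH
  u <- (lnd - MU[cbind(seq_len(n), mode_idx)]) / sig
  J1 <- stats::qnorm(Pm)
  s <- sqrt(1 - rho^2)
  A <- (J1 - rho * u) / s
  ll <- -log(sig) - lnd - 0.5 * log(2 * pi) - u^2 / 2
  ll <- ll + if (all(rho == 0)) log(Pm) else stats::pnorm(A, log.p = TRUE)
  if (!scores) return(ll)
  lam <- mills(A)
  S <- matrix(0, n, length(par))
  nonref <- setdiff(modes, reference_mode)
  ## utility coefficients: d ll / d eta_j = (lam / (s * phi(J1))) * dPm/deta_j
  wJ <- lam / (s * stats::dnorm(J1))
  for (i in seq_along(nonref)) {
    j <- match(nonref[i], modes)
    delta <- as.numeric(mode_idx == j)
    wj <- wJ * Pm * (delta - P[, j])
    S[, ((i - 1L) * p + 1L):(i * p)] <- wj * X
  }
  ## distance coefficients (chosen mode only)
  wt <- (u + lam * rho / s) / sig
  for (i in 1:3) {
    sel <- mode_idx == i
    cols <- (2L * p + (i - 1L) * p + 1L):(2L * p + i * p)
    S[sel, cols] <- wt[sel] * X[sel, , drop = FALSE]
  }
  ## ln sigma and atanh rho
  dlns <- -1 + u^2 + lam * rho * u / s
  dr <- lam * (-u / s + rho * A / s^2) * (1 - rho^2)
  off <- 5L * p
  if (pooled) {
    S[, off + 1L] <- dlns
    S[, off + 2L] <- dr
  } else {
    for (i in 1:3) {
      sel <- mode_idx == i
      S[sel, off + i] <- dlns[sel]
      S[sel, off + 3L + i] <- dr[sel]
    }
  }
  attr(ll, "scores") <- S
  ll
}

#' Joint model log-likelihood of a trip table
#'
#' Sum over trips of the log of the joint mode-and-distance density (see
#' the package vignette for the form). With all `rho = 0` this equals
#' the MNL log-likelihood plus the log-normal log-density exactly.
#'
#' @param trips A [cpm_trips()] table (all distances positive).
#' @param params A [joint_model_params()].
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(trips, params) {
  schema <- params$schema
  X <- cbind(`(Intercept)` = 1, table_design(trips, schema, params$scaler))
  mode_idx <- match(trips$mode, cpm_modes())
  p <- ncol(X)
  par <- joint_pack_params(params)
  sum(joint_ll_core(par, X, mode_idx, log(as.numeric(trips$distance_m)),
                    pooled = FALSE, reference_mode = params$reference_mode))
}

joint_pack_params <- function(params) {
  modes <- cpm_modes()
  nonref <- setdiff(modes, params$reference_mode)
  c(unlist(params$utility_coefs[nonref], use.names = FALSE),
    unlist(params$distance_coefs[modes], use.names = FALSE),
    log(params$sigma), atanh(params$rho))
}

#' Predict expected trip distance
#'
#' Expected distance for one covariate profile at one location,
#' `exp(theta_m' x + sigma_m^2 / 2)` (log-normal mean). Set `type =
#' "median"` for `exp(theta_m' x)`.
#'
#' @param design Encoded covariate vector ([encode_covariates()]).
#' @param trend Trend-surface terms ([trend_terms()]).
#' @param params A [joint_model_params()].
#' @param mode Mode whose distance to predict.
#' @param type `"mean"` (default) or `"median"`.
#' @return Positive scalar, metres.
#' @export
predict_distance <- function(design, trend, params, mode,
                             type = c("mean", "median")) {
  type <- match.arg(type)
  stopifnot(mode %in% cpm_modes())
  x <- c(1, design, trend)
  th <- params$distance_coefs[[mode]]
  stopifnot(length(x) == length(th))
  eta <- sum(th * x)
  if (type == "mean") exp(eta + params$sigma[[mode]]^2 / 2) else exp(eta)
}

#' Fit the joint mode-choice / trip-distance model
#'
#' Maximum likelihood on an unconstrained parameterization (`log sigma`,
#' `atanh rho`). Starting values come from an independent MNL fit
#' (`nnet::multinom`) and per-mode least squares on log distance with
#' `rho = 0`; the full likelihood is then maximized by BHHH
#' (outer-product Fisher scoring) with analytic per-trip scores.
#' Standard errors are computed from the outer product of scores at
#' the optimum.
#'
#' @param trips A [cpm_trips()] table.
#' @param schema A [covariate_schema()] (must match the table).
#' @param reference_mode Reference mode for the MNL utilities (default
#'   car).
#' @param pooled If `TRUE` (default) a single `sigma` and a single `rho`
#'   are shared by all modes; otherwise each mode gets its own.
#' @param scaler Optional pre-fitted [fit_scaler()]; by default fitted
#'   on the trip table's home coordinates.
#' @param control List with `maxit` and/or `reltol` for the maximizer.
#' @return Object of class `cpm_fit` with elements `params`
#'   ([joint_model_params()]), `loglik`, `loglik_null`,
#'   `mcfadden_adj_rho2`, `n_obs`, `std_errors`, `converged`.
#' @export
fit_joint <- function(trips, schema, reference_mode = "car", pooled = TRUE,
                      scaler = NULL, control = list()) {
  modes <- cpm_modes()
  stopifnot(reference_mode %in% modes)
  tab <- table(factor(trips$mode, levels = modes))
  if (any(tab == 0L))
    stop("no trips observed for mode(s): ",
         paste(names(tab)[tab == 0L], collapse = ", "), call. = FALSE)
  if (is.null(scaler)) scaler <- fit_scaler(cbind(trips$x, trips$y))
  X <- cbind(`(Intercept)` = 1, table_design(trips, schema, scaler))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mode_idx <- match(trips$mode, modes)
  lnd <- log(as.numeric(trips$distance_m))
  fit <- joint_fit_core(X, mode_idx, lnd, pooled, reference_mode, control)
  ## constants-only benchmark for McFadden's adjusted rho-squared
  X0 <- X[, 1L, drop = FALSE]
  fit0 <- joint_fit_core(X0, mode_idx, lnd, pooled, reference_mode,
                         control = list(maxit = 300L))
  p <- ncol(X)
  cn <- colnames(X)
  pr <- joint_unpack(fit$par, p, pooled, reference_mode)
  for (m in modes) {
    names(pr$beta[[m]]) <- cn
    names(pr$theta[[m]]) <- cn
  }
  params <- joint_model_params(pr$beta, pr$theta, pr$sigma, pr$rho, schema,
                               scaler, reference_mode)
  k <- length(fit$par)
  se <- joint_se(fit, p, pooled, reference_mode, cn)
  structure(list(params = params,
                 loglik = fit$loglik, loglik_null = fit0$loglik,
                 mcfadden_adj_rho2 = 1 - (fit$loglik - k) / fit0$loglik,
                 n_obs = nrow(X), std_errors = se,
                 converged = fit$converged, model = "joint_distance"),
            class = "cpm_fit")
}

joint_fit_core <- function(X, mode_idx, lnd, pooled, reference_mode, control) {
  modes <- cpm_modes()
  p <- ncol(X)
  n <- nrow(X)
  ## starting values: independent MNL + per-mode OLS, rho = 0
  if (p > 1L) {
    mf <- factor(modes[mode_idx], levels = c(reference_mode,
                                             setdiff(modes, reference_mode)))
    cap <- utils::capture.output(
      mnl0 <- nnet::multinom(mf ~ X - 1, maxit = 300L, trace = FALSE,
                             MaxNWts = 5000L))
    Bst <- coef(mnl0)  # rows: non-reference levels in factor order
    nonref <- setdiff(modes, reference_mode)
    beta_start <- c(Bst[1L, ], Bst[2L, ])
  } else {
    sh <- tabulate(mode_idx, 3L) / n
    nonref <- setdiff(modes, reference_mode)
    beta_start <- log(sh[match(nonref, modes)] /
                        sh[match(reference_mode, modes)])
  }
  theta_start <- numeric(0)
  resv <- numeric(0)
  for (i in 1:3) {
    sel <- mode_idx == i
    f <- stats::lm.fit(X[sel, , drop = FALSE], lnd[sel])
    theta_start <- c(theta_start, f$coefficients)
    resv <- c(resv, f$residuals)
  }
  s0 <- stats::sd(resv)
  par0 <- c(beta_start, theta_start,
            rep(log(s0), if (pooled) 1L else 3L),
            rep(0, if (pooled) 1L else 3L))
  fscore <- function(par) {
    ll <- joint_ll_core(par, X, mode_idx, lnd, pooled, reference_mode,
                        scores = TRUE)
    out <- sum(ll)
    attr(out, "scores") <- attr(ll, "scores")
    out
  }
  ctl <- utils::modifyList(list(maxit = 200L, reltol = 1e-10), control)
  opt <- maximize_bhhh(par0, fscore, maxit = ctl$maxit,
                       reltol = ctl$reltol)
  list(par = opt$par, loglik = opt$loglik, scores = opt$scores,
       converged = opt$converged)
}

## OPG standard errors mapped to the natural scale, with names.
joint_se <- function(fit, p, pooled, reference_mode, cn) {
  S <- fit$scores
  V <- tryCatch(solve(crossprod(S)), error = function(e) {
    warning("singular information matrix; standard errors unavailable")
    matrix(NA_real_, ncol(S), ncol(S))
  })
  se <- sqrt(pmax(diag(V), 0))
  pr <- joint_unpack(fit$par, p, pooled, reference_mode)
  modes <- cpm_modes()
  nonref <- setdiff(modes, reference_mode)
  nm <- c(paste0("utility.", rep(nonref, each = p), ".", cn),
          paste0("distance.", rep(modes, each = p), ".", cn))
  off <- 5L * p
  if (pooled) {
    se[off + 1L] <- se[off + 1L] * pr$sigma[1L]            # delta: sigma
    se[off + 2L] <- se[off + 2L] * (1 - pr$rho[1L]^2)      # delta: rho
    nm <- c(nm, "sigma", "rho")
  } else {
    se[off + 1:3] <- se[off + 1:3] * pr$sigma
    se[off + 4:6] <- se[off + 4:6] * (1 - pr$rho^2)
    nm <- c(nm, paste0("sigma.", modes), paste0("rho.", modes))
  }
  names(se) <- nm
  se
}

#' Score test for selectivity in the joint model
#'
#' Lagrange-multiplier (score) test of `rho = 0`: no correlation between
#' the mode-choice and log-distance errors. The restricted maximum
#' likelihood at `rho = 0` separates into an ordinary MNL fit and
#' per-mode least squares on log distance; the test evaluates the full
#' joint score there, so `rho` itself is never estimated. This is the
#' appropriate significance test for the selectivity correlation: with
#' no exclusion restrictions `rho` is identified only through the
#' nonlinearity of the selection correction, the likelihood is nearly
#' flat in `rho`, and Wald tests based on the curvature at `rho`-hat
#' badly over-reject.
#'
#' @param trips A [cpm_trips()] table.
#' @param schema A [covariate_schema()].
#' @param reference_mode Reference mode for the MNL utilities.
#' @param scaler Optional pre-fitted [fit_scaler()].
#' @return List with `statistic` (chi-squared, 1 df), `df`, `p.value`.
#' @export
selectivity_score_test <- function(trips, schema, reference_mode = "car",
                                   scaler = NULL) {
  modes <- cpm_modes()
  if (is.null(scaler)) scaler <- fit_scaler(cbind(trips$x, trips$y))
  X <- cbind(`(Intercept)` = 1, table_design(trips, schema, scaler))
  mode_idx <- match(trips$mode, modes)
  lnd <- log(as.numeric(trips$distance_m))
  mf <- factor(modes[mode_idx], levels = c(reference_mode,
                                           setdiff(modes, reference_mode)))
  mnl0 <- nnet::multinom(mf ~ X - 1, maxit = 1000L, trace = FALSE,
                         MaxNWts = 5000L, reltol = 1e-12)
  B <- coef(mnl0)
  theta <- numeric(0)
  rss <- 0
  for (i in 1:3) {
    sel <- mode_idx == i
    f <- stats::lm.fit(X[sel, , drop = FALSE], lnd[sel])
    theta <- c(theta, f$coefficients)
    rss <- rss + sum(f$residuals^2)
  }
  par0 <- c(B[1L, ], B[2L, ], theta, log(sqrt(rss / length(lnd))), 0)
  ll <- joint_ll_core(par0, X, mode_idx, lnd, pooled = TRUE,
                      reference_mode = reference_mode, scores = TRUE)
  S <- attr(ll, "scores")
  g <- colSums(S)
  stat <- drop(t(g) %*% solve(crossprod(S), g))
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("<cpm_fit> ", x$model, "\n  n = ", x$n_obs,
      ", logLik = ", format(x$loglik, digits = 8),
      " (null ", format(x$loglik_null, digits = 8), ")",
      "\n  McFadden adj rho^2 = ", format(x$mcfadden_adj_rho2, digits = 4),
      ", converged: ", x$converged, "\n", sep = "")
  invisible(x)
}
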