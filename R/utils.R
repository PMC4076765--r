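#' @keywords internal
#' @useDynLib cpmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Transport modes handled throughout the package, in canonical order.
#' Canonical transport modes
#'
#' The three modes the models distinguish, in the fixed order used for
#' coefficient tables and correlation matrices.
#'
#' @return Character vector `c("walk", "car", "transit")`.
#' @export
cpm_modes <- function() c("walk", "car", "transit")

## Frequency classes for the ordered trip-count models.
freq_class_labels <- function() c("0", "1", "2", "3+")

.cpm_env <- new.env(parent = emptyenv())

## Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
## construction; cached per order.
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.cpm_env[[key]])) return(.cpm_env[[key]])
  if (n == 1L) {
    gl <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    gl <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  }
  .cpm_env[[key]] <- gl
  gl
}

## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## RNG state afterwards. All package randomness is routed through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Clamp probabilities away from 0/1 before qnorm.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

## inverse-Mills-type ratio phi(x)/Phi(x), numerically stable in the left tail
mills <- function(x) exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))

`%||%` <- function(a, b) if (is.null(a)) b else a

## BHHH (Berndt-Hall-Hall-Hausman) maximizer: Fisher scoring with the
## outer product of per-observation scores as the information matrix,
## with Armijo backtracking. `fn` returns the scalar loglik with the
## n x p score matrix in attribute "scores". The standard choice for
## simulated / discrete-choice likelihoods: near the optimum of a
## correctly specified model OPG ~ observed information, giving
## near-quadratic convergence from consistent starting values.
maximize_bhhh <- function(par, fn, maxit = 100L, reltol = 1e-10,
                          gtol = 1e-5) {
  ll <- fn(par)
  evals <- 1L
  conv <- FALSE
  for (it in seq_len(maxit)) {
    S <- attr(ll, "scores")
    g <- colSums(S)
    H <- crossprod(S)
    d <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), ncol(H)), g),
                  error = function(e) g / max(abs(g)))
    step <- 1
    ok <- FALSE
    for (half in 1:25) {
      cand <- par + step * d
      llc <- tryCatch(fn(cand), error = function(e) -Inf)
      evals <- evals + 1L
      if (is.finite(llc) && llc > ll - 1e-12) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    improved <- llc - ll
    par <- cand
    ll <- llc
    if (improved < reltol * (abs(ll) + reltol) &&
        max(abs(colSums(attr(ll, "scores")))) / nrow(S) < gtol) {
      conv <- TRUE
      break
    }
  }
  list(par = par, loglik = as.numeric(ll), scores = attr(ll, "scores"),
       converged = conv || max(abs(colSums(attr(ll, "scores")))) /
         nrow(attr(ll, "scores")) < gtol,
       iterations = it, evals = evals)
}
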