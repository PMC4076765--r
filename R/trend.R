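## Trend-surface block: quadratic polynomial in standardized home
## coordinates plus straight-line distance to the central business
## district (CBD) in km. The block enters both behavioral models and
## drives spatial prediction on grids.

trend_names <- function() c("trend_x", "trend_y", "trend_xy",
                            "trend_x2", "trend_y2", "cbd_km")

#' Fit a coordinate scaler
#'
#' Computes the per-axis mean and standard deviation of the estimation
#' sample's home coordinates. Coordinates are standardized (z-scored)
#' before polynomial expansion: raw projected metres raised to the second
#' power would produce a catastrophically ill-conditioned design. The
#' scaler is serialized with every fitted model so grid prediction uses
#' the estimation-sample standardization.
#'
#' @param points Two-column matrix (or data.frame) of planar coordinates,
#'   map units (metres).
#' @return Object of class `cpm_scaler` with `center` and `scale`
#'   (length-2 numeric vectors; population standard deviation per axis,
#'   with an axis of zero spread left unscaled).
#' @export
fit_scaler <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L)
  if (nrow(unique(pts)) < 2L)
    stop("degenerate coordinate sample: need >= 2 distinct points",
         call. = FALSE)
  ctr <- colMeans(pts)
  scl <- sqrt(colMeans(sweep(pts, 2L, ctr)^2))
  scl[scl == 0] <- 1  # flat axis: center only
  structure(list(center = as.numeric(ctr), scale = as.numeric(scl)),
            class = "cpm_scaler")
}

validate_scaler <- function(scaler) {
  if (!is.list(scaler) || length(scaler$center) != 2L ||
      length(scaler$scale) != 2L || any(!is.finite(unlist(scaler[c("center", "scale")]))) ||
      any(scaler$scale <= 0))
    stop("invalid coordinate scaler", call. = FALSE)
  invisible(scaler)
}

#' Trend-surface terms at a location
#'
#' Returns the six-term spatial predictor block: scaled coordinates, their
#' product and squares, and Euclidean distance to the CBD in km.
#'
#' @param xy Length-2 coordinate pair, map units.
#' @param scaler A [fit_scaler()] result.
#' @param cbd_xy Length-2 CBD coordinate pair, map units.
#' @return Named numeric vector `(trend_x, trend_y, trend_xy, trend_x2,
#'   trend_y2, cbd_km)`.
#' @export
trend_terms <- function(xy, scaler, cbd_xy) {
  validate_scaler(scaler)
  stopifnot(length(xy) == 2L, length(cbd_xy) == 2L)
  drop(trend_terms_matrix(matrix(as.numeric(xy), 1L), scaler, cbd_xy = cbd_xy))
}

## Vectorized trend block. Either cbd_xy (distance computed) or cbd_km
## (precomputed, e.g. survey-supplied) must be given.
trend_terms_matrix <- function(xy, scaler, cbd_xy = NULL, cbd_km = NULL) {
  validate_scaler(scaler)
  xy <- as.matrix(xy)
  sx <- (xy[, 1L] - scaler$center[1L]) / scaler$scale[1L]
  sy <- (xy[, 2L] - scaler$center[2L]) / scaler$scale[2L]
  if (is.null(cbd_km)) {
    stopifnot(length(cbd_xy) == 2L)
    cbd_km <- sqrt((xy[, 1L] - cbd_xy[1L])^2 + (xy[, 2L] - cbd_xy[2L])^2) / 1000
  }
  out <- cbind(sx, sy, sx * sy, sx^2, sy^2, as.numeric(cbd_km))
  colnames(out) <- trend_names()
  out
}

scaler_to_list <- function(scaler) list(center = scaler$center,
                                        scale = scaler$scale)

scaler_from_list <- function(x) {
  s <- structure(list(center = as.numeric(unlist(x$center)),
                      scale = as.numeric(unlist(x$scale))),
                 class = "cpm_scaler")
  validate_scaler(s)
  s
}
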