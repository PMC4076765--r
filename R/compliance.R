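## Compliance Potential Mapping: overlay predicted walking distance and
## walking-frequency probabilities into rasters of expected total daily
## walking distance (TDWD), weekly walking minutes (WWM) and percent of
## a physical-activity guideline.

#' Physical-activity guideline configuration
#'
#' Defaults encode a weekly guideline of 150 minutes, a senior walking
#' speed of 68.4 m/min, and travel behavior repeated over 5 days a week.
#'
#' @param weekly_minutes Guideline minutes per week (> 0).
#' @param walking_speed Walking speed in metres per minute (> 0).
#' @param days_per_week Days per week the daily behavior repeats (> 0).
#' @return Object of class `guideline_config`.
#' @export
guideline_config <- function(weekly_minutes = 150, walking_speed = 68.4,
                             days_per_week = 5L) {
  stopifnot(weekly_minutes > 0, walking_speed > 0, days_per_week > 0)
  structure(list(weekly_minutes = weekly_minutes,
                 walking_speed = walking_speed,
                 days_per_week = as.integer(days_per_week)),
            class = "guideline_config")
}

#' Prediction grid specification
#'
#' A regular square grid of cells superimposed on the study area for
#' prediction and visualization; the grid has no role in estimation.
#' `origin_xy` is the lower-left corner; cell centroids are used for
#' prediction.
#'
#' @param origin_xy Lower-left corner, map units.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cbd_xy CBD coordinates, map units.
#' @param cell_size Cell side length, map units (default 250).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(origin_xy, n_rows, n_cols, cbd_xy, cell_size = 250) {
  stopifnot(length(origin_xy) == 2L, length(cbd_xy) == 2L, cell_size > 0,
            n_rows >= 1L, n_cols >= 1L)
  structure(list(origin_xy = as.numeric(origin_xy),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cbd_xy = as.numeric(cbd_xy)),
            class = "grid_spec")
}

## centroids, row-major from the bottom row up; returns (n_rows*n_cols) x 2
cell_centroids <- function(grid) {
  cx <- grid$origin_xy[1L] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$origin_xy[2L] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  cbind(x = rep(cx, times = grid$n_rows), y = rep(cy, each = grid$n_cols))
}

#' Expected total daily walking distance
#'
#' `TDWD = d_hat * sum_k k * P(k)` over trip-frequency classes
#' `k = 1, 2, 3+`, with the open class valued at `k_cap` trips (default
#' 3, a conservative floor for "three or more"). The zero-trip class
#' contributes nothing.
#'
#' @param d_hat Predicted walking trip distance, metres (> 0).
#' @param probs Probability vector over classes `{0, 1, 2, 3+}`.
#' @param k_cap Trip count at which the open class is valued.
#' @return Expected metres walked per day.
#' @export
tdwd <- function(d_hat, probs, k_cap = 3) {
  stopifnot(d_hat > 0, k_cap > 0)
  if (length(probs) != 4L || any(probs < -1e-12) ||
      abs(sum(probs) - 1) > 1e-6)
    stop("probs must be 4 nonnegative values summing to 1", call. = FALSE)
  d_hat * sum(c(0, 1, 2, k_cap) * probs)
}

#' Weekly walking minutes
#'
#' Scales daily walking distance to a week and converts to minutes via
#' walking speed: `WWM = TDWD * days_per_week / walking_speed`.
#'
#' @param tdwd_m Expected daily walking distance, metres.
#' @param cfg A [guideline_config()].
#' @return Minutes of walking per week.
#' @export
wwm <- function(tdwd_m, cfg = guideline_config()) {
  stopifnot(tdwd_m >= 0)
  tdwd_m * cfg$days_per_week / cfg$walking_speed
}

#' Percent of guideline met by walking
#'
#' `100 * WWM / weekly_minutes`; deliberately not capped at 100.
#'
#' @param wwm_min Weekly walking minutes.
#' @param cfg A [guideline_config()].
#' @return Percent of the weekly guideline.
#' @export
compliance_percent <- function(wwm_min, cfg = guideline_config()) {
  stopifnot(wwm_min >= 0)
  100 * wwm_min / cfg$weekly_minutes
}

#' Weekly walking distance equivalent of the guideline
#'
#' The guideline expressed as km of walking per week:
#' `weekly_minutes * walking_speed / 1000`. At the defaults (150 min,
#' 68.4 m/min) this is 10.26 km.
#'
#' @param cfg A [guideline_config()].
#' @return Km per week.
#' @export
guideline_distance_km <- function(cfg = guideline_config()) {
  cfg$weekly_minutes * cfg$walking_speed / 1000
}

#' A fixed person archetype for mapping
#'
#' Validates a named covariate assignment against a schema; the profile
#' is held constant over the grid so the maps show purely spatial
#' variation for that kind of person.
#'
#' @param covariates Named list: level labels for categorical schema
#'   variables, numbers for continuous ones.
#' @param schema A [covariate_schema()].
#' @return Object of class `cpm_profile` with the encoded design vector
#'   attached.
#' @export
person_profile <- function(covariates, schema) {
  design <- encode_covariates(covariates, schema)
  structure(list(covariates = covariates, design = design, schema = schema),
            class = "cpm_profile")
}

#' Build a compliance-potential raster
#'
#' For every grid-cell centroid: compute trend-surface terms, predict the
#' profile's walking trip distance (joint model) and walking-frequency
#' class probabilities (ordered probit model), and chain them through
#' [tdwd()], [wwm()] and [compliance_percent()]. Only walking
#' contributes; car and transit predictions feed no layer.
#'
#' @param profile A [person_profile()].
#' @param dist_model A [joint_model_params()] (or `cpm_fit` thereof).
#' @param freq_model An [ordered_probit_params()] (or `cpm_fit`).
#' @param grid A [grid_spec()].
#' @param cfg A [guideline_config()].
#' @param k_cap Valuation of the open frequency class, as in [tdwd()].
#' @return Object of class `compliance_raster`: the grid plus layer
#'   matrices (`n_rows` x `n_cols`) `d_hat`, `p1`, `p2`, `p3plus`,
#'   `tdwd`, `wwm`, `compliance`.
#' @export
build_compliance_raster <- function(profile, dist_model, freq_model, grid,
                                    cfg = guideline_config(), k_cap = 3) {
  if (inherits(dist_model, "cpm_fit")) dist_model <- dist_model$params
  if (inherits(freq_model, "cpm_fit")) freq_model <- freq_model$params
  stopifnot(inherits(dist_model, "joint_model_params"),
            inherits(freq_model, "ordered_probit_params"),
            inherits(grid, "grid_spec"))
  if (!identical(profile$schema$design_names, dist_model$schema$design_names) ||
      !identical(profile$schema$design_names, freq_model$schema$design_names))
    stop("profile and models must share one covariate schema", call. = FALSE)
  xy <- cell_centroids(grid)
  n <- nrow(xy)
  ## distance prediction: exp(theta' x + sigma^2/2) at each centroid
  trd <- trend_terms_matrix(xy, dist_model$scaler, cbd_xy = grid$cbd_xy)
  xfull <- cbind(`(Intercept)` = rep(1, n),
                 matrix(profile$design, n, length(profile$design),
                        byrow = TRUE,
                        dimnames = list(NULL, names(profile$design))),
                 trd)
  th <- dist_model$distance_coefs[["walk"]]
  d_hat <- exp(drop(xfull[, names(th), drop = FALSE] %*% th) +
                 dist_model$sigma[["walk"]]^2 / 2)
  ## frequency class probabilities
  trf <- trend_terms_matrix(xy, freq_model$scaler, cbd_xy = grid$cbd_xy)
  xf <- cbind(xfull[, setdiff(colnames(xfull), c("(Intercept)",
                                                 trend_names())),
                    drop = FALSE], trf)
  b <- freq_model$coefs[["walk"]]
  eta <- if (length(b)) drop(xf[, names(b), drop = FALSE] %*% b) else
    rep(0, n)
  cuts <- freq_model$thresholds[["walk"]]
  p0 <- stats::pnorm(cuts[1L] - eta)
  p1 <- stats::pnorm(cuts[2L] - eta) - p0
  p2 <- stats::pnorm(cuts[3L] - eta) - stats::pnorm(cuts[2L] - eta)
  p3 <- 1 - stats::pnorm(cuts[3L] - eta)
  tdwd_v <- d_hat * (1 * p1 + 2 * p2 + k_cap * p3)
  wwm_v <- tdwd_v * cfg$days_per_week / cfg$walking_speed
  comp_v <- 100 * wwm_v / cfg$weekly_minutes
  as_layer <- function(v) matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE)
  structure(list(grid = grid, cfg = cfg, k_cap = k_cap,
                 layers = list(d_hat = as_layer(d_hat), p1 = as_layer(p1),
                               p2 = as_layer(p2), p3plus = as_layer(p3),
                               tdwd = as_layer(tdwd_v),
                               wwm = as_layer(wwm_v),
                               compliance = as_layer(comp_v))),
            class = "compliance_raster")
}

#' @export
print.compliance_raster <- function(x, ...) {
  cat("<compliance_raster> ", x$grid$n_rows, "x", x$grid$n_cols,
      " cells of ", x$grid$cell_size, " map units\n",
      "  compliance range: ",
      paste(format(range(x$layers$compliance), digits = 4),
            collapse = " .. "), " %\n", sep = "")
  invisible(x)
}

#' Area distribution by compliance potential
#'
#' Histogram of grid area (km^2) across compliance bins. Bins are
#' left-closed `[e_i, e_{i+1})`; cells below the first or at/above the
#' last edge are collected in explicit underflow/overflow rows, so the
#' total tabulated area always equals the full grid area.
#'
#' @param raster A [build_compliance_raster()] result.
#' @param bin_edges Increasing numeric vector of bin edges (percent).
#' @param layer Layer to bin (default `"compliance"`).
#' @return data.frame with columns `lower`, `upper`, `area_km2`.
#' @export
area_by_compliance <- function(raster, bin_edges, layer = "compliance") {
  stopifnot(inherits(raster, "compliance_raster"),
            length(bin_edges) >= 2L, all(diff(bin_edges) > 0))
  v <- as.numeric(raster$layers[[layer]])
  cell_km2 <- (raster$grid$cell_size / 1000)^2
  lo <- c(-Inf, bin_edges)
  hi <- c(bin_edges, Inf)
  area <- vapply(seq_along(lo), function(i)
    sum(v >= lo[i] & v < hi[i]) * cell_km2, numeric(1))
  data.frame(lower = lo, upper = hi, area_km2 = area)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster interchange format (header of six keywords
#' followed by rows north to south).
#'
#' @param raster A [build_compliance_raster()] result.
#' @param layer Layer name.
#' @param path Output file path.
#' @export
write_raster_asc <- function(raster, layer, path) {
  g <- raster$grid
  m <- raster$layers[[layer]]
  if (is.null(m)) stop("no such layer: ", layer, call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
               paste("xllcorner", g$origin_xy[1L]),
               paste("yllcorner", g$origin_xy[2L]),
               paste("cellsize", g$cell_size),
               "NODATA_value -9999"), con)
  for (r in g$n_rows:1)  # top row first
    writeLines(paste(format(m[r, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Write all raster layers as a long-format CSV
#'
#' One row per cell: centroid coordinates plus every layer value.
#'
#' @inheritParams write_raster_asc
#' @export
write_raster_csv <- function(raster, path) {
  xy <- cell_centroids(raster$grid)
  df <- data.frame(cell_x = xy[, 1L], cell_y = xy[, 2L])
  ## layers are stored row-major bottom-up, matching centroid order
  for (nm in names(raster$layers)) {
    v <- as.numeric(t(raster$layers[[nm]]))
    df[[if (nm == "compliance") "compliance_pct" else nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quick-look plot of a raster layer
#'
#' Minimal image plot for inspection; cartographic styling is out of
#' scope.
#'
#' @param x A `compliance_raster`.
#' @param layer Layer to draw (default `"compliance"`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.compliance_raster <- function(x, layer = "compliance", ...) {
  g <- x$grid
  cx <- g$origin_xy[1L] + (seq_len(g$n_cols) - 0.5) * g$cell_size
  cy <- g$origin_xy[2L] + (seq_len(g$n_rows) - 0.5) * g$cell_size
  graphics::image(cx, cy, t(x$layers[[layer]]), xlab = "x", ylab = "y",
                  main = layer, ...)
  invisible(x)
}
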