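## JSON serialization of fitted model parameters.
##
## The coefficient layout mirrors published coefficient tables: one
## named map per mode. On reading, a coefficient that is absent, null
## or printed as "-" is treated as structurally zero (distance model)
## or excluded (frequency model), so published tables can be loaded
## directly as parameter fixtures.

coef_list <- function(v) as.list(v)

coef_from_list <- function(x, cols) {
  v <- stats::setNames(numeric(length(cols)), cols)
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val) || (is.character(val) && val %in% c("-", "")))
      next
    if (!nm %in% cols)
      stop("unknown coefficient column '", nm, "'", call. = FALSE)
    v[nm] <- as.numeric(val)
  }
  v
}

#' Write a fitted joint distance model to JSON
#'
#' @param fit A `cpm_fit` from [fit_joint()] or bare
#'   [joint_model_params()].
#' @param path Output path.
#' @export
write_joint_model <- function(fit, path) {
  params <- if (inherits(fit, "cpm_fit")) fit$params else fit
  stopifnot(inherits(params, "joint_model_params"))
  obj <- list(model = "joint_distance",
              reference_mode = params$reference_mode,
              schema = schema_to_list(params$schema),
              coordinate_scaler = scaler_to_list(params$scaler),
              utility_coefs = lapply(params$utility_coefs, coef_list),
              distance_coefs = lapply(params$distance_coefs, coef_list),
              sigma = as.list(params$sigma), rho = as.list(params$rho))
  if (inherits(fit, "cpm_fit")) {
    obj$loglik <- fit$loglik
    obj$std_errors <- as.list(fit$std_errors)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a joint distance model from JSON
#'
#' Tolerant of table-style fixtures: missing coefficients (including a
#' missing constant) load as zero; scalar `sigma`/`rho` are shared
#' across modes.
#'
#' @param path JSON path written by [write_joint_model()] or laid out
#'   like one.
#' @return A [joint_model_params()].
#' @export
read_joint_model <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$model, "joint_distance"))
    stop("not a joint_distance model file", call. = FALSE)
  schema <- schema_from_list(x$schema)
  scaler <- scaler_from_list(x$coordinate_scaler)
  cols <- joint_design_names(schema)
  uc <- lapply(cpm_modes(), function(m)
    coef_from_list(x$utility_coefs[[m]] %||% list(), cols))
  dc <- lapply(cpm_modes(), function(m)
    coef_from_list(x$distance_coefs[[m]] %||% list(), cols))
  names(uc) <- names(dc) <- cpm_modes()
  sg <- unlist(x$sigma); rh <- unlist(x$rho)
  joint_model_params(uc, dc, sg, rh, schema, scaler,
                     reference_mode = x$reference_mode %||% "car")
}

#' Write a fitted frequency model to JSON
#'
#' @param fit A `cpm_fit` from [fit_frequency()] or bare
#'   [ordered_probit_params()].
#' @param path Output path.
#' @export
write_frequency_model <- function(fit, path) {
  params <- if (inherits(fit, "cpm_fit")) fit$params else fit
  stopifnot(inherits(params, "ordered_probit_params"))
  obj <- list(model = "mvoprobit",
              schema = schema_to_list(params$schema),
              coordinate_scaler = scaler_to_list(params$scaler),
              coefs = lapply(params$coefs, coef_list),
              thresholds = lapply(params$thresholds, as.list),
              corr = unname(apply(params$corr, 1L, as.list, simplify = FALSE)))
  if (inherits(fit, "cpm_fit")) {
    obj$loglik <- fit$loglik
    obj$std_errors <- as.list(fit$std_errors)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a frequency model from JSON
#'
#' Coefficients printed as "-" or omitted are treated as structural
#' exclusions for that mode.
#'
#' @param path JSON path.
#' @return An [ordered_probit_params()].
#' @export
read_frequency_model <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$model, "mvoprobit"))
    stop("not a mvoprobit model file", call. = FALSE)
  schema <- schema_from_list(x$schema)
  scaler <- scaler_from_list(x$coordinate_scaler)
  cols <- c(schema$design_names, trend_names())
  coefs <- lapply(cpm_modes(), function(m) {
    raw <- x$coefs[[m]] %||% list()
    keep <- names(raw)[!vapply(raw, function(v)
      is.null(v) || (is.character(v) && v %in% c("-", "")), logical(1))]
    v <- coef_from_list(raw[keep], cols)
    v[keep]
  })
  names(coefs) <- cpm_modes()
  thr <- lapply(x$thresholds, function(v) as.numeric(unlist(v)))
  R <- do.call(rbind, lapply(x$corr, function(r) as.numeric(unlist(r))))
  ordered_probit_params(coefs, thr[cpm_modes()], R, schema, scaler)
}

#' Read a person profile from JSON
#'
#' A flat object of covariate assignments, validated against a schema.
#'
#' @param path JSON path.
#' @param schema A [covariate_schema()].
#' @return A [person_profile()].
#' @export
read_profile <- function(path, schema) {
  person_profile(jsonlite::read_json(path), schema)
}
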