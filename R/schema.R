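#' Covariate schema for travel-diary tables
#'
#' Declares the person/built-environment covariates that trip and person
#' tables carry, and fixes the reference level of every categorical
#' variable. The schema determines the design-matrix columns used by both
#' the trip-distance and trip-frequency models: each categorical variable
#' expands to indicator columns for its non-reference levels
#' (reference-cell dummy coding) and continuous variables pass through
#' unchanged.
#'
#' @param variables Named list. Each element describes one variable and is
#'   either `list(type = "categorical", levels = <character>, reference =
#'   <level>)` or `list(type = "continuous")`. Order is preserved and
#'   determines design-column order.
#' @return An object of class `cpm_schema` with elements `variables` and
#'   `design_names` (the deterministic design-column labels,
#'   `"<var>:<level>"` for dummies).
#' @examples
#' sch <- covariate_schema(list(
#'   age = list(type = "categorical",
#'              levels = c("younger", "senior", "elder"),
#'              reference = "younger"),
#'   street_density = list(type = "continuous")))
#' sch$design_names
#' @export
covariate_schema <- function(variables) {
  stopifnot(is.list(variables), length(names(variables)) == length(variables))
  if (anyDuplicated(names(variables)))
    stop("duplicate variable names in schema", call. = FALSE)
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (!is.list(v) || is.null(v$type) ||
        !v$type %in% c("categorical", "continuous"))
      stop("variable '", nm, "' must have type 'categorical' or 'continuous'",
           call. = FALSE)
    if (v$type == "categorical") {
      if (is.null(v$levels) || length(v$levels) < 2L || anyDuplicated(v$levels))
        stop("categorical variable '", nm, "' needs >= 2 distinct levels",
             call. = FALSE)
      if (is.null(v$reference) || length(v$reference) != 1L ||
          !v$reference %in% v$levels)
        stop("categorical variable '", nm,
             "' needs exactly one reference level drawn from its levels",
             call. = FALSE)
    }
  }
  design_names <- unlist(lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    if (v$type == "continuous") nm
    else paste0(nm, ":", setdiff(v$levels, v$reference))
  }), use.names = FALSE)
  structure(list(variables = variables, design_names = design_names),
            class = "cpm_schema")
}

#' @export
print.cpm_schema <- function(x, ...) {
  cat("<cpm_schema> ", length(x$variables), " variables, ",
      length(x$design_names), " design columns\n", sep = "")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    if (v$type == "continuous") cat("  ", nm, ": continuous\n", sep = "")
    else cat("  ", nm, ": ", paste(v$levels, collapse = "/"),
             " (ref ", v$reference, ")\n", sep = "")
  }
  invisible(x)
}

schema_covariate_names <- function(schema) names(schema$variables)

#' Encode one record's covariates as a design vector
#'
#' Expands categorical covariates to reference-cell dummy indicators and
#' passes continuous covariates through. The returned vector follows the
#' schema's deterministic column order; a record sitting at every
#' reference level with zero continuous values encodes to the zero
#' vector.
#'
#' @param covariates Named list or vector: categorical entries give a
#'   level label, continuous entries a numeric value. Must contain every
#'   schema variable.
#' @param schema A [covariate_schema()].
#' @return Named numeric vector of length `length(schema$design_names)`.
#' @export
encode_covariates <- function(covariates, schema) {
  stopifnot(inherits(schema, "cpm_schema"))
  covariates <- as.list(covariates)
  missing <- setdiff(names(schema$variables), names(covariates))
  if (length(missing))
    stop("missing covariates: ", paste(missing, collapse = ", "), call. = FALSE)
  out <- numeric(0)
  for (nm in names(schema$variables)) {
    v <- schema$variables[[nm]]
    val <- covariates[[nm]]
    if (v$type == "continuous") {
      x <- as.numeric(val)
      if (length(x) != 1L || !is.finite(x))
        stop("continuous covariate '", nm, "' must be a finite scalar",
             call. = FALSE)
      names(x) <- nm
      out <- c(out, x)
    } else {
      val <- as.character(val)
      if (length(val) != 1L || !val %in% v$levels)
        stop("unknown level '", val, "' for categorical covariate '", nm, "'",
             call. = FALSE)
      lv <- setdiff(v$levels, v$reference)
      x <- as.numeric(val == lv)
      names(x) <- paste0(nm, ":", lv)
      out <- c(out, x)
    }
  }
  out[schema$design_names]
}

## Vectorized design matrix for a table whose columns include the schema
## covariates (categoricals as character, continuous as numeric).
design_matrix <- function(df, schema) {
  n <- nrow(df)
  X <- matrix(0, n, length(schema$design_names),
              dimnames = list(NULL, schema$design_names))
  for (nm in names(schema$variables)) {
    v <- schema$variables[[nm]]
    if (!nm %in% names(df))
      stop("column '", nm, "' missing from table", call. = FALSE)
    if (v$type == "continuous") {
      x <- as.numeric(df[[nm]])
      if (anyNA(x)) stop("non-numeric values in continuous covariate '", nm,
                         "'", call. = FALSE)
      X[, nm] <- x
    } else {
      val <- as.character(df[[nm]])
      bad <- !val %in% v$levels
      if (any(bad))
        stop("unknown level(s) '", paste(unique(val[bad]), collapse = "', '"),
             "' for categorical covariate '", nm, "'", call. = FALSE)
      for (lv in setdiff(v$levels, v$reference))
        X[, paste0(nm, ":", lv)] <- as.numeric(val == lv)
    }
  }
  X
}

schema_to_list <- function(schema) {
  list(variables = lapply(schema$variables, function(v) {
    if (v$type == "continuous") list(type = "continuous")
    else list(type = "categorical", levels = as.list(v$levels),
              reference = v$reference)
  }))
}

schema_from_list <- function(x) {
  covariate_schema(lapply(x$variables, function(v) {
    if (identical(v$type, "continuous")) list(type = "continuous")
    else list(type = "categorical", levels = unlist(v$levels),
              reference = v$reference)
  }))
}
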