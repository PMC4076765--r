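## Trip and person tables.
##
## Trips and persons are plain data.frames carrying a `cpm_schema`
## attribute. One row of a trip table is one observed home-based trip
## (person id, mode, positive distance in metres, home coordinates in
## planar map units, distance to CBD in km, covariates). One row of a
## person table is one surveyed person with per-mode trip counts.

trip_base_cols <- function() c("person_id", "mode", "distance_m", "x", "y", "cbd_km")
person_base_cols <- function() c("person_id", "n_walk", "n_car", "n_transit",
                                 "x", "y", "cbd_km")

#' Assemble a trip table
#'
#' @param df data.frame with columns `person_id, mode, distance_m, x, y,
#'   cbd_km` plus one column per schema covariate.
#' @param schema A [covariate_schema()].
#' @return data.frame of class `cpm_trips` (rows with non-positive
#'   distance are rejected here; use [read_trips()] to drop them).
#' @export
cpm_trips <- function(df, schema) {
  stopifnot(inherits(schema, "cpm_schema"))
  miss <- setdiff(c(trip_base_cols(), schema_covariate_names(schema)), names(df))
  if (length(miss))
    stop("trip table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$mode %in% cpm_modes()))
    stop("mode must be one of ", paste(cpm_modes(), collapse = ", "),
         call. = FALSE)
  d <- as.numeric(df$distance_m)
  if (anyNA(d) || any(d <= 0))
    stop("distance_m must be positive and numeric", call. = FALSE)
  if (any(as.numeric(df$cbd_km) < 0)) stop("cbd_km must be nonnegative",
                                           call. = FALSE)
  design_matrix(df, schema)  # validates covariate columns/levels
  structure(as.data.frame(df), schema = schema,
            class = c("cpm_trips", "data.frame"))
}

#' Assemble a person table
#'
#' @param df data.frame with columns `person_id, n_walk, n_car,
#'   n_transit, x, y, cbd_km` plus one column per schema covariate.
#'   Counts are nonnegative integers (weekly-diary trip counts per mode).
#' @param schema A [covariate_schema()].
#' @return data.frame of class `cpm_persons`.
#' @export
cpm_persons <- function(df, schema) {
  stopifnot(inherits(schema, "cpm_schema"))
  miss <- setdiff(c(person_base_cols(), schema_covariate_names(schema)), names(df))
  if (length(miss))
    stop("person table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in c("n_walk", "n_car", "n_transit")) {
    v <- as.numeric(df[[cc]])
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop(cc, " must contain nonnegative integers", call. = FALSE)
  }
  design_matrix(df, schema)
  structure(as.data.frame(df), schema = schema,
            class = c("cpm_persons", "data.frame"))
}

table_schema <- function(x) attr(x, "schema")

read_delimited <- function(path, schema, base_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(base_cols, schema_covariate_names(schema)), names(df))
  if (length(miss))
    stop(what, " file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- intersect(c("distance_m", "x", "y", "cbd_km",
                          "n_walk", "n_car", "n_transit"), base_cols)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1L] + 1L  # header is line 1
      stop("unparseable numeric in column '", cc, "' at line ", line,
           " of ", path, call. = FALSE)
    }
    df[[cc]] <- v
  }
  df
}

#' Read a trip table from CSV
#'
#' Comma-separated with a mandatory header; columns `person_id, mode,
#' distance_m, x, y, cbd_km` plus the schema covariates. Rows with
#' non-positive distance are dropped (only trips with a distance greater
#' than zero enter the distance model); the number dropped is attached as
#' attribute `n_dropped` and reported via `message()`.
#'
#' @param path CSV file path.
#' @param schema A [covariate_schema()].
#' @return A [cpm_trips()] table with attribute `n_dropped`.
#' @export
read_trips <- function(path, schema) {
  df <- read_delimited(path, schema, trip_base_cols(), "trip")
  drop <- df$distance_m <= 0
  if (any(drop))
    message("read_trips: dropped ", sum(drop),
            " row(s) with non-positive distance")
  out <- cpm_trips(df[!drop, , drop = FALSE], schema)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Read a person table from CSV
#'
#' @inheritParams read_trips
#' @return A [cpm_persons()] table.
#' @export
read_persons <- function(path, schema) {
  df <- read_delimited(path, schema, person_base_cols(), "person")
  cpm_persons(df, schema)
}

#' Write a trip or person table to CSV
#'
#' Inverse of [read_trips()] / [read_persons()]: reading a written file
#' back with the same schema reproduces the table.
#'
#' @param x A `cpm_trips` or `cpm_persons` table.
#' @param path Output CSV path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Full model design for a table: encoded covariates + trend-surface block.
## Uses the table's stored cbd_km (survey-provided) rather than recomputing
## from coordinates.
table_design <- function(df, schema, scaler) {
  X <- design_matrix(df, schema)
  tr <- trend_terms_matrix(cbind(df$x, df$y), scaler, cbd_km = df$cbd_km)
  cbind(X, tr)
}
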