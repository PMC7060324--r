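#' A single farm record
#'
#' One farm's identity — region (one of two agro-ecological zones), farm
#' type (conventional `CF`, young organic `YOF`, old organic `OOF`), years
#' since transition to organic farming — plus its explanatory variable
#' values.
#'
#' Consistency defaults follow the study design: `YOF` implies fewer than 6
#' years since transition, `OOF` implies 11 to 26 years, `CF` implies 0;
#' bounds are configurable because survey data occasionally contain
#' inconsistent entries that must be resolved explicitly.
#'
#' @param farm_id Unique identifier.
#' @param region `"zone_A"` or `"zone_B"`.
#' @param farm_type `"CF"`, `"YOF"` or `"OOF"`.
#' @param years_since_transition Non-negative integer; 0 for `CF`.
#' @param values Named numeric vector of explanatory variable values.
#' @param yof_max,oof_range Type-consistency bounds (years).
#' @return An object of class `farm_record`.
#' @export
farm_record <- function(farm_id, region = c("zone_A", "zone_B"),
                        farm_type = c("CF", "YOF", "OOF"),
                        years_since_transition = 0L,
                        values = numeric(0),
                        yof_max = 6, oof_range = c(11, 26)) {
  region <- match.arg(region)
  farm_type <- match.arg(farm_type)
  tst <- as.numeric(years_since_transition)
  if (length(tst) != 1L || is.na(tst) || tst < 0)
    stop("years_since_transition must be a non-negative number", call. = FALSE)
  ok <- switch(farm_type,
               CF = tst == 0,
               YOF = tst > 0 && tst < yof_max,
               OOF = tst >= oof_range[1] && tst <= oof_range[2])
  if (!ok)
    stop("farm '", farm_id, "': years_since_transition (", tst,
         ") inconsistent with farm_type ", farm_type, call. = FALSE)
  structure(list(farm_id = as.character(farm_id), region = region,
                 farm_type = farm_type, years_since_transition = tst,
                 values = values),
            class = "farm_record")
}

#' @export
print.farm_record <- function(x, ...) {
  cat(sprintf("<farm_record> %s [%s, %s, TST=%g] %d variables\n",
              x$farm_id, x$region, x$farm_type, x$years_since_transition,
              length(x$values)))
  invisible(x)
}

id_cols <- c("farm_id", "region", "farm_type", "years_since_transition")

validate_values <- function(values, schema, farm_id) {
  for (s in schema) {
    val <- values[[s$name]]
    if (is.null(val) || is.na(val))
      stop("farm '", farm_id, "': missing value for variable '", s$name, "'",
           call. = FALSE)
    if (s$kind == "dummy" && !(val %in% c(0, 1)))
      stop("farm '", farm_id, "': dummy variable '", s$name,
           "' has non-binary value ", val, call. = FALSE)
    if (!is.null(s$range) && (val < s$range[1] || val > s$range[2]))
      stop("farm '", farm_id, "': variable '", s$name, "' value ", val,
           " outside valid range [", s$range[1], ", ", s$range[2], "]",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a farm table from CSV
#'
#' The CSV must have a header row and one row per farm, with columns
#' `farm_id`, `region`, `farm_type`, `years_since_transition` plus one
#' column per schema variable. Values are validated against each variable's
#' kind and range.
#'
#' @param path CSV file path (comma-separated, `.` decimal separator,
#'   UTF-8).
#' @param schema A [variable_schema()]; defaults to [default_schema()].
#' @param ... Passed to [farm_record()] (e.g. consistency bounds).
#' @return A list of [farm_record()] objects (class `farm_set`).
#' @export
read_farm_table <- function(path, schema = default_schema(), ...) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  farms_from_df(df, schema, ...)
}

#' Build farm records from a data frame
#'
#' @param df Data frame in the layout of [read_farm_table()].
#' @inheritParams read_farm_table
#' @return A `farm_set` (list of `farm_record`).
#' @export
farms_from_df <- function(df, schema = default_schema(), ...) {
  missing_cols <- setdiff(c(id_cols, schema_names(schema)), names(df))
  if (length(missing_cols))
    stop("farm table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$farm_id))
    stop("duplicate farm_id: ",
         paste(unique(df$farm_id[duplicated(df$farm_id)]), collapse = ", "),
         call. = FALSE)
  farms <- lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, schema_names(schema), drop = TRUE])
    names(vals) <- schema_names(schema)
    validate_values(as.list(vals), schema, df$farm_id[i])
    farm_record(df$farm_id[i], df$region[i], df$farm_type[i],
                df$years_since_transition[i], vals, ...)
  })
  structure(farms, class = "farm_set", schema = schema)
}

#' @export
print.farm_set <- function(x, ...) {
  reg <- table(vapply(x, `[[`, character(1), "region"))
  typ <- table(vapply(x, `[[`, character(1), "farm_type"))
  cat(sprintf("<farm_set> %d farms (%s; %s)\n", length(x),
              paste(sprintf("%s: %d", names(reg), reg), collapse = ", "),
              paste(sprintf("%s: %d", names(typ), typ), collapse = ", ")))
  invisible(x)
}

#' Farm set as a data frame
#' @param farms A `farm_set`.
#' @return Data frame with identity columns and one column per variable.
#' @export
farms_to_df <- function(farms) {
  stopifnot(inherits(farms, "farm_set"))
  ids <- data.frame(
    farm_id = vapply(farms, `[[`, character(1), "farm_id"),
    region = vapply(farms, `[[`, character(1), "region"),
    farm_type = vapply(farms, `[[`, character(1), "farm_type"),
    years_since_transition =
      vapply(farms, `[[`, numeric(1), "years_since_transition"),
    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(farms, `[[`, "values"))
  cbind(ids, as.data.frame(vals, check.names = FALSE))
}

#' Write a farm table to CSV
#' @param farms A `farm_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_farm_table <- function(farms, path) {
  utils::write.csv(farms_to_df(farms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the explanatory design matrix
#'
#' @param farms A `farm_set`.
#' @param schema Schema giving column order; defaults to the set's schema.
#' @return Numeric n x p matrix with farm ids as row names and variable
#'   names as column names; attribute `"schema"` carries the schema.
#' @export
design_matrix <- function(farms, schema = attr(farms, "schema")) {
  stopifnot(inherits(farms, "farm_set"))
  if (is.null(schema)) schema <- default_schema()
  nms <- schema_names(schema)
  X <- do.call(rbind, lapply(farms, function(f) f$values[nms]))
  rownames(X) <- vapply(farms, `[[`, character(1), "farm_id")
  colnames(X) <- nms
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  attr(X, "schema") <- schema
  X
}

#' Assemble / validate a response matrix
#'
#' The default responses are the seven crop performance indicators (see
#' [default_indicators()]); yield and count indicators must be strictly
#' positive for the relative prediction error to be defined.
#'
#' @param values Numeric n x m matrix or data frame of responses.
#' @param farm_ids Row identifiers; defaults to existing row names.
#' @param indicators Column names; defaults to [default_indicators()].
#' @param positive Names of indicators required to be strictly positive;
#'   defaults to all.
#' @return Numeric matrix with class attribute checks applied.
#' @export
response_matrix <- function(values, farm_ids = rownames(values),
                            indicators = default_indicators(),
                            positive = indicators) {
  Y <- as.matrix(values)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- indicators
  if (!identical(colnames(Y), indicators))
    Y <- Y[, indicators, drop = FALSE]
  if (anyNA(Y)) stop("response matrix contains missing values", call. = FALSE)
  for (ind in intersect(positive, colnames(Y)))
    if (any(Y[, ind] <= 0))
      stop("response '", ind, "' must be strictly positive", call. = FALSE)
  rownames(Y) <- farm_ids
  Y
}

#' Read a response table from CSV
#'
#' @param path CSV with a `farm_id` column plus one column per indicator.
#' @param indicators Expected indicator columns.
#' @return Response matrix with farm ids as row names.
#' @export
read_response_table <- function(path, indicators = default_indicators()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("farm_id", indicators), names(df))
  if (length(missing_cols))
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  response_matrix(df[, indicators, drop = FALSE], farm_ids = df$farm_id,
                  indicators = indicators)
}

#' Write a response table to CSV
#' @param Y Response matrix with farm ids as row names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(Y, path) {
  df <- data.frame(farm_id = rownames(Y), as.data.frame(Y),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
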