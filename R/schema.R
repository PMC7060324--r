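#' Declare a single explanatory variable
#'
#' A variable specification records how one column of the explanatory
#' (design) matrix is to be interpreted and validated: its measurement level
#' in the farm system (whole-farm description, management practice, field
#' history, current-year field management, soil, or landscape), its kind
#' (continuous, 0/1 dummy, ordinal scale, percentage, or dimensionless
#' index), its unit, whether it is standardized against the region median,
#' and the closed interval of admissible values.
#'
#' @param name Short unique identifier (used as the column name).
#' @param label Free-text description.
#' @param level One of `"farm_description"`, `"farm_management"`,
#'   `"field_history"`, `"field_current"`, `"soil"`, `"landscape"`.
#' @param kind One of `"continuous"`, `"dummy"`, `"ordinal"`,
#'   `"percentage"`, `"index"`.
#' @param unit Unit string; may be empty for dimensionless variables.
#' @param region_standardized Logical; `TRUE` when the analysis column holds
#'   deviations from the per-region median rather than raw values.
#' @param range Optional numeric length-2 closed interval of valid values
#'   for the analysis column, or `NULL` for unbounded.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, label = name,
                          level = c("farm_description", "farm_management",
                                    "field_history", "field_current",
                                    "soil", "landscape"),
                          kind = c("continuous", "dummy", "ordinal",
                                   "percentage", "index"),
                          unit = "", region_standardized = FALSE,
                          range = NULL) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "dummy") {
    if (is.null(range)) range <- c(0, 1)
    if (!identical(as.numeric(range), c(0, 1)))
      stop("dummy variable '", name, "' must have range [0, 1]", call. = FALSE)
  }
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || any(!is.finite(range)) || range[1] > range[2])
      stop("invalid range for variable '", name, "'", call. = FALSE)
    if (kind == "ordinal" && any(range != round(range)))
      stop("ordinal variable '", name, "' must have integer range bounds",
           call. = FALSE)
  }
  structure(list(name = name, label = label, level = level, kind = kind,
                 unit = unit, region_standardized = region_standardized,
                 range = range),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  rng <- if (is.null(x$range)) "unbounded" else
    sprintf("[%g, %g]", x$range[1], x$range[2])
  cat(sprintf("<variable_spec> %s (%s, %s%s) %s%s\n", x$name, x$level, x$kind,
              if (nzchar(x$unit)) paste0(", ", x$unit) else "", rng,
              if (x$region_standardized) " [region-standardized]" else ""))
  invisible(x)
}

#' Build a variable schema from specs
#'
#' A schema is an ordered list of [variable_spec()] objects with unique
#' names; it defines the columns of a design matrix.
#'
#' @param ... `variable_spec` objects, or a single list of them.
#' @return An object of class `variable_schema`.
#' @export
variable_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  if (!all(vapply(specs, inherits, logical(1), "variable_spec")))
    stop("all elements must be variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "variable_schema")
}

#' @export
print.variable_schema <- function(x, ...) {
  cat(sprintf("<variable_schema> %d variables\n", length(x)))
  lv <- table(vapply(x, `[[`, character(1), "level"))
  cat(" ", paste(sprintf("%s: %d", names(lv), lv), collapse = ", "), "\n")
  invisible(x)
}

#' Variable names of a schema
#' @param schema A `variable_schema`.
#' @return Character vector of variable names in schema order.
#' @export
schema_names <- function(schema) {
  stopifnot(inherits(schema, "variable_schema"))
  vapply(schema, `[[`, character(1), "name")
}

#' The default 34-variable explanatory schema
#'
#' The schema used throughout the package: 2 whole-farm descriptors (time
#' since transition to organic farming, farm size), 1 landscape index (LHI),
#' 8 farm-level management practices, 6 field-history (previous three
#' seasons) and 12 current-season field management variables, and 5 soil
#' parameters — 29 management/landscape variables plus 5 soil variables.
#' Ranges are the union of the two study regions' observed ranges; sowing
#' date and soil clay content are region-median standardized, so their
#' columns hold deviations and their ranges are symmetric envelopes.
#'
#' @return A `variable_schema` with 34 variables.
#' @export
default_schema <- function() {
  v <- variable_spec
  variable_schema(list(
    v("TST", "Time since transition to organic farming", "farm_description",
      "continuous", "year", range = c(0, 26)),
    v("Size", "Farm size", "farm_description", "continuous", "ha",
      range = c(11, 700)),
    v("LHI", "Landscape heterogeneity index, 1 km radius", "landscape",
      "index", range = c(-4, 4)),
    v("Leys", "Proportion of rotational leys", "farm_management",
      "percentage", "%", range = c(0, 87)),
    v("Grains", "Proportion of cereal crops", "farm_management",
      "percentage", "%", range = c(6, 95)),
    v("Ocrops", "Proportion of other crops", "farm_management",
      "percentage", "%", range = c(0, 56)),
    v("PP", "Presence of pasture", "farm_management", "dummy"),
    v("OFert_area", "Area with organic fertilizers", "farm_management",
      "continuous", "ha", range = c(0, 380)),
    v("AOFert", "Amount of organic fertilizers", "farm_management",
      "continuous", "t/ha", range = c(0, 70)),
    v("LDI", "Livestock density index", "farm_management", "index",
      range = c(0, 3.3)),
    v("SRM", "Straw and residue management (farm)", "farm_management",
      "ordinal", range = c(1, 3)),
    v("Freq_OFe", "Frequency of organic fertilizer application",
      "field_history", "continuous", range = c(0, 1)),
    v("OFe_AT", "Organic fertilizer application technique 2009-2011",
      "field_history", "ordinal", range = c(0, 2)),
    v("Min_N", "Mineral N on average 2009-2011", "field_history",
      "continuous", "kg/ha", range = c(0, 175)),
    v("Min_PK", "Mineral PK applied", "field_history", "dummy"),
    v("PEST", "Pesticide application 2009-2011", "field_history", "dummy"),
    v("STR_M", "Straw and residue management (field) 2009-2011",
      "field_history", "ordinal", range = c(0, 2)),
    v("Org_N12", "Nitrogen amount from organic fertilizers 2012",
      "field_current", "continuous", "kg/ha", range = c(0, 167)),
    v("OFe_AT12", "Organic fertilizer application technique 2012",
      "field_current", "ordinal", range = c(0, 2)),
    v("Min_N12", "Mineral N application 2012", "field_current",
      "continuous", "kg/ha", range = c(0, 175)),
    v("SMR_L12", "Straw and residues left before sowing 2012",
      "field_current", "dummy"),
    v("StdSd", "Sowing date, deviation from region median", "field_current",
      "continuous", "day", region_standardized = TRUE, range = c(-40, 40)),
    v("Seed", "Seed rate sown", "field_current", "continuous", "m-2",
      range = c(100, 220)),
    v("PC_pea", "Pea as preceding crop", "field_current", "dummy"),
    v("PC_leys", "Leys as preceding crop", "field_current", "dummy"),
    v("PC_cereal", "Cereals as preceding crop", "field_current", "dummy"),
    v("PEST_12", "Pesticide use 2012", "field_current", "dummy"),
    v("US_12", "Barley undersown with grass/clover", "field_current",
      "dummy"),
    v("Weed", "Percentage weed cover, mean of three assessments",
      "field_current", "percentage", "%", range = c(0, 40)),
    v("SMN1", "Soil mineral nitrogen before fertilisation", "soil",
      "continuous", "kg/ha", range = c(12, 57)),
    v("pH", "Soil pH", "soil", "continuous", range = c(5.6, 8)),
    v("Tot_C", "Total soil carbon", "soil", "percentage", "%",
      range = c(1.1, 12)),
    v("Tot_N", "Total soil nitrogen", "soil", "percentage", "%",
      range = c(0.1, 1)),
    v("Clay", "Soil clay content, deviation from region median", "soil",
      "percentage", "%", region_standardized = TRUE, range = c(-50, 50))
  ))
}

#' Default response indicator names
#'
#' The seven crop performance indicators: dry matter at stem elongation
#' (DM1, t/ha) and its N concentration (N_Cut1, %), total dry matter at
#' ripening (DM2, t/ha), grain mass (Grain_M, t/ha), grain N concentration
#' (Grain_N, %), straw N concentration (Straw_N, %), and ear count
#' (Ears, m-2).
#'
#' @return Character vector of length 7.
#' @export
default_indicators <- function() {
  c("DM1", "N_Cut1", "DM2", "Grain_M", "Grain_N", "Straw_N", "Ears")
}

#' Read / write a schema as YAML
#'
#' The YAML representation is a list of maps with fields `name`, `label`,
#' `level`, `kind`, `unit`, `region_standardized` and `range`
#' (`[min, max]` or absent). A copy of the default schema ships in
#' `system.file("extdata", "schema_34.yaml", package = "agropls")`.
#'
#' @param path File path.
#' @return `read_schema()` returns a `variable_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  variable_schema(lapply(raw, function(r) {
    variable_spec(name = r$name, label = r$label %||% r$name,
                  level = r$level, kind = r$kind, unit = r$unit %||% "",
                  region_standardized = isTRUE(r$region_standardized),
                  range = if (!is.null(r$range)) as.numeric(r$range))
  }))
}

#' @rdname read_schema
#' @param schema A `variable_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "variable_schema"))
  raw <- lapply(unname(schema), function(s) {
    out <- list(name = s$name, label = s$label, level = s$level,
                kind = s$kind, unit = s$unit,
                region_standardized = s$region_standardized)
    if (!is.null(s$range)) out$range <- s$range
    out
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
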