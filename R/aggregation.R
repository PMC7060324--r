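#' Declare an aggregation rule
#'
#' One rule maps raw survey answers (columns of the raw-answer table) to one
#' synthetic explanatory variable. Available methods:
#' \describe{
#'   \item{identity}{copy a single raw answer.}
#'   \item{proportion}{`100 * part / whole` from two raw answers (percent of
#'     farm area).}
#'   \item{count_over_years}{sum of per-year counts divided by
#'     `parameters$years` (frequency in 0..1).}
#'   \item{ordinal_scale}{copy an already-coded ordinal answer, checked to
#'     be integer-valued.}
#'   \item{dummy}{0/1 indicator: nonzero raw answer becomes 1.}
#'   \item{mean_over_assessments}{row mean over repeated assessments.}
#'   \item{index_formula}{a named index; currently `"lhi"`, computed by
#'     [compute_lhi()] from two proportion columns.}
#' }
#'
#' @param target Name of the schema variable the rule produces.
#' @param inputs Character vector of raw-answer column names.
#' @param method One of the methods above.
#' @param parameters Named list of method parameters (e.g. `years = 3`,
#'   `formula = "lhi"`, `region_standardize = TRUE`).
#' @return An object of class `aggregation_rule`.
#' @export
aggregation_rule <- function(target, inputs,
                             method = c("identity", "proportion",
                                        "count_over_years", "ordinal_scale",
                                        "dummy", "index_formula",
                                        "mean_over_assessments"),
                             parameters = list()) {
  method <- match.arg(method)
  structure(list(target = target, inputs = inputs, method = method,
                 parameters = parameters),
            class = "aggregation_rule")
}

#' Landscape heterogeneity index
#'
#' `LHI = sin(45 degrees) * (z1 + z2)` where `z1`, `z2` are z-scores of the
#' proportion of semi-natural grassland and the proportion of field border
#' around the field. The 45-degree factor (`sqrt(2)/2`) projects the two
#' standardized axes onto their diagonal, so equal enrichment of both
#' habitat types moves a farm along a single heterogeneity gradient. The
#' standardization population defaults to the farms supplied (both regions
#' pooled); explicit statistics may be given instead.
#'
#' @param prop_seminatural,prop_field_border Fractions in `[0, 1]`
#'   (vectors of equal length).
#' @param stats Optional list with `mean_sng`, `sd_sng`, `mean_fb`, `sd_fb`
#'   giving the standardization population statistics; when `NULL` they are
#'   computed from the supplied vectors.
#' @return Numeric vector of LHI values.
#' @export
compute_lhi <- function(prop_seminatural, prop_field_border, stats = NULL) {
  stopifnot(length(prop_seminatural) == length(prop_field_border))
  if (any(prop_seminatural < 0 | prop_seminatural > 1) ||
      any(prop_field_border < 0 | prop_field_border > 1))
    stop("landscape proportions must lie in [0, 1]", call. = FALSE)
  if (is.null(stats))
    stats <- list(mean_sng = mean(prop_seminatural),
                  sd_sng = stats::sd(prop_seminatural),
                  mean_fb = mean(prop_field_border),
                  sd_fb = stats::sd(prop_field_border))
  if (!is.finite(stats$sd_sng) || !is.finite(stats$sd_fb) ||
      stats$sd_sng <= 0 || stats$sd_fb <= 0)
    stop("degenerate standardization set: zero or undefined SD", call. = FALSE)
  z1 <- (prop_seminatural - stats$mean_sng) / stats$sd_sng
  z2 <- (prop_field_border - stats$mean_fb) / stats$sd_fb
  sin(pi / 4) * (z1 + z2)
}

#' Standardize values by the region median
#'
#' Subtracts the per-region median, so each region's median maps to exactly
#' zero; used for variables whose raw values differ between the two
#' agro-ecological zones for climatic rather than management reasons
#' (sowing date, soil clay content). No rescaling by spread is applied.
#'
#' @param values Numeric vector, one value per farm.
#' @param region Region label per farm (same length as `values`).
#' @return Numeric vector of deviations from the region median.
#' @export
standardize_by_region_median <- function(values, region) {
  stopifnot(length(values) == length(region))
  region <- as.character(region)
  out <- values
  for (r in unique(region)) {
    idx <- region == r
    if (!any(idx)) stop("empty region group '", r, "'", call. = FALSE)
    out[idx] <- values[idx] - stats::median(values[idx])
  }
  out
}

apply_rule <- function(rule, raw, region = NULL) {
  miss <- setdiff(rule$inputs, names(raw))
  if (length(miss)) {
    stop("rule '", rule$target, "': raw answer(s) missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (inp in rule$inputs) {
    bad <- which(is.na(raw[[inp]]))
    if (length(bad))
      stop("rule '", rule$target, "': missing raw answer '", inp,
           "' for farm ", raw$farm_id[bad[1]], call. = FALSE)
  }
  p <- rule$parameters
  out <- switch(rule$method,
    identity = as.numeric(raw[[rule$inputs[1]]]),
    proportion = 100 * raw[[rule$inputs[1]]] / raw[[rule$inputs[2]]],
    count_over_years = {
      years <- p$years %||% length(rule$inputs)
      rowSums(as.matrix(raw[rule$inputs])) / years
    },
    ordinal_scale = {
      v <- as.numeric(raw[[rule$inputs[1]]])
      if (any(v != round(v)))
        stop("rule '", rule$target, "': non-integer ordinal answer",
             call. = FALSE)
      v
    },
    dummy = as.numeric(raw[[rule$inputs[1]]] != 0),
    mean_over_assessments = rowMeans(as.matrix(raw[rule$inputs])),
    index_formula = {
      if (!identical(p$formula, "lhi"))
        stop("unknown index formula '", p$formula, "'", call. = FALSE)
      compute_lhi(raw[[rule$inputs[1]]], raw[[rule$inputs[2]]],
                  stats = p$stats)
    })
  if (isTRUE(p$region_standardize)) {
    if (is.null(region))
      stop("rule '", rule$target,
           "' requires region labels for standardization", call. = FALSE)
    out <- standardize_by_region_median(out, region)
  }
  out
}

#' Aggregate raw survey answers into explanatory variables
#'
#' Applies one [aggregation_rule()] per target variable to the raw-answer
#' table, producing the non-soil columns of the design matrix. Soil
#' parameters are laboratory measurements, not survey answers, and join the
#' design matrix directly.
#'
#' @param raw Data frame of raw answers with a `farm_id` column.
#' @param rules List of `aggregation_rule` objects.
#' @param region Optional region label per farm, needed by rules with
#'   `region_standardize = TRUE`.
#' @return Data frame with `farm_id` plus one column per rule target, in
#'   rule order.
#' @export
aggregate_survey <- function(raw, rules, region = NULL) {
  stopifnot(is.data.frame(raw), "farm_id" %in% names(raw))
  if (!all(vapply(rules, inherits, logical(1), "aggregation_rule")))
    stop("rules must be aggregation_rule objects", call. = FALSE)
  out <- data.frame(farm_id = raw$farm_id, stringsAsFactors = FALSE)
  for (rule in rules)
    out[[rule$target]] <- apply_rule(rule, raw, region)
  out
}

#' Default aggregation rules for the 29 non-soil schema variables
#'
#' One rule per non-soil variable of [default_schema()]. The raw-answer
#' column naming convention is documented per rule: per-year counts carry a
#' year suffix (`ofe_applications_2009` ...), repeated assessments an
#' assessment suffix (`weed_cover_1` ...), landscape proportions are
#' `prop_seminatural` and `prop_field_border`, and already-coded answers
#' reuse the variable name in lower case. Where the original questionnaire
#' admitted several answers per practice, the shipped rule assumes the
#' answers were pre-coded to the scale in the schema (the full
#' questionnaire-to-variable mapping is not public).
#'
#' @return Named list of [aggregation_rule()] objects (29 rules).
#' @export
default_rules <- function() {
  r <- aggregation_rule
  rules <- list(
    r("TST", "years_since_transition", "identity"),
    r("Size", "farm_size_ha", "identity"),
    r("LHI", c("prop_seminatural", "prop_field_border"), "index_formula",
      list(formula = "lhi")),
    r("Leys", c("area_leys_ha", "farm_size_ha"), "proportion"),
    r("Grains", c("area_cereals_ha", "farm_size_ha"), "proportion"),
    r("Ocrops", c("area_other_crops_ha", "farm_size_ha"), "proportion"),
    r("PP", "has_pasture", "dummy"),
    r("OFert_area", "ofert_area_ha", "identity"),
    r("AOFert", "ofert_amount_t_ha", "identity"),
    r("LDI", "livestock_density", "identity"),
    r("SRM", "straw_management_farm", "ordinal_scale"),
    r("Freq_OFe", c("ofe_applications_2009", "ofe_applications_2010",
                    "ofe_applications_2011"), "count_over_years",
      list(years = 3)),
    r("OFe_AT", "ofe_technique_0911", "ordinal_scale"),
    r("Min_N", c("min_n_2009", "min_n_2010", "min_n_2011"),
      "count_over_years", list(years = 3)),
    r("Min_PK", "min_pk_used", "dummy"),
    r("PEST", "pesticide_used_0911", "dummy"),
    r("STR_M", "straw_management_field", "ordinal_scale"),
    r("Org_N12", "org_n_2012", "identity"),
    r("OFe_AT12", "ofe_technique_2012", "ordinal_scale"),
    r("Min_N12", "min_n_2012", "identity"),
    r("SMR_L12", "straw_left_2012", "dummy"),
    r("StdSd", "sowing_doy_2012", "identity",
      list(region_standardize = TRUE)),
    r("Seed", "seed_rate", "identity"),
    r("PC_pea", "preceding_pea", "dummy"),
    r("PC_leys", "preceding_leys", "dummy"),
    r("PC_cereal", "preceding_cereal", "dummy"),
    r("PEST_12", "pesticide_used_2012", "dummy"),
    r("US_12", "undersown_2012", "dummy"),
    r("Weed", c("weed_cover_1", "weed_cover_2", "weed_cover_3"),
      "mean_over_assessments")
  )
  names(rules) <- vapply(rules, `[[`, character(1), "target")
  rules
}
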