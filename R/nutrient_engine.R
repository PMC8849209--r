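# Conversion of consumed food mass into gross and bioavailable nutrient
# availability, group aggregation, contribution decomposition, per-capita
# availability and display rendering.

#' Gross and bioavailable nutrient availability per commodity
#'
#' Converts consumed mass (tonnes) into nutrient quantities using the
#' per-100 g composition table: `gross = consumed * 1e4 * amount_per_100g`
#' (one tonne is 1e4 x 100 g).  For protein and the indispensable amino
#' acids the bioavailable quantity is `gross * coefficient`; for every
#' other nutrient bioavailable equals gross.  Missing composition cells
#' contribute zero, with a single summary warning; commodities carrying
#' protein/amino-acid composition but no bioavailability record default
#' to a coefficient of 1 with a warning.
#'
#' @param food Data frame from [food_mass()] (needs `commodity_id`,
#'   `consumed`).
#' @param composition Composition table (`commodity_id`, `nutrient_id`,
#'   `amount`, optional `unit`).
#' @param bioavailability Coefficient table (`commodity_id`,
#'   `nutrient_id`, `coefficient`); may be `NULL` or empty.
#' @param units Unit registry; defaults to [nutrient_registry()].
#' @return Data frame (commodity-major, registry nutrient order) with
#'   columns `commodity_id`, `nutrient_id`, `unit`, `gross`,
#'   `bioavailable`, in the registry unit of each nutrient per year.
#' @export
nutrient_availability <- function(food, composition, bioavailability = NULL,
                                  units = nutrient_registry()) {
  if ("unit" %in% names(composition) && nrow(composition)) {
    want <- units$unit[match(composition$nutrient_id, units$nutrient_id)]
    bad <- !is.na(want) & !is.na(composition$unit) & composition$unit != want
    if (any(bad)) {
      stop("composition unit mismatch vs registry for: ",
           paste(unique(composition$nutrient_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  grid <- expand.grid(nutrient_id = units$nutrient_id,
                      commodity_id = food$commodity_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("commodity_id", "nutrient_id")]
  key <- paste(grid$commodity_id, grid$nutrient_id)
  amount <- composition$amount[match(key, paste(composition$commodity_id,
                                                composition$nutrient_id))]
  n_missing <- sum(is.na(amount))
  if (n_missing > 0) {
    miss <- grid[is.na(amount), ]
    warning(sprintf(
      "%d missing composition cell(s) contribute zero (first: %s/%s)",
      n_missing, miss$commodity_id[1], miss$nutrient_id[1]), call. = FALSE)
    amount[is.na(amount)] <- 0
  }
  consumed <- food$consumed[match(grid$commodity_id, food$commodity_id)]
  gross <- consumed * TONNES_TO_100G * amount

  coef <- rep(1, nrow(grid))
  scaled <- grid$nutrient_id %in% bioavailable_nutrients()
  if (!is.null(bioavailability) && nrow(bioavailability)) {
    bkey <- paste(bioavailability$commodity_id, bioavailability$nutrient_id)
    hit <- match(key, bkey)
    coef[!is.na(hit)] <- bioavailability$coefficient[hit[!is.na(hit)]]
    defaulted <- scaled & is.na(hit) & gross > 0
  } else {
    defaulted <- scaled & gross > 0
  }
  if (any(defaulted)) {
    warning(sprintf(
      "bioavailability coefficient defaulted to 1 for %d (commodity, nutrient) pair(s) (e.g. %s)",
      sum(defaulted), grid$commodity_id[which(defaulted)[1]]), call. = FALSE)
  }
  bioavailable <- ifelse(scaled, gross * coef, gross)
  data.frame(
    commodity_id = grid$commodity_id,
    nutrient_id = grid$nutrient_id,
    unit = units$unit[match(grid$nutrient_id, units$nutrient_id)],
    gross = gross,
    bioavailable = bioavailable,
    stringsAsFactors = FALSE
  )
}

#' Aggregate nutrient availability by food group
#'
#' @param avail Data frame from [nutrient_availability()].
#' @param taxonomy Data frame mapping `commodity_id` to `group_id`
#'   (typically the balance table); every commodity must map to exactly
#'   one group.
#' @return Data frame with columns `group_id`, `nutrient_id`, `unit`,
#'   `gross`, `bioavailable`; group totals sum exactly to the global
#'   total for each nutrient.
#' @export
aggregate_by_group <- function(avail, taxonomy) {
  tax <- unique(as.data.frame(taxonomy)[c("commodity_id", "group_id")])
  if (anyDuplicated(tax$commodity_id)) {
    stop("commodity mapped to more than one group: ",
         paste(tax$commodity_id[duplicated(tax$commodity_id)],
               collapse = ", "), call. = FALSE)
  }
  group <- tax$group_id[match(avail$commodity_id, tax$commodity_id)]
  if (anyNA(group)) {
    stop("commodity(ies) not mapped to any group: ",
         paste(unique(avail$commodity_id[is.na(group)]), collapse = ", "),
         call. = FALSE)
  }
  g <- factor(group, levels = sort(unique(group)))
  n <- factor(avail$nutrient_id, levels = unique(avail$nutrient_id))
  # tapply sums each cell's records in input row order (commodity-major),
  # keeping accumulation order well defined for exact cross-checks
  gm <- tapply(avail$gross, list(g, n), sum)
  bm <- tapply(avail$bioavailable, list(g, n), sum)
  gm[is.na(gm)] <- 0
  bm[is.na(bm)] <- 0
  out <- data.frame(
    group_id = rep(levels(g), times = nlevels(n)),
    nutrient_id = rep(levels(n), each = nlevels(g)),
    gross = as.vector(gm),
    bioavailable = as.vector(bm),
    stringsAsFactors = FALSE
  )
  out$unit <- avail$unit[match(out$nutrient_id, avail$nutrient_id)]
  rownames(out) <- NULL
  out[c("group_id", "nutrient_id", "unit", "gross", "bioavailable")]
}

#' Decompose global availability into group contribution percentages
#'
#' For each nutrient, each group's share of the global total:
#' `100 * group / sum(groups)`.  On the `"mixed"` basis (default) the
#' bioavailable quantities are used for protein and the indispensable
#' amino acids and gross quantities for all other nutrients; `"gross"`
#' and `"bioavailable"` force one basis throughout.  A nutrient whose
#' global total is zero yields `NA` cells (undefined, not 0).
#'
#' @param group_totals Data frame from [aggregate_by_group()].
#' @param basis `"mixed"` (default), `"gross"` or `"bioavailable"`.
#' @return Data frame of class `nb_contributions` with columns
#'   `group_id`, `nutrient_id`, `percent`; attribute `basis`.
#' @export
contribution_percentages <- function(group_totals,
                                     basis = c("mixed", "gross",
                                               "bioavailable")) {
  basis <- match.arg(basis)
  value <- switch(basis,
    gross = group_totals$gross,
    bioavailable = group_totals$bioavailable,
    mixed = ifelse(group_totals$nutrient_id %in% bioavailable_nutrients(),
                   group_totals$bioavailable, group_totals$gross)
  )
  total <- tapply(value, group_totals$nutrient_id, sum)
  denom <- as.vector(total[group_totals$nutrient_id])
  percent <- ifelse(denom > 0, 100 * value / denom, NA_real_)
  out <- data.frame(group_id = group_totals$group_id,
                    nutrient_id = group_totals$nutrient_id,
                    percent = percent, stringsAsFactors = FALSE)
  structure(out, basis = basis,
            class = c("nb_contributions", "data.frame"))
}

#' Per-capita daily availability
#'
#' Divides an annual global total by population and days per year.  Mass
#' totals in tonnes are converted to grams per person per day; nutrient
#' totals stay in their registry unit.
#'
#' @param total Annual global total (registry unit, or tonnes when
#'   `mass_tonnes = TRUE`).
#' @param population Persons; must be positive.
#' @param days_per_year Days in the reference year (default 365).
#' @param mass_tonnes If `TRUE`, `total` is a mass in tonnes and the
#'   result is in grams per person per day.
#' @return Per-person per-day quantity.
#' @export
#' @examples
#' per_capita_daily(365, 1e6, mass_tonnes = TRUE)  # 1 g/person/day
per_capita_daily <- function(total, population, days_per_year = DAYS_PER_YEAR,
                             mass_tonnes = FALSE) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (mass_tonnes) total <- total * GRAMS_PER_TONNE
  total / (population * days_per_year)
}

#' Render a contribution table for display
#'
#' Applies the reporting convention of published contribution tables:
#' percentages are rounded half-up to whole numbers; values strictly
#' between 0 and 0.5 are shown as `"<0.5"`; exact zeros as
#' `"No contribution"`; undefined cells (zero global total) as `"n/a"`.
#' Raw values are preserved alongside.
#'
#' @param table An `nb_contributions` data frame.
#' @return The table with an added character column `display`.
#' @export
render_display <- function(table) {
  p <- table$percent
  display <- ifelse(
    is.na(p), "n/a",
    ifelse(p == 0, "No contribution",
           ifelse(p < 0.5, "<0.5",
                  formatC(round_half_up(p), format = "d"))))
  table$display <- display
  table
}

#' Parse a display-convention cell back to a number
#'
#' `"No contribution"` becomes 0, `"<0.5"` and `"n/a"` become `NA`
#' (the underlying value is not recoverable), anything else is parsed
#' numerically.
#'
#' @param x Character vector of display cells.
#' @return Numeric vector.
#' @export
parse_display <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "No contribution"] <- 0
  out
}

#' Reference table of meat contribution to 2018 global nutrient
#' availability
#'
#' Published model-derived estimates of the percentage of 2018 global
#' availability of each of the 29 nutrients provided by meat, with the
#' five-group disaggregation (ruminant, poultry, pig, other meat,
#' separated offal and fats).  Cells use the display convention of
#' [render_display()].  Shipped as a plain-text fixture for regression
#' and additivity checks.
#'
#' @return Data frame with columns `category`, `nutrient_id`, `all_meat`,
#'   `ruminant_meat`, `poultry_meat`, `pig_meat`, `other_meat`,
#'   `offal_and_fats` (display strings).
#' @export
meat_contribution_reference <- function() {
  read_table(system.file("extdata", "meat_contribution_2018.csv",
                         package = "nutribalance", mustWork = TRUE))
}
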