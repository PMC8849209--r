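# Counterfactual scenarios: food-group removal, production scaling,
# population change; nutrient-gap reports and replacement multipliers.

#' Declare a counterfactual scenario
#'
#' @param removals Character vector of group identifiers whose
#'   commodities are removed from the food system (entire ledgers set to
#'   zero).
#' @param scalings Named numeric vector of production multipliers per
#'   group (>= 0).  Groups not named receive `default_multiplier`.
#' @param default_multiplier Multiplier applied to groups neither removed
#'   nor listed in `scalings` (default 1).
#' @param target_year Optional year whose population row should be used.
#' @param population_override Optional headcount replacing the GLOBAL
#'   population.
#' @return An object of class `nb_scenario`.
#' @export
#' @examples
#' # remove all meat, grow everything else by 20%
#' scenario_spec(removals = meat_groups(), default_multiplier = 1.2)
scenario_spec <- function(removals = character(), scalings = numeric(),
                          default_multiplier = 1, target_year = NULL,
                          population_override = NULL) {
  if (length(scalings) && is.null(names(scalings))) {
    stop("scalings must be a named vector (group_id -> multiplier)",
         call. = FALSE)
  }
  if (any(scalings < 0) || default_multiplier < 0) {
    stop("multipliers must be >= 0", call. = FALSE)
  }
  both <- intersect(removals, names(scalings))
  if (length(both)) {
    stop("group(s) both removed and scaled: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(removals = removals, scalings = scalings,
                 default_multiplier = default_multiplier,
                 target_year = target_year,
                 population_override = population_override),
            class = "nb_scenario")
}

#' @export
print.nb_scenario <- function(x, ...) {
  cat("<nb_scenario>\n")
  cat("  removals:", if (length(x$removals))
    paste(x$removals, collapse = ", ") else "(none)", "\n")
  if (length(x$scalings)) {
    cat("  scalings:", paste(names(x$scalings), "x", x$scalings,
                             collapse = ", "), "\n")
  }
  cat("  default multiplier:", x$default_multiplier, "\n")
  if (!is.null(x$population_override)) {
    cat("  population override:", format(x$population_override), "\n")
  }
  invisible(x)
}

#' Read a scenario specification from YAML or JSON
#'
#' The file may contain `removals` (list), `scalings` (map of group to
#' multiplier), `default_multiplier`, `target_year`,
#' `population_override`.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`; YAML is a superset of
#'   JSON, so both parse).
#' @return An `nb_scenario`.
#' @export
read_scenario <- function(path) {
  spec <- yaml::read_yaml(path)
  scalings <- unlist(spec$scalings %||% numeric())
  if (length(scalings)) {
    scalings <- stats::setNames(as.numeric(scalings), names(scalings))
  }
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  scenario_spec(
    removals = as.character(spec$removals %||% character()),
    scalings = scalings,
    default_multiplier = as.numeric(spec$default_multiplier %||% 1),
    target_year = num_or_null(spec$target_year),
    population_override = num_or_null(spec$population_override)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a scenario to a dataset bundle
#'
#' Removed groups have every supply-side mass field of their commodities
#' set to zero.  Scaled groups have every mass field multiplied by their
#' multiplier, which scales the whole ledger uniformly and therefore
#' preserves each commodity's food fraction.  The identity scenario
#' returns the bundle unchanged.
#'
#' @param bundle An `nb_bundle`.
#' @param spec An `nb_scenario`.
#' @return The perturbed bundle.
#' @export
apply_scenario <- function(bundle, spec) {
  stopifnot(inherits(spec, "nb_scenario"))
  bal <- bundle$balances
  groups <- unique(bal$group_id)
  unknown <- setdiff(c(spec$removals, names(spec$scalings)), groups)
  if (length(unknown)) {
    stop("scenario names unknown group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mult <- rep(spec$default_multiplier, nrow(bal))
  if (length(spec$scalings)) {
    hit <- match(bal$group_id, names(spec$scalings))
    mult[!is.na(hit)] <- spec$scalings[hit[!is.na(hit)]]
  }
  mult[bal$group_id %in% spec$removals] <- 0
  if (!all(mult == 1)) {
    for (f in BALANCE_MASS_FIELDS) bal[[f]] <- bal[[f]] * mult
    if ("food" %in% names(bal)) bal$food <- bal$food * mult
    bundle$balances <- bal
  }
  if (!is.null(spec$population_override)) {
    if (spec$population_override <= 0) {
      stop("population_override must be > 0", call. = FALSE)
    }
    pop <- bundle$population
    year <- spec$target_year %||% max(pop$year)
    i <- which(pop$region_id == "GLOBAL" & pop$year == year)
    if (!length(i)) {
      pop <- rbind(pop, data.frame(region_id = "GLOBAL", year = year,
                                   headcount = spec$population_override))
    } else {
      pop$headcount[i] <- spec$population_override
    }
    bundle$population <- pop
  }
  bundle
}

# effective (bioavailability-adjusted where applicable) availability
# totals per group and per nutrient, plus population, for a bundle
scenario_state <- function(bundle, year = NULL) {
  food <- food_mass(bundle, year = year)
  avail <- nutrient_availability(food, bundle$composition,
                                 bundle$bioavailability,
                                 units = bundle$units)
  totals <- aggregate_by_group(avail, food)
  totals$effective <- ifelse(
    totals$nutrient_id %in% bioavailable_nutrients(),
    totals$bioavailable, totals$gross)
  list(food = food, totals = totals,
       population = global_population(bundle, year))
}

global_population <- function(bundle, year = NULL) {
  pop <- bundle$population
  if (is.null(year)) year <- max(pop$year)
  i <- which(pop$region_id == "GLOBAL" & pop$year == year)
  if (length(i)) return(pop$headcount[i[1]])
  i <- which(pop$year == year)
  if (!length(i)) stop("no population rows for year ", year, call. = FALSE)
  sum(pop$headcount[i])
}

#' Per-nutrient supply gaps against reference values
#'
#' Compares per-capita daily availability (bioavailable for protein and
#' the indispensable amino acids, gross otherwise) with the per-capita
#' daily requirement: `gap_percent = max(0, 100 * (1 - available /
#' requirement))`.  Nutrients without a requirement row are omitted with
#' a warning.
#'
#' @param bundle An `nb_bundle` (typically after [apply_scenario()]).
#' @param requirements Requirement table; defaults to the bundle's.
#' @param population Headcount; defaults to the bundle's GLOBAL row.
#' @param year Reference year.
#' @return Data frame with columns `nutrient_id`, `unit`,
#'   `available_per_capita_daily`, `requirement_per_capita_daily`,
#'   `gap_percent`, `surplus`.
#' @export
nutrient_gaps <- function(bundle, requirements = NULL, population = NULL,
                          year = NULL) {
  if (is.null(requirements)) requirements <- bundle$requirements
  if (!nrow(requirements)) stop("no requirement rows", call. = FALSE)
  if (any(requirements$per_capita_daily <= 0)) {
    stop("requirements must be positive", call. = FALSE)
  }
  st <- scenario_state(bundle, year = year)
  if (is.null(population)) population <- st$population
  tot <- tapply(st$totals$effective, st$totals$nutrient_id, sum)
  nutrients <- names(tot)
  covered <- nutrients %in% requirements$nutrient_id
  if (any(!covered)) {
    warning("nutrient(s) without requirement rows omitted: ",
            paste(nutrients[!covered], collapse = ", "), call. = FALSE)
  }
  nutrients <- nutrients[covered]
  avail_pc <- per_capita_daily(as.vector(tot[nutrients]), population)
  req <- requirements$per_capita_daily[match(nutrients,
                                             requirements$nutrient_id)]
  gap <- pmax(0, 100 * (1 - avail_pc / req))
  out <- data.frame(
    nutrient_id = nutrients,
    unit = bundle$units$unit[match(nutrients, bundle$units$nutrient_id)],
    available_per_capita_daily = avail_pc,
    requirement_per_capita_daily = req,
    gap_percent = gap,
    surplus = avail_pc >= req,
    stringsAsFactors = FALSE
  )
  out[order(match(out$nutrient_id, bundle$units$nutrient_id)), ,
      drop = FALSE]
}

#' Smallest donor scaling that closes a nutrient gap
#'
#' With the `removed_groups` zeroed out, returns the smallest multiplier
#' `m >= 1` such that scaling the donor group's production by `m` makes
#' per-capita availability of `nutrient` meet the requirement.  Solved in
#' closed form: `m = (R * P * 365 - A_other) / A_donor`, where `R` is the
#' per-capita daily requirement, `P` the population, `A_other` the annual
#' availability from all remaining non-donor sources and `A_donor` the
#' donor's baseline annual availability.  Returns `Inf` (cannot close)
#' when the donor supplies none of the nutrient.
#'
#' @param bundle Baseline `nb_bundle`.
#' @param donor_group Group to be scaled up.
#' @param removed_groups Groups removed from the system.
#' @param nutrient Nutrient identifier.
#' @param requirements,population,year As in [nutrient_gaps()].
#' @return A single multiplier (possibly `Inf`).
#' @export
replacement_multiplier <- function(bundle, donor_group, removed_groups,
                                   nutrient, requirements = NULL,
                                   population = NULL, year = NULL) {
  if (donor_group %in% removed_groups) {
    stop("donor group cannot also be removed", call. = FALSE)
  }
  if (is.null(requirements)) requirements <- bundle$requirements
  req <- requirements$per_capita_daily[match(nutrient,
                                             requirements$nutrient_id)]
  if (is.na(req) || req <= 0) {
    stop("no positive requirement for nutrient ", nutrient, call. = FALSE)
  }
  st <- scenario_state(bundle, year = year)
  if (is.null(population)) population <- st$population
  tot <- st$totals[st$totals$nutrient_id == nutrient, , drop = FALSE]
  groups <- setdiff(unique(st$food$group_id), removed_groups)
  if (!donor_group %in% unique(st$food$group_id)) {
    stop("unknown donor group: ", donor_group, call. = FALSE)
  }
  a_donor <- sum(tot$effective[tot$group_id == donor_group])
  a_other <- sum(tot$effective[tot$group_id %in% setdiff(groups,
                                                         donor_group)])
  needed <- req * population * DAYS_PER_YEAR
  if (a_donor <= 0) {
    warning("donor group supplies none of ", nutrient,
            "; gap cannot be closed by scaling", call. = FALSE)
    return(Inf)
  }
  max(1, (needed - a_other) / a_donor)
}
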