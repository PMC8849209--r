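# Top-level pipeline: run the whole mass-balance -> nutrient ->
# decomposition chain on a bundle and report results, with print and
# summary methods, plus the file-writing entry points the command-line
# interface wraps.

#' Run the full nutrient-availability model
#'
#' Executes every pipeline stage on a dataset bundle: commodity-tree
#' processing, net food supply, inedible/waste adjustment, conversion to
#' the 29-nutrient availability (gross and bioavailable), food-group
#' aggregation, contribution percentages and per-capita daily
#' availability, plus a headline summary for a set of focus groups
#' (by default the five meat groups).
#'
#' @param bundle An `nb_bundle`, or a directory path passed to
#'   [read_bundle()].
#' @param year Reference year (default: latest in the balances).
#' @param basis Contribution basis, see [contribution_percentages()].
#' @param focus_groups Groups summarised as the headline food group;
#'   groups absent from the bundle are ignored.  May be empty.
#' @param trade_mode Passed to [net_supply()].
#' @return An object of class `nb_model`: a list with elements
#'   `food` (per-commodity food-mass table), `availability`
#'   (commodity x nutrient), `group_totals`, `contributions` (with
#'   display column), `per_capita` (per nutrient), `focus` (headline
#'   summary or `NULL`), `population`, `year`, `basis`.
#' @export
#' @examples
#' fit <- nb_model(make_paperlike_world())
#' summary(fit)
nb_model <- function(bundle, year = NULL, basis = "mixed",
                     focus_groups = meat_groups(), trade_mode = "netted") {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "nb_bundle"))
  if (is.null(year)) year <- max(bundle$balances$year)
  if (!year %in% bundle$balances$year) {
    stop("reference year ", year, " not present in balances", call. = FALSE)
  }
  unknown <- setdiff(focus_groups, unique(bundle$balances$group_id))
  focus_groups <- intersect(focus_groups, unique(bundle$balances$group_id))

  food <- food_mass(bundle, year = year, trade_mode = trade_mode)
  avail <- nutrient_availability(food, bundle$composition,
                                 bundle$bioavailability,
                                 units = bundle$units)
  totals <- aggregate_by_group(avail, food)
  contributions <- render_display(contribution_percentages(totals, basis))
  population <- global_population(bundle, year)

  totals$effective <- ifelse(
    totals$nutrient_id %in% bioavailable_nutrients(),
    totals$bioavailable, totals$gross)
  global <- tapply(totals$effective, totals$nutrient_id, sum)
  nutrients <- bundle$units$nutrient_id
  per_capita <- data.frame(
    nutrient_id = nutrients,
    unit = bundle$units$unit,
    per_capita_daily = per_capita_daily(
      as.vector(global[nutrients]), population),
    stringsAsFactors = FALSE
  )

  focus <- NULL
  if (length(focus_groups)) {
    focus <- focus_summary(food, contributions, focus_groups, population)
  }
  structure(list(food = food, availability = avail, group_totals = totals,
                 contributions = contributions, per_capita = per_capita,
                 focus = focus, population = population, year = year,
                 basis = basis),
            class = "nb_model")
}

# headline block: focus-group share of food mass / energy / fat /
# protein, subgroup food-mass shares, per-capita focus mass
focus_summary <- function(food, contributions, focus_groups, population) {
  in_focus <- food$group_id %in% focus_groups
  total_mass <- sum(food$available_as_food)
  focus_mass <- sum(food$available_as_food[in_focus])
  by_group <- tapply(food$available_as_food[in_focus],
                     food$group_id[in_focus], sum)
  by_group <- by_group[intersect(focus_groups, names(by_group))]
  by_group <- stats::setNames(as.numeric(by_group), names(by_group))
  share_of <- function(nutrient) {
    rows <- contributions$group_id %in% focus_groups &
      contributions$nutrient_id == nutrient
    sum(contributions$percent[rows])
  }
  list(
    groups = focus_groups,
    mass_mt = focus_mass / 1e6,
    mass_share_pct = 100 * focus_mass / total_mass,
    subgroup_share_pct = 100 * by_group / focus_mass,
    per_capita_g_day = per_capita_daily(focus_mass, population,
                                        mass_tonnes = TRUE),
    energy_share_pct = share_of("energy"),
    fat_share_pct = share_of("fat"),
    protein_share_pct = share_of("protein")
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model>\n")
  cat(sprintf("  year %d, %d commodities, %d groups, basis '%s'\n",
              x$year, nrow(x$food), length(unique(x$food$group_id)),
              x$basis))
  cat(sprintf("  global food mass: %.1f Mt available, %.1f Mt consumed\n",
              sum(x$food$available_as_food) / 1e6,
              sum(x$food$consumed) / 1e6))
  if (!is.null(x$focus)) {
    cat(sprintf("  focus groups (%s): %.1f Mt, %.1f%% of food mass\n",
                paste(x$focus$groups, collapse = ", "),
                x$focus$mass_mt, x$focus$mass_share_pct))
  }
  invisible(x)
}

#' @export
summary.nb_model <- function(object, ...) {
  structure(object, class = c("summary.nb_model", class(object)))
}

#' @export
print.summary.nb_model <- function(x, ...) {
  print.nb_model(x)
  if (!is.null(x$focus)) {
    f <- x$focus
    cat(sprintf("  focus per-capita availability: %.1f g/person/day\n",
                f$per_capita_g_day))
    cat("  subgroup shares of focus food mass (%):\n")
    for (g in names(f$subgroup_share_pct)) {
      cat(sprintf("    %-18s %6.1f\n", g, f$subgroup_share_pct[[g]]))
    }
    cat(sprintf(
      "  focus share of energy %.1f%%, fat %.1f%%, protein %.1f%%\n",
      f$energy_share_pct, f$fat_share_pct, f$protein_share_pct))
  }
  contrib <- x$contributions
  focus_rows <- if (!is.null(x$focus)) {
    contrib[contrib$group_id %in% x$focus$groups, , drop = FALSE]
  } else contrib
  agg <- tapply(focus_rows$percent, focus_rows$nutrient_id, sum)
  shown <- sort(agg, decreasing = TRUE)
  shown <- shown[seq_len(min(8, length(shown)))]
  cat("  largest focus-group nutrient contributions (% of global):\n")
  for (n in names(shown)) {
    cat(sprintf("    %-14s %6.1f\n", n, shown[[n]]))
  }
  invisible(x)
}

#' Run the model and write its output tables
#'
#' The file-writing entry point behind the `run` subcommand: fits
#' [nb_model()] and writes `food_mass.csv`, `availability.csv`,
#' `contributions.csv` (raw and display columns), `per_capita.csv` and
#' `summary.csv` into `output_dir`.
#'
#' @param input Bundle or input directory.
#' @param output_dir Output directory (created if needed).
#' @param ... Passed to [nb_model()].
#' @return The fitted `nb_model`, invisibly.
#' @export
cmd_run <- function(input, output_dir, ...) {
  fit <- nb_model(input, ...)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(fit$food, file.path(output_dir, "food_mass.csv"))
  write_table(fit$availability, file.path(output_dir, "availability.csv"))
  write_table(fit$contributions, file.path(output_dir, "contributions.csv"))
  write_table(fit$per_capita, file.path(output_dir, "per_capita.csv"))
  if (!is.null(fit$focus)) {
    f <- fit$focus
    summary_df <- data.frame(
      quantity = c("focus_mass_mt", "focus_mass_share_pct",
                   "focus_per_capita_g_day", "focus_energy_share_pct",
                   "focus_fat_share_pct", "focus_protein_share_pct",
                   paste0("subgroup_share_pct:",
                          names(f$subgroup_share_pct))),
      value = c(f$mass_mt, f$mass_share_pct, f$per_capita_g_day,
                f$energy_share_pct, f$fat_share_pct, f$protein_share_pct,
                unname(f$subgroup_share_pct)),
      stringsAsFactors = FALSE
    )
    write_table(summary_df, file.path(output_dir, "summary.csv"))
  }
  invisible(fit)
}

#' Apply a scenario, run the model and write scenario outputs
#'
#' The entry point behind the `scenario` subcommand: perturbs the bundle
#' with [apply_scenario()], refits the model, writes the scenario
#' contribution table and the per-nutrient gap report (`gaps.csv`), and
#' optionally reports the replacement multiplier for a donor group and
#' nutrient.
#'
#' @param input Bundle or input directory.
#' @param scenario An `nb_scenario` or path to a YAML/JSON scenario file.
#' @param output_dir Output directory.
#' @param replace Optional list `list(donor = <group>, nutrient = <id>)`:
#'   report the smallest donor scaling closing that nutrient's gap under
#'   the scenario's removals.
#' @param ... Passed to [nb_model()].
#' @return List with elements `fit` (`nb_model` on the perturbed
#'   bundle), `gaps` (data frame) and `multiplier` (or `NULL`),
#'   invisibly.
#' @export
cmd_scenario <- function(input, scenario, output_dir, replace = NULL, ...) {
  if (is.character(input)) input <- read_bundle(input)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  perturbed <- apply_scenario(input, scenario)
  fit <- nb_model(perturbed, ...)
  gaps <- nutrient_gaps(perturbed, year = fit$year)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(fit$contributions,
              file.path(output_dir, "scenario_contributions.csv"))
  write_table(gaps, file.path(output_dir, "gaps.csv"))
  multiplier <- NULL
  if (!is.null(replace)) {
    multiplier <- replacement_multiplier(
      input, donor_group = replace$donor,
      removed_groups = scenario$removals, nutrient = replace$nutrient,
      year = fit$year)
    message(sprintf("replacement multiplier for %s via %s: %.6g",
                    replace$nutrient, replace$donor, multiplier))
  }
  invisible(list(fit = fit, gaps = gaps, multiplier = multiplier))
}
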