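# Input schemas, validation and CSV round-tripping.
#
# A dataset bundle is the unit every pipeline stage consumes: seven tables
# (balances, processing, composition, fractions, bioavailability,
# population, requirements) plus the nutrient unit registry.  All tables
# travel as plain comma-separated UTF-8 CSV with a header row and "."
# decimal; no other dialect is read or written.

BALANCE_MASS_FIELDS <- c("production", "imports", "exports", "feed", "seed",
                         "processing_input", "other_uses", "losses")

BUNDLE_FILES <- c(
  balances = "balances.csv", processing = "processing.csv",
  composition = "composition.csv", fractions = "fractions.csv",
  bioavailability = "bioavailability.csv", population = "population.csv",
  requirements = "requirements.csv", units = "units.csv"
)

#' Assemble a dataset bundle
#'
#' Collects the seven input tables and the unit registry into a single
#' validated object.  Empty data frames with the right columns are
#' substituted for omitted optional tables (`processing`,
#' `bioavailability`).
#'
#' @param balances Data frame of commodity supply ledgers: `commodity_id`,
#'   `group_id`, `year`, and the mass fields `production`, `imports`,
#'   `exports`, `feed`, `seed`, `processing_input`, `other_uses`,
#'   `losses`, all in tonnes.
#' @param processing Data frame of commodity-tree rules: `parent_id`,
#'   `child_id`, `extraction_rate` (mass fraction in (0, 1]).
#' @param composition Data frame: `commodity_id`, `nutrient_id`, `amount`
#'   (per 100 g edible portion; `NA` is an explicit missing marker),
#'   `unit`.
#' @param fractions Data frame: `kind` (`"inedible"` or `"waste"`),
#'   `commodity_id`, `region_id` (`"GLOBAL"` or a region; inedible rows
#'   must be GLOBAL), `fraction` in [0, 1).
#' @param bioavailability Data frame: `commodity_id`, `nutrient_id` (one
#'   of [bioavailable_nutrients()]), `coefficient` in (0, 1].
#' @param population Data frame: `region_id`, `year`, `headcount`.
#' @param requirements Data frame: `nutrient_id`, `per_capita_daily`.
#' @param units Unit registry data frame; defaults to
#'   [nutrient_registry()].
#' @param validate Validate before returning (default `TRUE`).
#' @param strict Passed to [validate_bundle()].
#' @return An object of class `nb_bundle`.
#' @export
nb_bundle <- function(balances, processing = NULL, composition,
                      fractions, bioavailability = NULL, population,
                      requirements, units = nutrient_registry(),
                      validate = TRUE, strict = TRUE) {
  if (is.null(processing)) {
    processing <- data.frame(parent_id = character(), child_id = character(),
                             extraction_rate = numeric(),
                             stringsAsFactors = FALSE)
  }
  if (is.null(bioavailability)) {
    bioavailability <- data.frame(commodity_id = character(),
                                  nutrient_id = character(),
                                  coefficient = numeric(),
                                  stringsAsFactors = FALSE)
  }
  bundle <- structure(
    list(balances = as.data.frame(balances),
         processing = as.data.frame(processing),
         composition = as.data.frame(composition),
         fractions = as.data.frame(fractions),
         bioavailability = as.data.frame(bioavailability),
         population = as.data.frame(population),
         requirements = as.data.frame(requirements),
         units = as.data.frame(units)),
    class = "nb_bundle"
  )
  if (validate) validate_bundle(bundle, strict = strict)
  bundle
}

#' @export
print.nb_bundle <- function(x, ...) {
  cat("<nb_bundle>\n")
  cat(sprintf("  commodities: %d (%d groups), year(s): %s\n",
              nrow(x$balances), length(unique(x$balances$group_id)),
              paste(sort(unique(x$balances$year)), collapse = ", ")))
  cat(sprintf("  processing rules: %d; composition rows: %d; nutrients: %d\n",
              nrow(x$processing), nrow(x$composition), nrow(x$units)))
  cat(sprintf("  fraction rows: %d; bioavailability rows: %d\n",
              nrow(x$fractions), nrow(x$bioavailability)))
  invisible(x)
}

# collect all invariant violations in one pass; returns character vector
bundle_problems <- function(bundle, strict = TRUE) {
  p <- character()
  bal <- bundle$balances
  need <- c("commodity_id", "group_id", "year", BALANCE_MASS_FIELDS)
  miss <- setdiff(need, names(bal))
  if (length(miss)) {
    return(sprintf("balances: missing column(s) %s",
                   paste(miss, collapse = ", ")))
  }
  for (f in BALANCE_MASS_FIELDS) {
    bad <- which(!is.na(bal[[f]]) & bal[[f]] < 0)
    if (length(bad)) {
      p <- c(p, sprintf("balances: negative %s for %s", f,
                        paste(bal$commodity_id[bad], collapse = ", ")))
    }
  }
  dup <- duplicated(bal[c("commodity_id", "year")])
  if (any(dup)) {
    p <- c(p, sprintf("balances: duplicate commodity/year: %s",
                      paste(unique(bal$commodity_id[dup]), collapse = ", ")))
  }

  known <- unique(c(bal$commodity_id, bundle$processing$child_id))

  pr <- bundle$processing
  if (nrow(pr)) {
    bad <- which(!(pr$extraction_rate > 0 & pr$extraction_rate <= 1))
    if (length(bad)) {
      p <- c(p, sprintf("processing: extraction_rate outside (0, 1] for %s",
                        paste(pr$parent_id[bad], collapse = ", ")))
    }
    sums <- tapply(pr$extraction_rate, pr$parent_id, sum)
    over <- names(sums)[sums > 1 + 1e-12]
    if (length(over)) {
      p <- c(p, sprintf("processing: extraction rates for parent %s sum to > 1",
                        paste(over, collapse = ", ")))
    }
    g <- igraph::graph_from_data_frame(pr[c("parent_id", "child_id")])
    if (!igraph::is_dag(g)) {
      p <- c(p, "processing: parent->child graph contains a cycle")
    }
    dangling <- setdiff(pr$parent_id, bal$commodity_id)
    if (length(dangling)) {
      p <- c(p, sprintf("processing: parent(s) not in balances: %s",
                        paste(dangling, collapse = ", ")))
    }
    dangling <- setdiff(pr$child_id, bal$commodity_id)
    if (length(dangling)) {
      p <- c(p, sprintf(
        "processing: child commodity(ies) lacking a balance row (needed for group membership): %s",
        paste(dangling, collapse = ", ")))
    }
  }

  comp <- bundle$composition
  reg <- bundle$units
  unknown <- setdiff(comp$commodity_id, known)
  if (length(unknown)) {
    p <- c(p, sprintf("composition: unknown commodity(ies): %s",
                      paste(unique(unknown), collapse = ", ")))
  }
  unknown <- setdiff(comp$nutrient_id, reg$nutrient_id)
  if (length(unknown)) {
    p <- c(p, sprintf("composition: nutrient(s) not in unit registry: %s",
                      paste(unique(unknown), collapse = ", ")))
  }
  bad <- which(!is.na(comp$amount) & comp$amount < 0)
  if (length(bad)) {
    p <- c(p, sprintf("composition: negative amount for %s",
                      paste(unique(comp$commodity_id[bad]), collapse = ", ")))
  }
  dup <- duplicated(comp[c("commodity_id", "nutrient_id")])
  if (any(dup)) {
    p <- c(p, sprintf("composition: duplicated (commodity, nutrient): %s",
                      paste(unique(paste(comp$commodity_id[dup],
                                         comp$nutrient_id[dup])),
                            collapse = ", ")))
  }
  if ("unit" %in% names(comp) && nrow(comp)) {
    want <- reg$unit[match(comp$nutrient_id, reg$nutrient_id)]
    bad <- which(!is.na(want) & !is.na(comp$unit) & comp$unit != want)
    if (length(bad)) {
      p <- c(p, sprintf("composition: unit mismatch vs registry for %s",
                        paste(unique(comp$nutrient_id[bad]), collapse = ", ")))
    }
  }
  if (strict && nrow(comp)) {
    # strict mode: every (commodity, nutrient) cell present, possibly as an
    # explicit NA marker; absent cells are errors
    have <- table(factor(comp$commodity_id, levels = unique(comp$commodity_id)))
    short <- names(have)[have < nrow(reg)]
    if (length(short)) {
      p <- c(p, sprintf(
        "composition: commodity(ies) missing cells for some of the %d registry nutrients: %s",
        nrow(reg), paste(short, collapse = ", ")))
    }
  }

  fr <- bundle$fractions
  if (nrow(fr)) {
    bad <- which(!(fr$fraction >= 0 & fr$fraction < 1))
    if (length(bad)) {
      p <- c(p, sprintf("fractions: fraction outside [0, 1) for %s",
                        paste(fr$commodity_id[bad], collapse = ", ")))
    }
    bad <- which(!fr$kind %in% c("inedible", "waste"))
    if (length(bad)) p <- c(p, "fractions: kind must be 'inedible' or 'waste'")
    bad <- which(fr$kind == "inedible" & fr$region_id != "GLOBAL")
    if (length(bad)) {
      p <- c(p, sprintf("fractions: inedible rows must have region_id GLOBAL (%s)",
                        paste(fr$commodity_id[bad], collapse = ", ")))
    }
    unknown <- setdiff(fr$commodity_id, known)
    if (length(unknown)) {
      p <- c(p, sprintf("fractions: unknown commodity(ies): %s",
                        paste(unique(unknown), collapse = ", ")))
    }
  }

  ba <- bundle$bioavailability
  if (nrow(ba)) {
    bad <- which(!(ba$coefficient > 0 & ba$coefficient <= 1))
    if (length(bad)) {
      p <- c(p, sprintf("bioavailability: coefficient outside (0, 1] for %s",
                        paste(ba$commodity_id[bad], collapse = ", ")))
    }
    bad <- setdiff(ba$nutrient_id, bioavailable_nutrients())
    if (length(bad)) {
      p <- c(p, sprintf(
        "bioavailability: only protein and indispensable amino acids permitted, got %s",
        paste(unique(bad), collapse = ", ")))
    }
    unknown <- setdiff(ba$commodity_id, known)
    if (length(unknown)) {
      p <- c(p, sprintf("bioavailability: unknown commodity(ies): %s",
                        paste(unique(unknown), collapse = ", ")))
    }
  }

  pop <- bundle$population
  if (!nrow(pop)) {
    p <- c(p, "population: at least one row required")
  } else if (any(pop$headcount <= 0)) {
    p <- c(p, "population: headcount must be > 0")
  }

  req <- bundle$requirements
  if (nrow(req) && any(req$per_capita_daily <= 0)) {
    p <- c(p, sprintf("requirements: per_capita_daily must be > 0 (%s)",
                      paste(req$nutrient_id[req$per_capita_daily <= 0],
                            collapse = ", ")))
  }
  p
}

#' Validate a dataset bundle
#'
#' Checks every table invariant (non-negative masses, fraction and
#' coefficient ranges, unit-registry agreement, referential integrity
#' across tables, acyclic processing graph with extraction-rate sums at
#' most 1) and stops with a message listing every violation found.
#'
#' @param bundle An `nb_bundle`.
#' @param strict If `TRUE` (default), absent composition cells are errors;
#'   if `FALSE` they are tolerated (downstream they contribute zero, with
#'   a warning).
#' @return The bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle, strict = TRUE) {
  p <- bundle_problems(bundle, strict = strict)
  if (length(p)) {
    stop("invalid bundle:\n  - ", paste(p, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(bundle)
}

#' Read a dataset bundle from a directory of CSV files
#'
#' Expects `balances.csv`, `composition.csv`, `fractions.csv`,
#' `population.csv`, `requirements.csv` and optionally `processing.csv`,
#' `bioavailability.csv`, `units.csv` (absent: default registry).  In
#' lenient mode absent composition cells are filled with explicit `NA`
#' missing markers, with a warning; in strict mode they are errors.
#'
#' @param dir Directory containing the CSV files.
#' @param strictness `"strict"` (default) or `"lenient"`.
#' @return A validated `nb_bundle`.
#' @export
read_bundle <- function(dir, strictness = c("strict", "lenient")) {
  strictness <- match.arg(strictness)
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  classes <- list(
    balances = c(commodity_id = "character", group_id = "character"),
    processing = c(parent_id = "character", child_id = "character",
                   extraction_rate = "numeric"),
    composition = c(commodity_id = "character", nutrient_id = "character",
                    amount = "numeric", unit = "character"),
    fractions = c(kind = "character", commodity_id = "character",
                  region_id = "character", fraction = "numeric"),
    bioavailability = c(commodity_id = "character",
                        nutrient_id = "character",
                        coefficient = "numeric"),
    population = c(region_id = "character", headcount = "numeric"),
    requirements = c(nutrient_id = "character",
                     per_capita_daily = "numeric"),
    units = c(nutrient_id = "character", unit = "character",
              class = "character")
  )
  tab <- function(name, required = TRUE) {
    path <- file.path(dir, BUNDLE_FILES[[name]])
    if (!file.exists(path)) {
      if (required) stop("missing input file: ", path, call. = FALSE)
      return(NULL)
    }
    out <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    # pin declared column types (a header-only file reads as all-logical)
    for (col in intersect(names(out), names(classes[[name]]))) {
      out[[col]] <- switch(classes[[name]][[col]],
                           character = as.character(out[[col]]),
                           numeric = as.numeric(out[[col]]))
    }
    out
  }
  units <- tab("units", required = FALSE)
  if (is.null(units)) units <- nutrient_registry()
  composition <- tab("composition")
  if (strictness == "lenient") {
    composition <- fill_missing_cells(composition, units)
  }
  nb_bundle(
    balances = tab("balances"),
    processing = tab("processing", required = FALSE),
    composition = composition,
    fractions = tab("fractions"),
    bioavailability = tab("bioavailability", required = FALSE),
    population = tab("population"),
    requirements = tab("requirements"),
    units = units,
    strict = (strictness == "strict")
  )
}

# add explicit NA marker rows for absent (commodity, nutrient) cells
fill_missing_cells <- function(composition, units) {
  full <- expand.grid(commodity_id = unique(composition$commodity_id),
                      nutrient_id = units$nutrient_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(composition$commodity_id, composition$nutrient_id)
  absent <- full[!paste(full$commodity_id, full$nutrient_id) %in% key, ]
  if (nrow(absent)) {
    warning(sprintf(
      "%d absent composition cell(s) treated as explicit missing values (first: %s/%s)",
      nrow(absent), absent$commodity_id[1], absent$nutrient_id[1]),
      call. = FALSE)
    absent$amount <- NA_real_
    absent$unit <- units$unit[match(absent$nutrient_id, units$nutrient_id)]
    composition <- rbind(composition[names(absent)], absent)
  }
  composition
}

#' Write a dataset bundle to a directory of CSV files
#'
#' @param bundle An `nb_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(BUNDLE_FILES)) {
    write_table(bundle[[name]], file.path(dir, BUNDLE_FILES[[name]]))
  }
  invisible(dir)
}

#' Write a table as CSV
#'
#' One fixed dialect: comma-separated, UTF-8, header row, `"."` decimal,
#' no row names, full double precision (so a round trip through
#' [read_table()] reproduces the table exactly).
#'
#' @param table A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)
  # full 17 significant digits so numeric round trips are exact
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.17g", df[[j]])
      df[[j]][df[[j]] %in% c("NA", "nan")] <- NA
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
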