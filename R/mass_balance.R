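# Supply-side mass balance: net food supply, commodity-tree processing,
# inedible-portion and in-home-waste adjustment.

#' Net supply of food from a commodity ledger
#'
#' For each balance row computes
#' `production + imports - exports - feed - seed - other_uses - losses -
#' processing_input`, i.e. the mass available as food.  Negative results
#' are clamped to zero with a warning (stock variation is not modelled).
#' In `strict_zero` trade mode, a commodity whose global net trade does
#' not cancel (`|imports - exports| > tolerance * production`) is an
#' error: at world level exports must equal imports.
#'
#' @param balances Data frame with the ledger columns of
#'   `balances.csv` (one or more rows).
#' @param trade_mode `"netted"` (default) or `"strict_zero"`.
#' @param tolerance Relative tolerance for the strict trade check
#'   (default `1e-6` of production).
#' @return Numeric vector of food-available mass in tonnes, named by
#'   `commodity_id`.
#' @export
#' @examples
#' b <- data.frame(commodity_id = "beef", group_id = "ruminant_meat",
#'                 year = 2018, production = 100, imports = 0, exports = 0,
#'                 feed = 3, seed = 0, processing_input = 0, other_uses = 0,
#'                 losses = 2)
#' net_supply(b)  # 95
net_supply <- function(balances, trade_mode = c("netted", "strict_zero"),
                       tolerance = 1e-6) {
  trade_mode <- match.arg(trade_mode)
  b <- as.data.frame(balances)
  if (trade_mode == "strict_zero") {
    imbalance <- abs(b$imports - b$exports) > tolerance * b$production
    if (any(imbalance)) {
      stop("global net trade does not cancel for: ",
           paste(b$commodity_id[imbalance], collapse = ", "), call. = FALSE)
    }
  }
  out <- b$production + b$imports - b$exports - b$feed - b$seed -
    b$other_uses - b$losses - b$processing_input
  neg <- out < 0
  if (any(neg)) {
    warning("negative net supply clamped to zero for: ",
            paste(b$commodity_id[neg], collapse = ", "), call. = FALSE)
    out[neg] <- 0
  }
  names(out) <- b$commodity_id
  out
}

#' Apply commodity-tree processing rules
#'
#' Distributes each parent's `processing_input` mass to its child
#' commodities as `child production += extraction_rate * parent
#' processing_input`; the residual `(1 - sum of rates)` share leaves the
#' food system (bone meal, hides, industrial render).  Children carry
#' their own `group_id` through their balance rows, which is how, e.g.,
#' separated offal and fats split off from carcass commodities into their
#' own food group.  Rules are applied in topological order of the
#' parent-child graph so multi-level chains (animal -> carcass -> cuts)
#' compose.
#'
#' @param balances Balance data frame.
#' @param rules Processing-rule data frame (`parent_id`, `child_id`,
#'   `extraction_rate`); may be empty.
#' @return The balance data frame with child production incremented.
#' @export
apply_processing <- function(balances, rules) {
  b <- as.data.frame(balances)
  r <- as.data.frame(rules)
  if (!nrow(r)) return(b)
  bad <- which(!(r$extraction_rate > 0 & r$extraction_rate <= 1))
  if (length(bad)) stop("extraction_rate outside (0, 1]", call. = FALSE)
  sums <- tapply(r$extraction_rate, r$parent_id, sum)
  if (any(sums > 1 + 1e-12)) {
    stop("extraction rates exceed 1 for parent: ",
         paste(names(sums)[sums > 1 + 1e-12], collapse = ", "),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(r[c("parent_id", "child_id")])
  if (!igraph::is_dag(g)) {
    stop("processing rules contain a cycle", call. = FALSE)
  }
  order_ids <- names(igraph::topo_sort(g, mode = "out"))
  for (parent in intersect(order_ids, unique(r$parent_id))) {
    i <- match(parent, b$commodity_id)
    if (is.na(i)) stop("processing parent not in balances: ", parent,
                       call. = FALSE)
    input <- b$processing_input[i]
    if (input == 0) next
    for (k in which(r$parent_id == parent)) {
      j <- match(r$child_id[k], b$commodity_id)
      if (is.na(j)) stop("processing child not in balances: ", r$child_id[k],
                         call. = FALSE)
      b$production[j] <- b$production[j] + r$extraction_rate[k] * input
    }
  }
  b
}

#' Edible and consumed mass after inedible-portion and waste adjustment
#'
#' From the mass available as food, the inedible portion (bone, skin,
#' ...) is removed first, then the in-home waste share of the edible
#' mass, approximating the mass actually consumed:
#' `edible = available * (1 - inedible)`, `consumed = edible *
#' (1 - waste)`.  The component masses are reported such that mass is
#' conserved exactly: `available = consumed + inedible_mass +
#' wasted_mass`.
#'
#' @param available_as_food Numeric vector of food-available mass
#'   (tonnes).
#' @param inedible_fraction,waste_fraction Fractions in [0, 1), recycled
#'   against `available_as_food`.
#' @param commodity_id Optional identifiers for the output rows.
#' @return Data frame with columns `available_as_food`,
#'   `edible_available`, `consumed`, `inedible_mass`, `wasted_mass` (and
#'   `commodity_id` first when given).
#' @export
#' @examples
#' consumed_mass(100, 0.20, 0.10)  # consumed 72, inedible 20, wasted 8
consumed_mass <- function(available_as_food, inedible_fraction,
                          waste_fraction, commodity_id = NULL) {
  if (any(inedible_fraction < 0 | inedible_fraction >= 1) ||
      any(waste_fraction < 0 | waste_fraction >= 1)) {
    stop("fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(available_as_food < 0)) {
    stop("available_as_food must be >= 0", call. = FALSE)
  }
  available_as_food <- as.vector(available_as_food)
  edible <- available_as_food * (1 - inedible_fraction)
  consumed <- edible * (1 - waste_fraction)
  # residuals by subtraction so the conservation identity is exact
  out <- data.frame(
    available_as_food = available_as_food,
    edible_available = edible,
    consumed = consumed,
    inedible_mass = available_as_food - edible,
    wasted_mass = edible - consumed
  )
  if (!is.null(commodity_id)) out <- cbind(commodity_id, out)
  out
}

# global waste fraction per commodity: regional rows averaged with
# regional population headcounts as weights (per-capita food mass assumed
# uniform, so population shares stand in for food-mass shares); a GLOBAL
# row, when present, takes precedence
waste_fraction_global <- function(fractions, population, commodity_id,
                                  year = NULL) {
  w <- fractions[fractions$kind == "waste", , drop = FALSE]
  pop <- population
  if (!is.null(year) && any(pop$year == year)) pop <- pop[pop$year == year, ]
  vapply(commodity_id, function(cid) {
    rows <- w[w$commodity_id == cid, , drop = FALSE]
    if (!nrow(rows)) return(0)
    if ("GLOBAL" %in% rows$region_id) {
      return(rows$fraction[match("GLOBAL", rows$region_id)])
    }
    wt <- pop$headcount[match(rows$region_id, pop$region_id)]
    if (anyNA(wt)) wt <- rep(1, nrow(rows))
    sum(rows$fraction * wt) / sum(wt)
  }, numeric(1))
}

inedible_fraction_of <- function(fractions, commodity_id) {
  ie <- fractions[fractions$kind == "inedible", , drop = FALSE]
  out <- ie$fraction[match(commodity_id, ie$commodity_id)]
  out[is.na(out)] <- 0
  out
}

#' Per-commodity food mass accounting for a bundle
#'
#' Runs the full mass-balance stage: commodity-tree processing, net food
#' supply, then inedible-portion and waste adjustment, yielding one row
#' per commodity.
#'
#' @param bundle A validated `nb_bundle`.
#' @param year Reference year; default: the most recent year in the
#'   balances.
#' @param trade_mode Passed to [net_supply()].
#' @return Data frame with columns `commodity_id`, `group_id`,
#'   `available_as_food`, `edible_available`, `consumed`,
#'   `inedible_mass`, `wasted_mass` (tonnes).
#' @export
food_mass <- function(bundle, year = NULL, trade_mode = "netted") {
  bal <- bundle$balances
  if (is.null(year)) year <- max(bal$year)
  bal <- bal[bal$year == year, , drop = FALSE]
  if (!nrow(bal)) stop("no balance rows for year ", year, call. = FALSE)
  bal <- apply_processing(bal, bundle$processing)
  available <- net_supply(bal, trade_mode = trade_mode)
  inedible <- inedible_fraction_of(bundle$fractions, bal$commodity_id)
  waste <- unname(waste_fraction_global(bundle$fractions, bundle$population,
                                        bal$commodity_id, year = year))
  out <- consumed_mass(available, inedible, waste,
                       commodity_id = bal$commodity_id)
  cbind(out[1], group_id = bal$group_id, out[-1])
}
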