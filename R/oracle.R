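# Independent brute-force recomputation of every pipeline quantity by
# naive per-record iteration.  Shares no helper with the vectorized
# pipeline (only the unit constants, which define the model, not the
# implementation); output schemas are identical so results can be
# compared cell by cell.

#' Brute-force oracle for a dataset bundle
#'
#' Recomputes food mass, nutrient availability, group contribution
#' percentages and nutrient gaps by explicit loops over records, one
#' commodity and one nutrient at a time.  Intended for small worlds
#' (<= 100 commodities); used to cross-check the pipeline exactly.
#'
#' @param bundle A validated `nb_bundle`.
#' @param year Reference year (default: latest in the balances).
#' @param basis Basis for contribution percentages (see
#'   [contribution_percentages()]).
#' @return List with elements `food`, `availability`, `contributions`,
#'   `gaps`, schema-identical to the pipeline outputs.
#' @export
oracle_outputs <- function(bundle, year = NULL, basis = "mixed") {
  bal <- bundle$balances
  if (is.null(year)) year <- max(bal$year)
  bal <- bal[bal$year == year, , drop = FALSE]
  if (nrow(bal) > 100) stop("oracle is for small worlds", call. = FALSE)
  units <- bundle$units
  scaled_set <- bioavailable_nutrients()

  # -- processing: single pass over rules (inputs are ledger data) ------
  production <- bal$production
  names(production) <- bal$commodity_id
  rules <- bundle$processing
  if (nrow(rules)) {
    for (k in seq_len(nrow(rules))) {
      inp <- bal$processing_input[bal$commodity_id == rules$parent_id[k]]
      production[rules$child_id[k]] <-
        production[rules$child_id[k]] + rules$extraction_rate[k] * inp
    }
  }

  # -- per-commodity food mass ------------------------------------------
  pop <- bundle$population
  pop_y <- if (any(pop$year == year)) pop[pop$year == year, ] else pop
  food_rows <- vector("list", nrow(bal))
  for (i in seq_len(nrow(bal))) {
    b <- bal[i, ]
    av <- production[[b$commodity_id]] + b$imports - b$exports - b$feed -
      b$seed - b$other_uses - b$losses - b$processing_input
    if (av < 0) av <- 0
    ie <- bundle$fractions[bundle$fractions$kind == "inedible" &
                             bundle$fractions$commodity_id == b$commodity_id, ]
    ie <- if (nrow(ie)) ie$fraction[1] else 0
    wa_rows <- bundle$fractions[bundle$fractions$kind == "waste" &
                                  bundle$fractions$commodity_id ==
                                  b$commodity_id, , drop = FALSE]
    if (!nrow(wa_rows)) {
      wa <- 0
    } else if ("GLOBAL" %in% wa_rows$region_id) {
      wa <- wa_rows$fraction[wa_rows$region_id == "GLOBAL"][1]
    } else {
      wt <- pop_y$headcount[match(wa_rows$region_id, pop_y$region_id)]
      if (anyNA(wt)) wt <- rep(1, nrow(wa_rows))
      wa <- sum(wa_rows$fraction * wt) / sum(wt)
    }
    edible <- av * (1 - ie)
    cons <- edible * (1 - wa)
    food_rows[[i]] <- data.frame(
      commodity_id = b$commodity_id, group_id = b$group_id,
      available_as_food = av, edible_available = edible, consumed = cons,
      inedible_mass = av - edible, wasted_mass = edible - cons,
      stringsAsFactors = FALSE)
  }
  food <- do.call(rbind, food_rows)

  # -- per-record nutrient availability ---------------------------------
  comp_key <- paste(bundle$composition$commodity_id,
                    bundle$composition$nutrient_id)
  ba_key <- paste(bundle$bioavailability$commodity_id,
                  bundle$bioavailability$nutrient_id)
  avail_rows <- list()
  r <- 0L
  for (i in seq_len(nrow(food))) {
    for (j in seq_len(nrow(units))) {
      nut <- units$nutrient_id[j]
      k <- match(paste(food$commodity_id[i], nut), comp_key)
      amt <- if (is.na(k)) NA_real_ else bundle$composition$amount[k]
      if (is.na(amt)) amt <- 0
      gross <- food$consumed[i] * 1e4 * amt
      bio <- gross
      if (nut %in% scaled_set) {
        k <- match(paste(food$commodity_id[i], nut), ba_key)
        coef <- if (is.na(k)) 1 else bundle$bioavailability$coefficient[k]
        bio <- gross * coef
      }
      r <- r + 1L
      avail_rows[[r]] <- data.frame(
        commodity_id = food$commodity_id[i], nutrient_id = nut,
        unit = units$unit[j], gross = gross, bioavailable = bio,
        stringsAsFactors = FALSE)
    }
  }
  availability <- do.call(rbind, avail_rows)

  # -- group totals and contribution percentages ------------------------
  group_ids <- sort(unique(food$group_id))
  contrib_rows <- list()
  r <- 0L
  for (j in seq_len(nrow(units))) {
    nut <- units$nutrient_id[j]
    use_bio <- switch(basis,
                      gross = FALSE,
                      bioavailable = TRUE,
                      mixed = nut %in% scaled_set)
    per_group <- numeric(length(group_ids))
    for (gi in seq_along(group_ids)) {
      vals <- numeric(0)
      for (i in seq_len(nrow(food))) {
        if (food$group_id[i] != group_ids[gi]) next
        row <- availability[availability$commodity_id ==
                              food$commodity_id[i] &
                              availability$nutrient_id == nut, ]
        vals <- c(vals, if (use_bio) row$bioavailable else row$gross)
      }
      per_group[gi] <- sum(vals)
    }
    denom <- sum(per_group)
    for (gi in seq_along(group_ids)) {
      r <- r + 1L
      contrib_rows[[r]] <- data.frame(
        group_id = group_ids[gi], nutrient_id = nut,
        percent = if (denom > 0) 100 * per_group[gi] / denom else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  contributions <- structure(do.call(rbind, contrib_rows), basis = basis,
                             class = c("nb_contributions", "data.frame"))

  # -- per-capita gaps ---------------------------------------------------
  gp <- pop$headcount[pop$region_id == "GLOBAL" & pop$year == year]
  if (!length(gp)) gp <- sum(pop_y$headcount)
  gp <- gp[1]
  req <- bundle$requirements
  gap_rows <- list()
  r <- 0L
  for (j in seq_len(nrow(units))) {
    nut <- units$nutrient_id[j]
    k <- match(nut, req$nutrient_id)
    if (is.na(k)) next
    vals <- numeric(0)
    for (gi in seq_along(group_ids)) {
      per_c <- numeric(0)
      for (i in seq_len(nrow(food))) {
        if (food$group_id[i] != group_ids[gi]) next
        row <- availability[availability$commodity_id ==
                              food$commodity_id[i] &
                              availability$nutrient_id == nut, ]
        per_c <- c(per_c, if (nut %in% scaled_set) row$bioavailable
                   else row$gross)
      }
      vals <- c(vals, sum(per_c))
    }
    total <- sum(vals)
    apc <- total / (gp * 365)
    g <- max(0, 100 * (1 - apc / req$per_capita_daily[k]))
    r <- r + 1L
    gap_rows[[r]] <- data.frame(
      nutrient_id = nut,
      unit = units$unit[j],
      available_per_capita_daily = apc,
      requirement_per_capita_daily = req$per_capita_daily[k],
      gap_percent = g,
      surplus = apc >= req$per_capita_daily[k],
      stringsAsFactors = FALSE)
  }
  gaps <- do.call(rbind, gap_rows)
  list(food = food, availability = availability,
       contributions = contributions, gaps = gaps)
}
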