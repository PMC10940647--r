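# Stage 4: gross-margin economics with density-responsive winter-wheat
# yield. All numeric tables (prices, base yields, yield penalties) are
# editable packaged stand-ins at 2019-plausible UK levels; the published
# model's own equation set and parameter tables are not public, so nothing
# here asserts their values — the module's contract is the accounting
# structure (itemised costs, density-weighted output, exact gross-margin
# identity).

#' Packaged 2019 price table (synthetic stand-in)
#'
#' Crop prices (GBP/t), herbicide product costs (GBP/l), per-pass operation
#' costs (GBP/ha, fuel + labour) and per-crop "other" costs (fertiliser,
#' seed, sundries; GBP/ha).
#'
#' @param file Optional CSV path overriding the packaged defaults
#'   (`key,item,value` rows).
#' @return A list of class `price_table` with components `crop_price`,
#'   `herbicide_cost`, `operation_cost`, `other_cost`, `price_year`.
#' @export
gen_price_tables <- function(file = NULL) {
  if (!is.null(file)) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    grab <- function(key) {
      d <- df[df$key == key, ]
      stats::setNames(d$value, d$item)
    }
    pt <- list(crop_price = grab("crop_price"),
               herbicide_cost = grab("herbicide_cost"),
               operation_cost = grab("operation_cost"),
               other_cost = grab("other_cost"),
               price_year = 2019L)
  } else {
    pt <- list(
      crop_price = c(winter_wheat = 150, winter_oilseed_rape = 330,
                     winter_barley = 135, spring_barley = 145,
                     spring_beans = 200, spring_oats = 130,
                     spring_wheat = 155, fallow = 0, cover_crop = 0),
      herbicide_cost = c(glyphosate = 5, selective = 25),
      operation_cost = c(drilling = 60, inversion_plough = 85, min_till = 45,
                         no_till = 15, spray_pass = 12, stale_seedbed = 25),
      other_cost = c(winter_wheat = 380, winter_oilseed_rape = 330,
                     winter_barley = 340, spring_barley = 280,
                     spring_beans = 250, spring_oats = 260,
                     spring_wheat = 300, fallow = 40, cover_crop = 90),
      price_year = 2019L)
  }
  if (any(unlist(pt[1:4]) < 0)) stop("prices must be >= 0")
  miss <- setdiff(crop_vocabulary(), names(pt$crop_price))
  if (length(miss)) stop("unpriced crop(s): ", paste(miss, collapse = ", "))
  class(pt) <- "price_table"
  pt
}

#' Packaged base-yield table (synthetic stand-in)
#'
#' Weed-free potential yields (t/ha) per crop, adjusted by soil and region
#' multipliers.
#'
#' @return Function of `(crop, soil, region)` returning t/ha, of class
#'   `base_yield_table`.
#' @export
gen_base_yields <- function() {
  base <- c(winter_wheat = 8.5, winter_oilseed_rape = 3.5,
            winter_barley = 7.0, spring_barley = 5.8, spring_beans = 4.2,
            spring_oats = 5.4, spring_wheat = 6.5, fallow = 0,
            cover_crop = 0)
  soil_mult <- c(heavy = 1.05, medium = 1.0, light = 0.88)
  region_mult <- c(north = 0.95, central = 1.0, east = 1.05)
  f <- function(crop, soil, region) {
    crop <- match.arg(crop, crop_vocabulary())
    unname(base[crop] * soil_mult[match.arg(soil, names(soil_mult))] *
             region_mult[match.arg(region, names(region_mult))])
  }
  class(f) <- c("base_yield_table", class(f))
  f
}

#' Winter-wheat yield-penalty table
#'
#' Proportional yield losses per density state with lower/central/upper
#' limits for sensitivity analysis. States below `high` carry zero penalty
#' (they are not economically damaging). Defaults: loss(high) = 0.15,
#' loss(very_high) = 0.35, bounds +/- 50% — labelled stand-ins.
#'
#' @param central_high,central_very_high Central proportional losses.
#' @param rel_bounds Relative half-width of the (lower, upper) band.
#' @return Matrix 5 states x 3 bounds of class `yield_penalty_table`.
#' @export
yield_penalty_table <- function(central_high = 0.15,
                                central_very_high = 0.35,
                                rel_bounds = 0.5) {
  if (central_high < 0 || central_very_high > 1 ||
      central_high > central_very_high) {
    stop("need 0 <= loss(high) <= loss(very_high) <= 1")
  }
  central <- c(0, 0, 0, central_high, central_very_high)
  tab <- cbind(lower = pmax(central * (1 - rel_bounds), 0),
               central = central,
               upper = pmin(central * (1 + rel_bounds), 1))
  rownames(tab) <- density_states()
  if (any(tab[, "lower"] > tab[, "central"] |
          tab[, "central"] > tab[, "upper"])) {
    stop("penalty bounds must satisfy lower <= central <= upper")
  }
  class(tab) <- c("yield_penalty_table", class(tab))
  tab
}

#' Density-weighted winter-wheat yield
#'
#' `yield = base * sum_s p_s (1 - loss_s)`; only winter wheat responds to
#' weed density, so non-wheat crops bypass this operation.
#'
#' @param base Weed-free potential yield (t/ha).
#' @param d A `density_distribution`.
#' @param penalties A [yield_penalty_table()].
#' @param bound "lower", "central" or "upper" penalty limit.
#' @return Yield in t/ha.
#' @examples
#' wheat_yield(8, c(0.1, 0.1, 0.2, 0.3, 0.3),
#'             yield_penalty_table(0.15, 0.35))
#' @export
wheat_yield <- function(base, d, penalties = yield_penalty_table(),
                        bound = c("central", "lower", "upper")) {
  bound <- match.arg(bound)
  d <- density_distribution(d)
  stopifnot(base >= 0)
  base * sum(d * (1 - penalties[, bound]))
}

#' Itemised variable costs for one management year
#'
#' Herbicide = glyphosate dose x cost + selective dose x cost. Operations =
#' tillage pass + drilling (when a crop is sown) + one pass per herbicide
#' application + one pass per stale seedbed. Other = the crop's fertiliser /
#' seed / sundry total, scaled by seed rate for the seed share.
#'
#' @param year A [management_year()].
#' @param prices A `price_table`.
#' @return Named numeric vector `c(herbicide, operations, other)` in GBP/ha.
#' @export
year_costs <- function(year, prices = gen_price_tables()) {
  stopifnot(inherits(year, "management_year"), inherits(prices, "price_table"))
  hc <- prices$herbicide_cost
  herbicide <- year$glyphosate_dose * hc[["glyphosate"]] +
    year$selective_dose * hc[["selective"]]
  oc <- prices$operation_cost
  drills <- as.numeric(year$sowing_window != "none")
  spray_passes <- year$glyphosate_applications + year$selective_applications
  operations <- oc[[year$tillage]] + drills * oc[["drilling"]] +
    spray_passes * oc[["spray_pass"]] +
    year$n_stale_seedbeds * oc[["stale_seedbed"]]
  if (!year$crop %in% names(prices$other_cost)) {
    stop("no 'other' costs priced for crop ", year$crop)
  }
  other <- prices$other_cost[[year$crop]] * (0.7 + 0.3 * year$seed_rate)
  c(herbicide = herbicide, operations = operations, other = other)
}

#' Economics of one year under a given density distribution
#'
#' Output = yield x crop price (winter-wheat yield is density-weighted,
#' other crops use their base yield); potential output is the zero-weed
#' equivalent; gross profit = output - total costs, an exact identity.
#'
#' @param year A [management_year()].
#' @param d `density_distribution` in force during the year.
#' @param prices A `price_table`.
#' @param base_yields A [gen_base_yields()] function.
#' @param penalties A [yield_penalty_table()].
#' @param bound Penalty limit.
#' @param soil,region Used to look up the base yield.
#' @return One-row data frame: crop, yield, wheat_yield, output,
#'   potential_output, cost_herbicide, cost_operations, cost_other,
#'   gross_profit.
#' @export
gross_profit_year <- function(year, d, prices = gen_price_tables(),
                              base_yields = gen_base_yields(),
                              penalties = yield_penalty_table(),
                              bound = "central", soil = "medium",
                              region = "central") {
  base <- base_yields(year$crop, soil, region)
  yld <- if (year$crop == "winter_wheat") {
    wheat_yield(base, d, penalties, bound)
  } else base
  price <- prices$crop_price[[year$crop]]
  costs <- year_costs(year, prices)
  output <- yld * price
  potential <- base * price
  data.frame(crop = year$crop, yield = yld,
             wheat_yield = if (year$crop == "winter_wheat") yld else 0,
             output = output, potential_output = potential,
             cost_herbicide = unname(costs["herbicide"]),
             cost_operations = unname(costs["operations"]),
             cost_other = unname(costs["other"]),
             gross_profit = output - sum(costs),
             stringsAsFactors = FALSE)
}

#' Rotation-level economic summary under a density trajectory
#'
#' Runs [gross_profit_year()] for every year of the plan and every
#' imputation, using the trajectory's year-t distribution for year t, then
#' averages over the rotation. Mean annual wheat yield is total wheat
#' produced divided by rotation length (so per-year figures are comparable
#' across scenarios growing wheat at different frequencies). The envelope is
#' the min/max across imputations.
#'
#' @param plan A `strategy`, `sequence_plan` or list of management years.
#' @param trajectory A `density_trajectory` covering the plan.
#' @param prices,base_yields,penalties,bound,soil,region As in
#'   [gross_profit_year()]; `soil`/`region` default to the plan's target
#'   when it has one.
#' @return List of class `econ_result`: `per_year` (data frame over
#'   imputation x year), `mean_gross_profit`, `mean_wheat_yield`,
#'   `annual_gross_profit` / `annual_wheat_yield` (per-year, averaged over
#'   imputations), and min/max envelopes of the two rotation means.
#' @export
rotation_summary <- function(plan, trajectory, prices = gen_price_tables(),
                             base_yields = gen_base_yields(),
                             penalties = yield_penalty_table(),
                             bound = "central", soil = NULL, region = NULL) {
  years <- plan_years(plan)
  T_len <- length(years)
  stopifnot(inherits(trajectory, "density_trajectory"),
            max(trajectory$years) >= T_len)
  if (is.null(soil)) soil <- if (!is.null(plan$target)) plan$target$soil
                             else "medium"
  if (is.null(region)) region <- if (!is.null(plan$target))
                                   plan$target$region else "central"
  n_imp <- dim(trajectory$p)[1]
  per_year <- do.call(rbind, lapply(seq_len(n_imp), function(j) {
    do.call(rbind, lapply(seq_len(T_len), function(t) {
      d <- trajectory_distribution(trajectory, t, j)
      row <- gross_profit_year(years[[t]], d, prices, base_yields,
                               penalties, bound, soil, region)
      cbind(imputation = j, year = t, row)
    }))
  }))
  by_imp_gp <- tapply(per_year$gross_profit, per_year$imputation, mean)
  by_imp_wy <- tapply(per_year$wheat_yield, per_year$imputation,
                      function(x) sum(x) / T_len)
  structure(list(
    per_year = per_year,
    mean_gross_profit = mean(by_imp_gp),
    mean_wheat_yield = mean(by_imp_wy),
    annual_gross_profit = as.numeric(tapply(per_year$gross_profit,
                                            per_year$year, mean)),
    annual_wheat_yield = as.numeric(tapply(per_year$wheat_yield,
                                           per_year$year, mean)),
    envelope = list(gross_profit = range(by_imp_gp),
                    wheat_yield = range(by_imp_wy)),
    bound = bound, soil = soil, region = region, n_years = T_len),
    class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf(paste0("rotation economics (%d yr, %s penalties): gross ",
                     "profit %.2f GBP/ha/yr, wheat %.2f t/ha/yr\n"),
              x$n_years, x$bound, x$mean_gross_profit, x$mean_wheat_yield))
  invisible(x)
}

#' Average fine-subcategory results back to coarse categories
#'
#' Models may run with soil and density differentiated more finely than
#' reported; the reported value for each coarse cell is the unweighted
#' arithmetic mean of its subcategory values.
#'
#' @param values Numeric vector of subcategory results for one coarse cell.
#' @return Their mean.
#' @export
refine_and_average <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("subcategory values must be non-empty and complete")
  }
  mean(values)
}

#' Write a price table to CSV
#'
#' Inverse of `gen_price_tables(file)`: rows of `key,item,value` that read
#' back to an identical table.
#'
#' @param prices A `price_table`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_price_table <- function(prices, path) {
  stopifnot(inherits(prices, "price_table"))
  rows <- do.call(rbind, lapply(
    c("crop_price", "herbicide_cost", "operation_cost", "other_cost"),
    function(key) data.frame(key = key, item = names(prices[[key]]),
                             value = unname(prices[[key]]),
                             stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
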