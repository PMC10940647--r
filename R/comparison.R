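# Stage 5: scenario contrasts. Opportunity cost = mean annual gross
# profit(BAU) - mean annual gross profit(MIT); productivity cost = mean
# annual wheat yield(BAU) - mean annual wheat yield(MIT). Negative values
# mean the mitigation strategy outperforms business as usual. Cumulative
# versions track 18-year switching sequences against continuous BAU, and
# scale_up turns per-hectare values into national totals via county cereal
# areas.

#' Opportunity cost of switching from BAU to MIT
#'
#' @param gp_bau,gp_mit Mean annual gross profits (GBP/ha/yr).
#' @return `gp_bau - gp_mit` (GBP/ha/yr); negative favours MIT.
#' @examples
#' opportunity_cost(582, 465) # 117
#' @export
opportunity_cost <- function(gp_bau, gp_mit) {
  stopifnot(is.numeric(gp_bau), is.numeric(gp_mit))
  gp_bau - gp_mit
}

#' Productivity cost of switching from BAU to MIT
#'
#' @param y_bau,y_mit Mean annual wheat yields (t/ha/yr).
#' @return `y_bau - y_mit` (t/ha/yr).
#' @examples
#' productivity_cost(4.42, 2.39) # 2.03
#' @export
productivity_cost <- function(y_bau, y_mit) {
  stopifnot(is.numeric(y_bau), is.numeric(y_mit))
  y_bau - y_mit
}

#' Cumulative opportunity and productivity costs of a switching sequence
#'
#' Year-by-year running sums of the per-year differences between the
#' reference sequence (continuous BAU, "BBB") and a switching sequence, in
#' gross profit and wheat yield. Points below zero mean switching to MIT at
#' some point outperforms never switching.
#'
#' @param ref_profit,ref_yield Per-year gross profit and wheat yield of the
#'   reference (BBB) sequence.
#' @param seq_profit,seq_yield Per-year values of the switching sequence.
#' @return Data frame: year, cum_opportunity_cost, cum_productivity_cost.
#' @export
cumulative_costs <- function(ref_profit, seq_profit, ref_yield, seq_yield) {
  n <- length(ref_profit)
  if (length(seq_profit) != n || length(ref_yield) != n ||
      length(seq_yield) != n) {
    stop("all four per-year series must have equal length")
  }
  data.frame(year = seq_len(n),
             cum_opportunity_cost = cumsum(ref_profit - seq_profit),
             cum_productivity_cost = cumsum(ref_yield - seq_yield))
}

#' County cereal areas with density-resistance category shares
#'
#' National scale-up assumes the distribution of density-resistance states
#' within a county equals the distribution observed there in the survey
#' data. The packaged areas are synthetic stand-ins at plausible county
#' cereal-area magnitudes.
#'
#' @param counties Character vector of county names (default: all 13).
#' @param classified Optional classification data frame (from
#'   [classify_fields()] merged with county labels) used to derive per-county
#'   category shares; defaults to the overall 14/56/30 mix for every county.
#' @param areas Optional named numeric vector of cereal areas (ha) per
#'   county, overriding the packaged stand-ins.
#' @return Data frame of class `county_area_table`: county, region,
#'   cereal_area, share_LD_LR, share_LD_HR, share_HD_HR.
#' @export
gen_county_areas <- function(counties = county_region_table()$county,
                             classified = NULL, areas = NULL) {
  region <- region_for_county(counties)  # errors on unknown county
  default_area <- c(
    "N.Yorks" = 120000, "E.R.Yorks" = 110000, "S.Yorks" = 45000,
    "Notts" = 70000, "Leics" = 65000, "Warw" = 60000, "Northants" = 80000,
    "Oxon" = 75000, "Bucks" = 50000, "Beds" = 55000, "Lincs" = 250000,
    "Cambs" = 140000, "Norfolk" = 160000)
  area <- if (is.null(areas)) unname(default_area[counties]) else {
    if (!all(counties %in% names(areas))) {
      stop("area missing for county: ",
           paste(setdiff(counties, names(areas)), collapse = ", "))
    }
    unname(areas[counties])
  }
  if (anyNA(area) || any(area < 0)) stop("county areas must be >= 0")
  shares <- matrix(rep(c(0.14, 0.56, 0.30), each = length(counties)),
                   ncol = 3, dimnames = list(NULL, c("share_LD_LR",
                                                     "share_LD_HR",
                                                     "share_HD_HR")))
  if (!is.null(classified)) {
    if (!all(c("county", "dr_category") %in% names(classified))) {
      stop("classified needs 'county' and 'dr_category' columns")
    }
    for (i in seq_along(counties)) {
      d <- classified[classified$county == counties[i] &
                        !isTRUE(classified$anomalous), ]
      if (nrow(d)) {
        tab <- table(factor(d$dr_category,
                            levels = c("LD-LR", "LD-HR", "HD-HR")))
        shares[i, ] <- as.numeric(tab) / nrow(d)
      }
    }
  }
  bad <- abs(rowSums(shares) - 1) > 1e-9
  if (any(bad)) stop("category shares must sum to 1 per county")
  out <- data.frame(county = counties, region = region, cereal_area = area,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(shares))
  class(out) <- c("county_area_table", class(out))
  out
}

#' Scale per-hectare values up to a national total
#'
#' `total = sum over counties and categories of area x category share x
#' per-ha value`, where the per-ha value is selected by the county's region
#' and the category. Linear in areas and in values; invariant to county
#' order.
#'
#' @param per_ha Data frame with columns `region`, `dr_category`, `value`
#'   (per-ha values, already averaged over soils unless soil shares are
#'   folded in upstream).
#' @param areas A [gen_county_areas()] table.
#' @return Numeric national total (same units as `value` x ha).
#' @export
scale_up <- function(per_ha, areas) {
  stopifnot(is.data.frame(per_ha),
            all(c("region", "dr_category", "value") %in% names(per_ha)))
  share_col <- c("LD-LR" = "share_LD_LR", "LD-HR" = "share_LD_HR",
                 "HD-HR" = "share_HD_HR")
  total <- 0
  for (i in seq_len(nrow(areas))) {
    for (cat in names(share_col)) {
      v <- per_ha$value[per_ha$region == areas$region[i] &
                          per_ha$dr_category == cat]
      if (length(v) == 0L) next
      if (length(v) > 1L) v <- mean(v)
      total <- total + areas$cereal_area[i] * areas[[share_col[cat]]][i] * v
    }
  }
  total
}

#' Value as a percentage of a reference quantity
#'
#' @param value,reference Numerics (e.g. scaled-up wheat loss vs annual UK
#'   domestic wheat consumption).
#' @param digits Rounding applied at this reporting layer (default 1).
#' @return `100 * value / reference`, rounded.
#' @examples
#' percent_of_reference(1287734, 15e6) # 8.6
#' @export
percent_of_reference <- function(value, reference, digits = 1) {
  if (reference == 0) stop("reference must be non-zero")
  round(100 * value / reference, digits)
}

#' Scenario comparison report
#'
#' Summarises per-strategy results into the standard reporting shape: per
#' scenario, the mean (with min/max across strategies, i.e. across regions,
#' soils and density-resistance categories) of the year-6 and annual-mean
#' damaging proportions, the mean annual gross profit and the mean annual
#' wheat yield.
#'
#' @param results Data frame with one row per strategy run and columns
#'   `scenario`, `dr_category`, `soil`, `region`, `prop_damaging_final`,
#'   `prop_damaging_annual`, `gross_profit`, `wheat_yield`.
#' @return List with `scenario_summary` (Table-1 shape) and `dr_costs`
#'   (per DR category: BAU vs MIT means, opportunity and productivity
#'   costs).
#' @export
compare_scenarios <- function(results) {
  need <- c("scenario", "dr_category", "prop_damaging_final",
            "prop_damaging_annual", "gross_profit", "wheat_yield")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ",
                         paste(miss, collapse = ", "))
  summ <- do.call(rbind, lapply(split(results, results$scenario), function(d) {
    stat <- function(x) c(mean = mean(x), min = min(x), max = max(x))
    data.frame(scenario = d$scenario[1],
               t(c(prop_final = stat(d$prop_damaging_final),
                   prop_annual = stat(d$prop_damaging_annual),
                   gross_profit = stat(d$gross_profit),
                   wheat_yield = stat(d$wheat_yield))),
               stringsAsFactors = FALSE)
  }))
  dr_costs <- NULL
  if (all(c("BAU", "MIT") %in% results$scenario)) {
    dr_costs <- do.call(rbind, lapply(
      split(results, results$dr_category), function(d) {
        b <- d[d$scenario == "BAU", ]; m <- d[d$scenario == "MIT", ]
        if (!nrow(b) || !nrow(m)) return(NULL)
        data.frame(dr_category = d$dr_category[1],
                   gp_bau = mean(b$gross_profit),
                   gp_mit = mean(m$gross_profit),
                   opportunity_cost = opportunity_cost(mean(b$gross_profit),
                                                       mean(m$gross_profit)),
                   wy_bau = mean(b$wheat_yield),
                   wy_mit = mean(m$wheat_yield),
                   productivity_cost = productivity_cost(mean(b$wheat_yield),
                                                         mean(m$wheat_yield)),
                   stringsAsFactors = FALSE)
      }))
  }
  list(scenario_summary = summ, dr_costs = dr_costs)
}
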