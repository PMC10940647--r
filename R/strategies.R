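# Stage 2: management strategies as validated data objects. BAU and CWW are
# built in code from the observed-practice description; MIT strategies are
# data (a packaged synthetic fixture, replaceable by real tables without code
# changes).

#' Controlled crop vocabulary
#' @return Character vector of crop names the package understands.
#' @export
crop_vocabulary <- function() {
  c("winter_wheat", "winter_oilseed_rape", "winter_barley",
    "spring_barley", "spring_beans", "spring_oats", "spring_wheat",
    "fallow", "cover_crop")
}

spring_crops <- function() {
  c("spring_barley", "spring_beans", "spring_oats", "spring_wheat")
}

#' Construct one year of management
#'
#' @param crop Crop name from [crop_vocabulary()].
#' @param sowing_window One of early_autumn, late_autumn, spring, none.
#' @param tillage One of inversion_plough, min_till, no_till.
#' @param n_stale_seedbeds Stale seedbed passes before drilling (needs a
#'   late_autumn or spring sowing window to leave pre-drilling time).
#' @param glyphosate_applications,glyphosate_dose Non-selective herbicide
#'   passes and total dose (l/ha) over the year.
#' @param selective_applications,selective_dose Selective (in-crop) herbicide
#'   passes and total dose (l/ha).
#' @param seed_rate Relative seed-rate multiplier (1 = standard).
#' @return A list of class `management_year`.
#' @export
management_year <- function(crop, sowing_window, tillage,
                            n_stale_seedbeds = 0,
                            glyphosate_applications = 0, glyphosate_dose = 0,
                            selective_applications = 0, selective_dose = 0,
                            seed_rate = 1) {
  crop <- match.arg(crop, crop_vocabulary())
  sowing_window <- match.arg(sowing_window,
                             c("early_autumn", "late_autumn", "spring", "none"))
  tillage <- match.arg(tillage, c("inversion_plough", "min_till", "no_till"))
  counts <- c(n_stale_seedbeds = n_stale_seedbeds,
              glyphosate_applications = glyphosate_applications,
              glyphosate_dose = glyphosate_dose,
              selective_applications = selective_applications,
              selective_dose = selective_dose, seed_rate = seed_rate)
  if (anyNA(counts) || any(counts < 0)) {
    stop("management counts, doses and seed rate must be >= 0")
  }
  if (n_stale_seedbeds > 0 && !sowing_window %in% c("late_autumn", "spring")) {
    stop("stale seedbeds require a late_autumn or spring sowing window ",
         "(crop ", crop, ", window ", sowing_window, ")")
  }
  structure(list(crop = crop, sowing_window = sowing_window,
                 tillage = tillage, n_stale_seedbeds = n_stale_seedbeds,
                 glyphosate_applications = glyphosate_applications,
                 glyphosate_dose = glyphosate_dose,
                 selective_applications = selective_applications,
                 selective_dose = selective_dose, seed_rate = seed_rate),
            class = "management_year")
}

#' Construct a 6-year management strategy
#'
#' @param strategy_id Identifier.
#' @param scenario "BAU", "CWW" or "MIT".
#' @param dr_category Target initial condition: "LD-LR", "LD-HR" or "HD-HR".
#' @param soil "heavy", "medium" or "light".
#' @param region "north", "central" or "east".
#' @param years List of exactly 6 [management_year()] objects.
#' @return A list of class `strategy`.
#' @export
strategy <- function(strategy_id, scenario, dr_category, soil, region, years) {
  scenario <- match.arg(scenario, c("BAU", "CWW", "MIT"))
  dr_category <- match.arg(dr_category, c("LD-LR", "LD-HR", "HD-HR"))
  soil <- match.arg(soil, c("heavy", "medium", "light"))
  region <- match.arg(region, c("north", "central", "east"))
  if (!is.list(years) || length(years) != 6L ||
      !all(vapply(years, inherits, logical(1), "management_year"))) {
    stop("a strategy is exactly 6 management years (got ",
         if (is.list(years)) length(years) else "non-list", ")")
  }
  structure(list(strategy_id = strategy_id, scenario = scenario,
                 target = list(dr_category = dr_category, soil = soil,
                               region = region),
                 years = years),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("strategy %s [%s] target %s / %s / %s\n", x$strategy_id,
              x$scenario, x$target$dr_category, x$target$soil,
              x$target$region))
  cat("  crops:", paste(vapply(x$years, `[[`, "", "crop"), collapse = ", "),
      "\n")
  invisible(x)
}

strategy_crops <- function(s) vapply(s$years, `[[`, character(1), "crop")

strategy_total <- function(s, field) {
  sum(vapply(s$years, `[[`, numeric(1), field))
}

n_wheat_years <- function(s) sum(strategy_crops(s) == "winter_wheat")

n_spring_crops <- function(s) sum(strategy_crops(s) %in% spring_crops())

#' Business-as-usual strategy
#'
#' The most common observed rotation: two years of winter wheat followed by
#' one year of winter oilseed rape, repeated to give six years. Wheat years
#' delay drilling to late autumn to allow one glyphosate-treated stale
#' seedbed.
#'
#' @param dr_category,soil,region Target initial condition labels (BAU is the
#'   same rotation for every initial condition).
#' @return A `strategy`.
#' @export
build_bau <- function(dr_category = "LD-LR", soil = "medium",
                      region = "central") {
  wheat <- management_year("winter_wheat", "late_autumn", "min_till",
                           n_stale_seedbeds = 1,
                           glyphosate_applications = 1, glyphosate_dose = 1.5,
                           selective_applications = 2, selective_dose = 2.0)
  osr <- management_year("winter_oilseed_rape", "early_autumn", "min_till",
                         selective_applications = 1, selective_dose = 1.0)
  strategy(paste("BAU", dr_category, soil, region, sep = "_"), "BAU",
           dr_category, soil, region,
           list(wheat, wheat, osr, wheat, wheat, osr))
}

#' Continuous winter wheat strategy
#'
#' Six consecutive winter wheat years managed as in BAU wheat years; probes
#' the outcome of always growing the highest-value crop.
#'
#' @inheritParams build_bau
#' @return A `strategy`.
#' @export
build_cww <- function(dr_category = "LD-LR", soil = "medium",
                      region = "central") {
  wheat <- management_year("winter_wheat", "late_autumn", "min_till",
                           n_stale_seedbeds = 1,
                           glyphosate_applications = 1, glyphosate_dose = 1.5,
                           selective_applications = 2, selective_dose = 2.0)
  strategy(paste("CWW", dr_category, soil, region, sep = "_"), "CWW",
           dr_category, soil, region, rep(list(wheat), 6))
}

# Qualitative design rules every MIT strategy must satisfy, relative to BAU:
#   (a) at least one spring crop;
#   (b) more stale seedbeds than BAU over the rotation;
#   (c) high-resistance targets: fewer wheat years than BAU, glyphosate dose
#       above BAU but no more than 3x BAU;
#   (d) LD-LR targets: lower total herbicide dose (glyphosate + selective)
#       than BAU.
validate_mit <- function(s, bau = build_bau()) {
  errs <- character(0)
  if (n_spring_crops(s) < 1) {
    errs <- c(errs, "no spring crop in rotation")
  }
  if (strategy_total(s, "n_stale_seedbeds") <=
      strategy_total(bau, "n_stale_seedbeds")) {
    errs <- c(errs, "stale seedbeds not increased over BAU")
  }
  gly <- strategy_total(s, "glyphosate_dose")
  gly_bau <- strategy_total(bau, "glyphosate_dose")
  if (s$target$dr_category %in% c("LD-HR", "HD-HR")) {
    if (n_wheat_years(s) >= n_wheat_years(bau)) {
      errs <- c(errs, "high-resistance target must grow wheat less often than BAU")
    }
    if (gly <= gly_bau || gly > 3 * gly_bau + 1e-9) {
      errs <- c(errs, sprintf(
        "high-resistance glyphosate dose %.1f outside (BAU, 3 x BAU] = (%.1f, %.1f]",
        gly, gly_bau, 3 * gly_bau))
    }
  }
  if (s$target$dr_category == "LD-LR") {
    tot <- gly + strategy_total(s, "selective_dose")
    tot_bau <- gly_bau + strategy_total(bau, "selective_dose")
    if (tot >= tot_bau) {
      errs <- c(errs, "LD-LR target must reduce total herbicide dose vs BAU")
    }
  }
  errs
}

#' Validate a strategy object
#'
#' Structural checks for any strategy plus the qualitative MIT design rules
#' (spring cropping, stale seedbeds, wheat frequency and glyphosate bounds
#' for high-resistance targets, reduced herbicide for LD-LR targets).
#'
#' @param s A `strategy`.
#' @return Invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_strategy <- function(s) {
  if (!inherits(s, "strategy")) stop("not a strategy object")
  errs <- if (s$scenario == "MIT") validate_mit(s) else character(0)
  if (length(errs)) {
    stop("strategy ", s$strategy_id, " failed validation:\n  ",
         paste(errs, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Load strategies from a CSV file
#'
#' The file holds one row per strategy-year with columns `strategy_id`,
#' `scenario`, `dr_category`, `soil`, `region`, `year`, `crop`,
#' `sowing_window`, `tillage`, `n_stale_seedbeds`,
#' `glyphosate_applications`, `glyphosate_dose`, `selective_applications`,
#' `selective_dose`, `seed_rate`. Every strategy must have exactly 6 years
#' and every MIT strategy must pass [validate_strategy()].
#'
#' @param file Path to a strategy CSV. Defaults to the packaged synthetic
#'   MIT fixture (27 strategies: 3 DR categories x 3 soils x 3 regions).
#' @return Named list of `strategy` objects.
#' @export
load_strategies <- function(file = system.file("extdata",
                                               "mit_strategies_synthetic.csv",
                                               package = "weedrot")) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("strategy_id", "scenario", "dr_category", "soil", "region",
            "year", "crop", "sowing_window", "tillage", "n_stale_seedbeds",
            "glyphosate_applications", "glyphosate_dose",
            "selective_applications", "selective_dose", "seed_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("strategy file missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$strategy_id), function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) != 6L) {
      stop("strategy ", d$strategy_id[1], " has ", nrow(d),
           " years; rotations must be exactly 6 years")
    }
    yrs <- lapply(seq_len(6), function(i) {
      management_year(d$crop[i], d$sowing_window[i], d$tillage[i],
                      d$n_stale_seedbeds[i], d$glyphosate_applications[i],
                      d$glyphosate_dose[i], d$selective_applications[i],
                      d$selective_dose[i], d$seed_rate[i])
    })
    s <- strategy(d$strategy_id[1], d$scenario[1], d$dr_category[1],
                  d$soil[1], d$region[1], yrs)
    validate_strategy(s)
    s
  })
  out[order(names(out))]
}

#' Build an 18-year switching sequence
#'
#' Sequence codes concatenate three 6-year blocks, each BAU ("B") or MIT
#' ("M"): BBB (never switch), BBM (switch after 12 years), BMM (after 6),
#' MMM (switch immediately). The density distribution carries across block
#' boundaries when the sequence is simulated.
#'
#' @param code One of "BBB", "BBM", "BMM", "MMM".
#' @param bau,mit The BAU and MIT `strategy` objects to draw blocks from.
#' @return A list of class `sequence_plan` with the resolved 18
#'   [management_year()]s.
#' @export
make_sequence <- function(code, bau, mit) {
  if (!code %in% c("BBB", "BBM", "BMM", "MMM")) {
    stop("unknown sequence code '", code,
         "' (expected BBB, BBM, BMM or MMM)")
  }
  stopifnot(inherits(bau, "strategy"), inherits(mit, "strategy"))
  blocks <- strsplit(code, "")[[1]]
  years <- unlist(lapply(blocks, function(b) {
    if (b == "B") bau$years else mit$years
  }), recursive = FALSE)
  structure(list(code = code, target = mit$target, years = years,
                 bau_id = bau$strategy_id, mit_id = mit$strategy_id),
            class = "sequence_plan")
}

#' @export
print.sequence_plan <- function(x, ...) {
  cat(sprintf("18-year sequence %s (%s -> %s)\n", x$code, x$bau_id, x$mit_id))
  invisible(x)
}

plan_years <- function(plan) {
  if (inherits(plan, "strategy") || inherits(plan, "sequence_plan")) {
    plan$years
  } else if (is.list(plan) &&
             all(vapply(plan, inherits, logical(1), "management_year"))) {
    plan
  } else {
    stop("plan must be a strategy, sequence_plan or list of management years")
  }
}
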