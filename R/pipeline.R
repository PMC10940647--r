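# Orchestration: configuration, seed fan-out, stage wiring and provenance.
# One global seed deterministically derives a per-stage seed, so any stage
# can be re-run in isolation.

#' Derive a per-stage seed from the global seed
#'
#' `stage_seed = (seed mod 1000003) * 1009 + stage_index, mod 2147483647`.
#'
#' @param seed Global integer seed.
#' @param stage Stage index (1..n).
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + stage) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param seed Global seed (mandatory).
#' @param out_dir Output directory for stage CSVs and the run manifest.
#' @param n_fields,grid_dims Survey generator size (defaults 125 fields,
#'   20 x 20 quadrats).
#' @param n_history_years Management-history length per field.
#' @param n_model_quadrats Quadrats per field used to build the transition
#'   training set (subsampled from the survey grid).
#' @param n_imputations Imputation count for the fitted model (default 37).
#' @param penalty_bound Wheat yield-penalty limit: lower / central / upper.
#' @param scenarios Scenarios to run.
#' @param sequence_codes Worst-case 18-year switching codes to evaluate
#'   (empty vector skips the worst-case stage).
#' @param strategy_file MIT strategy CSV (defaults to the packaged synthetic
#'   fixture).
#' @param price_file Optional price CSV overriding the packaged table.
#' @return A list of class `weedrot_config`.
#' @export
weedrot_config <- function(seed, out_dir = tempfile("weedrot_run_"),
                           n_fields = 125L, grid_dims = c(20L, 20L),
                           n_history_years = 6L, n_model_quadrats = 20L,
                           n_imputations = 37L,
                           penalty_bound = c("central", "lower", "upper"),
                           scenarios = c("BAU", "CWW", "MIT"),
                           sequence_codes = c("BBB", "BBM", "BMM", "MMM"),
                           strategy_file = system.file(
                             "extdata", "mit_strategies_synthetic.csv",
                             package = "weedrot"),
                           price_file = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  penalty_bound <- match.arg(penalty_bound)
  if (!file.exists(strategy_file)) {
    stop("strategy file does not exist: ", strategy_file)
  }
  if (!is.null(price_file) && !file.exists(price_file)) {
    stop("price file does not exist: ", price_file)
  }
  stopifnot(all(scenarios %in% c("BAU", "CWW", "MIT")),
            all(sequence_codes %in% c("BBB", "BBM", "BMM", "MMM")))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_fields = as.integer(n_fields),
                 grid_dims = as.integer(grid_dims),
                 n_history_years = as.integer(n_history_years),
                 n_model_quadrats = as.integer(n_model_quadrats),
                 n_imputations = as.integer(n_imputations),
                 penalty_bound = penalty_bound, scenarios = scenarios,
                 sequence_codes = sequence_codes,
                 strategy_file = strategy_file, price_file = price_file),
            class = "weedrot_config")
}

#' Save or load a pipeline configuration as JSON
#'
#' Configurations round-trip unchanged.
#' @param cfg A `weedrot_config`.
#' @param path File path.
#' @return `load_config()` returns the reconstructed config.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(weedrot_config, p[!vapply(p, is.null, logical(1))])
}

#' The synthetic world's generating transition model
#'
#' A fully-specified single-imputation model used as the known truth behind
#' the synthetic transition datasets. Cultural controls (spring sowing,
#' stale seedbeds, glyphosate) lower the linear predictor (densities fall);
#' high resistance raises it; previous state carries strong persistence.
#' Registered crop transitions cover all pairs of the generator's five
#' crops, with zero transition-specific deviations and sd 0.3.
#'
#' @return A `transition_model` with `n_imputations = 1`.
#' @export
synthetic_true_model <- function() {
  crops <- rownames(default_crop_transition_table())
  cts <- as.vector(outer(crops, crops, crop_transition_label))
  u_ct <- matrix(0, 1, length(cts), dimnames = list(NULL, cts))
  transition_model(
    cutpoints = c(1, 3, 5, 7),
    beta = c(prev_state2 = 2, prev_state3 = 4, prev_state4 = 6,
             prev_state5 = 8,
             sowing_late_autumn = -0.4, sowing_spring = -1.2,
             sowing_none = -0.5,
             tillage_min_till = 0.1, tillage_no_till = 0.3,
             n_stale_seedbeds = -0.35, glyphosate_applications = -0.15,
             selective_applications = -0.25, seed_rate = -0.2,
             resistance_high = 2),
    u = list(crop_transition = u_ct),
    sigma = list(crop_transition = 0.3, rotation = 0.2, field = 0.3))
}

#' Designed initial density distribution for a DR category
#'
#' Strategies are simulated from the density state they were designed for:
#' low-density categories start from the LD quadrat-state mix, HD-HR from
#' the HD mix.
#'
#' @param dr_category "LD-LR", "LD-HR" or "HD-HR".
#' @return A `density_distribution`.
#' @export
initial_distribution_for <- function(dr_category) {
  dr_category <- match.arg(dr_category, c("LD-LR", "LD-HR", "HD-HR"))
  cfg <- synthetic_config(seed = 1L)
  density_distribution(cfg$state_probs[
    if (dr_category == "HD-HR") "HD" else "LD", ])
}

resistance_for <- function(dr_category) {
  if (dr_category == "LD-LR") "low" else "high"
}

all_targets <- function() {
  expand.grid(dr_category = c("LD-LR", "LD-HR", "HD-HR"),
              soil = c("heavy", "medium", "light"),
              region = c("north", "central", "east"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

run_strategy <- function(s, model, prices, base_yields, penalties, bound,
                         seed, initial = NULL, resistance = NULL) {
  if (is.null(initial)) initial <- initial_distribution_for(s$target$dr_category)
  if (is.null(resistance)) resistance <- resistance_for(s$target$dr_category)
  traj <- simulate_density(model, s, initial, resistance, seed = seed)
  econ <- rotation_summary(s, traj, prices, base_yields, penalties, bound)
  pd <- trajectory_prop_damaging(traj)
  data.frame(strategy_id = s$strategy_id, scenario = s$scenario,
             dr_category = s$target$dr_category, soil = s$target$soil,
             region = s$target$region,
             prop_damaging_final = pd[length(pd)],
             prop_damaging_annual = mean(pd[-1]),
             gross_profit = econ$mean_gross_profit,
             wheat_yield = econ$mean_wheat_yield,
             gp_min = econ$envelope$gross_profit[1],
             gp_max = econ$envelope$gross_profit[2],
             wy_min = econ$envelope$wheat_yield[1],
             wy_max = econ$envelope$wheat_yield[2],
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the five stages in order — synthetic data generation,
#' classification, strategy assembly, transition-model fitting and density
#' simulation, economics, and scenario comparison (plus the worst-case
#' sequence stage when sequence codes are configured) — writing each stage's
#' tidy CSV output and a JSON run manifest (seeds, input checksums, stage
#' timings) to `cfg$out_dir`. Deterministic given the config.
#'
#' @param cfg A [weedrot_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with every stage's in-memory outputs plus the
#'   manifest.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "weedrot_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say(sprintf("[%s] done in %.1fs", stage, timings[[stage]]))
    r
  }
  outfile <- function(name) file.path(cfg$out_dir, name)

  # stage 1: synthetic survey world
  synth <- clock("synthetic_data", {
    sc <- synthetic_config(n_fields = cfg$n_fields,
                           grid_dims = cfg$grid_dims,
                           seed = stage_seed(cfg$seed, 1))
    d <- gen_survey_data(sc)
    utils::write.csv(d$surveys, outfile("surveys.csv"), row.names = FALSE)
    utils::write.csv(d$assays, outfile("assays.csv"), row.names = FALSE)
    d
  })

  # stage 2: classification
  classified <- clock("classification", {
    cl <- classify_fields(synth$surveys, synth$assays)
    cl$county <- synth$surveys$county[match(cl$field_id,
                                            synth$surveys$field_id)]
    cl$region <- region_for_county(cl$county)
    utils::write.csv(cl, outfile("classification.csv"), row.names = FALSE)
    cl
  })

  # stage 3: strategies
  strategies <- clock("strategies", {
    tg <- all_targets()
    out <- list()
    if ("BAU" %in% cfg$scenarios) {
      out <- c(out, lapply(seq_len(nrow(tg)), function(i) {
        build_bau(tg$dr_category[i], tg$soil[i], tg$region[i])
      }))
    }
    if ("CWW" %in% cfg$scenarios) {
      out <- c(out, lapply(seq_len(nrow(tg)), function(i) {
        build_cww(tg$dr_category[i], tg$soil[i], tg$region[i])
      }))
    }
    if ("MIT" %in% cfg$scenarios) {
      out <- c(out, load_strategies(cfg$strategy_file))
    }
    names(out) <- vapply(out, `[[`, "", "strategy_id")
    out
  })

  # stage 4a: transition training data from the known generating model
  records <- clock("transition_data", {
    hist <- gen_management_histories(synth$surveys,
                                     seed = stage_seed(cfg$seed, 2),
                                     n_years = cfg$n_history_years)
    res <- stats::setNames(classified$resistance, classified$field_id)
    grids <- split(synth$surveys$state, synth$surveys$field_id)
    set.seed(stage_seed(cfg$seed, 3))
    init <- lapply(grids, function(g) {
      g[sample.int(length(g), min(cfg$n_model_quadrats, length(g)))]
    })
    rec <- gen_transition_dataset(synthetic_true_model(), hist,
                                  seed = stage_seed(cfg$seed, 4),
                                  initial_states = init, resistance = res)
    utils::write.csv(rec, outfile("transition_records.csv"),
                     row.names = FALSE)
    rec
  })

  # stage 4b: fit
  model <- clock("fit_model", {
    m <- fit_transition_model(records, n_imputations = cfg$n_imputations,
                              seed = stage_seed(cfg$seed, 5))
    save_transition_model(m, outfile("transition_model.json"))
    m
  })

  prices <- gen_price_tables(cfg$price_file)
  base_yields <- gen_base_yields()
  penalties <- yield_penalty_table()

  # stage 5: simulate + economics per strategy
  results <- clock("simulate_economics", {
    r <- do.call(rbind, lapply(strategies, function(s) {
      run_strategy(s, model, prices, base_yields, penalties,
                   cfg$penalty_bound, seed = stage_seed(cfg$seed, 6))
    }))
    rownames(r) <- NULL
    utils::write.csv(r, outfile("strategy_results.csv"), row.names = FALSE)
    r
  })

  # stage 6: comparison + scale-up
  comparison <- clock("comparison", {
    cmp <- compare_scenarios(results)
    utils::write.csv(cmp$scenario_summary, outfile("scenario_summary.csv"),
                     row.names = FALSE)
    areas <- gen_county_areas(classified = classified)
    scaled <- NULL
    if (!is.null(cmp$dr_costs)) {
      scaled <- do.call(rbind, lapply(split(results, results$dr_category),
        function(d) {
          b <- d[d$scenario == "BAU", ]; m <- d[d$scenario == "MIT", ]
          if (!nrow(b) || !nrow(m)) return(NULL)
          per_ha_opp <- do.call(rbind, lapply(unique(d$region), function(rg) {
            data.frame(region = rg, dr_category = d$dr_category[1],
                       value = opportunity_cost(
                         mean(b$gross_profit[b$region == rg]),
                         mean(m$gross_profit[m$region == rg])))
          }))
          per_ha_prod <- per_ha_opp
          per_ha_prod$value <- vapply(unique(d$region), function(rg) {
            productivity_cost(mean(b$wheat_yield[b$region == rg]),
                              mean(m$wheat_yield[m$region == rg]))
          }, numeric(1))
          data.frame(dr_category = d$dr_category[1],
                     scaled_opportunity_cost = scale_up(per_ha_opp, areas),
                     scaled_productivity_cost = scale_up(per_ha_prod, areas),
                     stringsAsFactors = FALSE)
        }))
      utils::write.csv(cmp$dr_costs, outfile("dr_costs.csv"),
                       row.names = FALSE)
      if (!is.null(scaled)) {
        utils::write.csv(scaled, outfile("scaled_costs.csv"),
                         row.names = FALSE)
      }
    }
    list(report = cmp, areas = areas, scaled = scaled)
  })

  # stage 7: worst-case 18-year switching sequences
  worst_case <- NULL
  if (length(cfg$sequence_codes) && all(c("BAU", "MIT") %in% cfg$scenarios)) {
    worst_case <- clock("worst_case", {
      mits <- Filter(function(s) s$scenario == "MIT", strategies)
      rows <- list()
      for (s in mits) {
        bau <- build_bau(s$target$dr_category, s$target$soil,
                         s$target$region)
        per_code <- lapply(cfg$sequence_codes, function(code) {
          plan <- make_sequence(code, bau, s)
          traj <- simulate_density(model, plan, worst_case_distribution(),
                                   resistance = "high",
                                   seed = stage_seed(cfg$seed, 7))
          econ <- rotation_summary(plan, traj, prices, base_yields,
                                   penalties, cfg$penalty_bound,
                                   soil = s$target$soil,
                                   region = s$target$region)
          list(code = code, econ = econ)
        })
        names(per_code) <- cfg$sequence_codes
        ref <- per_code[["BBB"]]
        if (is.null(ref)) {
          bbb_plan <- make_sequence("BBB", bau, s)
          traj <- simulate_density(model, bbb_plan, worst_case_distribution(),
                                   resistance = "high",
                                   seed = stage_seed(cfg$seed, 7))
          ref <- list(code = "BBB",
                      econ = rotation_summary(bbb_plan, traj, prices,
                                              base_yields, penalties,
                                              cfg$penalty_bound,
                                              soil = s$target$soil,
                                              region = s$target$region))
        }
        for (pc in per_code) {
          cc <- cumulative_costs(ref$econ$annual_gross_profit,
                                 pc$econ$annual_gross_profit,
                                 ref$econ$annual_wheat_yield,
                                 pc$econ$annual_wheat_yield)
          rows[[length(rows) + 1L]] <- data.frame(
            mit_strategy = s$strategy_id, code = pc$code,
            dr_category = s$target$dr_category, soil = s$target$soil,
            region = s$target$region,
            gross_profit = pc$econ$mean_gross_profit,
            wheat_yield = pc$econ$mean_wheat_yield,
            opportunity_cost = opportunity_cost(ref$econ$mean_gross_profit,
                                                pc$econ$mean_gross_profit),
            productivity_cost = productivity_cost(ref$econ$mean_wheat_yield,
                                                  pc$econ$mean_wheat_yield),
            cum_opportunity_cost_18 = cc$cum_opportunity_cost[18],
            cum_productivity_cost_18 = cc$cum_productivity_cost[18],
            stringsAsFactors = FALSE)
        }
      }
      wc <- do.call(rbind, rows)
      rownames(wc) <- NULL
      utils::write.csv(wc, outfile("worst_case.csv"), row.names = FALSE)
      wc
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("weedrot")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(lapply(1:7, function(k)
      stage_seed(cfg$seed, k)), paste0("stage", 1:7)),
    config = unclass(cfg),
    input_checksums = as.list(tools::md5sum(
      c(cfg$strategy_file,
        if (!is.null(cfg$price_file)) cfg$price_file))),
    timings_sec = timings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(synth = synth, classified = classified,
                 strategies = strategies, records = records, model = model,
                 results = results, comparison = comparison,
                 worst_case = worst_case, manifest = manifest,
                 out_dir = cfg$out_dir))
}
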