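test_that("density-weighted wheat yield", {
  pen <- yield_penalty_table(0.2, 0.4, rel_bounds = 0.5)
  expect_equal(wheat_yield(7.3, c(1, 0, 0, 0, 0), pen), 7.3)   # no weeds
  expect_equal(wheat_yield(7.3, c(0, 0, 1, 0, 0), pen), 7.3)   # medium: zero penalty
  # hand-weighted sum: 8 * (1 - 0.3*0.2 - 0.3*0.4) = 8 * 0.82
  expect_equal(wheat_yield(8, c(0.1, 0.1, 0.2, 0.3, 0.3), pen), 6.56)
  expect_error(wheat_yield(8, c(0.5, 0.5, 0.5, 0, 0), pen), "sum to 1")
  expect_error(yield_penalty_table(0.5, 0.3), "loss\\(high\\) <= loss\\(very_high\\)")
})

test_that("cost breakdown is itemised and linear in doses", {
  prices <- gen_price_tables()
  fallow <- management_year("fallow", "none", "min_till")
  expect_equal(unname(year_costs(fallow, prices)["herbicide"]), 0)
  y1 <- toy_wheat_year()
  y2 <- management_year("winter_wheat", "late_autumn", "min_till",
                        n_stale_seedbeds = 1, glyphosate_applications = 1,
                        glyphosate_dose = 3, selective_applications = 2,
                        selective_dose = 2)
  c1 <- year_costs(y1, prices); c2 <- year_costs(y2, prices)
  gly_share1 <- y1$glyphosate_dose * prices$herbicide_cost[["glyphosate"]]
  gly_share2 <- y2$glyphosate_dose * prices$herbicide_cost[["glyphosate"]]
  expect_equal(gly_share2, 2 * gly_share1)   # doubling dose doubles the share
  expect_equal(unname(c2["herbicide"] - c1["herbicide"]), gly_share1)
  expect_equal(unname(c1["operations"] - c2["operations"]), 0)
  # an HD-HR mitigation rotation spends at least as much on glyphosate as BAU
  mit <- load_strategies()[["MIT_HD-HR_heavy_north"]]
  bau <- build_bau("HD-HR", "heavy", "north")
  tot <- function(s) sum(vapply(s$years, `[[`, 0, "glyphosate_dose"))
  expect_gte(tot(mit), tot(bau))
})

test_that("gross profit identity holds exactly, with a hand-computed oracle", {
  prices <- gen_price_tables()
  by <- gen_base_yields()
  pen <- yield_penalty_table(0.2, 0.4)
  d <- density_distribution(c(0.1, 0.1, 0.2, 0.3, 0.3))
  r <- gross_profit_year(toy_wheat_year(), d, prices, by, pen)
  expect_equal(r$gross_profit,
               r$output - (r$cost_herbicide + r$cost_operations +
                             r$cost_other))
  expect_lte(r$output, r$potential_output)
  # arithmetic oracle: base 8 t/ha at 150 GBP/t, 18% loss, 400 GBP costs
  yld <- wheat_yield(8, d, pen)
  expect_equal(yld * 150, 984)
  expect_equal(984 - 400, 584)
  # zero-weed field: no income gap
  r0 <- gross_profit_year(toy_wheat_year(),
                          density_distribution(c(1, 0, 0, 0, 0)),
                          prices, by, pen)
  expect_equal(r0$output, r0$potential_output)
})

test_that("identity and monotonicity hold across all packaged strategies", {
  prices <- gen_price_tables(); by <- gen_base_yields()
  pen <- yield_penalty_table()
  strategies <- c(list(build_bau(), build_cww()), load_strategies())
  worse <- density_distribution(c(0.0, 0.1, 0.2, 0.3, 0.4))
  better <- density_distribution(c(0.2, 0.2, 0.2, 0.2, 0.2))
  for (s in strategies) {
    for (y in s$years) {
      rw <- gross_profit_year(y, worse, prices, by, pen,
                              soil = s$target$soil, region = s$target$region)
      rb <- gross_profit_year(y, better, prices, by, pen,
                              soil = s$target$soil, region = s$target$region)
      expect_equal(rw$gross_profit,
                   rw$output - (rw$cost_herbicide + rw$cost_operations +
                                  rw$cost_other), tolerance = 1e-12)
      # more damaging density never increases yield, output or profit
      expect_lte(rw$wheat_yield, rb$wheat_yield)
      expect_lte(rw$output, rb$output + 1e-12)
      expect_lte(rw$gross_profit, rb$gross_profit + 1e-12)
    }
  }
})

test_that("penalty-bound sensitivity ordering: lower >= central >= upper profit", {
  prices <- gen_price_tables(); by <- gen_base_yields()
  pen <- yield_penalty_table()
  m <- flat_model(n_imp = 2)
  for (s in list(build_bau(), load_strategies()[["MIT_HD-HR_heavy_north"]])) {
    traj <- simulate_density(m, s, worst_case_distribution(), "high",
                             seed = 2)
    gp <- vapply(c("lower", "central", "upper"), function(b) {
      rotation_summary(s, traj, prices, by, pen, bound = b)$mean_gross_profit
    }, numeric(1))
    expect_true(gp["lower"] >= gp["central"] && gp["central"] >= gp["upper"])
  }
})

test_that("rotation summary conventions", {
  m <- flat_model(n_imp = 3)
  bau <- build_bau()
  traj <- simulate_density(m, bau, density_distribution(c(1, 0, 0, 0, 0)),
                           "low", seed = 4)
  rs <- rotation_summary(bau, traj)
  # identical imputations => zero-width envelope
  expect_equal(diff(rs$envelope$gross_profit), 0)
  expect_equal(diff(rs$envelope$wheat_yield), 0)
  # mean annual wheat yield is rotation total over rotation length
  wheat_rows <- rs$per_year[rs$per_year$imputation == 1 &
                              rs$per_year$crop == "winter_wheat", ]
  expect_equal(rs$mean_wheat_yield, sum(wheat_rows$wheat_yield) / 6)
  # constant profit averages to itself
  py <- rs$per_year[rs$per_year$imputation == 1, ]
  expect_equal(rs$mean_gross_profit, mean(py$gross_profit))
})

test_that("wheat production scales with wheat-year count at fixed density", {
  m <- identity_like_model()
  init <- density_distribution(c(1, 0, 0, 0, 0))
  wy <- function(s) {
    traj <- simulate_density(m, s, init, "low", seed = 1)
    rotation_summary(s, traj)$mean_wheat_yield
  }
  y_cww <- wy(build_cww())   # 6 wheat years
  y_bau <- wy(build_bau())   # 4 wheat years
  expect_equal(y_bau / y_cww, 4 / 6, tolerance = 1e-6)
})

test_that("refine_and_average is the unweighted subcategory mean", {
  expect_equal(refine_and_average(c(600, 700)), 650)
  expect_equal(refine_and_average(rep(42, 5)), 42)
  set.seed(8)
  v <- runif(7, 100, 900)
  expect_equal(refine_and_average(v), sum(v) / 7)
  expect_error(refine_and_average(numeric(0)), "non-empty")
})
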