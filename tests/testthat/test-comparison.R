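test_that("opportunity and productivity costs: reported cells, antisymmetry, zero", {
  expect_equal(opportunity_cost(649, 743), -94)
  expect_equal(opportunity_cost(582, 465), 117)
  expect_equal(productivity_cost(4.42, 2.39), 2.03)
  expect_equal(productivity_cost(4.60, 3.25), 1.35)
  set.seed(13)
  for (i in 1:20) {
    a <- runif(1, 100, 900); b <- runif(1, 100, 900)
    expect_equal(opportunity_cost(a, b), -opportunity_cost(b, a))
    expect_equal(productivity_cost(a, b), -productivity_cost(b, a))
  }
  expect_equal(opportunity_cost(432.1, 432.1), 0)
  expect_equal(productivity_cost(3.3, 3.3), 0)
})

test_that("cumulative costs are running sums against the reference", {
  cc <- cumulative_costs(c(100, 100, 100), c(90, 110, 120),
                         c(1, 1, 1), c(1, 1, 1))
  expect_equal(cc$cum_opportunity_cost, c(10, 0, -20))
  expect_equal(cc$cum_productivity_cost, c(0, 0, 0))
  # identical sequences: all-zero series
  cc0 <- cumulative_costs(c(5, 5), c(5, 5), c(2, 2), c(2, 2))
  expect_true(all(cc0$cum_opportunity_cost == 0))
  # 18-year cumulative equals 18 x the mean annual difference
  set.seed(3)
  rp <- runif(18, 400, 700); sp <- runif(18, 400, 700)
  cc18 <- cumulative_costs(rp, sp, rep(4, 18), rep(3, 18))
  expect_equal(cc18$cum_opportunity_cost[18], 18 * mean(rp - sp))
  expect_error(cumulative_costs(1:3, 1:2, 1:3, 1:3), "equal length")
})

test_that("scale-up: single term, linearity, permutation, enumeration oracle", {
  areas1 <- gen_county_areas("Lincs", areas = c(Lincs = 1000))
  areas1$share_LD_LR <- 0; areas1$share_LD_HR <- 0; areas1$share_HD_HR <- 1
  per_ha <- data.frame(region = "east", dr_category = "HD-HR", value = 117)
  expect_equal(scale_up(per_ha, areas1), 117000)

  counties <- c("N.Yorks", "Leics", "Cambs")
  areas3 <- gen_county_areas(counties)
  set.seed(5)
  per_ha3 <- expand.grid(region = c("north", "central", "east"),
                         dr_category = c("LD-LR", "LD-HR", "HD-HR"),
                         stringsAsFactors = FALSE)
  per_ha3$value <- runif(9, -150, 300)
  tot <- scale_up(per_ha3, areas3)
  # enumeration oracle
  share <- c("LD-LR" = "share_LD_LR", "LD-HR" = "share_LD_HR",
             "HD-HR" = "share_HD_HR")
  brute <- 0
  for (i in 1:3) for (cat in names(share)) {
    brute <- brute + areas3$cereal_area[i] * areas3[[share[cat]]][i] *
      per_ha3$value[per_ha3$region == areas3$region[i] &
                      per_ha3$dr_category == cat]
  }
  expect_equal(tot, brute)
  # doubling areas doubles the total
  areas6 <- areas3; areas6$cereal_area <- areas6$cereal_area * 2
  expect_equal(scale_up(per_ha3, areas6), 2 * tot)
  # county order is irrelevant
  expect_equal(scale_up(per_ha3, areas3[3:1, ]), tot)
  expect_error(gen_county_areas("Atlantis"), "Atlantis")
})

test_that("percentage reporting matches the printed precision", {
  expect_equal(percent_of_reference(1287734, 15e6), 8.6)
  expect_equal(percent_of_reference(867055, 15e6), 5.8)
  expect_equal(percent_of_reference(1.638, 8.6, digits = 0), 19)
  expect_error(percent_of_reference(1, 0), "non-zero")
})

test_that("scenario report: degenerate and toy inputs", {
  base <- data.frame(scenario = "BAU", dr_category = "LD-HR", soil = "heavy",
                     region = "north", prop_damaging_final = 0.75,
                     prop_damaging_annual = 0.5, gross_profit = 614.42,
                     wheat_yield = 4.6, stringsAsFactors = FALSE)
  r27 <- base[rep(1, 27), ]
  rep27 <- compare_scenarios(r27)$scenario_summary
  expect_equal(rep27$gross_profit.mean, 614.42)
  expect_equal(rep27$gross_profit.min, rep27$gross_profit.max)
  two <- rbind(base, transform(base, scenario = "MIT", gross_profit = 500,
                               wheat_yield = 3.1, prop_damaging_final = 0.3,
                               prop_damaging_annual = 0.2))
  out <- compare_scenarios(two)
  expect_equal(out$dr_costs$opportunity_cost, 614.42 - 500)
  expect_equal(out$dr_costs$productivity_cost, 4.6 - 3.1)
  expect_equal(nrow(out$scenario_summary), 2)
})

test_that("envelopes bracket contributing values in the report", {
  set.seed(31)
  res <- expand.grid(scenario = c("BAU", "MIT"),
                     dr_category = c("LD-LR", "LD-HR", "HD-HR"),
                     soil = c("heavy", "light"),
                     region = c("north", "east"),
                     stringsAsFactors = FALSE)
  res$prop_damaging_final <- runif(nrow(res))
  res$prop_damaging_annual <- runif(nrow(res))
  res$gross_profit <- runif(nrow(res), 300, 900)
  res$wheat_yield <- runif(nrow(res), 2, 6)
  summ <- compare_scenarios(res)$scenario_summary
  for (i in seq_len(nrow(summ))) {
    d <- res[res$scenario == summ$scenario[i], ]
    expect_equal(summ$gross_profit.min[i], min(d$gross_profit))
    expect_equal(summ$gross_profit.max[i], max(d$gross_profit))
    expect_true(summ$gross_profit.min[i] <= summ$gross_profit.mean[i] &&
                  summ$gross_profit.mean[i] <= summ$gross_profit.max[i])
  }
})
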