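test_that("survey generator honours the category mix and is deterministic", {
  cfg <- synthetic_config(n_fields = 1000, grid_dims = c(5, 5),
                          category_mix = c(0.14, 0.56, 0.30), seed = 1)
  d1 <- gen_survey_data(cfg)
  d2 <- gen_survey_data(cfg)
  expect_identical(d1, d2)   # byte-identical on same config + seed
  prop <- prop.table(table(factor(d1$truth$category,
                                  c("LD-LR", "LD-HR", "HD-HR"))))
  se <- sqrt(c(0.14, 0.56, 0.30) * c(0.86, 0.44, 0.70) / 1000)
  expect_true(all(abs(as.numeric(prop) - c(0.14, 0.56, 0.30)) <= 3 * se))
})

test_that("degenerate mix: all fields classify LD-LR", {
  cfg <- synthetic_config(n_fields = 10, category_mix = c(1, 0, 0),
                          grid_dims = c(10, 10), seed = 7)
  d <- gen_survey_data(cfg)
  cl <- classify_fields(d$surveys, d$assays)
  expect_true(all(cl$dr_category == "LD-LR"))
})

test_that("config validation rejects bad inputs", {
  expect_error(synthetic_config(n_fields = 10,
                                category_mix = c(0.5, 0.4, 0.2), seed = 1),
               "summing to 1")
  expect_error(synthetic_config(n_fields = 0, seed = 1), "at least one")
  expect_error(synthetic_config(n_fields = 10), "seed is mandatory")
})

test_that("management histories: structure, withheld transitions, determinism", {
  cfg <- synthetic_config(n_fields = 70, grid_dims = c(3, 3), seed = 2)
  d <- gen_survey_data(cfg)
  h1 <- gen_management_histories(d$surveys, seed = 2)
  h2 <- gen_management_histories(d$surveys, seed = 2)
  expect_identical(h1, h2)
  yrs <- tapply(h1$year, h1$field_id, length)
  expect_true(all(yrs >= 2))   # every field has at least one transition
  withheld <- "spring_beans->winter_wheat"
  h3 <- gen_management_histories(d$surveys, seed = 2, withheld = withheld)
  pairs <- unlist(tapply(h3$crop, h3$field_id, function(cr) {
    paste(head(cr, -1), tail(cr, -1), sep = "->")
  }))
  expect_false(withheld %in% pairs)
  expect_error(gen_management_histories(d$surveys[0, ], seed = 1), "empty")
  expect_error(gen_management_histories(d$surveys, seed = 1,
                                        withheld = "wheat->maize"),
               "not in the crop set")
})

test_that("transition dataset samples from the exact model distribution", {
  cfg <- synthetic_config(n_fields = 50, grid_dims = c(2, 2), seed = 5)
  d <- gen_survey_data(cfg)
  h <- gen_management_histories(d$surveys, seed = 5, n_years = 2)

  # identity-like model: every quadrat keeps its state
  rec <- gen_transition_dataset(identity_like_model(), h, seed = 5,
                                n_quadrats = 40)
  expect_identical(rec$next_state, rec$prev_state)
  expect_equal(nrow(rec), 50 * 40)   # quadrats x (years - 1)

  # flat model: marginal next-state frequencies converge to the logistic
  # CDF differences at the cutpoints, within 3 binomial SE at n = 10,000
  rec2 <- gen_transition_dataset(flat_model(), h, seed = 6,
                                 n_quadrats = 200)
  expect_equal(nrow(rec2), 10000)
  freq <- prop.table(table(factor(rec2$next_state, 0:4)))
  p <- flat_expected()
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(as.numeric(freq) - p) <= 3 * se))

  # determinism
  expect_identical(rec2, gen_transition_dataset(flat_model(), h, seed = 6,
                                                n_quadrats = 200))

  # vocabulary mismatch is an error, not silence
  narrow <- transition_model(c(-2, -1, 1, 2),
                             u = list(crop_transition = matrix(
                               0, 1, 1, dimnames = list(NULL, "winter_wheat->winter_wheat"))))
  expect_error(gen_transition_dataset(narrow, h, seed = 1),
               "vocabulary mismatch")
})

test_that("county and price tables are complete and round-trip", {
  tab <- county_region_table()
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$region %in% c("north", "central", "east")))
  expect_error(region_for_county("Cornwall"), "Cornwall")

  pt <- gen_price_tables()
  expect_true(all(crop_vocabulary() %in% names(pt$crop_price)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_price_table(pt, path)
  pt2 <- gen_price_tables(path)
  expect_equal(pt2$crop_price, pt$crop_price)
  expect_equal(pt2$operation_cost, pt$operation_cost)
  expect_equal(pt2$other_cost, pt$other_cost)
  expect_equal(pt2$herbicide_cost, pt$herbicide_cost)
})
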