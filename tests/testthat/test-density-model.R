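test_that("covariate encoding is deterministic and flags unseen transitions", {
  bau <- build_bau()
  # year 3 is oilseed rape after wheat
  c3 <- encode_covariates(bau$years[[3]], prev_crop = "winter_wheat")
  expect_identical(c3$crop_transition, "winter_wheat->winter_oilseed_rape")
  expect_identical(c3, encode_covariates(bau$years[[3]],
                                         prev_crop = "winter_wheat"))
  # missing-transition flag against a model with a restricted dictionary
  narrow <- transition_model(c(-2, -1, 1, 2),
                             u = list(crop_transition = matrix(
                               0.5, 1, 1,
                               dimnames = list(NULL, "winter_wheat->winter_wheat"))))
  cov <- encode_covariates(bau$years[[3]], "winter_wheat", model = narrow)
  expect_true(cov$missing)
  cov2 <- encode_covariates(bau$years[[1]], "winter_wheat", model = narrow)
  expect_false(cov2$missing)
  expect_error(encode_covariates(bau$years[[1]], "maize"))
  # proxies are applied before encoding and recorded
  covp <- encode_covariates(bau$years[[3]], "winter_wheat", model = narrow,
                            proxy_map = c("winter_wheat->winter_oilseed_rape" =
                                            "winter_wheat->winter_wheat"))
  expect_false(covp$missing)
  expect_true(covp$proxied)
})

test_that("transition matrix is the cumulative-logit Markov kernel", {
  cov <- encode_covariates(toy_wheat_year(), "winter_wheat")
  # zero coefficients: every row equals the logistic CDF differences
  M <- transition_matrix(flat_model(), cov)
  for (s in 1:5) {
    expect_equal(unname(M[s, ]), flat_expected(), tolerance = 1e-9)
  }
  expect_equal(unname(round(M[1, ], 4)),
               c(0.1192, 0.1497, 0.4621, 0.1497, 0.1192), tolerance = 1e-4)
  # rows always sum to 1, including under random coefficients
  set.seed(11)
  for (i in 1:5) {
    rb <- rnorm(length(weedrot:::fixed_effect_names()))
    names(rb) <- weedrot:::fixed_effect_names()
    Mr <- transition_matrix(transition_model(sort(rnorm(4, sd = 2)) +
                                               c(0, 1e-3, 2e-3, 3e-3),
                                             beta = rb), cov)
    expect_equal(unname(rowSums(Mr)), rep(1, 5), tolerance = 1e-12)
  }
  # a large positive effect concentrates mass on very_high
  big <- transition_model(c(-2, -1, 1, 2),
                          beta = c(resistance_high = 50))
  Mb <- transition_matrix(big, encode_covariates(toy_wheat_year(),
                                                 "winter_wheat", "high"))
  expect_true(all(Mb[, "very_high"] > 1 - 1e-9))
})

test_that("raising eta shifts the next state up (stochastic dominance)", {
  cov_lo <- encode_covariates(toy_wheat_year(), "winter_wheat", "low")
  cov_hi <- encode_covariates(toy_wheat_year(), "winter_wheat", "high")
  m <- transition_model(c(-2, -1, 1, 2), beta = c(resistance_high = 1.5))
  M_lo <- transition_matrix(m, cov_lo)
  M_hi <- transition_matrix(m, cov_hi)
  for (s in 1:5) {
    # higher eta => cumulative distribution everywhere below (mass higher)
    expect_true(all(cumsum(M_hi[s, 1:4]) < cumsum(M_lo[s, 1:4])))
  }
})

test_that("simulate_density matches the explicit matrix-chain oracle", {
  set.seed(21)
  rb <- c(prev_state2 = 1, prev_state3 = 2, prev_state4 = 3,
          prev_state5 = 4, sowing_spring = -0.8, n_stale_seedbeds = -0.3)
  m <- transition_model(c(-1, 0, 1, 2), beta = rb)
  spring <- management_year("spring_barley", "spring", "min_till",
                            n_stale_seedbeds = 2)
  plan <- list(toy_wheat_year(), spring, toy_wheat_year())
  init <- density_distribution(c(0.2, 0.2, 0.2, 0.2, 0.2))
  traj <- simulate_density(m, plan, init, "high", seed = 1)
  # oracle: hand-multiplied chain
  p <- as.numeric(init)
  prev <- "winter_wheat"
  for (t in 1:3) {
    covt <- encode_covariates(plan[[t]], prev, "high", model = m)
    p <- as.numeric(p %*% transition_matrix(m, covt, 1))
    prev <- plan[[t]]$crop
  }
  expect_equal(as.numeric(trajectory_distribution(traj, 3, 1)), p,
               tolerance = 1e-12)
  expect_equal(max(traj$years), 3)
  # identity model: trajectory constant at the initial distribution
  ti <- simulate_density(identity_like_model(), plan, init, "high", seed = 1)
  for (y in ti$years) {
    expect_equal(as.numeric(trajectory_distribution(ti, y, 1)),
                 as.numeric(init), tolerance = 1e-6)
  }
})

test_that("probability is conserved and envelopes bracket imputations", {
  m <- flat_model(n_imp = 6)
  mit <- load_strategies()[["MIT_HD-HR_heavy_north"]]
  traj <- simulate_density(m, mit, worst_case_distribution(), "high",
                           seed = 3)
  sums <- apply(traj$p, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(traj$min <= traj$mean + 1e-12) &&
                all(traj$mean <= traj$max + 1e-12))
})

test_that("missing transitions get per-imputation draws, reproducibly", {
  narrow <- transition_model(
    matrix(rep(c(-2, -1, 1, 2), 8), 8, 4, byrow = TRUE),
    u = list(crop_transition = matrix(
      0, 8, 1, dimnames = list(NULL, "winter_wheat->winter_wheat"))),
    sigma = list(crop_transition = 1, rotation = 0.3, field = 0.3))
  mit <- load_strategies()[["MIT_LD-HR_medium_central"]]
  t1 <- simulate_density(narrow, mit, worst_case_distribution(), "high",
                         seed = 9)
  expect_gt(length(t1$imputed_transitions), 0)
  # imputations genuinely differ (independent random-effect draws)
  final <- t1$p[, dim(t1$p)[2], ]
  expect_gt(max(apply(final, 2, sd)), 0)
  t2 <- simulate_density(narrow, mit, worst_case_distribution(), "high",
                         seed = 9)
  expect_identical(t1$p, t2$p)
})

test_that("fit recovers generating parameters on a moderate dataset", {
  w <- small_world(seed = 101, n_fields = 50, grid = c(4, 4), n_years = 6)
  fit <- fit_transition_model(w$records, n_imputations = 1, seed = 101)
  truth <- synthetic_true_model()$beta[1, ]
  sc <- fit$scaling
  for (v in sc$var) truth[v] <- truth[v] * sc$scale[sc$var == v]
  est <- fit$beta[1, ]
  expect_lt(max(abs(est - truth)), 0.3)   # looser than acceptance (n ~ 4000)
  expect_equal(fit$diagnostics$convergence, 0)
  expect_error(fit_transition_model(transform(w$records, next_state = 2)),
               "degenerate")
})

test_that("fit agrees with the proportional-odds reference on RE-free data", {
  skip_if_not_installed("MASS")
  w <- small_world(seed = 55, n_fields = 60, grid = c(4, 4), n_years = 5)
  rec <- w$records
  fit <- fit_transition_model(rec, n_imputations = 1, seed = 55)
  df <- data.frame(y = ordered(rec$next_state),
                   s2 = as.numeric(rec$prev_state == 1),
                   s3 = as.numeric(rec$prev_state == 2),
                   s4 = as.numeric(rec$prev_state == 3),
                   s5 = as.numeric(rec$prev_state == 4),
                   spring = as.numeric(rec$sowing_window == "spring"),
                   late = as.numeric(rec$sowing_window == "late_autumn"),
                   none = as.numeric(rec$sowing_window == "none"),
                   mint = as.numeric(rec$tillage == "min_till"),
                   notill = as.numeric(rec$tillage == "no_till"),
                   stale = rec$n_stale_seedbeds,
                   gly = rec$glyphosate_applications,
                   sel = rec$selective_applications,
                   rate = rec$seed_rate,
                   res = as.numeric(rec$resistance == "high"))
  po <- MASS::polr(y ~ s2 + s3 + s4 + s5 + late + spring + none + mint +
                     notill + stale + gly + sel + rate + res, data = df)
  # put the package fit back on the raw covariate scale for comparison
  est <- fit$beta[1, ]
  sc <- fit$scaling
  for (v in sc$var) est[v] <- est[v] / sc$scale[sc$var == v]
  ref <- po$coefficients[c("s2", "s3", "s4", "s5", "late", "spring", "none",
                           "mint", "notill", "stale", "gly", "sel", "rate",
                           "res")]
  expect_equal(unname(est), unname(ref), tolerance = 0.05)
})

test_that("models round-trip through JSON", {
  w <- small_world(seed = 77, n_fields = 20, grid = c(3, 3), n_years = 4)
  fit <- fit_transition_model(w$records, n_imputations = 3, seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  save_transition_model(fit, path)
  back <- load_transition_model(path)
  expect_equal(back$cutpoints, fit$cutpoints)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$u$crop_transition, fit$u$crop_transition)
  expect_equal(back$sigma, fit$sigma)
  cov <- encode_covariates(toy_wheat_year(), "winter_wheat", model = back)
  expect_equal(transition_matrix(back, cov, 2),
               transition_matrix(fit, cov, 2), tolerance = 1e-12)
})
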