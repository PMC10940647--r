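# Shared fixtures, all built in code.

# near-deterministic model: state s maps back to s with P ~ 1 - 4e-9
identity_like_model <- function() {
  transition_model(
    cutpoints = c(20, 60, 100, 140),
    beta = c(prev_state2 = 40, prev_state3 = 80, prev_state4 = 120,
             prev_state5 = 160))
}

# flat model: no covariate effects, marginal next-state distribution fixed
# by the cutpoints alone
flat_model <- function(cutpoints = c(-2, -1, 1, 2), n_imp = 1) {
  transition_model(cutpoints = matrix(rep(cutpoints, n_imp), n_imp, 4,
                                      byrow = TRUE))
}

# expected marginal for cutpoints (-2,-1,1,2): logistic CDF differences
flat_expected <- function(cutpoints = c(-2, -1, 1, 2)) {
  diff(c(0, plogis(cutpoints), 1))
}

toy_wheat_year <- function(...) {
  management_year("winter_wheat", "late_autumn", "min_till",
                  n_stale_seedbeds = 1, glyphosate_applications = 1,
                  glyphosate_dose = 1.5, selective_applications = 2,
                  selective_dose = 2, ...)
}

# small synthetic world shared by recovery-style tests
small_world <- function(seed, n_fields = 40, grid = c(5, 5), n_years = 6,
                        resistance_from_assays = TRUE) {
  cfg <- synthetic_config(n_fields = n_fields, grid_dims = grid, seed = seed)
  d <- gen_survey_data(cfg)
  cl <- classify_fields(d$surveys, d$assays)
  hist <- gen_management_histories(d$surveys, seed = seed + 1,
                                   n_years = n_years)
  res <- if (resistance_from_assays) {
    stats::setNames(cl$resistance, cl$field_id)
  } else "high"
  grids <- split(d$surveys$state, d$surveys$field_id)
  rec <- gen_transition_dataset(synthetic_true_model(), hist,
                                seed = seed + 2, initial_states = grids,
                                resistance = res)
  list(cfg = cfg, data = d, classified = cl, histories = hist, records = rec)
}
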