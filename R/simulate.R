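# Stage 3, part 2: project a field's density-state distribution forward
# under a management plan. The update is distribution-level Markov:
# p_{t} = p_{t-1} M_t, where M_t is the transition matrix implied by year
# t's covariates (crop transition = previous year's crop -> this year's
# crop). Resistance is held fixed throughout: the model does not let
# resistance evolve.

#' Simulate a density-state trajectory under a management plan
#'
#' For every imputation, iterates `p_t = p_{t-1} %*% M_t` over the plan's
#' years, where `M_t` comes from [transition_matrix()] for year `t`'s
#' covariates. Crop transitions absent from the model's design dictionary
#' receive one independent draw from the fitted crop-transition
#' random-effect distribution per imputation (the multiple-imputation path);
#' every applied proxy and imputed transition is recorded on the result.
#' Trajectories include year 0 (the initial distribution), so "year 6" is
#' read at index 6.
#'
#' @param model A `transition_model`.
#' @param plan A `strategy`, `sequence_plan`, or list of
#'   [management_year()]s.
#' @param initial Initial `density_distribution` (year 0).
#' @param resistance "low" or "high"; held constant over the whole run.
#' @param seed Integer seed for the missing-transition imputation draws.
#' @param prev_crop_initial Crop assumed grown the year before the plan
#'   starts (default winter wheat, the dominant preceding crop).
#' @param proxy_map Optional named character vector of crop-transition
#'   proxies applied before encoding (see [encode_covariates()]).
#' @return A `density_trajectory`: list with array `p`
#'   (imputations x years+1 x 5), `mean`, `min`, `max` (years+1 x 5
#'   matrices), `years` (0..T), `imputed_transitions`, `proxied_transitions`.
#' @export
simulate_density <- function(model, plan, initial, resistance = "high",
                             seed = 1L, prev_crop_initial = "winter_wheat",
                             proxy_map = NULL) {
  stopifnot(inherits(model, "transition_model"))
  initial <- density_distribution(initial)
  years <- plan_years(plan)
  T_len <- length(years)
  n_imp <- model$n_imputations

  prev <- prev_crop_initial
  covs <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    covs[[t]] <- encode_covariates(years[[t]], prev, resistance,
                                   model = model, proxy_map = proxy_map)
    prev <- years[[t]]$crop
  }
  cts <- vapply(covs, `[[`, character(1), "crop_transition")
  missing_ct <- unique(cts[vapply(covs, `[[`, logical(1), "missing")])
  proxied <- unique(cts[vapply(covs, `[[`, logical(1), "proxied")])

  # one independent crop-transition draw per (imputation, unseen transition)
  imputed_u <- matrix(0, n_imp, length(missing_ct),
                      dimnames = list(NULL, missing_ct))
  if (length(missing_ct)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    imputed_u[] <- stats::rnorm(n_imp * length(missing_ct),
                                sd = model$sigma$crop_transition)
  }

  p <- array(NA_real_, dim = c(n_imp, T_len + 1L, 5L),
             dimnames = list(NULL, paste0("year", 0:T_len), density_states()))
  for (j in seq_len(n_imp)) {
    cur <- as.numeric(initial)
    p[j, 1, ] <- cur
    for (t in seq_len(T_len)) {
      ov <- if (covs[[t]]$missing) imputed_u[j, covs[[t]]$crop_transition]
            else NULL
      M <- transition_matrix(model, covs[[t]], imputation = j,
                             u_ct_override = ov)
      cur <- as.numeric(cur %*% M)
      cur <- cur / sum(cur)  # guard against accumulated round-off
      p[j, t + 1L, ] <- cur
    }
  }
  agg <- function(f) apply(p, c(2, 3), f)
  mean_p <- agg(mean)
  mean_p <- mean_p / rowSums(mean_p)
  structure(list(p = p, mean = mean_p, min = agg(min), max = agg(max),
                 years = 0:T_len, resistance = resistance,
                 imputed_transitions = missing_ct,
                 proxied_transitions = proxied),
            class = "density_trajectory")
}

#' @export
print.density_trajectory <- function(x, ...) {
  cat(sprintf("density trajectory: %d imputation(s), years 0..%d\n",
              dim(x$p)[1], max(x$years)))
  if (length(x$imputed_transitions)) {
    cat("  imputed crop transitions:",
        paste(x$imputed_transitions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Distribution at a given year of a trajectory
#'
#' @param traj A `density_trajectory`.
#' @param year Year index (0 = initial).
#' @param imputation Imputation index, or `NULL` for the across-imputation
#'   mean.
#' @return A `density_distribution`.
#' @export
trajectory_distribution <- function(traj, year, imputation = NULL) {
  stopifnot(inherits(traj, "density_trajectory"))
  if (!year %in% traj$years) stop("year ", year, " outside trajectory")
  i <- year + 1L
  v <- if (is.null(imputation)) traj$mean[i, ] else traj$p[imputation, i, ]
  density_distribution(v / sum(v))
}

#' Per-year damaging proportion of a trajectory
#'
#' @param traj A `density_trajectory`.
#' @param imputation Imputation index or `NULL` for the mean trajectory.
#' @return Numeric vector over years 0..T of `prop_damaging`.
#' @export
trajectory_prop_damaging <- function(traj, imputation = NULL) {
  vapply(traj$years, function(y) {
    prop_damaging(trajectory_distribution(traj, y, imputation))
  }, numeric(1))
}

#' Export a trajectory as tidy data
#'
#' @param traj A `density_trajectory`.
#' @return Data frame with columns imputation, year, state, proportion.
#' @export
trajectory_to_df <- function(traj) {
  d <- dim(traj$p)
  expand <- expand.grid(imputation = seq_len(d[1]), year = traj$years,
                        state = density_states(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand$proportion <- as.vector(traj$p)
  expand[order(expand$imputation, expand$year), ]
}
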