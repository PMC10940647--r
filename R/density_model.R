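# Stage 3, part 1: the density-structured transition model. A hierarchical
# proportional-odds cumulative-logit regression maps (previous density state,
# management covariates, resistance) to the distribution of the next ordinal
# state:
#
#   P(state_{t+1} <= k | x) = logistic(c_k - eta),
#   eta = x'beta + u_croptrans + u_rotation + u_field,
#
# with strictly increasing cutpoints c_1 < ... < c_4 and zero-mean Gaussian
# random effects for crop transition, rotation and field. Missing crop
# transitions (pairs never observed in training) are multiply imputed: each
# of the n_imputations coefficient sets carries an independent draw from the
# fitted crop-transition random-effect distribution.

fixed_effect_names <- function() {
  c("prev_state2", "prev_state3", "prev_state4", "prev_state5",
    "sowing_late_autumn", "sowing_spring", "sowing_none",
    "tillage_min_till", "tillage_no_till",
    "n_stale_seedbeds", "glyphosate_applications",
    "selective_applications", "seed_rate", "resistance_high")
}

numeric_covariates <- function() {
  c("n_stale_seedbeds", "glyphosate_applications",
    "selective_applications", "seed_rate")
}

default_scaling <- function() {
  data.frame(var = numeric_covariates(), center = 0, scale = 1,
             stringsAsFactors = FALSE)
}

#' Construct a transition model from explicit parameters
#'
#' Builds the fitted-model container directly from coefficient sets; used by
#' the fitter, by the synthetic-data generator (as a known true model), and
#' in tests. All parameter matrices have one row per imputation.
#'
#' @param cutpoints Numeric matrix `n_imp x 4` of strictly increasing ordinal
#'   thresholds (a plain vector of 4 is recycled to one imputation).
#' @param beta Numeric matrix `n_imp x p`, columns named as in
#'   `weedrot:::fixed_effect_names()`; omitted effects are taken as 0.
#' @param u Named list of random-effect matrices (`crop_transition`,
#'   `rotation`, `field`), each `n_imp x q` with level names as columns. May
#'   be empty.
#' @param sigma Named list of random-effect standard deviations (scalars).
#' @param scaling Data frame (var, center, scale) used to standardise the
#'   numeric covariates before applying `beta`; defaults to identity.
#' @param diagnostics Optional list of fit diagnostics.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(cutpoints, beta = NULL, u = list(),
                             sigma = list(crop_transition = 0.5,
                                          rotation = 0.5, field = 0.5),
                             scaling = default_scaling(),
                             diagnostics = NULL) {
  if (is.null(dim(cutpoints))) cutpoints <- matrix(cutpoints, nrow = 1)
  if (ncol(cutpoints) != 4L) stop("5 states need exactly 4 cutpoints")
  if (any(apply(cutpoints, 1, function(r) any(diff(r) <= 0)))) {
    stop("cutpoints must be strictly increasing within every imputation")
  }
  n_imp <- nrow(cutpoints)
  full <- matrix(0, n_imp, length(fixed_effect_names()),
                 dimnames = list(NULL, fixed_effect_names()))
  if (!is.null(beta)) {
    if (is.null(dim(beta))) beta <- matrix(beta, nrow = n_imp,
                                           ncol = length(beta), byrow = TRUE,
                                           dimnames = list(NULL, names(beta)))
    unknown <- setdiff(colnames(beta), fixed_effect_names())
    if (length(unknown)) stop("unknown fixed effect(s): ",
                              paste(unknown, collapse = ", "))
    full[, colnames(beta)] <- beta
  }
  structure(list(n_imputations = n_imp, cutpoints = cutpoints, beta = full,
                 u = u, sigma = sigma, scaling = scaling,
                 vocab = list(crop_transitions =
                                if (!is.null(u$crop_transition))
                                  colnames(u$crop_transition) else character(0)),
                 diagnostics = diagnostics),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition model: %d imputation(s), %d crop transitions,\n",
              x$n_imputations, length(x$vocab$crop_transitions)))
  cat(sprintf("  cutpoints (imp 1): %s\n",
              paste(round(x$cutpoints[1, ], 3), collapse = ", ")))
  cat(sprintf("  sigma: ct %.3f, rotation %.3f, field %.3f\n",
              x$sigma$crop_transition, x$sigma$rotation, x$sigma$field))
  invisible(x)
}

crop_transition_label <- function(prev_crop, crop) {
  paste(prev_crop, crop, sep = "->")
}

#' Encode a management year as a covariate vector
#'
#' Deterministic fixed-effect encoding of one year of management plus the
#' crop transition into it. An optional proxy map replaces crop transitions
#' with stand-ins before encoding (each application is recorded in the
#' result). A transition absent from the model's design dictionary is flagged
#' missing — triggering the imputation path — never silently zeroed.
#'
#' @param year A [management_year()].
#' @param prev_crop Crop grown the previous year.
#' @param resistance "low" or "high" (held fixed: resistance does not
#'   evolve).
#' @param model Optional `transition_model` supplying the design dictionary
#'   and covariate scaling.
#' @param proxy_map Optional named character vector mapping crop-transition
#'   labels (e.g. `"spring_beans->winter_wheat"`) to stand-in labels.
#' @return List with `x` (named numeric fixed-effect vector, excluding the
#'   previous-state terms), `crop_transition`, `proxied`, `missing`.
#' @export
encode_covariates <- function(year, prev_crop, resistance = "high",
                              model = NULL, proxy_map = NULL) {
  stopifnot(inherits(year, "management_year"))
  prev_crop <- match.arg(prev_crop, crop_vocabulary())
  resistance <- match.arg(resistance, c("low", "high"))
  ct <- crop_transition_label(prev_crop, year$crop)
  proxied <- FALSE
  if (!is.null(proxy_map) && ct %in% names(proxy_map)) {
    ct <- unname(proxy_map[[ct]])
    proxied <- TRUE
  }
  scaling <- if (is.null(model)) default_scaling() else model$scaling
  sc <- function(var, value) {
    row <- scaling[scaling$var == var, ]
    (value - row$center) / row$scale
  }
  x <- c(sowing_late_autumn = as.numeric(year$sowing_window == "late_autumn"),
         sowing_spring = as.numeric(year$sowing_window == "spring"),
         sowing_none = as.numeric(year$sowing_window == "none"),
         tillage_min_till = as.numeric(year$tillage == "min_till"),
         tillage_no_till = as.numeric(year$tillage == "no_till"),
         n_stale_seedbeds = sc("n_stale_seedbeds", year$n_stale_seedbeds),
         glyphosate_applications = sc("glyphosate_applications",
                                      year$glyphosate_applications),
         selective_applications = sc("selective_applications",
                                     year$selective_applications),
         seed_rate = sc("seed_rate", year$seed_rate),
         resistance_high = as.numeric(resistance == "high"))
  # a model with no registered crop transitions models them all as exactly
  # zero deviations; only a non-empty dictionary can declare one missing
  missing <- if (is.null(model) ||
                 length(model$vocab$crop_transitions) == 0L) FALSE else
    !(ct %in% model$vocab$crop_transitions)
  list(x = x, crop_transition = ct, proxied = proxied, missing = missing)
}

# linear predictor shared by all rows of a transition matrix (everything
# except the previous-state effect)
base_eta <- function(model, cov, imputation, u_ct_override = NULL) {
  b <- model$beta[imputation, ]
  eta <- sum(b[names(cov$x)] * cov$x)
  u_ct <- if (!is.null(u_ct_override)) {
    u_ct_override
  } else if (!cov$missing &&
             cov$crop_transition %in% model$vocab$crop_transitions) {
    model$u$crop_transition[imputation, cov$crop_transition]
  } else 0
  eta + u_ct
}

#' Transition matrix implied by the model for given covariates
#'
#' The explicit Markov form of the ordinal regression: row `s` is the
#' next-state distribution given previous state `s` (1 = absent .. 5 =
#' very_high) under the supplied management covariates. Rows are differences
#' of the logistic CDF at the cutpoints and sum to 1 by construction.
#'
#' @param model A `transition_model`.
#' @param covariates Output of [encode_covariates()].
#' @param imputation Imputation index (1-based).
#' @param u_ct_override Optional crop-transition random-effect value to use
#'   instead of a dictionary lookup (the imputation path for missing
#'   transitions).
#' @return A 5x5 row-stochastic matrix.
#' @export
transition_matrix <- function(model, covariates, imputation = 1L,
                              u_ct_override = NULL) {
  stopifnot(inherits(model, "transition_model"))
  if (imputation < 1L || imputation > model$n_imputations) {
    stop("imputation index out of range")
  }
  eta0 <- base_eta(model, covariates, imputation, u_ct_override)
  b <- model$beta[imputation, ]
  prev_eff <- c(0, b[paste0("prev_state", 2:5)])
  cp <- model$cutpoints[imputation, ]
  M <- t(vapply(seq_len(5), function(s) {
    eta <- eta0 + prev_eff[s]
    cum <- c(stats::plogis(cp - eta), 1)
    diff(c(0, cum))
  }, numeric(5)))
  dimnames(M) <- list(density_states(), density_states())
  M
}

# ---- fitting -----------------------------------------------------------

build_design <- function(records) {
  need <- c("prev_state", "next_state", "prev_crop", "crop", "sowing_window",
            "tillage", "n_stale_seedbeds", "glyphosate_applications",
            "selective_applications", "seed_rate", "resistance",
            "field_id", "rotation_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(records$next_state)) < 2L) {
    stop("degenerate data: all observed next states identical")
  }
  scaling <- default_scaling()
  for (v in numeric_covariates()) {
    scaling$center[scaling$var == v] <- mean(records[[v]])
    s <- stats::sd(records[[v]])
    scaling$scale[scaling$var == v] <- if (is.na(s) || s < 1e-12) 1 else s
  }
  sc <- function(v) (records[[v]] - scaling$center[scaling$var == v]) /
    scaling$scale[scaling$var == v]
  X <- cbind(prev_state2 = as.numeric(records$prev_state == 1),
             prev_state3 = as.numeric(records$prev_state == 2),
             prev_state4 = as.numeric(records$prev_state == 3),
             prev_state5 = as.numeric(records$prev_state == 4),
             sowing_late_autumn = as.numeric(records$sowing_window == "late_autumn"),
             sowing_spring = as.numeric(records$sowing_window == "spring"),
             sowing_none = as.numeric(records$sowing_window == "none"),
             tillage_min_till = as.numeric(records$tillage == "min_till"),
             tillage_no_till = as.numeric(records$tillage == "no_till"),
             n_stale_seedbeds = sc("n_stale_seedbeds"),
             glyphosate_applications = sc("glyphosate_applications"),
             selective_applications = sc("selective_applications"),
             seed_rate = sc("seed_rate"),
             resistance_high = as.numeric(records$resistance == "high"))
  ct <- factor(crop_transition_label(records$prev_crop, records$crop))
  rot <- factor(records$rotation_id)
  fld <- factor(records$field_id)
  list(X = X, y = records$next_state + 1L, ct = ct, rot = rot, fld = fld,
       scaling = scaling)
}

# Negative penalised log-likelihood and analytic gradient for the cumulative
# logit. theta = (a1, log d2..4, beta, u_ct, u_rot, u_fld); cutpoints are
# a1 + cumsum(0, exp(log d)).
make_objective <- function(des, sigma) {
  X <- des$X; y <- des$y
  n <- length(y); p <- ncol(X)
  q1 <- nlevels(des$ct); q2 <- nlevels(des$rot); q3 <- nlevels(des$fld)
  i_ct <- as.integer(des$ct); i_rot <- as.integer(des$rot)
  i_fld <- as.integer(des$fld)
  idx <- list(cut = 1:4, beta = 4 + seq_len(p),
              ct = 4 + p + seq_len(q1), rot = 4 + p + q1 + seq_len(q2),
              fld = 4 + p + q1 + q2 + seq_len(q3))
  has_upper <- y <= 4L   # A = c_y finite
  has_lower <- y >= 2L   # B = c_{y-1} finite
  pen_scale <- function(sig) 1 / (2 * max(sig, 1e-3)^2)
  unpack_cuts <- function(th) {
    d <- exp(th[2:4])
    list(cp = th[1] + cumsum(c(0, d)), d = d)
  }
  eta_of <- function(th) {
    as.numeric(X %*% th[idx$beta]) + th[idx$ct][i_ct] +
      th[idx$rot][i_rot] + th[idx$fld][i_fld]
  }
  probs <- function(th) {
    cuts <- unpack_cuts(th); cp <- cuts$cp
    eta <- eta_of(th)
    A <- ifelse(has_upper, cp[pmin(y, 4L)] - eta, Inf)
    B <- ifelse(has_lower, cp[pmax(y - 1L, 1L)] - eta, -Inf)
    FA <- stats::plogis(A); FB <- stats::plogis(B)
    P <- pmax(FA - FB, 1e-12)
    list(cp = cp, d = cuts$d, eta = eta, A = A, B = B, FA = FA, FB = FB,
         P = P)
  }
  # weak ridge on the fixed effects (prior sd 100): negligible bias, keeps
  # the problem well-posed when a design column has no variation
  lam_beta <- 1 / (2 * 100^2)
  nll <- function(th) {
    pr <- probs(th)
    -sum(log(pr$P)) + lam_beta * sum(th[idx$beta]^2) +
      pen_scale(sigma$crop_transition) * sum(th[idx$ct]^2) +
      pen_scale(sigma$rotation) * sum(th[idx$rot]^2) +
      pen_scale(sigma$field) * sum(th[idx$fld]^2)
  }
  grad <- function(th) {
    pr <- probs(th)
    fA <- ifelse(is.finite(pr$A), pr$FA * (1 - pr$FA), 0)
    fB <- ifelse(is.finite(pr$B), pr$FB * (1 - pr$FB), 0)
    w_eta <- (fA - fB) / pr$P          # d(-logP)/d eta
    g <- numeric(length(th))
    g[idx$beta] <- as.numeric(crossprod(X, w_eta)) +
      2 * lam_beta * th[idx$beta]
    g[idx$ct] <- tapply_sum(w_eta, i_ct, q1) +
      2 * pen_scale(sigma$crop_transition) * th[idx$ct]
    g[idx$rot] <- tapply_sum(w_eta, i_rot, q2) +
      2 * pen_scale(sigma$rotation) * th[idx$rot]
    g[idx$fld] <- tapply_sum(w_eta, i_fld, q3) +
      2 * pen_scale(sigma$field) * th[idx$fld]
    # cutpoint block: d(-logP)/dA = -fA/P, d(-logP)/dB = +fB/P
    wA <- -fA / pr$P; wB <- fB / pr$P
    g[1] <- sum(wA[has_upper]) + sum(wB[has_lower])
    for (m in 2:4) {
      contrA <- wA[has_upper & y >= m]
      contrB <- wB[has_lower & (y - 1L) >= m]
      g[m] <- pr$d[m - 1] * (sum(contrA) + sum(contrB))
    }
    g
  }
  list(nll = nll, grad = grad, idx = idx, n = n, p = p,
       levels = list(ct = levels(des$ct), rot = levels(des$rot),
                     fld = levels(des$fld)))
}

tapply_sum <- function(x, index, nlev) {
  out <- numeric(nlev)
  s <- rowsum(x, index)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit the hierarchical ordinal transition model
#'
#' Maximum penalised-likelihood estimation of the cumulative-logit transition
#' model with ridge (Gaussian) penalties on the three random-effect blocks,
#' alternating coefficient optimisation (BFGS with analytic gradients) with
#' moment updates of the random-effect standard deviations. Multiple
#' imputation is realised at prediction time: the returned model carries
#' `n_imputations` coefficient sets which are identical for everything
#' observed in training, and [simulate_density()] draws an independent
#' crop-transition effect per imputation for transitions the data never saw.
#'
#' @param records Data frame of observed transitions, one row per quadrat
#'   transition, with columns `prev_state`, `next_state` (integers 0..4),
#'   `prev_crop`, `crop`, `sowing_window`, `tillage`, `n_stale_seedbeds`,
#'   `glyphosate_applications`, `selective_applications`, `seed_rate`,
#'   `resistance`, `field_id`, `rotation_id`.
#' @param n_imputations Number of imputation coefficient sets (default 37).
#' @param seed Integer seed (initialisation only; the fit is deterministic).
#' @param n_sigma_updates Outer iterations of the sigma/coefficient
#'   alternation.
#' @param maxit BFGS iteration cap per inner fit.
#' @return A `transition_model` with fitted cutpoints, fixed effects,
#'   random-effect values and scales, per-coefficient standard errors and
#'   convergence diagnostics (`$diagnostics`).
#' @export
fit_transition_model <- function(records, n_imputations = 37L, seed = 1L,
                                 n_sigma_updates = 3L, maxit = 400L) {
  stopifnot(n_imputations >= 1L)
  des <- build_design(records)
  sigma <- list(crop_transition = 0.5, rotation = 0.5, field = 0.5)
  obj <- make_objective(des, sigma)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  th <- numeric(4 + obj$p + length(obj$levels$ct) + length(obj$levels$rot) +
                  length(obj$levels$fld))
  th[1] <- -1.5; th[2:4] <- 0  # cutpoints start at (-1.5, -0.5, 0.5, 1.5)
  fit <- NULL
  for (it in seq_len(n_sigma_updates)) {
    obj <- make_objective(des, sigma)
    fit <- stats::optim(th, obj$nll, obj$grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    th <- fit$par
    for (b in c("ct", "rot", "fld")) {
      u <- th[obj$idx[[b]]]
      key <- switch(b, ct = "crop_transition", rot = "rotation",
                    fld = "field")
      if (length(u) >= 2) {
        sigma[[key]] <- max(sqrt(mean(u^2)), 0.05)
      } else {
        sigma[[key]] <- 0.05
      }
    }
  }
  grad_norm <- sqrt(sum(obj$grad(th)^2))
  if (fit$convergence != 0 && grad_norm > 1e-2 * obj$n) {
    warning("transition-model fit did not converge (optim code ",
            fit$convergence, ", gradient norm ", format(grad_norm), ")")
  }
  # observed-information standard errors for the fixed effects
  se_beta <- rep(NA_real_, obj$p)
  H <- tryCatch(stats::optimHess(th, obj$nll, obj$grad), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) se_beta <- sqrt(pmax(diag(V)[obj$idx$beta], 0))
  }
  names(se_beta) <- fixed_effect_names()
  d <- exp(th[2:4])
  cp <- th[1] + cumsum(c(0, d))
  beta <- th[obj$idx$beta]; names(beta) <- fixed_effect_names()
  u_ct <- th[obj$idx$ct]; names(u_ct) <- obj$levels$ct
  u_rot <- th[obj$idx$rot]; names(u_rot) <- obj$levels$rot
  u_fld <- th[obj$idx$fld]; names(u_fld) <- obj$levels$fld
  rep_mat <- function(v) matrix(v, n_imputations, length(v), byrow = TRUE,
                                dimnames = list(NULL, names(v)))
  m <- transition_model(
    cutpoints = matrix(cp, n_imputations, 4, byrow = TRUE),
    beta = rep_mat(beta),
    u = list(crop_transition = rep_mat(u_ct), rotation = rep_mat(u_rot),
             field = rep_mat(u_fld)),
    sigma = sigma, scaling = des$scaling,
    diagnostics = list(convergence = fit$convergence,
                       nll = fit$value, grad_norm = grad_norm,
                       n_records = obj$n, counts = fit$counts,
                       se_beta = se_beta))
  m
}

# ---- persistence -------------------------------------------------------

#' Save or load a transition model as JSON
#'
#' Round-trips every coefficient set, random-effect value, scale parameter
#' and the design dictionary.
#'
#' @param model A `transition_model`.
#' @param path File path.
#' @return `load_transition_model()` returns the reconstructed model.
#' @export
save_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  payload <- list(
    n_imputations = model$n_imputations,
    cutpoints = model$cutpoints,
    beta = model$beta, beta_names = colnames(model$beta),
    u = lapply(model$u, function(m) list(values = m, levels = colnames(m))),
    sigma = model$sigma, scaling = model$scaling,
    diagnostics = model$diagnostics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_transition_model
#' @export
load_transition_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, names) {
    m <- matrix(as.numeric(m), nrow = p$n_imputations)
    colnames(m) <- names
    m
  }
  beta <- as_mat(p$beta, p$beta_names)
  u <- lapply(p$u, function(el) as_mat(el$values, el$levels))
  transition_model(cutpoints = matrix(as.numeric(p$cutpoints),
                                      nrow = p$n_imputations),
                   beta = beta, u = u, sigma = p$sigma,
                   scaling = as.data.frame(p$scaling),
                   diagnostics = p$diagnostics)
}
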