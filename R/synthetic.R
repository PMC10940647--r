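# Synthetic inputs emulating the field data the pipeline was designed for:
# quadrat surveys of ordinal density states across 125 fields in 13 counties,
# two-herbicide glasshouse resistance assays, multi-year management
# histories, transition datasets sampled from a known model, and the price /
# county-area tables. Everything is a pure function of (config, seed).

#' County-to-region lookup table
#'
#' The 13 surveyed English counties with their broad region (north, central,
#' east). The assignment (and the 13th county, Norfolk) is a synthetic
#' stand-in for the study's unavailable supplementary table.
#'
#' @return Data frame with columns `county`, `region`.
#' @export
county_region_table <- function() {
  data.frame(
    county = c("N.Yorks", "E.R.Yorks", "S.Yorks", "Notts",
               "Leics", "Warw", "Northants", "Oxon", "Bucks", "Beds",
               "Lincs", "Cambs", "Norfolk"),
    region = c(rep("north", 4), rep("central", 6), rep("east", 3)),
    stringsAsFactors = FALSE)
}

region_for_county <- function(county) {
  tab <- county_region_table()
  i <- match(county, tab$county)
  if (anyNA(i)) {
    stop("unknown county: ", paste(county[is.na(i)], collapse = ", "))
  }
  tab$region[i]
}

#' Synthetic-data configuration
#'
#' @param n_fields Number of fields (default 125, the surveyed count).
#' @param grid_dims Quadrat grid (rows, cols) per field; default 20 x 20.
#' @param category_mix Proportions of fields in the LD-LR / LD-HR / HD-HR
#'   initial-condition classes; defaults to the observed 14% / 56% / 30%.
#' @param seed Integer seed; mandatory, no implicit randomness.
#' @param mortality_shapes Beta shape pairs for assay mortality noise, per
#'   resistance class. Defaults give mean 0.90 (susceptible) and 0.40
#'   (resistant) at concentration 50, keeping classes separable across the
#'   0.72 threshold while exercising boundary cases.
#' @param state_probs 2 x 5 matrix of per-category quadrat-state
#'   probabilities (rows LD, HD).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_fields = 125L, grid_dims = c(20L, 20L),
                             category_mix = c(`LD-LR` = 0.14, `LD-HR` = 0.56,
                                              `HD-HR` = 0.30),
                             seed,
                             mortality_shapes = list(low = c(45, 5),
                                                     high = c(20, 30)),
                             state_probs = rbind(
                               LD = c(0.45, 0.35, 0.15, 0.04, 0.01),
                               HD = c(0.05, 0.10, 0.20, 0.35, 0.30))) {
  if (missing(seed)) stop("seed is mandatory: no implicit randomness")
  if (n_fields < 1L) stop("need at least one field")
  if (length(category_mix) != 3L || abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must be 3 proportions summing to 1")
  }
  if (any(category_mix < 0)) stop("category_mix proportions must be >= 0")
  stopifnot(length(grid_dims) == 2L, all(grid_dims >= 1L))
  names(category_mix) <- c("LD-LR", "LD-HR", "HD-HR")
  structure(list(n_fields = as.integer(n_fields),
                 grid_dims = as.integer(grid_dims),
                 category_mix = category_mix,
                 seed = as.integer(seed),
                 mortality_shapes = mortality_shapes,
                 state_probs = state_probs),
            class = "synthetic_config")
}

rbeta_mean_conc <- function(n, shapes) stats::rbeta(n, shapes[1], shapes[2])

#' Generate synthetic field surveys and resistance assays
#'
#' Each field gets a latent density-resistance category drawn from the
#' configured mix; quadrat states are drawn from the category-specific state
#' distribution (LD concentrated in states 0--2, HD in 3--4); assay
#' mortalities are Beta draws whose means put low-resistance fields above
#' and high-resistance fields below the 0.72 classification threshold.
#' Fully reproducible from the config's seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `surveys` (one row per quadrat: field_id, county,
#'   region, soil, year, row, col, state), `assays` (field_id,
#'   mortality_atlantis, mortality_cycloxydim), and `truth` (field_id,
#'   latent category, soil, region).
#' @export
gen_survey_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_fields
  ids <- sprintf("F%03d", seq_len(n))
  category <- sample(names(cfg$category_mix), n, replace = TRUE,
                     prob = cfg$category_mix)
  counties <- county_region_table()
  county <- sample(counties$county, n, replace = TRUE)
  soil <- sample(c("heavy", "medium", "light"), n, replace = TRUE)
  nq <- prod(cfg$grid_dims)
  surveys <- do.call(rbind, lapply(seq_len(n), function(i) {
    probs <- cfg$state_probs[if (startsWith(category[i], "LD")) "LD" else "HD", ]
    st <- sample(0:4, nq, replace = TRUE, prob = probs)
    data.frame(field_id = ids[i], county = county[i],
               region = region_for_county(county[i]), soil = soil[i],
               year = 2019L,
               row = rep(seq_len(cfg$grid_dims[1]), cfg$grid_dims[2]),
               col = rep(seq_len(cfg$grid_dims[2]),
                         each = cfg$grid_dims[1]),
               state = st, stringsAsFactors = FALSE)
  }))
  res_class <- ifelse(category == "LD-LR", "low", "high")
  shp <- cfg$mortality_shapes
  assays <- data.frame(
    field_id = ids,
    mortality_atlantis = ifelse(res_class == "low",
                                rbeta_mean_conc(n, shp$low),
                                rbeta_mean_conc(n, shp$high)),
    mortality_cycloxydim = ifelse(res_class == "low",
                                  rbeta_mean_conc(n, shp$low),
                                  rbeta_mean_conc(n, shp$high)),
    stringsAsFactors = FALSE)
  list(surveys = surveys, assays = assays,
       truth = data.frame(field_id = ids, category = category, soil = soil,
                          county = county,
                          region = region_for_county(county),
                          stringsAsFactors = FALSE))
}

default_crop_transition_table <- function() {
  crops <- c("winter_wheat", "winter_oilseed_rape", "spring_barley",
             "spring_beans", "spring_oats", "fallow")
  P <- matrix(c(
    # to: ww,  osr,  sbar, sbea, soat, fal   from:
    0.42, 0.28, 0.10, 0.10, 0.05, 0.05,    # winter_wheat
    0.65, 0.05, 0.10, 0.10, 0.05, 0.05,    # winter_oilseed_rape
    0.50, 0.15, 0.10, 0.10, 0.10, 0.05,    # spring_barley
    0.55, 0.15, 0.10, 0.05, 0.10, 0.05,    # spring_beans
    0.50, 0.15, 0.10, 0.15, 0.05, 0.05,    # spring_oats
    0.60, 0.10, 0.10, 0.10, 0.05, 0.05),   # fallow
    nrow = 6, byrow = TRUE, dimnames = list(crops, crops))
  P
}

# Management for one generated field-year. Sowing window follows the crop,
# but tillage, stale seedbeds, herbicide programmes and seed rate vary
# independently of it so the fitted model can separate their effects.
random_management_for_crop <- function(crop) {
  sowing <- if (crop == "fallow") "none"
    else if (crop %in% spring_crops()) "spring"
    else sample(c("early_autumn", "late_autumn"), 1, prob = c(0.4, 0.6))
  tillage <- sample(c("inversion_plough", "min_till", "no_till"), 1,
                    prob = c(0.3, 0.5, 0.2))
  stale <- if (sowing %in% c("late_autumn", "spring")) {
    min(stats::rpois(1, 1.2), 4L)
  } else 0L
  gapp <- sample(0:3, 1, prob = c(0.2, 0.4, 0.3, 0.1))
  sapp <- if (crop == "fallow") 0L else sample(0:3, 1,
                                               prob = c(0.15, 0.35, 0.35, 0.15))
  jit <- stats::runif(1, 0.85, 1.15)
  list(crop = crop, sowing_window = sowing, tillage = tillage,
       n_stale_seedbeds = stale, glyphosate_applications = gapp,
       glyphosate_dose = round(gapp * 1.5 * jit, 2),
       selective_applications = sapp,
       selective_dose = round(sapp * 1.0 * jit, 2),
       seed_rate = round(stats::runif(1, 0.8, 1.4), 2))
}

#' Generate per-field multi-year management histories
#'
#' Year-to-year crop sequences follow a configurable crop-transition
#' frequency table; management details per year are the crop's typical
#' programme with small random jitter in doses and seed rates so the fitted
#' model sees covariate variation. Transition pairs listed in `withheld` are
#' never generated, deliberately leaving holes that exercise the
#' missing-transition imputation path downstream.
#'
#' @param surveys Survey data frame (or the list from [gen_survey_data()]);
#'   only `field_id` is used.
#' @param seed Integer seed.
#' @param n_years Years of history per field (default 6).
#' @param transition_table Row-stochastic crop-to-crop frequency table.
#' @param withheld Character vector of crop-transition labels
#'   (`"cropA->cropB"`) to exclude.
#' @param n_rotations Number of distinct rotation identifiers shared across
#'   fields (random-effect grouping).
#' @return Data frame, one row per field-year: field_id, rotation_id, year,
#'   crop plus the [management_year()] fields.
#' @export
gen_management_histories <- function(surveys, seed, n_years = 6L,
                                     transition_table =
                                       default_crop_transition_table(),
                                     withheld = character(0),
                                     n_rotations = 8L) {
  if (is.list(surveys) && !is.data.frame(surveys)) surveys <- surveys$surveys
  ids <- unique(surveys$field_id)
  if (!length(ids)) stop("empty survey set")
  crops <- rownames(transition_table)
  P <- transition_table
  for (w in withheld) {
    pair <- strsplit(w, "->", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% crops)) {
      stop("withheld transition '", w, "' not in the crop set")
    }
    P[pair[1], pair[2]] <- 0
  }
  if (any(rowSums(P) <= 0)) stop("withholding emptied a transition row")
  P <- P / rowSums(P)
  set.seed(as.integer(seed))
  # rotation templates: shared crop sequences fields are assigned to
  rot_seq <- lapply(seq_len(n_rotations), function(r) {
    s <- character(n_years)
    s[1] <- sample(crops, 1)
    for (t in 2:n_years) s[t] <- sample(crops, 1, prob = P[s[t - 1], ])
    s
  })
  rot_of_field <- sample(seq_len(n_rotations), length(ids), replace = TRUE)
  rows <- lapply(seq_along(ids), function(i) {
    sq <- rot_seq[[rot_of_field[i]]]
    do.call(rbind, lapply(seq_len(n_years), function(t) {
      m <- random_management_for_crop(sq[t])
      data.frame(field_id = ids[i],
                 rotation_id = sprintf("R%02d", rot_of_field[i]),
                 year = t, crop = m$crop, sowing_window = m$sowing_window,
                 tillage = m$tillage, n_stale_seedbeds = m$n_stale_seedbeds,
                 glyphosate_applications = m$glyphosate_applications,
                 glyphosate_dose = m$glyphosate_dose,
                 selective_applications = m$selective_applications,
                 selective_dose = m$selective_dose,
                 seed_rate = m$seed_rate,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Sample an observed transition dataset from a known model
#'
#' For every field, quadrat initial states are iterated through the history:
#' the next state of each quadrat is sampled from the exact categorical
#' distribution implied by `true_model` for that year's covariates. The
#' record count equals quadrats x (years - 1) per field.
#'
#' @param true_model A single-imputation `transition_model` with known
#'   coefficients (the generating oracle for parameter recovery).
#' @param histories Data frame from [gen_management_histories()].
#' @param seed Integer seed.
#' @param initial_states Named list mapping field_id to an integer vector of
#'   quadrat states (e.g. the survey grid). If `NULL`, `n_quadrats` states
#'   are drawn uniformly per field.
#' @param resistance Either a single level ("low"/"high") or a named vector
#'   per field_id.
#' @param n_quadrats Quadrats per field when `initial_states` is `NULL`.
#' @return Data frame of transition records in the schema consumed by
#'   [fit_transition_model()].
#' @export
gen_transition_dataset <- function(true_model, histories, seed,
                                   initial_states = NULL,
                                   resistance = "high", n_quadrats = 25L) {
  stopifnot(inherits(true_model, "transition_model"))
  if (true_model$n_imputations != 1L) {
    stop("the generating model must be a single, fully-specified imputation")
  }
  set.seed(as.integer(seed))
  out <- vector("list", 0)
  for (id in unique(histories$field_id)) {
    h <- histories[histories$field_id == id, ]
    h <- h[order(h$year), ]
    if (nrow(h) < 2L) next
    states <- if (!is.null(initial_states)) {
      as.integer(initial_states[[id]])
    } else {
      sample(0:4, n_quadrats, replace = TRUE)
    }
    res <- if (length(resistance) == 1L) resistance else
      unname(resistance[[id]])
    for (t in seq_len(nrow(h) - 1L)) {
      yr <- h[t + 1L, ]
      my <- management_year(yr$crop, yr$sowing_window, yr$tillage,
                            yr$n_stale_seedbeds, yr$glyphosate_applications,
                            yr$glyphosate_dose, yr$selective_applications,
                            yr$selective_dose, yr$seed_rate)
      cov <- encode_covariates(my, h$crop[t], res, model = true_model)
      if (cov$missing) {
        stop("generating model lacks crop transition ", cov$crop_transition,
             ": model/covariate vocabulary mismatch")
      }
      M <- transition_matrix(true_model, cov, 1L)
      nxt <- vapply(states, function(s) {
        sample.int(5L, 1L, prob = M[s + 1L, ]) - 1L
      }, integer(1))
      out[[length(out) + 1L]] <- data.frame(
        field_id = id, rotation_id = h$rotation_id[1], year = yr$year,
        prev_state = states, next_state = nxt,
        prev_crop = h$crop[t], crop = yr$crop,
        sowing_window = yr$sowing_window, tillage = yr$tillage,
        n_stale_seedbeds = yr$n_stale_seedbeds,
        glyphosate_applications = yr$glyphosate_applications,
        selective_applications = yr$selective_applications,
        seed_rate = yr$seed_rate, resistance = res,
        stringsAsFactors = FALSE)
      states <- nxt
    }
  }
  do.call(rbind, out)
}
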