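# Stage 1: map raw surveys and resistance assays onto density categories,
# low/high resistance, and the three initial-condition classes
# LD-LR / LD-HR / HD-HR.

#' Field-level density category cut-offs
#'
#' Mean quadrat score is categorised as: \[0, 0.5\] absent; (0.5, 1.5) low;
#' \[1.5, 2.5) medium; \[2.5, 3.5) high; \[3.5, Inf) very_high.
#'
#' @param score Mean quadrat density score (numeric, >= 0).
#' @return One of the [density_states()] labels.
#' @keywords internal
density_category_from_score <- function(score) {
  stopifnot(is.numeric(score), length(score) == 1L, !is.na(score), score >= 0)
  if (score <= 0.5) "absent"
  else if (score < 1.5) "low"
  else if (score < 2.5) "medium"
  else if (score < 3.5) "high"
  else "very_high"
}

#' Mean density score and category for a field
#'
#' The field-level density summary is the arithmetic mean of the quadrat
#' states (ordinal scores 0--4) over the whole survey grid, categorised with
#' the standard cut-offs (0.5 / 1.5 / 2.5 / 3.5; the lowest boundary belongs
#' to `absent`, the others to the higher category).
#'
#' @param grid Numeric matrix or vector of quadrat states, each in 0..4.
#' @return List with `score` (mean) and `category` (label).
#' @examples
#' mean_density_score(matrix(0, 2, 2)) # absent
#' mean_density_score(c(2, 2, 2))      # medium
#' @export
mean_density_score <- function(grid) {
  states <- as.numeric(grid)
  if (length(states) == 0L) stop("survey grid is empty")
  if (anyNA(states) || any(states < 0 | states > 4) ||
      any(states != round(states))) {
    stop("quadrat states must be integers in 0..4")
  }
  score <- mean(states)
  list(score = score, category = density_category_from_score(score))
}

#' Classify herbicide resistance from assay mortalities
#'
#' Resistance is dichotomised on the mean glasshouse assay mortality across
#' the two selective herbicides (mesosulfuron+iodosulfuron and cycloxydim).
#' Mean mortality >= 0.72 means the herbicides still kill, i.e. *low*
#' resistance; below 0.72 is *high* resistance. The boundary is assigned to
#' the low-resistance side.
#'
#' @param mortality_atlantis,mortality_cycloxydim Assay mortalities in
#'   \[0, 1\].
#' @return List with `mean_mortality` and `resistance` ("low" or "high").
#' @examples
#' classify_resistance(0.95, 0.80) # low resistance
#' classify_resistance(0.50, 0.60) # high resistance
#' @export
classify_resistance <- function(mortality_atlantis, mortality_cycloxydim) {
  m <- c(mortality_atlantis, mortality_cycloxydim)
  if (length(m) != 2L || anyNA(m)) stop("both assay mortalities are required")
  if (any(m < 0 | m > 1)) stop("assay mortality must lie in [0, 1]")
  mm <- mean(m)
  list(mean_mortality = mm,
       resistance = if (mm >= 0.72) "low" else "high")
}

#' Combine density and resistance dichotomies into a DR category
#'
#' Field density is dichotomised by economic impact: `absent`, `low` and
#' `medium` are low density (LD, zero wheat-yield penalty), `high` and
#' `very_high` are high density (HD). Combined with the resistance dichotomy
#' this yields LD-LR, LD-HR or HD-HR. High density with low resistance is
#' never observed under sensible management; it is returned labelled
#' "HD-HR" with `anomalous = TRUE` rather than silently dropped.
#'
#' @param density_category One of [density_states()].
#' @param resistance "low" or "high".
#' @return List with `dr_category` and logical `anomalous`.
#' @examples
#' assign_dr_category("medium", "high")    # LD-HR
#' assign_dr_category("very_high", "high") # HD-HR
#' @export
assign_dr_category <- function(density_category, resistance) {
  density_category <- match.arg(density_category, density_states())
  resistance <- match.arg(resistance, c("low", "high"))
  hd <- density_category %in% c("high", "very_high")
  if (!hd) {
    list(dr_category = if (resistance == "low") "LD-LR" else "LD-HR",
         anomalous = FALSE)
  } else if (resistance == "high") {
    list(dr_category = "HD-HR", anomalous = FALSE)
  } else {
    # HD-LR: only arises through poor management; flagged, not dropped.
    list(dr_category = "HD-HR", anomalous = TRUE)
  }
}

#' Classify a set of surveyed fields
#'
#' Joins survey grids with assay results and emits one classification row per
#' field. Classification depends only on the field's own data and is
#' idempotent.
#'
#' @param surveys Data frame with columns `field_id`, `state` (one row per
#'   quadrat), as written by [gen_survey_data()].
#' @param assays Data frame with columns `field_id`, `mortality_atlantis`,
#'   `mortality_cycloxydim`.
#' @return Data frame with one row per field: `field_id`, `score`,
#'   `density_category`, `mean_mortality`, `resistance`, `dr_category`,
#'   `anomalous`.
#' @export
classify_fields <- function(surveys, assays) {
  stopifnot(is.data.frame(surveys), is.data.frame(assays))
  if (nrow(surveys) == 0L) stop("no survey rows to classify")
  ids <- unique(surveys$field_id)
  miss <- setdiff(ids, assays$field_id)
  if (length(miss)) {
    stop("missing resistance assays for field(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    dens <- mean_density_score(surveys$state[surveys$field_id == id])
    a <- assays[match(id, assays$field_id), ]
    res <- classify_resistance(a$mortality_atlantis, a$mortality_cycloxydim)
    dr <- assign_dr_category(dens$category, res$resistance)
    data.frame(field_id = id, score = dens$score,
               density_category = dens$category,
               mean_mortality = res$mean_mortality,
               resistance = res$resistance,
               dr_category = dr$dr_category, anomalous = dr$anomalous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prevalence of DR categories across classified fields
#'
#' @param classified Data frame from [classify_fields()] (needs columns
#'   `dr_category`, `anomalous`).
#' @return Named numeric vector of proportions over LD-LR, LD-HR, HD-HR and
#'   (if present) `anomalous`; sums to 1.
#' @export
summarise_prevalence <- function(classified) {
  if (!is.data.frame(classified) || nrow(classified) == 0L) {
    stop("no classified fields supplied")
  }
  lab <- ifelse(classified$anomalous, "anomalous", classified$dr_category)
  lev <- c("LD-LR", "LD-HR", "HD-HR")
  if (any(lab == "anomalous")) lev <- c(lev, "anomalous")
  tab <- table(factor(lab, levels = lev))
  prop <- as.numeric(tab) / nrow(classified)
  names(prop) <- lev
  prop
}
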