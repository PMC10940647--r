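#' weedrot: density-structured weed population dynamics and rotation economics
#'
#' The package tracks the distribution of a field's grid cells over five
#' ordinal black-grass density states (absent, low, medium, high, very_high),
#' projects that distribution forward under management using a hierarchical
#' cumulative-logit transition model, attaches a gross-margin economic layer
#' with density-responsive winter-wheat yield, and compares management
#' scenarios through opportunity and productivity costs.
#'
#' @keywords internal
"_PACKAGE"

#' Ordinal density state labels
#'
#' The five ordinal black-grass density states, in increasing order. Quadrat
#' scores 0--4 index these labels (0 = absent, 4 = very_high).
#'
#' @return Character vector of length 5.
#' @export
density_states <- function() {
  c("absent", "low", "medium", "high", "very_high")
}

#' Construct a density-state distribution
#'
#' A `density_distribution` is the central state variable: the proportions of
#' a field's grid cells in each of the five ordinal density states.
#'
#' @param p Numeric vector of 5 non-negative proportions summing to 1
#'   (tolerance 1e-9), ordered absent..very_high.
#' @return A named numeric vector of class `density_distribution`.
#' @examples
#' density_distribution(c(0.1, 0.1, 0.2, 0.3, 0.3))
#' @export
density_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 5L) {
    stop("a density distribution has exactly 5 states, got ", length(p))
  }
  if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("density-state proportions must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("density-state proportions must sum to 1 (got ",
         format(sum(p), digits = 12), ")")
  }
  p <- pmin(pmax(p, 0), 1)
  names(p) <- density_states()
  class(p) <- c("density_distribution", "numeric")
  p
}

#' Worst-case initial density distribution
#'
#' The stated worst-case starting point for 18-year sequence runs: highly
#' resistant black-grass at very high density everywhere, i.e. proportions
#' (0.1, 0.1, 0.2, 0.3, 0.3) so that 70% of grid cells (everything not
#' already very_high) can still move into higher states.
#'
#' @return A `density_distribution`.
#' @export
worst_case_distribution <- function() {
  density_distribution(c(0.1, 0.1, 0.2, 0.3, 0.3))
}

#' Proportion of a field at economically damaging density
#'
#' Only the two highest density states carry a winter-wheat yield penalty, so
#' the damaging proportion is `p[high] + p[very_high]`.
#'
#' @param d A `density_distribution` (or 5-vector accepted by
#'   [density_distribution()]).
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' prop_damaging(c(0.1, 0.1, 0.2, 0.3, 0.3)) # 0.6
#' @export
prop_damaging <- function(d) {
  d <- density_distribution(d)
  unname(d[["high"]] + d[["very_high"]])
}

#' @export
print.density_distribution <- function(x, ...) {
  cat("density distribution (proportion of grid cells per state):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
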