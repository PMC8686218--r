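# Fuzzy adaptive control of the genetic manipulation rates.  Inputs are
# the population-diversity ratio d = F_min / F_ave (d near 1: fitness
# spread is small, the population is converging; d near 0: large spread,
# high diversity) and the iteration fraction.  Outputs are the crossover,
# point-mutation and adjacent-mutation rates of the next generation.
#
# The qualitative control laws: as the population converges (diversity
# low, d -> 1) the mutation and adjacent-mutation rates rise to
# re-diversify; when diversity is high (d -> 0) the crossover rate rises
# and the mutation rate falls; late iterations shift one linguistic level
# toward exploitation.

#' Membership degrees of the five linguistic levels
#'
#' Triangular interior memberships with trapezoidal shoulders over
#' `breakpoints` (default 0, 0.25, 0.5, 0.75, 1); the five levels
#' \{XL, ML, M, MH, XH\} form a partition of unity on the normalized axis.
#'
#' @param x numeric value(s) in `[0, 1]`.
#' @param breakpoints five increasing knots.
#' @return A `length(x) x 5` matrix of membership degrees.
#' @export
fuzzy_memberships <- function(x, breakpoints = seq(0, 1, by = 0.25)) {
  stopifnot(length(breakpoints) == 5L, !is.unsorted(breakpoints))
  out <- matrix(0, length(x), 5L,
                dimnames = list(NULL, c("XL", "ML", "M", "MH", "XH")))
  for (l in 1:5) {
    lo <- if (l == 1L) -Inf else breakpoints[l - 1L]
    mid <- breakpoints[l]
    hi <- if (l == 5L) Inf else breakpoints[l + 1L]
    up <- if (is.infinite(lo)) rep(1, length(x)) else
      pmax(0, pmin(1, (x - lo) / (mid - lo)))
    down <- if (is.infinite(hi)) rep(1, length(x)) else
      pmax(0, pmin(1, (hi - x) / (hi - mid)))
    out[, l] <- pmin(up, down)
  }
  out
}

.clamp_level <- function(l) pmin(5L, pmax(1L, l))

#' Construct a fuzzy rate controller
#'
#' A fuzzy controller with a 5x5 rule base mapping (diversity level,
#' iteration level) to an output rate level: min-AND rule firing, scaled
#' implication with additive aggregation, and centroid defuzzification
#' over `[rate_min, rate_max]`.
#'
#' @param rule_table 5x5 integer matrix of output levels 1..5; rows index
#'   the d-level, columns the iteration level.
#' @param rate_min,rate_max output rate bounds.
#' @param breakpoints input-axis knots, shared by both inputs.
#' @return Object of class `fuzzy_controller`.
#' @export
fuzzy_controller <- function(rule_table, rate_min = 0.05, rate_max = 0.95,
                             breakpoints = seq(0, 1, by = 0.25)) {
  rule_table <- matrix(as.integer(rule_table), 5L, 5L)
  if (any(rule_table < 1L | rule_table > 5L))
    stop("rule table entries must be output levels 1..5")
  if (!(rate_min > 0 && rate_min < rate_max && rate_max < 1))
    stop("need 0 < rate_min < rate_max < 1")
  structure(list(rule_table = rule_table, rate_min = rate_min,
                 rate_max = rate_max, breakpoints = breakpoints,
                 ygrid = seq(0, 1, length.out = 201L)),
            class = "fuzzy_controller")
}

#' Defuzzified output rate of one controller
#'
#' @param controller a [fuzzy_controller()].
#' @param d diversity ratio in `[0, 1]`.
#' @param iter_frac iteration fraction in `[0, 1]`.
#' @return Rate in `[rate_min, rate_max]`.
#' @export
defuzzify <- function(controller, d, iter_frac) {
  mu_d <- fuzzy_memberships(d, controller$breakpoints)[1, ]
  mu_i <- fuzzy_memberships(iter_frac, controller$breakpoints)[1, ]
  act <- numeric(5L)
  for (dl in 1:5)
    for (il in 1:5) {
      w <- min(mu_d[dl], mu_i[il])
      o <- controller$rule_table[dl, il]
      act[o] <- act[o] + w
    }
  # scaled implication with additive aggregation: the aggregate output set
  # is sum_o act_o * mf_o(y); its centroid moves monotonically with the
  # rule activations, which keeps the qualitative control laws intact
  ymf <- fuzzy_memberships(controller$ygrid, controller$breakpoints)
  agg <- as.numeric(ymf %*% act)
  cen <- if (sum(agg) > 0) sum(controller$ygrid * agg) / sum(agg) else 0.5
  controller$rate_min + cen * (controller$rate_max - controller$rate_min)
}

#' Default controllers for the three manipulation rates
#'
#' Mutation and adjacent-mutation share a rule table whose output level
#' rises with d (more mutation as the population converges) and drops one
#' level in late iterations; the crossover table mirrors it (output level
#' falls with d, rises late).
#'
#' @param rate_min,rate_max output rate bounds.
#' @return Named list of three [fuzzy_controller()] objects: `crossover`,
#'   `mutation`, `adjacent`.
#' @export
default_rate_controllers <- function(rate_min = 0.05, rate_max = 0.95) {
  dl <- matrix(1:5, 5L, 5L)              # diversity level by row
  late <- matrix(rep(c(0L, 0L, 0L, 1L, 1L), each = 5L), 5L, 5L)
  mut <- .clamp_level(dl - late)
  crs <- .clamp_level(6L - dl + late)
  list(crossover = fuzzy_controller(crs, rate_min, rate_max),
       mutation = fuzzy_controller(mut, rate_min, rate_max),
       adjacent = fuzzy_controller(mut, rate_min, rate_max))
}

#' Population-diversity ratio
#'
#' `d = F_min / (F_ave + eps)` for non-negative minimised scores (so
#' `F_best = F_min <= F_ave` always and d lies in (0, 1]); an all-equal
#' population gives d = 1.  For a hypothetical maximised fitness with
#' `F_best > F_ave` the complementary ratio `F_ave / F_max` is returned.
#'
#' @param fitness numeric vector of population scores.
#' @param minimize whether lower scores are better (the K2 convention).
#' @return Diversity ratio d.
#' @export
diversity <- function(fitness, minimize = TRUE) {
  if (!length(fitness)) stop("empty population")
  eps <- 1e-12
  if (minimize) min(fitness) / (mean(fitness) + eps)
  else mean(fitness) / (max(fitness) + eps)
}

#' Update the three genetic manipulation rates
#'
#' Pure function of the diversity state: same inputs, same rates.
#'
#' @param state list with `d` (diversity ratio) and `iter_frac`.
#' @param controllers a [default_rate_controllers()]-shaped list.
#' @return Named numeric vector `c(crossover, mutation, adjacent)`.
#' @export
update_rates <- function(state, controllers = default_rate_controllers()) {
  c(crossover = defuzzify(controllers$crossover, state$d, state$iter_frac),
    mutation = defuzzify(controllers$mutation, state$d, state$iter_frac),
    adjacent = defuzzify(controllers$adjacent, state$d, state$iter_frac))
}
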