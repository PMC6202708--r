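#' Two-point logistic curve
#'
#' Every survival and catchability function in the model is parameterized by
#' two (driver, value) anchor points through which a logistic curve passes:
#' `f(x) = plogis(a + b x)` with `a`, `b` solved from the anchors. This makes
#' each curve directly testable at its anchors.
#'
#' @param x numeric vector of driver values.
#' @param anchors numeric of length 4: `c(x1, p1, x2, p2)` with `p1`, `p2` in
#'   (0, 1) and `x1 != x2`.
#' @return numeric vector of curve values in (0, 1).
#' @examples
#' two_point_logistic(c(24, 28), c(24, 0.999, 28, 0.8))
#' @export
two_point_logistic <- function(x, anchors) {
  stopifnot(length(anchors) == 4, anchors[1] != anchors[3],
            all(anchors[c(2, 4)] > 0), all(anchors[c(2, 4)] < 1))
  eng_two_point_logistic(as.numeric(x), as.numeric(anchors))
}

#' Order trout by size-based dominance
#'
#' Larger trout get first access to food and preferred habitat. Order is
#' strictly descending length; ties are broken by descending weight, then
#' ascending id, so the ordering is deterministic.
#'
#' @param pop data.frame with columns `length`, `weight`, `id`.
#' @return the data.frame reordered by dominance (most dominant first).
#' @export
rank_by_dominance <- function(pop) {
  if (nrow(pop) == 0) return(pop)
  pop[order(-pop$length, -pop$weight, pop$id), , drop = FALSE]
}

#' Short-term fitness measure of a cell for a trout
#'
#' The score a trout maximizes during habitat selection: the product of the
#' six daily survival probabilities in the cell raised to the fitness horizon,
#' times `min(1, projectedLength / maturity threshold)`, where the projected
#' length extrapolates today's growth in that cell over the horizon. Scores
#' lie in [0, 1]; a risk-free cell for a fish already at or above its maturity
#' threshold scores 1.
#'
#' @param length,weight,k,p_mat_threshold fish state (cm, g, condition,
#'   threshold cm).
#' @param depth,velocity,cover,food cell state for the day (m, m/s, fraction,
#'   g available food).
#' @param temperature water temperature (C).
#' @param max_length length of the largest trout in the reach (cm), for the
#'   piscivory size rule.
#' @param pisc_density density of piscivorous trout (fish/ha).
#' @param params parameter list from [default_params()].
#' @param horizon days (default: configured fitness horizon).
#' @return list with `fitness`, the six `survival` probabilities, `intake`,
#'   `dw`, `projected_length`, `size_factor`.
#' @export
fitness_measure <- function(length, weight, k, p_mat_threshold,
                            depth, velocity, cover, food, temperature,
                            max_length = length, pisc_density = 0,
                            params = default_params(), horizon = NULL) {
  if (is.null(horizon)) horizon <- params$bioenergetics$fitness_horizon
  eng_fitness_measure(length, weight, k, p_mat_threshold, depth, velocity,
                      cover, food, temperature, max_length, pisc_density,
                      flatten_params(params), horizon)
}

#' Daily habitat selection for a population
#'
#' Processes trout in dominance order; each claims the cell maximizing its
#' fitness measure given the food left by more dominant fish, then depletes
#' that cell's food by its intake. Assignment is deterministic given the
#' population and cell state; ties go to the lowest cell id.
#'
#' @param pop data.frame with `id`, `length`, `weight`, `p_mat_threshold`.
#' @param cells reach data.frame with current `depth`, `velocity`, `cover`,
#'   `food` (see [update_cells()]).
#' @param temperature water temperature (C).
#' @param params parameter list.
#' @return list with `cell` (1-based assignment per fish, in input order),
#'   `intake` (g), `dw` (g/day), `food_remaining` per cell.
#' @export
select_habitat <- function(pop, cells, temperature,
                           params = default_params()) {
  if (nrow(pop) == 0) {
    return(list(cell = integer(0), intake = numeric(0), dw = numeric(0),
                food_remaining = cells$food))
  }
  eng_select_habitat_day(pop$length, pop$weight, pop$p_mat_threshold,
                         as.integer(pop$id), cells$depth, cells$velocity,
                         cells$cover, cells$food, temperature,
                         flatten_params(params))
}

#' Daily bioenergetic growth
#'
#' Net energy is intake times the food energy density minus respiration (a
#' function of weight, temperature and the cell's velocity); the weight change
#' is net energy divided by the tissue energy density and may be negative.
#' Length increases only while weight is at or above the healthy weight for
#' the current length, so length is monotone over life; weight is floored at
#' `k_floor` times healthy weight (starvation survival then acts on the
#' condition factor).
#'
#' @param length,weight fish state vectors.
#' @param intake realized food intake (g/day) per fish.
#' @param temperature water temperature (C).
#' @param velocity cell velocity (m/s) per fish.
#' @param params parameter list.
#' @return list with updated `length`, `weight`, condition factor `k`, and the
#'   applied `dw`.
#' @export
grow <- function(length, weight, intake, temperature, velocity,
                 params = default_params()) {
  eng_grow(length, weight, intake, temperature,
           rep_len(velocity, base::length(length)), flatten_params(params))
}

#' Daily natural survival draws
#'
#' Applies the six natural mortality sources (high temperature, high velocity,
#' stranding, starvation, terrestrial predation, piscivory) as sequential
#' Bernoulli survival draws in that fixed order; the cause of death is the
#' first source whose draw fails.
#'
#' @param pop data.frame with `length` and condition `k`.
#' @param depth,velocity,cover per-fish cell state vectors.
#' @param temperature water temperature (C).
#' @param max_length longest trout in the reach (cm).
#' @param pisc_density piscivore density (fish/ha).
#' @param params parameter list.
#' @return integer vector: 0 = survived, otherwise 1..6 indexing the cause
#'   (see [mortality_causes()]).
#' @export
survive_natural <- function(pop, depth, velocity, cover, temperature,
                            max_length = max(pop$length), pisc_density = 0,
                            params = default_params()) {
  n <- nrow(pop)
  eng_survive_natural(pop$length, pop$k, rep_len(depth, n),
                      rep_len(velocity, n), rep_len(cover, n), temperature,
                      max_length, pisc_density, flatten_params(params))
}

#' Names of the mortality causes
#'
#' @return character vector of the nine causes in their fixed attribution
#'   order: the six natural sources, then the three fishing outcomes.
#' @export
mortality_causes <- function() {
  c("highTemperature", "highVelocity", "stranding", "starvation",
    "terrestrialPredation", "piscivory", "harvest", "illegalHarvest",
    "hooking")
}
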