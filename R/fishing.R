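#' Harvest regulation
#'
#' Convenience constructor for the fishing block of the configuration: the
#' exploitation-rate target ExpR (fraction of the harvestable stock harvested
#' over a season), the minimum and maximum length limits (`max_ll = 100`
#' behaves as a plain minimum-length regulation), the season window, and the
#' voluntary-release, noncompliance and hooking-mortality rates.
#'
#' @param exp_rate ExpR in [0, 1].
#' @param min_ll minimum-length limit (cm).
#' @param max_ll maximum-length limit (cm); 100 = no upper limit.
#' @param ... further overrides of the fishing block (see [default_params()]).
#' @return the fishing parameter sub-list.
#' @examples
#' reg <- harvest_regulation(0.35, 19, 100)
#' p <- default_params(fishing = reg)
#' @export
harvest_regulation <- function(exp_rate = 0, min_ll = 19, max_ll = 100, ...) {
  stopifnot(exp_rate >= 0, exp_rate <= 1, min_ll < max_ll)
  utils::modifyList(list(exp_rate = exp_rate, min_ll = min_ll,
                         max_ll = max_ll), list(...))
}

#' Is a length legal to harvest?
#'
#' Legal means within the closed interval \code{[min_ll, max_ll]}. Under a
#' harvest-slot regulation fish below the minimum and above the maximum are
#' protected; `max_ll = 100` reduces the slot to a plain minimum-length limit.
#'
#' @param length numeric vector of fish lengths (cm).
#' @param regulation a list with `min_ll` and `max_ll` (e.g. from
#'   [harvest_regulation()] or `params$fishing`).
#' @return logical vector.
#' @export
legal_length <- function(length, regulation) {
  length >= regulation$min_ll & length <= regulation$max_ll
}

#' Fishing pressure from an exploitation-rate target
#'
#' Converts the exploitation-rate target into the season-constant fishing
#' pressure:
#' \deqn{anglePressure = \frac{ExpR \times harvestableStock \times
#'   anglingEfficiency}{reachLength \times seasonLength}}
#' in angler-hours per km per day, where anglingEfficiency is the number of
#' angler-hours needed to catch and keep one trout.
#'
#' @param exp_rate ExpR (fraction).
#' @param harvestable_stock number of trout legal now or projected to become
#'   legal during the season.
#' @param angling_efficiency angler-h per kept trout.
#' @param reach_length_km reach length (km).
#' @param season_length_days angling-season length (days).
#' @return pressure in angler-h km^-1 day^-1.
#' @examples
#' compute_angle_pressure(0.35, 200, 5, 1, 214)  # 350/214
#' @export
compute_angle_pressure <- function(exp_rate, harvestable_stock,
                                   angling_efficiency, reach_length_km,
                                   season_length_days) {
  if (reach_length_km <= 0 || season_length_days <= 0) {
    stop("reach length and season length must be positive")
  }
  exp_rate * harvestable_stock * angling_efficiency /
    (reach_length_km * season_length_days)
}

#' Length-dependent capture rate
#'
#' Expected number of captures per day for a fish: fishing pressure times a
#' saturating two-point-logistic catchability of length, scaled to the
#' `q_max` plateau (approached by about 25 cm; capture is less likely for
#' smaller fish). Zero pressure gives rate zero.
#'
#' @param length fish length vector (cm).
#' @param angle_pressure angler-h km^-1 day^-1.
#' @param params parameter list.
#' @return expected captures per day per fish.
#' @export
capture_rate <- function(length, angle_pressure, params = default_params()) {
  stopifnot(all(length > 0), angle_pressure >= 0)
  f <- params$fishing
  anchors <- c(f$q_anchor_lengths[1], f$q_anchor_fracs[1],
               f$q_anchor_lengths[2], f$q_anchor_fracs[2])
  angle_pressure * f$q_max * two_point_logistic(length, anchors)
}

#' Harvestable stock at the start of the angling season
#'
#' Counts trout of legal size at season start plus trout whose projected
#' end-of-season length reaches the minimum-length limit. The projection
#' extrapolates the day's realized growth rate (weight change `dw` in the
#' assigned cell) over the whole season with the bioenergetic length-weight
#' inverse; the maximum-length limit is not applied.
#'
#' @param pop data.frame with `length` and `weight`.
#' @param regulation list with `min_ll`.
#' @param season_length_days angling-season length in days.
#' @param dw per-fish daily weight change (g/day) under start-of-season
#'   conditions (recycled); used when `gain` is NULL.
#' @param gain optional fixed projected length gain (cm) over the season,
#'   bypassing the bioenergetic projection.
#' @param params parameter list.
#' @return integer count.
#' @export
estimate_harvestable_stock <- function(pop, regulation, season_length_days,
                                       dw = 0, gain = NULL,
                                       params = default_params()) {
  if (nrow(pop) == 0) return(0L)
  if (!is.null(gain)) {
    proj <- pop$length + gain
  } else {
    b <- params$bioenergetics
    wproj <- pop$weight + season_length_days * rep_len(dw, nrow(pop))
    proj <- ifelse(wproj > 0, pmax(pop$length, (wproj / b$lw_a)^(1 / b$lw_b)),
                   pop$length)
  }
  sum(pop$length >= regulation$min_ll | proj >= regulation$min_ll)
}

#' One day of angling over a population
#'
#' Each fish is captured `Poisson(capture_rate)` times; events are processed
#' sequentially and stop at death. Legal-size captures are kept with
#' probability `1 - release_frac`, otherwise released; non-legal captures are
#' illegally kept with probability `noncompliance`, otherwise released; every
#' release kills with probability `hooking_mortality`.
#'
#' @param pop data.frame with `length`.
#' @param angle_pressure angler-h km^-1 day^-1.
#' @param params parameter list (regulation taken from its fishing block).
#' @return list with `outcome` per fish (0 alive, 7 harvest, 8 illegal
#'   harvest, 9 hooking; see [mortality_causes()]) and the ledger counters
#'   `captures`, `legal_captures`, `illegal_captures`, `keeps`,
#'   `illegal_keeps`, `releases`, `hooking_deaths`.
#' @export
angling_daily <- function(pop, angle_pressure, params = default_params()) {
  stopifnot(angle_pressure >= 0)
  eng_angling_day(pop$length, angle_pressure, flatten_params(params))
}
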