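#' Daily spawning readiness check for a female
#'
#' A female spawns on a given day only if all gates hold: the date is within
#' the spawning season; her length is at or above her expressed maturity
#' threshold; her condition factor is at least `k_spawn`; the water
#' temperature lies in the spawning window; flow is below the spate threshold;
#' and she has not already spawned this season. If all gates hold she spawns
#' that day with probability `p_spawn_daily`.
#'
#' @param female list/row with `length`, `p_mat_threshold`, `k`, `spawned`.
#' @param doy day of year.
#' @param temperature,flow environment of the day.
#' @param params parameter list.
#' @return logical.
#' @export
spawn_check <- function(female, doy, temperature, flow,
                        params = default_params()) {
  r <- params$reproduction
  gates <- doy >= r$spawn_start_doy && doy <= r$spawn_end_doy &&
    female$length >= female$p_mat_threshold &&
    female$k >= r$k_spawn &&
    temperature >= r$spawn_temp[1] && temperature <= r$spawn_temp[2] &&
    flow < r$spawn_max_flow &&
    !isTRUE(female$spawned)
  gates && stats::runif(1) < r$p_spawn_daily
}

#' Fecundity with the egg size-number trade-off
#'
#' Egg number grows exponentially with female length,
#' `round(a * L^b * (g_ref / gEmergence)^3)`: at fixed gonad investment, egg
#' mass scales with hatchling length cubed, so females whose genotypic size at
#' emergence exceeds the population reference produce larger but cubically
#' fewer eggs.
#'
#' @param length female length (cm).
#' @param g_emergence female's genotypic size at emergence (cm); defaults to
#'   the reference (trade-off factor 1).
#' @param params parameter list (`g_ref` is the configured initial emergence
#'   mean).
#' @return integer egg count.
#' @examples
#' fecundity(25)  # round(0.07 * 25^2.4)
#' @export
fecundity <- function(length, g_emergence = NULL, params = default_params()) {
  if (any(length <= 0)) stop("female length must be positive")
  r <- params$reproduction
  g_ref <- params$genetics$emergence$mean
  if (is.null(g_emergence)) g_emergence <- g_ref
  stopifnot(all(g_emergence > 0))
  round(r$fecundity_a * length^r$fecundity_b * (g_ref / g_emergence)^3)
}

#' Select the males fertilizing a redd
#'
#' The largest available mature male is always included; additionally
#' `k ~ Poisson(lambda_mates)` males are sampled uniformly without replacement
#' from the remaining (smaller) mature males, capped at their number. With no
#' mature male present there is no spawning and the result is empty.
#'
#' @param males data.frame of mature males with `id`, `length`, `weight`.
#' @param params parameter list.
#' @return data.frame of the selected fathers (largest first).
#' @export
select_mates <- function(males, params = default_params()) {
  if (nrow(males) == 0) return(males[0, , drop = FALSE])
  males <- rank_by_dominance(males)
  lambda <- params$reproduction$lambda_mates
  extra <- if (lambda > 0 && nrow(males) > 1) {
    k <- min(stats::rpois(1, lambda), nrow(males) - 1L)
    if (k > 0) 1L + sample.int(nrow(males) - 1L, k) else integer(0)
  } else {
    integer(0)
  }
  males[c(1L, extra), , drop = FALSE]
}

#' One day of redd development
#'
#' Eggs die with daily probabilities from temperature extremes (two two-point
#' logistics), dewatering when the cell depth is zero, scouring when flow
#' exceeds the scouring threshold, and a constant background rate; the
#' survivor count is a binomial draw. Development accumulates `max(0, T)`
#' degree-days; once the threshold is reached, a fixed fraction (rounded up)
#' of the surviving eggs hatches per day.
#'
#' @param eggs current viable egg count.
#' @param dd accumulated degree-days (C d).
#' @param temperature,depth,flow environment of the day.
#' @param params parameter list.
#' @return list with updated `eggs`, `dd`, the day's `deaths` and `hatch`
#'   counts.
#' @export
redd_daily <- function(eggs, dd, temperature, depth, flow,
                       params = default_params()) {
  stopifnot(eggs >= 0, dd >= 0)
  eng_redd_day(as.integer(eggs), dd, temperature, depth, flow,
               flatten_params(params))
}

#' Create hatchlings from a redd
#'
#' For every hatchling a father is drawn uniformly from the redd's
#' contributing males; the genotype is inherited under the infinitesimal model
#' ([inherit_genotype()]), sex is Bernoulli(0.5), the length is the expressed
#' phenotypic size at emergence, and the weight is the healthy weight at that
#' length.
#'
#' @param n number of hatchlings.
#' @param mother genotype (named vector or single-row data.frame).
#' @param fathers data.frame of father genotypes (>= 1 row).
#' @param params parameter list.
#' @param evolution if FALSE (the no-evolution control), hatchling genotypes
#'   are drawn from the initial trait distributions instead of inherited.
#' @return data.frame of new trout: `sex`, `age` (0), `length`, `weight`,
#'   genotype and phenotype columns, and `father` (the drawn father's row).
#' @export
emerge <- function(n, mother, fathers, params = default_params(),
                   evolution = TRUE) {
  stopifnot(n >= 1, nrow(as_genotype_df(fathers)) >= 1)
  fa <- as_genotype_df(fathers)
  pick <- sample.int(nrow(fa), n, replace = TRUE)
  if (evolution) {
    geno <- inherit_genotype(as_genotype_df(mother)[rep(1, n), , drop = FALSE],
                             fa[pick, , drop = FALSE], params)
  } else {
    geno <- founder_genotypes(n, params)
  }
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  phen <- express_phenotype(geno, sex, params)
  b <- params$bioenergetics
  data.frame(sex = sex, age = 0L, length = phen$p_emergence,
             weight = b$lw_a * phen$p_emergence^b$lw_b, geno, phen,
             father = pick)
}
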