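#' Generate a synthetic initial trout population
#'
#' Draws an age-structured starting population for January 1 of the first
#' simulated year. Counts per age class are the configured densities (fish/ha)
#' times the reach area, rounded; lengths are normal per age class (truncated
#' at 1 cm); sex is Bernoulli(`sex_ratio`) female; genotypes come from the
#' initial trait distributions ([founder_genotypes()]) and phenotypes from
#' [express_phenotype()]; weight is the healthy weight at length
#' (`lw_a * L^lw_b`, condition factor 1).
#'
#' @param params parameter list from [default_params()].
#' @param area_ha wetted area of the reach in hectares (defaults to the
#'   configured reach geometry).
#' @param seed integer seed.
#' @return a data.frame of class `ecotrout_population`, one row per fish:
#'   `id`, `sex`, `age`, `length`, `weight`, the four genotype columns,
#'   `p_emergence`, `p_mat_threshold`.
#' @examples
#' pop <- generate_initial_population(seed = 1)
#' table(pop$age)
#' @export
generate_initial_population <- function(params = default_params(),
                                        area_ha = NULL, seed = 1) {
  sp <- params$population
  stopifnot(all(sp$density >= 0), all(sp$length_sd >= 0),
            sp$sex_ratio >= 0, sp$sex_ratio <= 1)
  if (sum(sp$density) <= 0) stop("initial population has zero total abundance")
  if (is.null(area_ha)) {
    area_ha <- params$reach$length_km * 1000 * params$reach$mean_width / 1e4
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))

  counts <- round(sp$density * area_ha)
  n <- sum(counts)
  if (n == 0) stop("reach too small for the configured densities")
  age <- rep(sp$ages, counts)
  mu <- rep(sp$length_mean, counts)
  sdv <- rep(sp$length_sd, counts)
  len <- pmax(1, stats::rnorm(n, mu, sdv))
  sex <- ifelse(stats::runif(n) < sp$sex_ratio, "F", "M")
  geno <- founder_genotypes(n, params)
  phen <- express_phenotype(geno, sex, params)
  b <- params$bioenergetics
  out <- data.frame(
    id = seq_len(n), sex = sex, age = as.integer(age),
    length = len, weight = b$lw_a * len^b$lw_b,
    geno, phen
  )
  class(out) <- c("ecotrout_population", "data.frame")
  out
}
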