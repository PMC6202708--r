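rec_names <- c(
  "year",
  "den_age0", "den_age1", "den_age2", "den_age3p",
  "bio_age0", "bio_age1", "bio_age2", "bio_age3p",
  "w_age0", "w_age1", "w_age2", "w_age3p",
  "den_total", "bio_total", "adult_juv_ratio",
  "spawner_density", "spawner_mean_age", "spawner_biomass",
  "g_mat_male", "g_mat_female", "g_emergence", "g_neutral",
  "eggs_per_ha",
  "captures", "legal_captures", "illegal_captures",
  "harvest", "illegal_harvest", "releases", "hooking_deaths",
  "harvestable_stock", "angle_pressure", "realized_exp_rate",
  "n_census", "emerged", "deaths_natural", "deaths_fishing"
)

#' Names of the 15 annual population outputs
#'
#' Density, biomass and mean weight for age classes 0, 1, 2 and 3+, total
#' density and biomass, and the adult (age 2+) to juvenile (age 0-1) biomass
#' ratio — all recorded each year at the September 1 census.
#'
#' @return character vector of length 15 naming columns of the annual records.
#' @export
population_output_names <- function() {
  c("den_age0", "den_age1", "den_age2", "den_age3p",
    "bio_age0", "bio_age1", "bio_age2", "bio_age3p",
    "w_age0", "w_age1", "w_age2", "w_age3p",
    "den_total", "bio_total", "adult_juv_ratio")
}

#' Run one simulation
#'
#' Executes the full daily schedule for the configured number of years:
#' environment and cell update, dominance-ordered habitat selection,
#' bioenergetic growth, the six natural mortality sources, angling (within the
#' season, after the burn-in), spawning and redd dynamics with genetic
#' transmission, and the annual recorders (population outputs at the September
#' 1 census, spawner and egg outputs at the end of the spawning season,
#' fishery outputs at the end of the angling season).
#'
#' The run is a pure function of (params, seed). The reach and the climate
#' series act as the study site: they come from the dedicated `reach$seed`
#' and `environment$seed` (so scenarios and replicates share one site and one
#' weather history, like a gauge record), while the initial population and
#' all demographic, genetic and fishing randomness derive from `seed`.
#' Setting either site seed to NULL derives it from the run seed instead.
#'
#' @param params parameter list from [default_params()].
#' @param seed integer seed.
#' @param env optional environment data.frame ([generate_environment()]); must
#'   cover at least `years * 365` days.
#' @param reach optional reach ([generate_reach()]).
#' @param init_pop optional initial population
#'   ([generate_initial_population()]).
#' @return an object of class `ecotrout_sim`: a list with `records` (one row
#'   per simulated year), `final_population`, `params`, `seed`, `area_ha`, and
#'   the structural diagnostics `accounting_ok` (daily population accounting
#'   closes) and `egg_conservation_ok` (emergences + egg deaths = eggs laid,
#'   per redd).
#' @examples
#' \donttest{
#' p <- default_params(experiment = list(years = 3L, burn_in = 1L))
#' sim <- run_simulation(p, seed = 1)
#' summary(sim)
#' }
#' @export
run_simulation <- function(params = default_params(), seed = 1, env = NULL,
                           reach = NULL, init_pop = NULL) {
  validate_params(params)
  seed <- as.integer(seed)
  years <- as.integer(params$experiment$years)
  if (is.null(env)) {
    env_seed <- params$environment$seed
    if (is.null(env_seed)) env_seed <- seed
    env <- generate_environment(years, params, seed = env_seed)
  }
  if (nrow(env) < years * 365) stop("environment series too short for the run")
  if (is.null(reach)) {
    reach_seed <- params$reach$seed
    if (is.null(reach_seed)) reach_seed <- seed + 1L
    reach <- generate_reach(params, seed = reach_seed)
  }
  if (is.null(init_pop)) {
    area_ha <- sum(reach$area) / 1e4
    init_pop <- generate_initial_population(params, area_ha = area_ha,
                                            seed = seed + 2L)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(seed + 3L)
  out <- eng_run(flatten_params(params), reach, env, init_pop, years)
  records <- as.data.frame(out$records)
  names(records) <- rec_names
  structure(
    list(records = records, final_population = out$final_population,
         params = params, seed = seed, area_ha = out$area_ha,
         accounting_ok = out$accounting_ok,
         egg_conservation_ok = out$egg_conservation_ok,
         deaths_by_cause = stats::setNames(out$deaths_by_cause,
                                           mortality_causes())),
    class = "ecotrout_sim"
  )
}

#' @export
print.ecotrout_sim <- function(x, ...) {
  f <- x$params$fishing
  cat("<ecotrout_sim>", nrow(x$records), "years,",
      sprintf("%.2f ha reach\n", x$area_ha))
  cat(sprintf("  regulation: ExpR=%.2f MinLL=%g MaxLL=%g (burn-in %d y)\n",
              f$exp_rate, f$min_ll, f$max_ll, x$params$experiment$burn_in))
  last <- x$records[nrow(x$records), ]
  cat(sprintf("  final year: %.0f fish/ha, %.1f kg/ha, %.0f eggs/ha\n",
              last$den_total, last$bio_total, last$eggs_per_ha))
  invisible(x)
}

#' @export
summary.ecotrout_sim <- function(object, window = NULL, ...) {
  r <- object$records
  if (is.null(window)) window <- analysis_window(nrow(r))
  w <- r[seq(nrow(r) - window + 1, nrow(r)), ]
  out <- list(
    years = nrow(r), window = window,
    population = colMeans(w[population_output_names()], na.rm = TRUE),
    spawners = colMeans(w[c("spawner_density", "spawner_mean_age",
                            "spawner_biomass", "g_mat_male", "g_mat_female",
                            "g_emergence", "g_neutral", "eggs_per_ha")],
                        na.rm = TRUE),
    fishery = colMeans(w[c("harvest", "illegal_harvest", "hooking_deaths",
                           "realized_exp_rate")], na.rm = TRUE)
  )
  class(out) <- "summary.ecotrout_sim"
  out
}

#' @export
print.summary.ecotrout_sim <- function(x, ...) {
  cat(sprintf("ecotrout simulation: %d years; means over the final %d:\n",
              x$years, x$window))
  cat("population outputs:\n")
  print(round(x$population, 2))
  cat("spawner outputs:\n")
  print(round(x$spawners, 3))
  cat("fishery outputs:\n")
  print(round(x$fishery, 3))
  invisible(x)
}

#' @export
plot.ecotrout_sim <- function(x, outputs = c("den_total", "bio_total",
                                             "adult_juv_ratio",
                                             "g_mat_female"), ...) {
  r <- x$records
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in outputs) {
    graphics::plot(r$year, r[[v]], type = "l", xlab = "year", ylab = v, ...)
  }
  invisible(x)
}
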