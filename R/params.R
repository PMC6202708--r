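#' Default model configuration
#'
#' Builds the full nested parameter list driving the simulation: synthetic
#' climate, reach geometry, initial population, quantitative genetics,
#' bioenergetics, the six natural survival functions, reproduction, and the
#' fishing module. Every value can be overridden by passing a named list of
#' replacements; unknown names are an error so typos cannot silently fall back
#' to defaults.
#'
#' Units follow stream-salmonid convention: lengths in cm, weights in g,
#' temperature in degrees C, flow in m^3/s, depth in m, velocity in m/s,
#' densities per hectare, energy in J.
#'
#' @param ... named overrides, e.g. \code{fishing = list(exp_rate = 0.35)}.
#'   Sub-lists are merged field by field.
#' @return a nested list of class \code{"ecotrout_params"}.
#' @examples
#' p <- default_params(fishing = list(exp_rate = 0.35, min_ll = 19))
#' p$fishing$min_ll
#' @export
default_params <- function(...) {
  p <- list(
    environment = list(
      seed           = 7L,  # climate seed: one series per experiment, shared
                            # by all scenarios and replicates (like a gauge
                            # record); set NULL to derive from the run seed
      temp_mean      = 9.5,   # annual mean water temperature (C)
      temp_amplitude = 7.5,   # sinusoid amplitude (C); summer ~17, winter ~2
      temp_peak_doy  = 212,   # day-of-year of the warmest water (late July)
      temp_ar1       = 0.90,  # AR(1) coefficient of the temperature noise
      temp_noise_sd  = 0.8,   # innovation SD (C)
      flow_log_mean  = 0.0,   # log m^3/s; exp(0) = 1 m^3/s median flow
      flow_amplitude = 0.45,  # seasonal amplitude on the log scale
      flow_peak_doy  = 45,    # winter/early-spring high-flow peak
      flow_ar1       = 0.85,
      flow_noise_sd  = 0.30
    ),
    reach = list(
      seed        = 77L,    # habitat seed: the site is fixed across replicates
      length_km   = 1.0,
      n_cells     = 20L,
      mean_width  = 6.0,    # m; total area = length_km * 1000 * mean_width
      area_cv     = 0.3,    # relative spread of cell areas
      depth_coef  = c(0.25, 0.55),  # a_d range: depth = a_d * Q^b_d
      depth_exp   = c(0.30, 0.50),  # b_d range
      vel_coef    = c(0.05, 0.60),  # a_v range: velocity = a_v * Q^b_v
      vel_exp     = c(0.30, 0.50),  # b_v range
      drift_prod  = 0.8,    # g drift food m^-2 day^-1 per (m/s) at the cell
      search_prod = 0.06,   # g stationary search food m^-2 day^-1 (flow-free)
      cover_range = c(0.0, 0.6)
    ),
    population = list(
      # abundance (fish/ha) and length mean/SD (cm) per age class at Jan 1
      ages        = 0:5,
      density     = c(2000, 500, 200, 60, 25, 15),
      length_mean = c(7, 13, 18, 23, 26, 29),
      length_sd   = c(1.0, 1.5, 2.0, 2.0, 2.0, 2.5),
      sex_ratio   = 0.5      # probability female
    ),
    genetics = list(
      # infinitesimal model; h^2 = VA/(VA+VE) = 0.2 for every trait
      emergence  = list(mean = 2.8, va = 0.02, ve = 0.08, vmut = 0.02 * 0.001),
      mat_male   = list(mean = 15,  va = 0.8,  ve = 3.2,  vmut = 0.8 * 0.001),
      mat_female = list(mean = 17,  va = 0.8,  ve = 3.2,  vmut = 0.8 * 0.001),
      neutral    = list(mean = 0,   va = 1.0,  ve = 4.0,  vmut = 1.0 * 0.001),
      floor_frac = 0.1       # phenotype/genotype floor as fraction of the mean
    ),
    bioenergetics = list(
      lw_a        = 0.0095,  # healthy weight (g) = lw_a * L(cm)^lw_b
      lw_b        = 3.03,
      cmax_a      = 0.053,    # max daily intake (g food) = a * W^b * f(T)
      cmax_b      = 0.65,
      cmax_t_opt  = 14.0,    # f(T) = exp(-((T - t_opt)/t_sig)^2)
      cmax_t_sig  = 12.0,
      resp_a      = 40.0,    # respiration (J/day) = a * W^b * exp(c*T) * (1 + d*v)
      resp_b      = 0.80,
      resp_c      = 0.064,
      resp_d      = 1.0,
      e_food      = 5200,    # J per g of invertebrate drift food
      e_fish      = 5900,    # J per g of fish tissue
      k_floor     = 0.4,     # condition factor floor before starvation acts
      fitness_horizon = 90,  # days for the habitat-selection fitness measure
      swim_a      = 0.20,    # max sustainable swim speed (m/s) =
      swim_b      = 0.040,   #   (swim_a + swim_b * L) * (swim_c + swim_d * T)
      swim_c      = 0.80,
      swim_d      = 0.02
    ),
    survival = list(
      # two-point logistic anchors (driver1, surv1, driver2, surv2), daily
      temperature = c(24, 0.999, 28, 0.80),       # driver: T (C), decreasing
      velocity    = c(1.0, 0.9995, 1.8, 0.90),    # driver: v / maxSwim
      stranding   = c(0.2, 0.990, 2.0, 0.9999),   # driver: depth / body length
      starvation  = c(0.5, 0.85, 0.9, 0.9995),    # driver: condition K
      terrestrial = c(5, 0.9999, 30, 0.9960),     # driver: length (cm)
      terr_depth_b = 1.5,    # logit bonus per m of depth
      terr_cover_b = 2.0,    # logit bonus per unit cover fraction
      piscivory   = c(3, 0.97, 12, 0.999),       # driver: length (cm)
      pisc_min_length = 18,  # cm; trout at least this long are piscivores
      pisc_ref_density = 150 # piscivores/ha giving the anchored risk
    ),
    reproduction = list(
      spawn_start_doy = 305, # Nov 1
      spawn_end_doy   = 365, # Dec 31
      p_spawn_daily   = 0.1,
      k_spawn         = 0.95,
      spawn_temp      = c(1, 12),  # C window
      spawn_max_flow  = 4.0,       # m^3/s spate threshold
      fecundity_a     = 0.07,      # eggs = round(a * L^b * (g_ref/gEmergence)^3)
      fecundity_b     = 2.4,
      lambda_mates    = 1.5,       # Poisson number of extra (smaller) males
      egg_background  = 0.990,     # daily background egg survival
      egg_temp_lo     = c(-1, 0.93, 1.0, 0.999),   # low-T anchors, increasing
      egg_temp_hi     = c(14, 0.999, 18, 0.90),    # high-T anchors, decreasing
      egg_dewater     = 0.90,      # daily egg survival while cell depth = 0
      egg_scour_flow  = 6.0,       # m^3/s; above it scouring mortality applies
      egg_scour       = 0.80,      # daily egg survival on scouring days
      dd_emerge       = 430,       # degree-days to full development
      hatch_frac      = 0.1        # fraction of developed eggs hatching per day
    ),
    fishing = list(
      exp_rate          = 0,     # ExpR: fraction of harvestable stock harvested
      min_ll            = 19,    # cm
      max_ll            = 100,   # cm; 100 = no upper limit (plain MLL)
      season_start_doy  = 91,    # Apr 1
      season_end_doy    = 304,   # Oct 31
      release_frac      = 0.60,  # voluntary release of legal-size captures
      noncompliance     = 0.05,  # illegal keep of non-legal captures
      hooking_mortality = 0.20,  # death probability per release event
      angling_efficiency = 5.0,  # angler-h per kept trout
      q_max             = 0.0075, # catchability plateau: captures per fish per angler-h km
      q_anchor_lengths  = c(10, 25),  # cm; q passes 0.1*q_max and 0.9*q_max here
      q_anchor_fracs    = c(0.1, 0.9)
    ),
    experiment = list(
      years        = 40L,
      burn_in      = 10L,   # fishing-free years before regulations start
      evolution    = TRUE,
      census_doy   = 244    # Sep 1 (non-leap calendar; the model year has 365 d)
    )
  )
  p <- merge_params(p, list(...))
  class(p) <- "ecotrout_params"
  validate_params(p)
  p
}

# recursive merge with strict name checking
merge_params <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("unknown parameter: ", path, nm, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]],
                                 path = paste0(path, nm, "$"))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_params <- function(p) {
  stopifnot(
    p$environment$temp_noise_sd >= 0, p$environment$flow_noise_sd >= 0,
    p$reach$length_km > 0, p$reach$n_cells >= 1, p$reach$mean_width > 0,
    all(p$population$density >= 0), sum(p$population$density) > 0,
    all(p$population$length_sd >= 0),
    p$population$sex_ratio >= 0, p$population$sex_ratio <= 1,
    p$fishing$exp_rate >= 0, p$fishing$exp_rate <= 1,
    p$fishing$min_ll < p$fishing$max_ll,
    p$fishing$release_frac >= 0, p$fishing$release_frac <= 1,
    p$fishing$noncompliance >= 0, p$fishing$noncompliance <= 1,
    p$fishing$hooking_mortality >= 0, p$fishing$hooking_mortality <= 1,
    p$experiment$years >= 1, p$experiment$burn_in >= 0
  )
  for (tr in c("emergence", "mat_male", "mat_female", "neutral")) {
    g <- p$genetics[[tr]]
    if (g$va < 0 || g$ve < 0 || g$vmut < 0) {
      stop("negative variance component for trait ", tr, call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.ecotrout_params <- function(x, ...) {
  cat("<ecotrout_params>\n")
  cat(sprintf("  reach: %.1f km, %d cells, mean width %.1f m\n",
              x$reach$length_km, x$reach$n_cells, x$reach$mean_width))
  cat(sprintf("  fishing: ExpR=%.2f MinLL=%g MaxLL=%g season doy %d-%d\n",
              x$fishing$exp_rate, x$fishing$min_ll, x$fishing$max_ll,
              x$fishing$season_start_doy, x$fishing$season_end_doy))
  cat(sprintf("  experiment: %d y (burn-in %d), evolution %s\n",
              x$experiment$years, x$experiment$burn_in,
              if (x$experiment$evolution) "on" else "off"))
  invisible(x)
}

# Flatten the nested parameter list into the named numeric vector consumed by
# the C++ engine. Kept in one place so R wrappers and the engine always agree.
flatten_params <- function(p) {
  g <- p$genetics; b <- p$bioenergetics; s <- p$survival
  r <- p$reproduction; f <- p$fishing
  anch <- function(v) as.numeric(v)
  out <- c(
    lw_a = b$lw_a, lw_b = b$lw_b,
    cmax_a = b$cmax_a, cmax_b = b$cmax_b,
    cmax_t_opt = b$cmax_t_opt, cmax_t_sig = b$cmax_t_sig,
    resp_a = b$resp_a, resp_b = b$resp_b, resp_c = b$resp_c, resp_d = b$resp_d,
    e_food = b$e_food, e_fish = b$e_fish, k_floor = b$k_floor,
    fitness_horizon = b$fitness_horizon,
    swim_a = b$swim_a, swim_b = b$swim_b, swim_c = b$swim_c, swim_d = b$swim_d,
    surv_temp = anch(s$temperature), surv_vel = anch(s$velocity),
    surv_strand = anch(s$stranding), surv_starv = anch(s$starvation),
    surv_terr = anch(s$terrestrial),
    terr_depth_b = s$terr_depth_b, terr_cover_b = s$terr_cover_b,
    surv_pisc = anch(s$piscivory),
    pisc_min_length = s$pisc_min_length, pisc_ref_density = s$pisc_ref_density,
    g_em_mean = g$emergence$mean, g_em_va = g$emergence$va,
    g_em_ve = g$emergence$ve, g_em_vmut = g$emergence$vmut,
    g_mm_mean = g$mat_male$mean, g_mm_va = g$mat_male$va,
    g_mm_ve = g$mat_male$ve, g_mm_vmut = g$mat_male$vmut,
    g_mf_mean = g$mat_female$mean, g_mf_va = g$mat_female$va,
    g_mf_ve = g$mat_female$ve, g_mf_vmut = g$mat_female$vmut,
    g_nt_mean = g$neutral$mean, g_nt_va = g$neutral$va,
    g_nt_ve = g$neutral$ve, g_nt_vmut = g$neutral$vmut,
    g_floor_frac = g$floor_frac,
    spawn_start_doy = r$spawn_start_doy, spawn_end_doy = r$spawn_end_doy,
    p_spawn_daily = r$p_spawn_daily, k_spawn = r$k_spawn,
    spawn_temp_lo = r$spawn_temp[1], spawn_temp_hi = r$spawn_temp[2],
    spawn_max_flow = r$spawn_max_flow,
    fecundity_a = r$fecundity_a, fecundity_b = r$fecundity_b,
    lambda_mates = r$lambda_mates,
    egg_background = r$egg_background,
    egg_temp_lo = anch(r$egg_temp_lo), egg_temp_hi = anch(r$egg_temp_hi),
    egg_dewater = r$egg_dewater,
    egg_scour_flow = r$egg_scour_flow, egg_scour = r$egg_scour,
    dd_emerge = r$dd_emerge, hatch_frac = r$hatch_frac,
    exp_rate = f$exp_rate, min_ll = f$min_ll, max_ll = f$max_ll,
    season_start_doy = f$season_start_doy, season_end_doy = f$season_end_doy,
    release_frac = f$release_frac, noncompliance = f$noncompliance,
    hooking_mortality = f$hooking_mortality,
    angling_efficiency = f$angling_efficiency,
    q_max = f$q_max,
    q_anchor = c(f$q_anchor_lengths, f$q_anchor_fracs),
    reach_length_km = p$reach$length_km,
    evolution = as.numeric(p$experiment$evolution),
    census_doy = p$experiment$census_doy,
    burn_in = p$experiment$burn_in
  )
  out
}
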