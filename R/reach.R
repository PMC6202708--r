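#' Generate a synthetic stream reach
#'
#' Builds the set of rectangular habitat cells representing the modeled reach.
#' Each cell carries hydraulic-geometry power-law parameters mapping reach flow
#' to local depth and velocity (`depth = depth_coef * Q^depth_exp`, likewise
#' for velocity), an area, a static cover fraction, and food-production rates
#' (flow-dependent drift plus a stationary search-food floor). Cell areas are
#' scaled so they sum exactly to `length_km * 1000 * mean_width` m^2.
#'
#' @param params parameter list from [default_params()] (the `reach` block),
#'   or the block itself.
#' @param seed integer seed; the reach is a pure function of (params, seed).
#' @return a data.frame of class `ecotrout_reach`, one row per cell, with
#'   columns `cell`, `area`, `depth_coef`, `depth_exp`, `vel_coef`, `vel_exp`,
#'   `cover`, `drift_prod`, `search_prod`, plus the dynamic columns `depth`,
#'   `velocity`, `food` initialised to NA until [update_cells()] is called.
#' @examples
#' reach <- generate_reach(seed = 1)
#' sum(reach$area)
#' @export
generate_reach <- function(params = default_params(), seed = 1) {
  r <- if (!is.null(params$reach)) params$reach else params
  stopifnot(r$length_km > 0, r$n_cells >= 1)
  rng_ok <- function(x) length(x) == 2 && x[2] >= x[1]
  if (!rng_ok(r$depth_coef) || !rng_ok(r$depth_exp) ||
      !rng_ok(r$vel_coef) || !rng_ok(r$vel_exp) || !rng_ok(r$cover_range)) {
    stop("each hydraulic-geometry range must be c(lo, hi) with hi >= lo")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))

  n <- as.integer(r$n_cells)
  total_area <- r$length_km * 1000 * r$mean_width
  w <- stats::runif(n, max(0.01, 1 - r$area_cv), 1 + r$area_cv)
  area <- total_area * w / sum(w)
  ru <- function(rg) stats::runif(n, rg[1], rg[2])
  out <- data.frame(
    cell = seq_len(n),
    area = area,
    depth_coef = ru(r$depth_coef),
    depth_exp = ru(r$depth_exp),
    vel_coef = ru(r$vel_coef),
    vel_exp = ru(r$vel_exp),
    cover = ru(r$cover_range),
    drift_prod = rep(r$drift_prod, n),
    search_prod = rep(r$search_prod, n),
    depth = NA_real_, velocity = NA_real_, food = NA_real_
  )
  class(out) <- c("ecotrout_reach", "data.frame")
  out
}

#' Update flow-dependent cell state
#'
#' Sets each cell's current depth, velocity and daily food availability from
#' the reach flow. Depth and velocity follow the per-cell hydraulic-geometry
#' power laws; daily food is drift production (proportional to velocity times
#' area times the drift production rate) plus the stationary search-food floor
#' (`search_prod * area`), which does not depend on flow.
#'
#' @param cells a reach data.frame from [generate_reach()].
#' @param flow reach flow in m^3/s (> 0).
#' @return the cells data.frame with `depth`, `velocity`, `food` set.
#' @export
update_cells <- function(cells, flow) {
  if (!is.numeric(flow) || length(flow) != 1 || !is.finite(flow) || flow <= 0) {
    stop("flow must be a single positive number")
  }
  cells$depth <- cells$depth_coef * flow^cells$depth_exp
  cells$velocity <- cells$vel_coef * flow^cells$vel_exp
  cells$food <- cells$drift_prod * cells$velocity * cells$area +
    cells$search_prod * cells$area
  cells
}
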