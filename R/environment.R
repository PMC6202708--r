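#' Generate a synthetic daily environment series
#'
#' Produces the daily water-temperature and stream-flow series that drives the
#' simulation. Temperature is an annual sinusoid plus AR(1) noise, truncated at
#' 0 C; flow is lognormal around a seasonal baseline with AR(1) noise on the
#' log scale. The model calendar has 365-day years (no leap days), so dates are
#' indexed by (year, day-of-year).
#'
#' @param years number of years (>= 1).
#' @param params a parameter list from [default_params()] (only the
#'   `environment` block is used), or the block itself.
#' @param seed integer seed; the series is a pure function of (params, seed).
#' @param start_year first calendar year label (cosmetic).
#' @return a data.frame with columns `date` (Date), `year`, `doy`,
#'   `temperature` (C), `flow` (m^3/s).
#' @examples
#' env <- generate_environment(2, seed = 1)
#' range(env$temperature)
#' @export
generate_environment <- function(years, params = default_params(), seed = 1,
                                 start_year = 2001L) {
  if (!is.numeric(years) || length(years) != 1 || years < 1) {
    stop("years must be a single number >= 1")
  }
  e <- if (!is.null(params$environment)) params$environment else params
  if (e$temp_noise_sd < 0 || e$flow_noise_sd < 0) {
    stop("negative noise SD")
  }
  years <- as.integer(years)
  n <- 365L * years
  doy <- rep.int(seq_len(365L), years)
  yr <- rep(seq_len(years), each = 365L)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))

  phase <- 2 * pi * (doy - e$temp_peak_doy) / 365
  t_base <- e$temp_mean + e$temp_amplitude * cos(phase)
  t_noise <- ar1_noise(n, e$temp_ar1, e$temp_noise_sd)
  temperature <- pmax(0, t_base + t_noise)

  f_phase <- 2 * pi * (doy - e$flow_peak_doy) / 365
  f_base <- e$flow_log_mean + e$flow_amplitude * cos(f_phase)
  f_noise <- ar1_noise(n, e$flow_ar1, e$flow_noise_sd)
  flow <- exp(f_base + f_noise)

  data.frame(
    date = as.Date(paste0(start_year, "-01-01")) + seq_len(n) - 1L,
    year = yr + start_year - 1L,
    doy = doy,
    temperature = temperature,
    flow = flow
  )
}

# AR(1) noise with stationary marginal SD `sd`
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- rho * x[i] + eps[i]
  x
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read an environment series as CSV
#'
#' The on-disk format has columns `date` (ISO-8601), `temperature`, `flow`.
#' Reading validates the header, date parseability, and that the dates form a
#' contiguous daily sequence.
#'
#' @param env a data.frame as returned by [generate_environment()].
#' @param path file path.
#' @return `read_environment_csv` returns the environment data.frame (with
#'   `year` and `doy` reconstructed); `write_environment_csv` returns `path`
#'   invisibly.
#' @export
write_environment_csv <- function(env, path) {
  stopifnot(all(c("date", "temperature", "flow") %in% names(env)))
  utils::write.csv(
    data.frame(date = as.character(env$date),
               temperature = env$temperature,
               flow = env$flow),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_environment_csv
#' @export
read_environment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "temperature", "flow")
  if (!all(need %in% names(df))) {
    stop("environment CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("environment CSV is empty")
  d <- as.Date(df$date)
  if (anyNA(d)) stop("unparseable dates in environment CSV")
  if (nrow(df) > 1 && any(diff(as.integer(d)) != 1L)) {
    stop("gap in the daily date sequence of the environment CSV")
  }
  if (anyNA(df$temperature) || anyNA(df$flow)) stop("missing values")
  if (any(df$flow <= 0)) stop("non-positive flow in environment CSV")
  # model calendar: 365-day years counted from the first record
  i <- seq_len(nrow(df)) - 1L
  y0 <- as.POSIXlt(d[1])$year + 1900L
  data.frame(date = d, year = y0 + i %/% 365L, doy = i %% 365L + 1L,
             temperature = df$temperature, flow = df$flow)
}
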