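#' Analysis window length
#'
#' The endpoint analyses average each output over the final years of a run:
#' 15 years for runs of 100 years or more, otherwise the final 15% (at least
#' 3 years).
#'
#' @param n_years run length in years.
#' @return window length in years.
#' @export
analysis_window <- function(n_years) {
  if (n_years >= 100) 15L else max(3L, as.integer(round(0.15 * n_years)))
}

#' Endpoint comparison of a scenario against the baseline
#'
#' Per-replicate means over the analysis window are compared between a
#' scenario arm and the baseline arm by a Welch two-sample t-test at
#' alpha = 0.05; the effect size is the percent change of the pooled scenario
#' mean from the pooled baseline mean:
#' `(mean_scenario - mean_baseline) / mean_baseline * 100`.
#'
#' @param scenario,baseline numeric matrices or data.frames (years x
#'   replicates) of annual values, or vectors of per-replicate window means.
#' @param window analysis window in years (ignored when vectors of window
#'   means are supplied).
#' @return list of class `ecotrout_comparison`: `mean_scenario`,
#'   `mean_baseline`, `percent_change` (NA with `undefined = TRUE` when the
#'   baseline mean is 0), `t`, `df`, `p`, `significant`.
#' @export
endpoint_comparison <- function(scenario, baseline, window = NULL) {
  wm <- function(x) {
    if (is.null(dim(x))) return(as.numeric(x))
    x <- as.matrix(x)
    if (is.null(window)) window <- analysis_window(nrow(x))
    colMeans(x[seq(nrow(x) - window + 1, nrow(x)), , drop = FALSE],
             na.rm = TRUE)
  }
  ms <- wm(scenario)
  mb <- wm(baseline)
  if (length(ms) < 2 || length(mb) < 2) {
    stop("need at least 2 replicates per arm")
  }
  m1 <- mean(ms)
  m0 <- mean(mb)
  undefined <- m0 == 0
  pc <- if (undefined) NA_real_ else (m1 - m0) / m0 * 100
  if (stats::var(ms) == 0 && stats::var(mb) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(ms) +
                                                     length(mb) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(ms, mb)
  }
  structure(
    list(mean_scenario = m1, mean_baseline = m0, percent_change = pc,
         undefined = undefined, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         significant = tt$p.value < 0.05),
    class = "ecotrout_comparison"
  )
}

#' @export
print.ecotrout_comparison <- function(x, ...) {
  cat(sprintf("scenario %.4g vs baseline %.4g: %+.1f%% (t=%.2f, p=%.4g%s)\n",
              x$mean_scenario, x$mean_baseline, x$percent_change, x$t, x$p,
              if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotone trend in an annual series:
#' `S = sum_{i<j} sign(x_j - x_i)`, with the tie-corrected variance
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie-group
#' sizes t), the +-1 continuity-corrected normal deviate Z, and a two-sided
#' normal p-value.
#'
#' @param x numeric series (n >= 3; constant series give S = 0, p = 1).
#' @return list of class `ecotrout_trend`: `S`, `var_S`, `Z`, `p`,
#'   `direction` (sign of S), `n`.
#' @examples
#' mann_kendall(c(1, 2, 3, 4))$S  # 6
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  s <- 0L
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  }
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s == 0) 0 else if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) {
    (s + 1) / sqrt(var_s)
  } else 0
  p <- if (var_s == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(S = as.integer(s), var_S = var_s, Z = z, p = min(p, 1),
                 direction = sign(s), n = n),
            class = "ecotrout_trend")
}

#' @export
print.ecotrout_trend <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S=%d, Var(S)=%.2f, Z=%.3f, p=%.4g (n=%d)\n",
              x$S, x$var_S, x$Z, x$p, x$n))
  invisible(x)
}

#' Balanced factorial ANOVA with variance decomposition
#'
#' Fits the three angling parameters (MaxLL, MinLL, ExpR) as factors with all
#' two-way interactions on per-replicate window means of one output, on a
#' balanced full-factorial design, and decomposes the percent of variance
#' explained by each term as its share of the total sum of squares (exact and
#' orthogonal on a balanced design). The effect direction of each main effect
#' is the sign of the linear contrast of the group means over the factor's
#' ordered levels.
#'
#' @param data data.frame with columns `exp_rate`, `min_ll`, `max_ll`,
#'   `value` — one row per scenario x replicate (e.g. from [window_means()]).
#' @return data.frame of class `ecotrout_anova`: one row per term
#'   (`max_ll`, `min_ll`, `exp_rate`, the three two-way interactions, and
#'   `residual`) with `direction`, `F`, `p`, `pct_variance`.
#' @export
factorial_anova <- function(data) {
  stopifnot(all(c("exp_rate", "min_ll", "max_ll", "value") %in% names(data)))
  if (anyNA(data$value)) stop("missing values in the response")
  counts <- table(data$exp_rate, data$min_ll, data$max_ll)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unbalanced design: every scenario needs the same replicate count")
  }
  d <- data.frame(
    A = factor(data$max_ll), B = factor(data$min_ll),
    C = factor(data$exp_rate), value = data$value
  )
  single <- vapply(d[c("A", "B", "C")], nlevels, 1L) == 1L
  form <- stats::as.formula(paste(
    "value ~",
    paste0("(", paste(c("A", "B", "C")[!single], collapse = " + "), ")^2")
  ))
  fit <- stats::aov(form, data = d)
  an <- as.data.frame(stats::anova(fit))
  ss_total <- sum(an[["Sum Sq"]])
  term_map <- c(A = "max_ll", B = "min_ll", C = "exp_rate",
                `A:B` = "max_ll:min_ll", `A:C` = "max_ll:exp_rate",
                `B:C` = "min_ll:exp_rate", Residuals = "residual")
  rn <- trimws(rownames(an))
  # direction of each main effect: linear contrast of ordered level means
  dir_of <- function(fct) {
    lev <- sort(unique(as.numeric(as.character(d[[fct]]))))
    if (length(lev) < 2) return(0)
    gm <- tapply(d$value, as.numeric(as.character(d[[fct]])), mean)
    w <- lev - mean(lev)
    sign(sum(w * gm[as.character(lev)]))
  }
  out <- data.frame(
    term = unname(term_map[rn]),
    direction = vapply(rn, function(t) {
      if (t %in% c("A", "B", "C")) dir_of(t) else NA_real_
    }, 1.0),
    F = an[["F value"]],
    p = an[["Pr(>F)"]],
    pct_variance = an[["Sum Sq"]] / ss_total * 100,
    row.names = NULL
  )
  class(out) <- c("ecotrout_anova", "data.frame")
  out
}

#' Spawning potential ratio
#'
#' SSBR (spawning stock biomass per recruit) is the window-mean spawner
#' biomass divided by the window-mean recruitment (age-0 density at the
#' census), computed for a fished and an unfished run; the SPR is their ratio.
#' Values below the 0.35 reference indicate the potential for recruitment
#' overfishing.
#'
#' @param fished,unfished annual-record data.frames (from `ecotrout_sim`
#'   objects or grid rows) with columns `spawner_biomass` and `den_age0`.
#' @param window analysis window (default [analysis_window()]).
#' @return list with `spr`, `ssbr_fished`, `ssbr_unfished`, the 0.35
#'   `reference`, and `undefined` (TRUE when a window has no recruits).
#' @export
spawning_potential_ratio <- function(fished, unfished, window = NULL) {
  rec <- function(x) if (inherits(x, "ecotrout_sim")) x$records else x
  f <- rec(fished); u <- rec(unfished)
  if (is.null(window)) window <- analysis_window(nrow(f))
  ssbr <- function(r) {
    w <- r[seq(nrow(r) - window + 1, nrow(r)), ]
    recruits <- mean(w$den_age0, na.rm = TRUE)
    if (is.na(recruits) || recruits == 0) return(NA_real_)
    mean(w$spawner_biomass, na.rm = TRUE) / recruits
  }
  sf <- ssbr(f); su <- ssbr(u)
  undefined <- is.na(sf) || is.na(su) || su == 0
  list(spr = if (undefined) NA_real_ else sf / su,
       ssbr_fished = sf, ssbr_unfished = su,
       reference = 0.35, undefined = undefined)
}
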