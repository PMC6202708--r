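#' Quantitative-genetic state and inheritance
#'
#' The model tracks four heritable traits per individual under the
#' infinitesimal model: genotypic size at emergence (cm), the sex-specific
#' genotypic maturity length thresholds (cm; every individual carries both the
#' male and the female threshold and expresses only its own sex's), and a
#' neutral trait used to separate drift from selection. Offspring genotypic
#' values are drawn from a normal distribution centred on the midparent value
#' with variance `VA/2 + Vmut`, held constant across generations; phenotypes
#' add an independent environmental deviation with variance `VE`.
#'
#' @name genetics
NULL

trait_names <- c("g_emergence", "g_mat_male", "g_mat_female", "g_neutral")

genetics_blocks <- function(params) {
  g <- if (!is.null(params$genetics)) params$genetics else params
  list(g$emergence, g$mat_male, g$mat_female, g$neutral)
}

#' Draw a genotype for a new individual from its parents
#'
#' Each trait is drawn independently as
#' `Normal(midparent, sqrt(VA/2 + Vmut))`. Draws below the configured floor
#' (`floor_frac` times the initial trait mean, for traits with positive means)
#' are truncated up to the floor so lengths stay positive.
#'
#' @param mother,father named numeric vectors (or single-row data.frames) with
#'   elements `g_emergence`, `g_mat_male`, `g_mat_female`, `g_neutral`. Both
#'   may contain several rows/individuals; they are recycled pairwise.
#' @param params parameter list from [default_params()].
#' @param n number of offspring per mother/father pair.
#' @return a data.frame with one row per offspring and the four genotype
#'   columns.
#' @examples
#' p <- default_params()
#' mo <- fa <- c(g_emergence = 2.8, g_mat_male = 15, g_mat_female = 17,
#'               g_neutral = 0)
#' inherit_genotype(mo, fa, p, n = 3)
#' @export
inherit_genotype <- function(mother, father, params = default_params(), n = 1) {
  mo <- as_genotype_df(mother)
  fa <- as_genotype_df(father)
  k <- max(nrow(mo), nrow(fa))
  mo <- mo[rep_len(seq_len(nrow(mo)), k), , drop = FALSE]
  fa <- fa[rep_len(seq_len(nrow(fa)), k), , drop = FALSE]
  blocks <- genetics_blocks(params)
  floor_frac <- params$genetics$floor_frac
  out <- vector("list", 4)
  for (i in seq_along(trait_names)) {
    tr <- trait_names[i]
    b <- blocks[[i]]
    mid <- rep((mo[[tr]] + fa[[tr]]) / 2, each = n)
    sdv <- sqrt(b$va / 2 + b$vmut)
    val <- stats::rnorm(length(mid), mid, sdv)
    if (b$mean > 0) val <- pmax(val, floor_frac * b$mean)
    out[[i]] <- val
  }
  names(out) <- trait_names
  as.data.frame(out)
}

as_genotype_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(trait_names %in% names(x)))
    return(x[trait_names])
  }
  stopifnot(all(trait_names %in% names(x)))
  as.data.frame(as.list(x[trait_names]))
}

#' Express phenotypes from a genotype
#'
#' The phenotypic size at emergence is the genotypic value plus a
#' `Normal(0, VE)` environmental deviation; the expressed maturity threshold
#' is the own-sex genotypic threshold plus its environmental deviation. Both
#' are fixed at creation of the individual and floored at `floor_frac` times
#' the initial trait mean.
#'
#' @param genotype data.frame (or named vector) of genotypic values.
#' @param sex character vector, "F" or "M", recycled against the genotypes.
#' @param params parameter list from [default_params()].
#' @return data.frame with columns `p_emergence` and `p_mat_threshold`.
#' @export
express_phenotype <- function(genotype, sex, params = default_params()) {
  g <- as_genotype_df(genotype)
  sex <- rep_len(as.character(sex), nrow(g))
  stopifnot(all(sex %in% c("F", "M")))
  gb <- params$genetics
  floor_frac <- gb$floor_frac
  p_em <- stats::rnorm(nrow(g), g$g_emergence, sqrt(gb$emergence$ve))
  p_em <- pmax(p_em, floor_frac * gb$emergence$mean)
  own <- ifelse(sex == "F", g$g_mat_female, g$g_mat_male)
  ve_mat <- ifelse(sex == "F", gb$mat_female$ve, gb$mat_male$ve)
  mean_mat <- ifelse(sex == "F", gb$mat_female$mean, gb$mat_male$mean)
  p_mat <- stats::rnorm(nrow(g), own, sqrt(ve_mat))
  p_mat <- pmax(p_mat, floor_frac * mean_mat)
  data.frame(p_emergence = p_em, p_mat_threshold = p_mat)
}

#' Draw founder genotypes from the initial trait distributions
#'
#' Founders (and, in the no-evolution control, all offspring) receive each
#' genotypic value from `Normal(initial mean, VA)` independently per trait.
#'
#' @param n number of individuals.
#' @param params parameter list from [default_params()].
#' @return data.frame of genotypes.
#' @export
founder_genotypes <- function(n, params = default_params()) {
  blocks <- genetics_blocks(params)
  floor_frac <- params$genetics$floor_frac
  out <- vector("list", 4)
  for (i in seq_along(trait_names)) {
    b <- blocks[[i]]
    val <- stats::rnorm(n, b$mean, sqrt(b$va))
    if (b$mean > 0) val <- pmax(val, floor_frac * b$mean)
    out[[i]] <- val
  }
  names(out) <- trait_names
  as.data.frame(out)
}
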