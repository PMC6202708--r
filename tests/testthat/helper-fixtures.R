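# Small fixtures built in code for the unit tests.

# a parameter set with a tiny reach and short run, for fast whole-run tests
tiny_params <- function(...) {
  default_params(
    reach = list(n_cells = 6L, length_km = 0.25),
    experiment = list(years = 2L, burn_in = 2L),
    ...
  )
}

# a small population data.frame in the shape the operation wrappers expect
make_fish <- function(length, weight = NULL, sex = "F", age = 2L,
                      p_mat = 17, k = 1, id = seq_along(length)) {
  p <- default_params()
  if (is.null(weight)) weight <- p$bioenergetics$lw_a *
      length^p$bioenergetics$lw_b
  data.frame(id = id, sex = rep_len(sex, base::length(length)),
             age = rep_len(age, base::length(length)),
             length = length, weight = weight,
             p_mat_threshold = rep_len(p_mat, base::length(length)),
             k = rep_len(k, base::length(length)))
}

# cells data.frame with fully specified state (depth/velocity/cover/food)
make_cells <- function(depth, velocity, cover = 0, food = 100) {
  n <- max(lengths(list(depth, velocity, cover, food)))
  data.frame(cell = seq_len(n), depth = rep_len(depth, n),
             velocity = rep_len(velocity, n), cover = rep_len(cover, n),
             food = rep_len(food, n))
}

# parameters in which every natural survival curve is flat at the given
# per-source probabilities (two equal anchors give a constant logistic), so
# expected death counts are exact
flat_survival_params <- function(p_each = rep(0.999, 6), ...) {
  flat <- function(p) c(0, p, 1, p)
  default_params(
    survival = list(
      temperature = flat(p_each[1]), velocity = flat(p_each[2]),
      stranding = flat(p_each[3]), starvation = flat(p_each[4]),
      terrestrial = flat(p_each[5]), terr_depth_b = 0, terr_cover_b = 0,
      piscivory = flat(p_each[6])
    ),
    ...
  )
}

# genotype row helper
geno <- function(em = 2.8, mm = 15, mf = 17, nt = 0) {
  c(g_emergence = em, g_mat_male = mm, g_mat_female = mf, g_neutral = nt)
}
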