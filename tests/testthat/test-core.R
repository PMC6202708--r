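test_that("two-point logistic passes exactly through its anchors", {
  anchors <- c(24, 0.999, 28, 0.8)
  expect_equal(two_point_logistic(c(24, 28), anchors), c(0.999, 0.8))
  # monotone decreasing between and beyond the anchors here
  x <- seq(20, 32, by = 0.5)
  expect_true(all(diff(two_point_logistic(x, anchors)) < 0))
})

test_that("every configured survival curve returns its anchors exactly", {
  p <- default_params()
  for (nm in c("temperature", "velocity", "stranding", "starvation",
               "terrestrial", "piscivory")) {
    a <- p$survival[[nm]]
    expect_equal(two_point_logistic(a[c(1, 3)], a), a[c(2, 4)],
                 tolerance = 1e-12)
  }
  a <- p$reproduction$egg_temp_hi
  expect_equal(two_point_logistic(a[c(1, 3)], a), a[c(2, 4)],
               tolerance = 1e-12)
})

test_that("dominance ranks by length, then weight, then id", {
  pop <- make_fish(length = c(20, 15, 25))
  expect_equal(rank_by_dominance(pop)$length, c(25, 20, 15))

  tie <- make_fish(length = c(20, 20), weight = c(80, 90))
  expect_equal(rank_by_dominance(tie)$weight, c(90, 80))

  tie2 <- make_fish(length = c(20, 20), weight = c(80, 80), id = c(7, 3))
  expect_equal(rank_by_dominance(tie2)$id, c(3, 7))

  expect_equal(nrow(rank_by_dominance(pop[0, ])), 0L)
})

test_that("fitness is 1 for a risk-free cell and a mature fish", {
  p <- flat_survival_params(rep(1 - 1e-12, 6))
  f <- fitness_measure(length = 20, weight = 60, k = 1, p_mat_threshold = 17,
                       depth = 0.5, velocity = 0.2, cover = 0.3, food = 100,
                       temperature = 10, params = p)
  expect_equal(f$fitness, 1, tolerance = 1e-6)
  expect_equal(f$size_factor, 1)
})

test_that("fitness matches the closed form survival^horizon x size factor", {
  # constant per-source survival 0.999^(1/6) makes daily survival 0.999
  p <- flat_survival_params(rep(0.999^(1 / 6), 6))
  f <- fitness_measure(length = 20, weight = 60, k = 1, p_mat_threshold = 17,
                       depth = 0.5, velocity = 0.2, cover = 0, food = 100,
                       temperature = 10, max_length = 50, pisc_density = 1e6,
                       params = p, horizon = 90)
  expect_equal(f$survival_daily, 0.999, tolerance = 1e-9)
  expect_equal(f$fitness, 0.999^90, tolerance = 1e-6)
  expect_equal(0.999^90, 0.9139, tolerance = 1e-4)
})

test_that("at equal risk, higher growth scores higher for an immature fish", {
  p <- flat_survival_params(rep(0.999, 6))
  lo <- fitness_measure(5, 1.2, 1, 17, 0.5, 0.2, 0, food = 0.01,
                        temperature = 10, params = p)
  hi <- fitness_measure(5, 1.2, 1, 17, 0.5, 0.2, 0, food = 10,
                        temperature = 10, params = p)
  expect_gt(hi$fitness, lo$fitness)
  expect_gt(hi$projected_length, lo$projected_length)
})

test_that("habitat selection prefers richer cells and depletes food", {
  p <- flat_survival_params(rep(0.9999, 6))
  cells <- make_cells(depth = 0.5, velocity = 0.2, food = c(0.05, 10))
  one <- make_fish(10)
  sel <- select_habitat(one, cells, temperature = 10, params = p)
  expect_equal(sel$cell, 2L)

  # identical cells: tie goes to the lowest cell id
  cells_eq <- make_cells(depth = 0.5, velocity = 0.2, food = c(10, 10))
  expect_equal(select_habitat(one, cells_eq, 10, p)$cell, 1L)

  # two equal fish, food for one: the second gets lower realized intake
  two <- make_fish(c(10, 10), id = c(1, 2))
  b <- p$bioenergetics
  cmax <- b$cmax_a * two$weight[1]^b$cmax_b *
    exp(-((10 - b$cmax_t_opt) / b$cmax_t_sig)^2)
  cells1 <- make_cells(depth = 0.5, velocity = 0.2, food = cmax * 1.2)
  sel2 <- select_habitat(two, cells1, 10, p)
  expect_equal(sel2$intake[1], cmax)
  expect_lt(sel2$intake[2], 0.5 * cmax)
  # dominance privilege: the more dominant fish never gets less
  expect_gte(sel2$intake[1], sel2$intake[2])
})

test_that("growth follows the bioenergetic closed form and the length rules", {
  p <- default_params()
  b <- p$bioenergetics
  # independent recomputation of the weight change at stated conditions
  W <- 100; Temp <- 10; v <- 0.2
  cmax <- b$cmax_a * W^b$cmax_b * exp(-((Temp - b$cmax_t_opt) / b$cmax_t_sig)^2)
  resp <- b$resp_a * W^b$resp_b * exp(b$resp_c * Temp) * (1 + b$resp_d * v)
  dw_expect <- (cmax * b$e_food - resp) / b$e_fish
  g <- grow(length = 21.5, weight = W, intake = cmax, temperature = Temp,
            velocity = v, params = p)
  expect_equal(g$dw, dw_expect, tolerance = 1e-10)

  # zero intake: weight strictly decreases by the respiration equivalent
  L0 <- 20; W0 <- b$lw_a * L0^b$lw_b
  g0 <- grow(L0, W0, intake = 0, temperature = 10, velocity = 0.2, params = p)
  expect_lt(g0$weight, W0)
  expect_equal(g0$length, L0)  # length never shrinks

  # below healthy weight, gains restore condition but not length
  W_low <- 0.9 * W0
  g1 <- grow(L0, W_low, intake = 0.8, temperature = 10, velocity = 0.1,
             params = p)
  expect_gt(g1$weight, W_low)
  expect_equal(g1$length, L0)
  expect_lt(g1$k, 1)

  # at or above healthy weight, surplus becomes length at condition 1
  g2 <- grow(L0, W0, intake = 2, temperature = 10, velocity = 0.1, params = p)
  expect_gt(g2$length, L0)
  expect_equal(g2$k, 1, tolerance = 1e-10)
})

test_that("natural survival has the configured expectation and benign regime", {
  p <- flat_survival_params(rep(0.995^(1 / 6), 6))
  n <- 10000
  pop <- make_fish(rep(20, n), p_mat = 17)
  set.seed(11)
  out <- survive_natural(pop, depth = 0.5, velocity = 0.2, cover = 0.3,
                         temperature = 10, params = p)
  deaths <- sum(out > 0)
  expect_lt(abs(deaths - n * 0.005), 3 * sqrt(n * 0.005 * 0.995))
  expect_true(all(out %in% 0:6))

  # benign conditions under the default curves: daily survival over 0.99
  pd <- default_params()
  f <- fitness_measure(25, 160, 1, 17, depth = 0.8, velocity = 0.1,
                       cover = 0.5, food = 100, temperature = 12,
                       max_length = 25, pisc_density = 0, params = pd)
  expect_gt(f$survival_daily, 0.99)
})

test_that("cause attribution follows the fixed evaluation order", {
  # all mortality concentrated in one source at a time
  for (k in 1:6) {
    ps <- rep(1 - 1e-12, 6); ps[k] <- 1e-12
    p <- flat_survival_params(ps)
    pop <- make_fish(c(10, 20))
    set.seed(2)
    out <- survive_natural(pop, 0.5, 0.2, 0, 10, max_length = 100,
                           pisc_density = 1e6, params = p)
    expect_true(all(out == k))
  }
  expect_equal(mortality_causes()[7:9],
               c("harvest", "illegalHarvest", "hooking"))
})
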