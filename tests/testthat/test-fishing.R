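test_that("legality is the closed interval [MinLL, MaxLL]", {
  expect_true(legal_length(19.0, harvest_regulation(0.3, 19, 100)))
  expect_false(legal_length(16.9, harvest_regulation(0.3, 17, 100)))
  expect_false(legal_length(26, harvest_regulation(0.3, 17, 25)))
  expect_true(legal_length(25, harvest_regulation(0.3, 17, 25)))
  # MaxLL = 100 behaves as a plain minimum-length limit
  expect_true(all(legal_length(c(19, 40, 99, 100),
                               harvest_regulation(0.3, 19, 100))))
})

test_that("fishing pressure is the exact exploitation-rate conversion", {
  expect_identical(compute_angle_pressure(0.35, 200, 5, 1, 214), 350 / 214)
  expect_identical(compute_angle_pressure(0, 200, 5, 1, 214), 0)
  # linear in each argument
  base <- compute_angle_pressure(0.35, 200, 5, 1, 214)
  expect_equal(compute_angle_pressure(0.7, 200, 5, 1, 214), 2 * base)
  expect_equal(compute_angle_pressure(0.35, 400, 5, 1, 214), 2 * base)
  expect_equal(compute_angle_pressure(0.35, 200, 10, 1, 214), 2 * base)
  expect_equal(compute_angle_pressure(0.35, 200, 5, 2, 214), base / 2)
  expect_error(compute_angle_pressure(0.35, 200, 5, 0, 214), "positive")
})

test_that("capture rate is length-selective, saturating and pressure-linear", {
  p <- default_params()
  expect_equal(capture_rate(c(5, 25), 0, p), c(0, 0))
  expect_lt(capture_rate(5, 2, p), capture_rate(25, 2, p))
  expect_equal(capture_rate(20, 4, p), 2 * capture_rate(20, 2, p))
  # anchors: q passes 0.1 and 0.9 of the plateau at the anchor lengths
  f <- p$fishing
  expect_equal(capture_rate(f$q_anchor_lengths, 1, p),
               f$q_max * f$q_anchor_fracs, tolerance = 1e-12)
  # near plateau by 25 cm and monotone nondecreasing in length
  expect_gt(capture_rate(25, 1, p) / (f$q_max * 1), 0.89)
  x <- capture_rate(seq(3, 45, by = 1), 1, p)
  expect_true(all(diff(x) >= 0))
})

test_that("harvestable stock counts legal and projected-to-legal trout", {
  reg <- harvest_regulation(0.35, 19, 100)
  pop <- make_fish(c(15, 18, 22, 30))
  expect_equal(estimate_harvestable_stock(pop, reg, 214, gain = 2), 3)
  expect_equal(estimate_harvestable_stock(pop, reg, 214, gain = 0), 2)
  expect_equal(estimate_harvestable_stock(pop,
                                          harvest_regulation(0.35, 60, 100),
                                          214, gain = 2), 0)
  expect_equal(estimate_harvestable_stock(pop[0, ], reg, 214), 0L)
  # bioenergetic projection: dw = 0 means only currently legal fish count
  expect_equal(estimate_harvestable_stock(pop, reg, 214, dw = 0), 2)
  # a large positive growth rate recruits the 18 cm fish but not the 15 cm one
  p <- default_params()
  b <- p$bioenergetics
  dw <- (b$lw_a * 19.2^b$lw_b - b$lw_a * 18^b$lw_b) / 214
  expect_equal(estimate_harvestable_stock(pop, reg, 214, dw = dw, params = p),
               3)
})

test_that("angling outcomes recover the configured rates", {
  p <- default_params(fishing = list(exp_rate = 0.5, min_ll = 19,
                                     max_ll = 100))
  # a pressure x catchability giving about 1 capture per fish per day
  n <- 30000
  pop <- make_fish(rep(25, n))
  pressure <- 1 / capture_rate(25, 1, p)
  set.seed(21)
  res <- angling_daily(pop, pressure, p)
  expect_gt(res$captures, 10000)
  # ledger conservation is exact
  expect_identical(res$captures,
                   res$keeps + res$illegal_keeps + res$releases)
  expect_identical(res$legal_captures + res$illegal_captures, res$captures)
  expect_lte(res$hooking_deaths, res$releases)
  # all captures are legal-size here; voluntary release fraction ~ 60%
  expect_equal(res$illegal_captures, 0)
  se_rel <- sqrt(0.6 * 0.4 / res$captures)
  expect_lt(abs(res$releases / res$captures - 0.6), 3 * se_rel)
  # hooking deaths ~ 20% of releases
  se_hook <- sqrt(0.2 * 0.8 / res$releases)
  expect_lt(abs(res$hooking_deaths / res$releases - 0.2), 3 * se_hook)
  # outcome codes are consistent with the ledger
  expect_equal(sum(res$outcome == 7), res$keeps)
  expect_equal(sum(res$outcome == 9), res$hooking_deaths)
})

test_that("non-legal captures are kept only by noncompliance", {
  p <- default_params(fishing = list(min_ll = 19, max_ll = 100))
  n <- 20000
  pop <- make_fish(rep(16, n))  # all below MinLL
  pressure <- 1 / capture_rate(16, 1, p)
  set.seed(22)
  res <- angling_daily(pop, pressure, p)
  expect_equal(res$legal_captures, 0)
  expect_gt(res$illegal_captures, 5000)
  frac <- res$illegal_keeps / res$illegal_captures
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / res$illegal_captures))
  # slot-protected large fish are treated as non-legal too
  ps <- default_params(fishing = list(min_ll = 17, max_ll = 25))
  big <- make_fish(rep(30, 5000))
  set.seed(23)
  res_big <- angling_daily(big, 1 / capture_rate(30, 1, ps), ps)
  expect_equal(res_big$legal_captures, 0)
  expect_gt(res_big$illegal_captures, 0)
})

test_that("zero pressure angles nothing and consumes no randomness", {
  p <- default_params()
  pop <- make_fish(rep(25, 100))
  set.seed(31); before <- .Random.seed
  res <- angling_daily(pop, 0, p)
  expect_identical(.Random.seed, before)
  expect_equal(res$captures, 0)
  expect_true(all(res$outcome == 0))
})
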