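test_that("spawning readiness requires every gate", {
  p <- default_params(reproduction = list(p_spawn_daily = 1))
  fem <- list(length = 20, p_mat_threshold = 17, k = 1, spawned = FALSE)
  ok <- function(f = fem, doy = 320, temp = 6, flow = 1) {
    spawn_check(f, doy, temp, flow, p)
  }
  expect_true(ok())
  expect_false(ok(modifyList(fem, list(length = 16))))       # below threshold
  expect_false(ok(modifyList(fem, list(spawned = TRUE))))    # once per season
  expect_false(ok(modifyList(fem, list(k = 0.8))))           # poor condition
  expect_false(ok(doy = 100))                                # out of season
  expect_false(ok(temp = 15))                                # too warm
  expect_false(ok(flow = 10))                                # spate
  # with p_spawn < 1 the readiness is a daily Bernoulli
  p2 <- default_params(reproduction = list(p_spawn_daily = 0))
  expect_false(spawn_check(fem, 320, 6, 1, p2))
})

test_that("fecundity follows the exponential law and the egg-size trade-off", {
  p <- default_params()
  expect_equal(fecundity(25, params = p), round(0.07 * 25^2.4))
  # larger females never produce fewer eggs at equal genotype
  expect_true(all(diff(fecundity(seq(15, 35, 1), params = p)) >= 0))
  # doubling genotypic egg size cuts the count eightfold before rounding
  g_ref <- p$genetics$emergence$mean
  expect_equal(fecundity(25, g_emergence = 2 * g_ref, params = p),
               round(0.07 * 25^2.4 / 8))
  expect_error(fecundity(-5), "positive")
})

test_that("mate selection always includes the largest male", {
  males <- make_fish(c(22, 18, 16, 15, 14), sex = "M")
  one <- males[3, ]
  expect_equal(select_mates(one, default_params())$id, one$id)

  p0 <- default_params(reproduction = list(lambda_mates = 0))
  expect_equal(select_mates(males, p0)$length, 22)

  set.seed(41)
  for (i in 1:20) {
    sel <- select_mates(males, default_params())
    expect_equal(sel$length[1], 22)
    expect_equal(anyDuplicated(sel$id), 0L)
  }
  expect_equal(nrow(select_mates(males[0, ], default_params())), 0L)
})

test_that("extra mate count matches the capped-Poisson expectation", {
  males <- make_fish(c(22, 18, 16, 15, 14, 13), sex = "M")  # 5 smaller males
  lam <- 1.5
  p <- default_params(reproduction = list(lambda_mates = lam))
  set.seed(42)
  n <- 10000
  extras <- replicate(n, nrow(select_mates(males, p)) - 1L)
  # E[min(Poisson(1.5), 5)] by direct enumeration
  k <- 0:50
  expected <- sum(pmin(k, 5) * dpois(k, lam))
  se <- sd(extras) / sqrt(n)
  expect_lt(abs(mean(extras) - expected), 3 * se)
})

test_that("redd development is degree-day driven with exact egg accounting", {
  p <- default_params(reproduction = list(egg_background = 1))
  # benign: cold-side and warm-side survival ~1 at 6 C, depth > 0, low flow
  set.seed(43)
  r <- redd_daily(100, 0, temperature = 6, depth = 0.4, flow = 1, params = p)
  expect_equal(r$eggs, 100)
  expect_equal(r$dd, 6)
  expect_equal(r$hatch, 0)

  # constant 6 C: development completes on day ceil(430/6) = 72
  eggs <- 500; dd <- 0; day <- 0
  repeat {
    day <- day + 1
    r <- redd_daily(eggs, dd, 6, 0.4, 1, p)
    eggs <- r$eggs; dd <- r$dd
    if (r$hatch > 0) break
  }
  expect_equal(day, ceiling(430 / 6))

  # dewatering: expected survivors 90 of 100 at 0.9/day
  p2 <- default_params(reproduction = list(egg_background = 1,
                                           egg_dewater = 0.9))
  set.seed(44)
  deaths <- replicate(300, redd_daily(100, 0, 6, 0, 1, p2)$deaths)
  expect_lt(abs(mean(deaths) - 10), 3 * sqrt(100 * 0.1 * 0.9 / 300))

  # egg conservation: deaths + hatches account for every egg
  set.seed(45)
  eggs <- 200; dd <- 0; total_d <- 0; total_h <- 0
  p3 <- default_params()
  while (eggs > 0) {
    r <- redd_daily(eggs, dd, 8, 0.4, 1, p3)
    total_d <- total_d + r$deaths; total_h <- total_h + r$hatch
    eggs <- r$eggs; dd <- r$dd
  }
  expect_equal(total_d + total_h, 200)
})

test_that("emergence transmits genetics from the mother and a drawn father", {
  p0 <- default_params(genetics = list(
    emergence = list(mean = 2.8, va = 0, ve = 0, vmut = 0),
    mat_male = list(mean = 15, va = 0, ve = 0, vmut = 0),
    mat_female = list(mean = 17, va = 0, ve = 0, vmut = 0),
    neutral = list(mean = 0, va = 0, ve = 0, vmut = 0)
  ))
  mo <- geno(em = 3.0, nt = 2)
  fa <- as.data.frame(as.list(geno(em = 3.0, nt = 4)))
  set.seed(46)
  kids <- emerge(50, mo, fa, p0)
  # zero variance: length is exactly the midparent emergence genotype
  expect_true(all(kids$length == 3.0))
  expect_true(all(kids$g_neutral == 3.0))
  expect_true(all(kids$father == 1L))
  b <- p0$bioenergetics
  expect_equal(kids$weight, rep(b$lw_a * 3.0^b$lw_b, 50))

  # two fathers drawn uniformly
  fa2 <- rbind(fa, as.data.frame(as.list(geno(nt = 8))))
  set.seed(47)
  kids2 <- emerge(10000, mo, fa2, p0)
  frac <- mean(kids2$father == 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # sexes are Bernoulli(0.5)
  expect_lt(abs(mean(kids2$sex == "F") - 0.5), 3 * sqrt(0.25 / 10000))
})
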