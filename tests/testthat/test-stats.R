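# independent brute-force oracle for the Mann-Kendall statistic: literal pair
# enumeration for S and run-length tie counting for the variance
mk_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) s <- s + sign(x[j] - x[i])
  }
  runs <- rle(sort(x))$lengths
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(runs * (runs - 1) * (2 * runs + 5))) / 18
  list(S = s, var_S = v)
}

test_that("Mann-Kendall handles the worked examples", {
  expect_equal(mann_kendall(c(1, 2, 3, 4))$S, 6L)
  expect_equal(mann_kendall(c(3, 1, 2))$S, -1L)
  const <- mann_kendall(c(2, 2, 2, 2))
  expect_equal(const$S, 0L)
  expect_equal(const$p, 1)
  expect_equal(const$direction, 0)
  expect_error(mann_kendall(c(1, 2)), "at least 3")
})

test_that("Mann-Kendall matches brute force on every short {1,2,3} series", {
  for (n in 3:8) {
    grid <- as.matrix(expand.grid(rep(list(1:3), n)))
    # exhaustive for n <= 5; a fixed systematic subsample above keeps the
    # check broad without redundant work
    idx <- if (nrow(grid) <= 243) seq_len(nrow(grid)) else {
      seq(1, nrow(grid), by = ceiling(nrow(grid) / 600))
    }
    for (r in idx) {
      x <- grid[r, ]
      got <- mann_kendall(x)
      want <- mk_oracle(x)
      expect_identical(got$S, as.integer(want$S))
      expect_equal(got$var_S, want$var_S)
    }
  }
})

test_that("Mann-Kendall direction agrees with Kendall correlation", {
  set.seed(51)
  for (i in 1:25) {
    x <- rnorm(12) + 0.2 * seq_len(12) * sample(c(-1, 1), 1)
    tau <- cor(seq_along(x), x, method = "kendall")
    expect_equal(sign(mann_kendall(x)$S), sign(tau))
  }
})

test_that("endpoint comparison computes percent change and Welch t", {
  id <- endpoint_comparison(c(10, 10, 10), c(10, 10, 10))
  expect_equal(id$t, 0)
  expect_equal(id$percent_change, 0)
  expect_false(id$significant)

  pc <- endpoint_comparison(c(12, 12), c(10, 10))
  expect_equal(pc$percent_change, 20)

  set.seed(52)
  strong <- endpoint_comparison(rnorm(6, 5), rnorm(6, 0))
  expect_true(strong$significant)

  # symmetry: swapping arms negates t and mirrors the percent change
  a <- c(11, 12, 13); b <- c(9, 10, 11)
  f <- endpoint_comparison(a, b); r <- endpoint_comparison(b, a)
  expect_equal(f$t, -r$t)
  expect_equal(f$p, r$p)

  z <- endpoint_comparison(c(1, 2), c(0, 0))
  expect_true(z$undefined)
  expect_true(is.na(z$percent_change))

  # matrix input: per-replicate window means over the final years
  m_s <- matrix(rep(c(1, 2), each = 10), nrow = 10)  # 2 replicates
  m_b <- matrix(rep(c(1, 1), each = 10), nrow = 10)
  mm <- endpoint_comparison(m_s, m_b, window = 5)
  expect_equal(mm$mean_scenario, 1.5)
})

test_that("factorial ANOVA attributes all variance to the only active factor", {
  d <- expand.grid(exp_rate = c(0.05, 0.35, 0.65), min_ll = c(17, 19, 21),
                   max_ll = c(25, 100), replicate = 1:2)
  d$value <- 10 * d$exp_rate
  # a noise-free response makes the F tests degenerate, which is expected here
  an <- suppressWarnings(factorial_anova(d))
  expect_equal(an$pct_variance[an$term == "exp_rate"], 100, tolerance = 1e-9)
  expect_equal(sum(an$pct_variance), 100, tolerance = 1e-9)
  expect_equal(an$direction[an$term == "exp_rate"], 1)
  other <- setdiff(an$term, c("exp_rate", "residual"))
  expect_true(all(an$pct_variance[an$term %in% other] < 1e-9))
})

test_that("pure-noise variance shares approach degrees-of-freedom shares", {
  set.seed(53)
  d <- expand.grid(exp_rate = c(0.05, 0.35, 0.65), min_ll = c(17, 19, 21),
                   max_ll = c(25, 27, 100), replicate = 1:40)
  d$value <- rnorm(nrow(d))
  an <- factorial_anova(d)
  n <- nrow(d)
  # E[SS_term]/E[SS_total] = df_term/(n-1) under the null
  for (tm in c("exp_rate", "min_ll", "max_ll")) {
    expect_lt(abs(an$pct_variance[an$term == tm] - 100 * 2 / (n - 1)), 1.5)
  }
  expect_lt(abs(an$pct_variance[an$term == "min_ll:exp_rate"] -
                  100 * 4 / (n - 1)), 2)
})

test_that("ANOVA shares match an independent balanced-design oracle", {
  set.seed(54)
  d <- expand.grid(exp_rate = c(0.05, 0.35, 0.65), min_ll = c(17, 21),
                   max_ll = c(25, 100), replicate = 1:4)
  d$value <- 3 * d$exp_rate - 0.1 * d$min_ll + rnorm(nrow(d), 0, 0.2)
  an <- factorial_anova(d)

  # oracle: classic balanced-design group-mean sums of squares
  gm <- mean(d$value)
  ss <- function(f) {
    m <- tapply(d$value, d[[f]], mean)
    cnt <- table(d[[f]])
    sum(cnt * (m - gm)^2)
  }
  ss2 <- function(f1, f2) {
    m12 <- tapply(d$value, list(d[[f1]], d[[f2]]), mean)
    m1 <- tapply(d$value, d[[f1]], mean)
    m2 <- tapply(d$value, d[[f2]], mean)
    cnt <- table(d[[f1]], d[[f2]])
    dev <- sweep(sweep(m12, 1, m1), 2, m2) + gm
    sum(cnt * dev^2)
  }
  ss_tot <- sum((d$value - gm)^2)
  expect_equal(an$pct_variance[an$term == "exp_rate"],
               100 * ss("exp_rate") / ss_tot, tolerance = 1e-8)
  expect_equal(an$pct_variance[an$term == "min_ll"],
               100 * ss("min_ll") / ss_tot, tolerance = 1e-8)
  expect_equal(an$pct_variance[an$term == "min_ll:exp_rate"],
               100 * ss2("min_ll", "exp_rate") / ss_tot, tolerance = 1e-8)
  expect_equal(an$direction[an$term == "exp_rate"], 1)
  expect_equal(an$direction[an$term == "min_ll"], -1)
  expect_equal(sum(an$pct_variance), 100, tolerance = 1e-8)
})

test_that("unbalanced designs are rejected", {
  d <- expand.grid(exp_rate = c(0.05, 0.35), min_ll = c(17, 21),
                   max_ll = c(25, 100), replicate = 1:2)
  d$value <- rnorm(nrow(d))
  expect_error(factorial_anova(d[-1, ]), "unbalanced")
})

test_that("spawning potential ratio is the SSBR ratio", {
  rec <- function(sb, a0) data.frame(spawner_biomass = sb, den_age0 = a0)
  same <- rec(rep(10, 10), rep(100, 10))
  expect_equal(spawning_potential_ratio(same, same, window = 5)$spr, 1)

  halved <- rec(rep(5, 10), rep(100, 10))
  expect_equal(spawning_potential_ratio(halved, same, window = 5)$spr, 0.5)

  # hand arithmetic on constant windows
  f <- rec(rep(6, 10), rep(50, 10)); u <- rec(rep(9, 10), rep(30, 10))
  expect_equal(spawning_potential_ratio(f, u, window = 4)$spr,
               (6 / 50) / (9 / 30))
  z <- spawning_potential_ratio(rec(rep(1, 5), rep(0, 5)), same, window = 3)
  expect_true(z$undefined)
})

test_that("the analysis window scales with run length", {
  expect_equal(analysis_window(100), 15L)
  expect_equal(analysis_window(120), 15L)
  expect_equal(analysis_window(40), 6L)
  expect_equal(analysis_window(10), 3L)
})
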