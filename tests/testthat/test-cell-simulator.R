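# Single-cell life histories: waiting times, cycle structure, division,
# lineage stationarity.

cfg <- model_config()

test_that("stochastic delays follow the exponential inversion formula", {
  expect_equal(sample_stochastic_delay(0, 10), rep(0, 10))
  expect_equal(stochastic_delay_from_uniform(2, exp(-1)), 2)
  expect_equal(stochastic_delay_from_uniform(2, 1), 0)
  expect_error(stochastic_delay_from_uniform(2, 0), "r must")
  expect_error(sample_stochastic_delay(-1), "lambda")

  set.seed(11)
  x <- sample_stochastic_delay(2, 2e4)
  expect_true(all(x >= 0))
  # mean within 3 standard errors of 2 h
  expect_lt(abs(mean(x) - 2), 3 * 2 / sqrt(2e4))
})

test_that("residence times decompose into timer/threshold plus noise", {
  d <- hc_det_config()
  conc <- c(cyca = 1, cycb = 1, cyce = 1)

  # timer states with lambda = 0: exactly their deterministic component
  r1 <- residence_time(1, conc, 3, d)
  expect_equal(r1$total, 0)
  r4 <- residence_time(4, conc, 3, d)
  expect_equal(r4$total, 7)
  expect_equal(r4$t_stoch, 0)

  # threshold state 2: deterministic part equals the amount solver
  m <- 3
  r2 <- residence_time(2, conc, m, d)
  expect_equal(r2$t_det,
               amount_crossing_time(1, d$rates[2, "kse"], d$rates[2, "kde"],
                                    m, d$gamma, d$thresholds[["theta_e"]],
                                    "up"))
  expect_equal(r2$total, r2$t_det + r2$t_stoch)

  # threshold noise factors shift the effective threshold
  r2b <- residence_time(2, conc, m, d, theta_factors = c(1.1, 1, 1, 1))
  expect_gt(r2b$t_det, r2$t_det)
})

test_that("a simulated cycle is ordered, continuous and respects the S floor", {
  set.seed(5)
  h <- simulate_cycle(cfg)
  expect_s3_class(h, "cell_cycle")
  # states visited in order: exit ages nondecreasing
  expect_true(all(diff(c(0, h$a_exit)) >= 0))
  # S phase alone guarantees a 7 h cycle floor
  expect_gte(h$a9, 7)
  expect_gte(h$a_exit[4] - h$a_exit[3], 7)
  # concentrations continuous: recomputing each state's closed form from
  # its entry value reproduces the stored exit value
  rts <- cfg$rates
  for (n in 1:9) {
    dt <- h$a_exit[n] - c(0, h$a_exit)[n]
    for (spec in list(c("cyca", "ksa", "kda"), c("cycb", "ksb", "kdb"),
                      c("cyce", "kse", "kde"))) {
      expect_equal(
        unname(cyclin_at(h$conc[n, spec[1]], rts[n, spec[2]],
                         rts[n, spec[3]], dt)),
        unname(h$conc[n + 1, spec[1]]))
    }
  }
  # mass at division follows exponential growth over the full cycle
  expect_equal(h$m_div, mass_at(h$m0, cfg$gamma, h$a9))
})

test_that("with all stochasticity disabled the cycle is seed-independent", {
  d <- hc_det_config()
  set.seed(1); h1 <- simulate_cycle(d)
  set.seed(999); h2 <- simulate_cycle(d)
  expect_identical(h1, h2)
  set.seed(1); l1 <- simulate_lineage(3, 0, d)
  set.seed(999); l2 <- simulate_lineage(3, 0, d)
  expect_identical(l1, l2)
})

test_that("division conserves mass and reproduces the asymmetry SD", {
  set.seed(3)
  h <- simulate_cycle(cfg)
  d0 <- divide(h, deterministic_config(cfg))
  expect_equal(d0$delta, 0.5)
  expect_equal(d0$daughter_mass, h$m_div / 2)

  dd <- replicate(2e4, divide(h, cfg)$delta)
  expect_equal(mean(dd), 0.5, tolerance = 1e-3)
  expect_equal(sd(dd), 0.0167, tolerance = 0.03)
  # the two daughters always partition the mother exactly
  d1 <- divide(h, cfg)
  expect_equal(d1$daughter_mass + d1$other_mass, h$m_div)
})

test_that("lineage bookkeeping, inheritance and initial conditions hold", {
  l <- simulate_lineage(6, 2, cfg, seed = 8)
  expect_equal(nrow(l), 4)
  single <- simulate_lineage(1, 0, cfg, seed = 8)
  expect_equal(nrow(single), 1)
  expect_equal(single$t0, 0)
  expect_equal(single$m0, 3)
  expect_equal(c(single$cyca0, single$cycb0, single$cyce0), c(1, 1, 1))
  # daughters inherit the mother's division-time concentrations and a
  # delta fraction of her mass; birth times accumulate
  l2 <- simulate_lineage(2, 0, cfg, seed = 8)
  expect_equal(l2$t0[2], l2$a9[1])
  expect_equal(l2$cyca0[2], l2$cyca9[1])
  expect_true(isTRUE(all.equal(l2$m0[2], l2$delta[1] * l2$m_div[1])) ||
              isTRUE(all.equal(l2$m0[2], (1 - l2$delta[1]) * l2$m_div[1])))
})

test_that("size control keeps birth mass stationary across generations", {
  l <- simulate_lineage(5000, 1000, cfg, seed = 21)
  # balanced growth: mean cycle length matches the mass doubling time
  expect_equal(mean(l$a9), log(2) / cfg$gamma, tolerance = 0.02)
  # no practically meaningful trend: the fitted drift over the whole
  # series stays below 2% of the mean birth mass (successive birth
  # masses are mother-daughter correlated, so i.i.d. p-values would
  # overstate significance)
  slope <- coef(lm(m0 ~ cell, data = l))[["cell"]]
  expect_lt(abs(slope) * nrow(l), 0.02 * mean(l$m0))
  # thinned consecutive blocks come from the same birth-size
  # distribution (thinning every 5th cell breaks the lineage
  # autocorrelation)
  idx <- seq(1, nrow(l), by = 5)
  half <- floor(length(idx) / 2)
  ks <- suppressWarnings(ks.test(l$m0[idx[1:half]],
                                 l$m0[idx[(half + 1):(2 * half)]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("linear growth mode runs and books mass accordingly", {
  lin <- model_config(growth = "linear")
  set.seed(2)
  h <- simulate_cycle(lin)
  expect_equal(h$m_div, h$m0 * (1 + lin$gamma * h$a9))
  expect_gte(h$a9, 7)
})
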