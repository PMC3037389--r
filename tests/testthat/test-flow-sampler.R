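# Flow sampler: age distribution, state lookup, DNA/cyclin read-out,
# instrument noise.

cfg <- model_config()

test_that("cycle-fraction transform matches the asynchronous age density", {
  expect_equal(phase_from_uniform(0), 0)
  expect_equal(phase_from_uniform(1 - 1e-12), 1, tolerance = 1e-11)
  expect_equal(phase_from_uniform(0.5), -log2(0.75))
  expect_error(phase_from_uniform(1), "r must")

  set.seed(31)
  phi <- sample_phase(2e5)
  expect_true(all(phi >= 0 & phi < 1))
  # newborns are twice as dense as dividing cells
  ratio <- sum(phi < 0.01) / sum(phi >= 0.99)
  expect_equal(ratio, 2, tolerance = 0.1)
  # full-distribution check against the analytic CDF 2*(1 - 2^-phi)
  ks <- suppressWarnings(ks.test(phi, function(q) 2 * (1 - 2^(-q))))
  expect_gt(ks$p.value, 0.01)
})

test_that("state lookup uses half-open residence intervals", {
  # stochastic history: the G1a wait is positive, so age 0 is state 1
  hs <- simulate_lineage(1, 0, cfg, seed = 30)
  expect_equal(locate_state(hs, 0), 1L)
  expect_equal(locate_state(hs, hs$a9 - 1e-9), 9L)
  # a boundary age belongs to the later state: exit of G1b-late is S entry
  expect_equal(locate_state(hs, hs$a3), 4L)
  expect_equal(locate_state(hs, hs$a1), 2L)
  # in the deterministic fixture state 1 has zero residence, so a
  # newborn is already past it
  h <- hc_det_history()
  expect_equal(locate_state(h, 0), 2L)
  expect_error(locate_state(h, h$a9), "age")
  expect_error(locate_state(h, -0.1), "age")
})

test_that("cyclin read-out at arbitrary ages is exact and continuous", {
  h <- hc_det_history()
  d <- hc_det_config()
  expect_equal(cyclin_at_age(h, 0, "A", d), h$cyca0)
  expect_equal(cyclin_at_age(h, h$a3, "A", d), h$cyca3)
  expect_equal(cyclin_at_age(h, h$a5, "B", d), h$cycb5)
  # approaching a boundary from below converges to the stored value
  expect_equal(cyclin_at_age(h, h$a4 - 1e-10, "E", d), h$cyce4,
               tolerance = 1e-6)
  # mid-state value against the numerical ODE oracle
  mid <- (h$a3 + h$a4) / 2
  expect_equal(cyclin_at_age(h, mid, "A", d),
               ode_cyclin(h$cyca3, unname(d$rates[4, "ksa"]),
                          unname(d$rates[4, "kda"]), mid - h$a3),
               tolerance = 1e-8)
})

test_that("DNA content is 1 in G1, interpolates through S, and 2 after", {
  h <- hc_det_history()
  expect_equal(dna_at_age(h, h$a3 / 2), 1)
  expect_equal(dna_at_age(h, (h$a3 + h$a4) / 2), 1.5)
  expect_equal(dna_at_age(h, (h$a4 + h$a9) / 2), 2)
  ages <- seq(0, h$a9 - 1e-6, length.out = 200)
  dna <- dna_at_age(h[rep(1, 200), ], ages)
  expect_true(all(dna >= 1 & dna <= 2))
  expect_true(all(diff(dna) >= 0))
})

test_that("instrument noise is multiplicative with per-channel SDs", {
  h <- simulate_lineage(2500, 500, cfg, seed = 14)
  ev <- simulate_flow_sample(h, cfg, seed = 15)
  expect_equal(nrow(ev), nrow(h))
  expect_equal(sd(ev$dna_meas / ev$dna_true), cfg$noise_dna,
               tolerance = 0.1)
  expect_equal(sd(ev$cyca_meas / ev$cyca_true), cfg$noise_cyclin,
               tolerance = 0.05)
  expect_equal(sd(ev$cycb_meas / ev$cycb_true), cfg$noise_cyclin,
               tolerance = 0.05)
  # noise factors are independent across channels
  expect_lt(abs(cor(ev$dna_meas / ev$dna_true,
                    ev$cyca_meas / ev$cyca_true)), 0.05)

  # sigma = 0 reproduces the true values exactly
  quiet <- model_config(noise_dna = 0, noise_cyclin = 0)
  ev0 <- simulate_flow_sample(h, quiet, seed = 16)
  expect_identical(ev0$dna_meas, ev0$dna_true)
  expect_identical(ev0$cyca_meas, ev0$cyca_true)
})

test_that("events carry consistent state labels, DNA bookkeeping and mass", {
  h <- simulate_lineage(2500, 500, cfg, seed = 17)
  ev <- simulate_flow_sample(h, cfg, seed = 18)
  # phase label agrees with the located state
  lab <- c("G0/G1", "S", "G2/M")[ifelse(ev$state <= 3, 1,
                                        ifelse(ev$state == 4, 2, 3))]
  expect_identical(ev$phase, lab)
  expect_true(all(ev$dna_meas > 0))
  # fraction with replicated DNA equals fraction of ages past S exit
  expect_equal(mean(ev$dna_true == 2), mean(ev$age_h >= h$a4))
  # mass is read out noise-free at the sampled age
  expect_equal(ev$mass, mass_at(h$m0, cfg$gamma, ev$age_h))
  # resampling mode draws the requested number of events
  ev2 <- simulate_flow_sample(h[1:100, ], cfg, seed = 19, n_events = 500)
  expect_equal(nrow(ev2), 500)
})

test_that("the cyclin A/B trajectory closes on itself over the cycle", {
  h <- simulate_lineage(4500, 500, cfg, seed = 20)
  ev <- simulate_flow_sample(h, cfg, seed = 21)
  bins <- cut(ev$phi, seq(0, 1, 0.01), include.lowest = TRUE)
  mA <- tapply(ev$cyca_true, bins, mean)
  mB <- tapply(ev$cycb_true, bins, mean)
  # first and last phi-bin means nearly coincide relative to the loop size
  gapA <- abs(mA[1] - mA[100]) / diff(range(mA))
  gapB <- abs(mB[1] - mB[100]) / diff(range(mB))
  expect_lt(gapA, 0.05)
  expect_lt(gapB, 0.05)
})

test_that("a fully deterministic sample lies on the limit cycle exactly", {
  d <- hc_det_config()
  h <- simulate_lineage(60, 50, d)
  ev <- simulate_flow_sample(h, d, seed = 22)
  # past burn-in every history is the same converged cycle, so each
  # event must reproduce that single trajectory evaluated at its phase
  ref <- h[1, ]
  for (k in seq_len(nrow(ev))) {
    expect_equal(ev$cyca_true[k],
                 cyclin_at_age(ref, ev$age_h[k], "A", d) *
                   mass_at(ref$m0, d$gamma, ev$age_h[k]))
  }
  expect_identical(ev$cyca_meas, ev$cyca_true)
})
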