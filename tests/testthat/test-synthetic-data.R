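test_that("trajectory follows the ramp-and-geometric-decay law", {
  # retention 1 preserves the induced level through every reversal gen
  s1 <- scenario_spec(baseline_omega = 0.3, induced_omega = 0.9,
                      retention = 1, n_induction_generations = 3,
                      n_reversal_generations = 4)
  tr1 <- build_trajectory(s1)
  expect_equal(tr1$omega_true[tr1$phase == "reversal"], rep(0.9, 4))
  # retention 0 is immediate loss
  s0 <- scenario_spec(baseline_omega = 0.3, induced_omega = 0.9,
                      retention = 0)
  tr0 <- build_trajectory(s0)
  expect_equal(tr0$omega_true[tr0$phase == "reversal"], rep(0.3, 5))
  # stated arithmetic: baseline .3, induced .9, retention .5
  s5 <- scenario_spec(baseline_omega = 0.3, induced_omega = 0.9,
                      retention = 0.5, n_reversal_generations = 3)
  tr5 <- build_trajectory(s5)
  rev <- tr5[tr5$phase == "reversal", ]
  expect_equal(rev$omega_true, c(0.6, 0.45, 0.375))
  expect_equal(rev$label, c("F5R1", "F5R2", "F5R3"))
})

test_that("trajectory endpoints: immediate induction and baseline limit", {
  s <- scenario_spec(induction_lag = 0)
  tr <- build_trajectory(s)
  expect_equal(tr$omega_true[1], s$induced_omega)
  # limit of the geometric decay is the baseline for retention < 1
  s2 <- scenario_spec(retention = 0.6, n_reversal_generations = 60)
  tr2 <- build_trajectory(s2)
  expect_equal(tail(tr2$omega_true, 1), s2$baseline_omega, tolerance = 1e-8)
  # linear ramp reaches the induced level after induction_lag generations
  sl <- scenario_spec(baseline_omega = 0.3, induced_omega = 0.9,
                      induction_lag = 2, n_induction_generations = 4)
  trl <- build_trajectory(sl)
  expect_equal(trl$omega_true[trl$phase == "induction"],
               c(0.5, 0.7, 0.9, 0.9))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(scenario_spec(retention = 1.2), "retention")
  expect_error(scenario_spec(retention = -0.1), "retention")
  expect_error(scenario_spec(induced_omega = 1), "strictly inside")
  expect_error(scenario_spec(kappa_true = 2), "exceed 2")
  s <- scenario_spec()
  expect_error(
    simulate_counts(data.frame(label = "F1", omega_true = 0.5,
                               kappa_true = 1.5), s, seed = 1),
    "kappa_true must exceed 2")
})

test_that("simulation is seed-deterministic and prefix-stable", {
  s <- scenario_spec(n_induction_generations = 3,
                     n_reversal_generations = 2)
  tr <- build_trajectory(s)
  t1 <- simulate_counts(tr, s, seed = 99)
  t2 <- simulate_counts(tr, s, seed = 99)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_counts(tr, s, seed = 100)))
  # appending generations leaves earlier generations' counts unchanged
  s_long <- scenario_spec(n_induction_generations = 3,
                          n_reversal_generations = 4)
  t_long <- simulate_counts(build_trajectory(s_long), s_long, seed = 99)
  expect_identical(t1, t_long[seq_len(nrow(t1)), ])
})

test_that("all simulated counts respect 0 <= n_eu <= n_animals", {
  set.seed(5)
  for (i in 1:15) {
    s <- scenario_spec(
      baseline_omega = runif(1, 0.05, 0.6),
      induced_omega = runif(1, 0.7, 0.99),
      kappa_true = runif(1, 2.5, 80),
      retention = runif(1),
      n_induction_generations = sample(1:4, 1),
      n_reversal_generations = sample(0:4, 1),
      plates_per_generation = sample(1:15, 1),
      animals_per_plate = sample(c(1, 5, 20, 60), 1),
      induction_lag = sample(0:3, 1)
    )
    tab <- simulate_counts(build_trajectory(s), s, seed = 1000 + i)
    expect_true(all(tab$n_eu >= 0 & tab$n_eu <= tab$n_animals))
    expect_equal(nrow(tab),
                 (s$n_induction_generations + s$n_reversal_generations) *
                   s$plates_per_generation)
  }
})

test_that("plate fractions converge to the Beta mean of the truth", {
  # omega = .3, kappa = 10: Beta mean = (0.3*8+1)/10 = 0.34
  s <- scenario_spec(plates_per_generation = 5000, animals_per_plate = 20)
  truth <- data.frame(label = "F1", omega_true = 0.3, kappa_true = 10)
  tab <- simulate_counts(truth, s, seed = 7)
  expect_equal(mean(tab$n_eu / tab$n_animals), 0.34, tolerance = 0.02)
  # and the simulated theta moments match Beta(a, b) at large plate size
  s2 <- scenario_spec(plates_per_generation = 4000,
                      animals_per_plate = 2000)
  truth2 <- data.frame(label = "F1", omega_true = 0.6, kappa_true = 12)
  tab2 <- simulate_counts(truth2, s2, seed = 8)
  th <- tab2$n_eu / tab2$n_animals
  a <- 0.6 * 10 + 1
  b <- 0.4 * 10 + 1
  expect_equal(mean(th), a / (a + b), tolerance = 0.01)
  expect_equal(var(th), a * b / ((a + b)^2 * (a + b + 1)),
               tolerance = 0.05)
})

test_that("near-complete induction yields near-complete Eu fractions", {
  # Monte-Carlo oracle: grand mean Eu fraction over many seeds at
  # omega = .995, kappa = 50 stays at or above 0.97
  s <- scenario_spec(plates_per_generation = 10, animals_per_plate = 20)
  truth <- data.frame(label = "F1", omega_true = 0.995, kappa_true = 50)
  fr <- vapply(1:1000, function(i) {
    tab <- simulate_counts(truth, s, seed = i)
    mean(tab$n_eu / tab$n_animals)
  }, numeric(1))
  expect_gte(mean(fr), 0.97)
})

test_that("prior predictive draws match the hyperprior", {
  pr <- hyper_prior(alpha = 1, beta = 1)
  sims <- lapply(1:2000, function(i) {
    simulate_prior_predictive(pr, plates = 2, animals = 5, seed = i)
  })
  omega <- vapply(sims, function(x) x$params$omega, numeric(1))
  kappa <- vapply(sims, function(x) x$params$kappa, numeric(1))
  # omega ~ Beta(1,1) is uniform
  expect_gt(stats::ks.test(omega, punif)$p.value, 0.001)
  # kappa - offset ~ Gamma(3, 1), mean 3
  expect_gt(min(kappa), pr$kappa_offset)
  expect_equal(mean(kappa - pr$kappa_offset), 3, tolerance = 0.15)
  # counts respect bounds
  expect_true(all(vapply(sims, function(x) {
    all(x$table$n_eu >= 0 & x$table$n_eu <= x$table$n_animals)
  }, logical(1))))
})
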