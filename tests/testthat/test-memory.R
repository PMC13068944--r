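printed_500nM <- data.frame(
  condition_id = "b12_500nM",
  generation = c("F5R1", "F5R2", "F5R3"),
  mean_theta = c(0.93, 0.68, 0.47),
  hdi_lower = c(0.841, 0.520, 0.305),
  hdi_upper = c(0.987, 0.842, 0.637),
  stringsAsFactors = FALSE
)

test_that("baseline band: configured passthrough and input validation", {
  b <- baseline_band(bounds = c(0.2, 0.45))
  expect_equal(c(b$lower, b$upper), c(0.2, 0.45))
  expect_equal(b$source, "configured")
  expect_error(baseline_band(bounds = c(0.5, 0.2)), "lower <= upper")
  expect_error(baseline_band(), "either explicit bounds or")
  expect_error(baseline_band(draws = list()), "no baseline fits")
})

test_that("fitted baseline band covers the generating baseline omega", {
  # coverage property over simulated baseline groups at omega_true = .3
  hits <- 0L
  for (i in 1:100) {
    truth <- data.frame(label = "F1", omega_true = 0.3, kappa_true = 10)
    s <- scenario_spec()
    tab <- simulate_counts(truth, s, seed = 3000 + i)
    g <- make_group(tab$n_eu, n = tab$n_animals)
    fit <- suppressWarnings(sample_posterior(
      g, hyper_prior(),
      sampler_settings(n_chains = 2L, n_warmup = 500L, n_draws = 2500L,
                       target_ess = 300, seed = 4000 + i)))
    b <- baseline_band(draws = fit)
    expect_equal(b$source, "fitted")
    if (b$lower <= 0.3 && b$upper >= 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 88L)
})

test_that("elevation rule: HDI lower strictly above the band upper", {
  band <- baseline_band(bounds = c(0.2, 0.5))
  expect_true(classify_generation(printed_500nM[1, ], band))   # [.841,.987]
  expect_false(classify_generation(printed_500nM[3, ], band))  # [.305,.637]
  tie <- data.frame(hdi_lower = 0.5, hdi_upper = 0.9)
  expect_false(classify_generation(tie, band))                 # strict tie
})

test_that("memory duration counts consecutive elevated generations", {
  band <- baseline_band(bounds = c(0.2, 0.5))
  # the reported reversal sequence of the 500 nM condition lasts 2 gens
  expect_equal(memory_duration(printed_500nM, band), 2L)
  # all below band
  low <- transform(printed_500nM, hdi_lower = c(0.1, 0.2, 0.15))
  expect_equal(memory_duration(low, band), 0L)
  # a rebound after a lapse does not extend memory
  bounce <- transform(printed_500nM, hdi_lower = c(0.8, 0.3, 0.9))
  expect_equal(memory_duration(bounce, band), 1L)
  # rows arrive unordered but carry labels
  expect_equal(memory_duration(printed_500nM[c(3, 1, 2), ], band), 2L)
  expect_warning(d0 <- memory_duration(printed_500nM[0, ], band),
                 "no reversal")
  expect_equal(d0, 0L)
})

test_that("duration maps to the field's memory categories", {
  expect_equal(categorize_memory(0), "none")
  expect_equal(categorize_memory(1), "intergenerational")
  expect_equal(categorize_memory(2), "intergenerational")
  expect_equal(categorize_memory(3), "transgenerational")
  expect_equal(categorize_memory(7), "transgenerational")
  expect_error(categorize_memory(-1), "non-negative")
})

test_that("raising the band upper bound never increases duration", {
  set.seed(101)
  for (i in 1:30) {
    m <- sample(1:6, 1)
    lo <- runif(m, 0, 0.9)
    d <- data.frame(condition_id = "c",
                    generation = sprintf("F5R%d", 1:m),
                    hdi_lower = lo, hdi_upper = lo + runif(m, 0, 0.1))
    u <- sort(runif(2, 0, 1))
    d1 <- memory_duration(d, baseline_band(bounds = c(0, u[1])))
    d2 <- memory_duration(d, baseline_band(bounds = c(0, u[2])))
    expect_lte(d2, d1)
  }
})

test_that("classify_memory produces one call per condition", {
  band <- baseline_band(bounds = c(0.2, 0.5))
  other <- data.frame(condition_id = "b12_1500nM",
                      generation = c("F5R1", "F5R2", "F5R3"),
                      mean_theta = c(0.95, 0.9, 0.85),
                      hdi_lower = c(0.9, 0.82, 0.74),
                      hdi_upper = c(0.99, 0.97, 0.95),
                      stringsAsFactors = FALSE)
  induction <- data.frame(condition_id = "b12_500nM", generation = "F1",
                          mean_theta = 0.95, hdi_lower = 0.878,
                          hdi_upper = 0.994, stringsAsFactors = FALSE)
  calls <- classify_memory(rbind(printed_500nM, other, induction), band)
  calls <- calls[order(calls$condition_id), ]
  expect_equal(calls$condition_id, c("b12_1500nM", "b12_500nM"))
  expect_equal(calls$duration, c(3L, 2L))
  expect_equal(calls$category, c("transgenerational", "intergenerational"))
  expect_equal(calls$flags, c("1|1|1", "1|1|0"))
})
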