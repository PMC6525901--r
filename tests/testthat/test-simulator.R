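test_that("Johnson SB draws live in the support and match integrated moments", {
  spec <- arrival_spec("johnson_sb", c(0.025, 0.803, -8.16, 85.98))
  set.seed(9)
  x <- sample_johnson_sb(1e6, spec)
  expect_true(all(x > -8.16 & x < -8.16 + 85.98))
  m1 <- bedalloc:::johnson_sb_moment(spec, 1)
  m2 <- bedalloc:::johnson_sb_moment(spec, 2)
  sdx <- sqrt(m2 - m1^2)
  expect_lt(abs(mean(x) - m1), 3 * sdx / sqrt(length(x)))
  se_var <- sqrt((mean((x - mean(x))^4) - stats::var(x)^2) / length(x))
  expect_lt(abs(stats::var(x) - (m2 - m1^2)), 3 * se_var)
  # parameter validation
  expect_error(arrival_spec("johnson_sb", c(0, -1, 0, 1)), "delta")
  expect_error(arrival_spec("johnson_sb", c(0, 1, 0, -2)), "lambda")
})

test_that("daily arrival counts clamp negatives and round half-up", {
  # uniform spanning negatives: counts must be nonnegative integers with
  # mean matching the clamped closed form
  spec <- arrival_spec("uniform", c(-0.72, 43.75))
  set.seed(4)
  n <- sample_daily_arrivals(1e5, spec)
  expect_true(all(n >= 0))
  expect_type(n, "integer")
  lo <- -0.72; hi <- 43.75
  mean_clamped <- (hi^2 / 2) / (hi - lo)   # E[max(X,0)] for uniform
  expect_lt(abs(mean(n) - mean_clamped), 0.15)
  expect_error(arrival_spec("uniform", c(5, 2)), "hi > lo")
})

test_that("deterministic loads give the closed-form occupancy", {
  cfg <- dept_sim_config(NULL, los_days = 1, admit_prob = 1, beds = 10,
                         horizon_days = 365, seed = 1)
  s <- simulate_department(cfg, arrivals = rep(5L, 365))
  expect_equal(s$discharges, 1825)
  expect_equal(s$bor, 0.5)
  expect_equal(s$queue_end, 0)
  # saturation: demand twice capacity pins BOR at 1 and queues the rest
  s2 <- simulate_department(cfg, arrivals = rep(20L, 365))
  expect_equal(s2$bor, 1)
  expect_equal(s2$discharges, 3650)
  expect_equal(s2$queue_end, 10 * 365)
})

test_that("bed-days are conserved and BOR never exceeds 1", {
  cfg <- dept_sim_config(NULL, los_days = 7, admit_prob = 1, beds = 25,
                         horizon_days = 60, seed = 1)
  admitted <- c(rep(3L, 30), rep(0L, 30))
  s <- simulate_department(cfg, admitted = admitted)
  # under-capacity: every admission starts service on arrival day, so
  # occupied bed-days = sum over stays of their in-horizon service days
  starts <- rep(seq_len(60), admitted)
  expect_equal(s$occupied_bed_days, sum(pmin(7, 60 - starts + 1)))
  expect_equal(s$discharges, sum(starts + 7 - 1 <= 60))
  expect_lte(s$bor, 1)
  # with arrivals <= beds/los per day the queue never builds up
  expect_equal(s$queue_end, 0)
})

test_that("runs are bit-identical under the same seed", {
  spec <- arrival_spec("johnson_sb", c(0.289, 0.983, -3.34, 35.11))
  cfg <- dept_sim_config(spec, los_days = 9, admit_prob = 0.5, beds = 70,
                         seed = 123)
  expect_identical(simulate_department(cfg), simulate_department(cfg))
  sw1 <- sweep_beds(cfg, c(60, 70, 80), replications = 3)
  sw2 <- sweep_beds(cfg, c(60, 70, 80), replications = 3)
  expect_identical(sw1, sw2)
})

test_that("sweeps under common random numbers are monotone in beds", {
  spec <- arrival_spec("uniform", c(-3.2, 92.36))
  cfg <- dept_sim_config(spec, los_days = 5, admit_prob = 0.3, beds = 114,
                         seed = 21)
  sw <- sweep_beds(cfg, seq(80, 200, by = 20), replications = 4)
  expect_true(all(diff(sw$bor) <= 0))
  expect_true(all(diff(sw$discharges) >= 0))
  # an admit probability of zero empties the system
  cfg0 <- dept_sim_config(spec, los_days = 5, admit_prob = 0, beds = 50,
                          seed = 21)
  sw0 <- sweep_beds(cfg0, c(20, 40), replications = 2)
  expect_equal(sw0$discharges, c(0, 0))
  expect_equal(sw0$bor, c(0, 0))
})

test_that("validation errors are relative differences in percent", {
  v <- validate_simulation(list(discharges = 5984, bor = 0.695), 5478, 0.752)
  expect_equal(unname(round(v["discharges"], 1)), 9.2)
  expect_equal(unname(round(v["bor"], 1)), 7.6)
  expect_equal(unname(validate_simulation(list(discharges = 100, bor = 0.5),
                                          100, 0.5)),
               c(0, 0))
  expect_error(validate_simulation(list(discharges = 1, bor = 0.5), 0, 0.5),
               "positive")
})

test_that("sweep tables round-trip through CSV", {
  spec <- arrival_spec("uniform", c(5, 15))
  cfg <- dept_sim_config(spec, los_days = 3, admit_prob = 0.8, beds = 40,
                         seed = 3)
  sw <- sweep_beds(cfg, c(30, 40, 50), replications = 2)
  f <- tempfile(fileext = ".csv")
  write_sweep(sw, f)
  back <- read_sweep(f)
  expect_equal(back$beds, sw$beds)
  expect_equal(back$bor, round(sw$bor, 6))
  unlink(f)
})
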