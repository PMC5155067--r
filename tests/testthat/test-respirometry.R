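test_that("CER hand-arithmetic oracle and scaling laws", {
  tr <- resp_trace(time = c(0, 1), co2_fraction = c(0.01, 0.01),
                   flow = c(1, 1), dry_mass = 10)
  cer <- compute_cer(tr, molar_volume = 24)$cer
  expect_equal(cer, rep(1 * 60 * 0.01 * (44.01 / 24) * 1000 / 10, 2))
  expect_equal(round(cer[1], 1), 110.0)
  # zero flow gives zero CER; doubling dry mass halves CER
  tr0 <- resp_trace(c(0, 1), c(0.01, 0.01), c(0, 0), dry_mass = 10)
  expect_equal(compute_cer(tr0)$cer, c(0, 0))
  tr2 <- resp_trace(c(0, 1), c(0.01, 0.01), c(1, 1), dry_mass = 20)
  expect_equal(compute_cer(tr2)$cer, cer / 2)
})

test_that("trace validation rejects impossible inputs", {
  expect_error(resp_trace(c(0, 0), c(0, 0), c(1, 1), 10), "strictly increasing")
  expect_error(resp_trace(c(0, 1), c(0, 1.2), c(1, 1), 10), "\\[0, 1\\]")
  expect_error(resp_trace(c(0, 1), c(0, 0.1), c(-1, 1), 10), "non-negative")
  expect_error(resp_trace(c(0, 1), c(0, 0.1), c(1, 1), -5), "positive")
})

test_that("cCER closed forms: constant and linear CER", {
  t <- seq(0, 10, by = 0.5)
  expect_equal(integrate_ccer(t, rep(3, length(t))), 30)
  expect_equal(integrate_ccer(t, 2 * t / 10), 10)  # linear 0 -> 2 over 10 h
  expect_warning(z <- integrate_ccer(0, 5), "fewer than two")
  expect_equal(z, 0)
})

test_that("cCER is additive over segments and monotone when CER >= 0", {
  set.seed(53)
  t <- sort(runif(40, 0, 100))
  cer <- abs(rnorm(40, 2))
  whole <- integrate_ccer(t, cer)
  expect_equal(integrate_ccer(t[1:20], cer[1:20]) +
                 integrate_ccer(t[20:40], cer[20:40]), whole)
  run <- integrate_ccer(t, cer, cumulative = TRUE)
  expect_true(all(diff(run) >= 0))
  expect_equal(run[length(run)], whole)
})

test_that("two-segment piecewise-constant flow equals hand integration", {
  # flow 1 L/min for 0-10 h then 2 L/min for 10-20 h at constant fraction
  time <- c(seq(0, 10, 0.1), seq(10.1, 20, 0.1))
  flow <- ifelse(time <= 10, 1, 2)
  tr <- resp_trace(time, rep(0.01, length(time)), flow, dry_mass = 10)
  got <- integrate_ccer(tr$time, compute_cer(tr)$cer)
  c1 <- 1 * 60 * 0.01 * (44.01 / 24) * 1000 / 10  # 110.025 mg/g/h per L/min
  # trapezoid spends one 0.1 h panel crossing the step: mean of both levels
  hand <- c1 * 10 + 2 * c1 * 9.9 + (c1 + 2 * c1) / 2 * 0.1
  expect_equal(got, hand, tolerance = 1e-10)
})

test_that("simulated trace recovers its planted cumulative respiration", {
  tr <- simulate_respirometry(total_ccer = 299)
  cer <- compute_cer(tr)
  got <- integrate_ccer(cer$time, cer$cer)
  # fine-grid quadrature of the analytic curve is the oracle
  fine_t <- seq(0, 168, by = 0.01)
  oracle <- pracma::trapz(fine_t, attr(tr, "analytic_cer")(fine_t))
  expect_equal(got, oracle, tolerance = 0.01)
  expect_equal(oracle, 299, tolerance = 0.005)
})

test_that("trapezoid error shrinks about quadratically with sampling density", {
  exact <- 299
  err <- vapply(c(4, 2, 1), function(h) {
    tr <- simulate_respirometry(time = seq(0, 168, by = h), total_ccer = exact)
    cer <- compute_cer(tr)
    abs(integrate_ccer(cer$time, cer$cer) - exact)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[2], 3)  # halving h cuts the error ~4x
})

test_that("respirometry traces round-trip through TSV with their dry mass", {
  tr <- simulate_respirometry(time = seq(0, 24, 2), dry_mass = 37.5,
                              total_ccer = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resp_trace(tr, path)
  back <- read_resp_trace(path)
  expect_equal(attr(back, "dry_mass_g"), 37.5)
  expect_equal(back$co2_fraction, tr$co2_fraction, tolerance = 1e-12)
})

test_that("baseline CO2 subtraction lowers CER and floors at zero", {
  tr <- resp_trace(c(0, 1), c(0.010, 0.002), c(1, 1), 10,
                   co2_baseline = 0.004)
  cer <- compute_cer(tr)$cer
  plain <- compute_cer(resp_trace(c(0, 1), c(0.006, 0), c(1, 1), 10))$cer
  expect_equal(cer, plain)
})

test_that("sensor noise is reproducible under a fixed seed", {
  a <- simulate_respirometry(noise_sd = 1e-4, seed = 99)
  b <- simulate_respirometry(noise_sd = 1e-4, seed = 99)
  expect_equal(a, b)
})
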